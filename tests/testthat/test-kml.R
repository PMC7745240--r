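test_that("Lloyd runs recover separated duplicate groups exactly", {
  X <- rbind(matrix(0, 5, 3), matrix(10, 5, 3))
  init <- rep(c(1L, 2L), 5)  # deliberately scrambled start
  fit <- suppressWarnings(kmeans_single(X, 2, init))
  expect_equal(fit$objective, 0)
  expect_equal(unname(sort(fit$centroids[, 1])), c(0, 10))
  expect_length(unique(fit$assignments[1:5]), 1)
  expect_length(unique(fit$assignments[6:10]), 1)

  # k = n puts every point in its own cluster: zero objective
  Y <- matrix(rnorm(15), 5, 3)
  fitn <- suppressWarnings(kmeans_single(Y, 5, 1:5))
  expect_equal(fitn$objective, 0)

  expect_error(kmeans_single(Y, 6, rep(1, 5)), class = "trajresp_value_error")
  expect_error(kmeans_single(Y, 3, c(1L, 1L, 1L, 2L, 2L)),
               class = "trajresp_value_error")
})

test_that("engine matches the brute-force Lloyd oracle step for step", {
  for (s in 1:30) {
    inst <- random_instance(s)
    fit <- kmeans_single(inst$X, inst$k, inst$init)
    ora <- oracle_lloyd(inst$X, inst$k, inst$init)
    expect_equal(fit$objective, ora$objective, tolerance = 1e-9)
    expect_equal(fit$assignments, ora$assignments)
  }
})

test_that("the objective never rises from its initial partition", {
  for (s in 1:20) {
    inst <- random_instance(s + 100)
    cent0 <- rowsum(inst$X, factor(inst$init, levels = seq_len(inst$k))) /
      as.vector(table(factor(inst$init, levels = seq_len(inst$k))))
    obj0 <- sum((inst$X - cent0[inst$init, ])^2)
    fit <- kmeans_single(inst$X, inst$k, inst$init)
    expect_lte(fit$objective, obj0 + 1e-9)
    # objective is recomputable from centroids + assignments
    recomputed <- sum((inst$X - fit$centroids[fit$assignments, ])^2)
    expect_equal(fit$objective, recomputed, tolerance = 1e-9)
  }
})

test_that("multi-restart fit keeps the best run and is deterministic", {
  two <- make_two_class_traj(n = 120, sd = 8, seed = 3)
  fit <- kml_fit(two$traj, k = 3, n_restarts = 10, seed = 5)
  expect_length(fit$restart_objectives, 10)
  expect_equal(fit$objective, min(fit$restart_objectives))
  expect_true(all(fit$objective <= fit$restart_objectives + 1e-12))

  fit2 <- kml_fit(two$traj, k = 3, n_restarts = 10, seed = 5)
  expect_equal(fit$assignments, fit2$assignments)
  expect_equal(fit$objective, fit2$objective)
})

test_that("well-separated two-class data is recovered up to label switching", {
  for (s in 1:10) {
    two <- make_two_class_traj(n = 150, sd = 2, seed = s)  # gap >> 10 * sd
    fit <- kml_fit(two$traj, k = 2, n_restarts = 10, seed = s)
    labs <- label_trajectories(fit)
    got <- unname(labs[as.character(fit$assignments)])
    expect_equal(got, two$latent)
  }
})

test_that("Calinski-Harabasz matches hand computation and the oracle", {
  # 1-D points 0,1,2 vs 10,11,12: grand mean 6, tr(B) = 150, tr(W) = 4
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  expect_equal(calinski_harabasz(x, c(1, 1, 1, 2, 2, 2)), 150)

  for (s in 1:25) {
    inst <- random_instance(s + 300)
    assign <- withr::with_seed(s, {
      repeat {
        a <- sample.int(inst$k, nrow(inst$X), replace = TRUE)
        if (length(unique(a)) == inst$k) break
      }
      a
    })
    expect_equal(calinski_harabasz(inst$X, assign),
                 oracle_ch(inst$X, assign), tolerance = 1e-9)
  }

  # scale invariance: CH is a ratio of scatters
  inst <- random_instance(7)
  a <- rep_len(seq_len(inst$k), nrow(inst$X))
  expect_equal(calinski_harabasz(inst$X * 3.7, a),
               calinski_harabasz(inst$X, a), tolerance = 1e-9)

  # zero within-scatter partitions are flagged as infinite
  dup <- rbind(matrix(0, 2, 2), matrix(10, 2, 2))
  expect_warning(ch <- calinski_harabasz(dup, c(1, 1, 2, 2)), "infinite")
  expect_identical(ch, Inf)

  expect_error(calinski_harabasz(x, rep(1, 6)), class = "trajresp_value_error")
})

test_that("CH-based selection recovers the latent cluster count", {
  hits2 <- vapply(1:10, function(s) {
    two <- make_two_class_traj(n = 200, sd = 8, seed = s + 40)
    select_k(two$traj, k_range = 2:6, n_restarts = 10, seed = s)$selected_k == 2
  }, TRUE)
  expect_gte(mean(hits2), 0.9)

  means3 <- list(a = c(10, 15, 20), b = c(35, 45, 55), c = c(60, 75, 90))
  hits3 <- vapply(1:10, function(s) {
    m <- withr::with_seed(s, {
      cl <- sample(names(means3), 200, replace = TRUE)
      t(vapply(cl, function(g) means3[[g]] + rnorm(3, 0, 3), numeric(3)))
    })
    colnames(m) <- paste0("pct_w", c(2, 4, 6))
    select_k(m, k_range = 2:6, n_restarts = 10, seed = s)$selected_k == 3
  }, TRUE)
  expect_gte(mean(hits3), 0.9)

  # two distinct duplicated points: k = 2 with infinite CH
  dup <- rbind(matrix(0, 4, 3), matrix(10, 4, 3))
  sel <- suppressWarnings(select_k(dup, k_range = 2:4, n_restarts = 5, seed = 1))
  expect_equal(sel$selected_k, 2)
  expect_identical(sel$best$ch_index, Inf)
})

test_that("trajectory labels rank clusters by final-week response", {
  two <- make_two_class_traj(n = 100, sd = 4, seed = 2)
  fit <- kml_fit(two$traj, k = 2, n_restarts = 5, seed = 2)
  labs <- label_trajectories(fit)
  hi_cluster <- which.max(fit$centroids[, "pct_w6"])
  expect_equal(unname(labs[as.character(hi_cluster)]), "high")

  # label assignment is invariant to permuting cluster indices
  perm <- c(2L, 1L)
  fitp <- fit
  fitp$centroids <- fit$centroids[perm, , drop = FALSE]
  fitp$assignments <- perm[fit$assignments]
  labsp <- label_trajectories(fitp)
  expect_equal(unname(labsp[as.character(perm[hi_cluster])]), "high")

  # k = 3 is named by rank of the final-week centroid
  m3 <- structure(matrix(c(5, 40, 80, 8, 45, 85, 10, 50, 90), 3),
                  dimnames = list(NULL, c("pct_w2", "pct_w4", "pct_w6")))
  mod3 <- list(k = 3L, centroids = m3, weeks = colnames(m3))
  class(mod3) <- "kml_model"
  expect_equal(unname(label_trajectories(mod3)),
               c("cluster_1", "cluster_2", "cluster_3"))
})

test_that("tidy/glance/augment expose the fitted model as tibbles", {
  two <- make_two_class_traj(n = 80, sd = 5, seed = 14)
  sel <- cluster_trajectories(two$traj, k_range = 2:3, n_restarts = 5, seed = 9)
  td <- generics::tidy(sel$best)
  expect_equal(nrow(td), sel$selected_k)
  expect_equal(sum(td$size), 80)
  gl <- generics::glance(sel$best)
  expect_equal(gl$k, sel$selected_k)
  aug <- generics::augment(sel$best, two$traj)
  expect_equal(nrow(aug), 80)
  expect_true(all(c(".cluster", ".label") %in% names(aug)))
  expect_equal(generics::tidy(sel), sel$criteria)

  p1 <- ggplot2::autoplot(sel)
  p2 <- ggplot2::autoplot(sel$best, data = two$traj)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
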