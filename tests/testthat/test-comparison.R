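# Builds per-patient label/flag vectors realising given 2x2 cell counts.
make_classes <- function(hi_resp, hi_non, lo_resp, lo_non) {
  list(
    labels = c(rep("high", hi_resp + hi_non), rep("low", lo_resp + lo_non)),
    flags = c(rep(TRUE, hi_resp), rep(FALSE, hi_non),
              rep(TRUE, lo_resp), rep(FALSE, lo_non))
  )
}

test_that("threshold classification honours cutoff and boundary rule", {
  expect_true(classify_threshold(73.58))
  expect_false(classify_threshold(31.99))
  expect_true(classify_threshold(50))
  expect_false(classify_threshold(50, strict = TRUE))
  expect_equal(classify_threshold(c(49.9, 50, 50.1)), c(FALSE, TRUE, TRUE))
  expect_error(classify_threshold(NaN), class = "trajresp_value_error")
})

test_that("paired cross-tab counts concordant and discordant patients", {
  cls <- make_classes(1424, 47, 302, 1237)
  ct <- paired_crosstab(cls$labels, cls$flags)
  expect_equal(ct$counts["high", "non_responder"], 47L)
  expect_equal(ct$counts["low", "responder"], 302L)
  expect_equal(discordant_count(ct), 349L)
  expect_equal(sum(ct$counts), 3010L)

  all_hi <- paired_crosstab(rep("high", 12), rep(TRUE, 12))
  expect_equal(as.vector(all_hi$counts), c(12L, 0L, 0L, 0L))
  expect_equal(discordant_count(all_hi), 0L)
  expect_error(paired_crosstab(c("high", "low"), TRUE),
               class = "trajresp_value_error")
})

test_that("composition table puts one count per patient per method", {
  cls <- make_classes(1424, 47, 302, 1237)
  comp <- composition_table(cls$labels, cls$flags)
  expect_equal(unname(comp$counts),
               matrix(c(1471L, 1539L, 1726L, 1284L), 2, byrow = TRUE))
  expect_equal(unname(rowSums(comp$counts)), c(3010, 3010))

  same <- composition_table(c(rep("high", 6), rep("low", 4)),
                            c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_equal(pearson_chi2(same)$statistic, 0)
})

test_that("Pearson chi-squared equals the scatter formula (no correction)", {
  cls <- make_classes(1424, 47, 302, 1237)
  res <- pearson_chi2(composition_table(cls$labels, cls$flags))
  expect_equal(res$statistic, 43.37, tolerance = 0.005)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  expect_equal(pearson_chi2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(pearson_chi2(matrix(c(5, 0, 0, 5), 2))$statistic, 10)

  # random tables vs the textbook sum over cells
  withr::with_seed(5, {
    for (i in 1:50) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(pearson_chi2(tab)$statistic, sum((tab - E)^2 / E),
                   tolerance = 1e-9)
    }
  })
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)),
               class = "trajresp_value_error")
})

test_that("Fisher exact p-values match margin-constrained enumeration", {
  res <- fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))
  expect_equal(res$p_value, 0.00276, tolerance = 1e-3)
  expect_equal(res$p_value,
               oracle_fisher_p(matrix(c(1, 9, 11, 3), 2, byrow = TRUE)),
               tolerance = 1e-9)

  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 6), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "trajresp_value_error")

  withr::with_seed(11, {
    for (i in 1:40) {
      tab <- matrix(rpois(4, 6), 2)
      expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("BH adjustment follows the step-up rule and is idempotent", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))

  withr::with_seed(3, {
    for (i in 1:20) {
      p <- runif(sample(2:15, 1))
      adj <- bh_fdr(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      ord <- order(p)
      expect_equal(adj[ord], sort(adj))          # monotone in rank order
      perm <- sample(length(p))
      expect_equal(bh_fdr(p[perm]), adj[perm])   # order invariance
    }
  })
  # re-adjusting a flat adjusted vector changes nothing
  flat <- bh_fdr(c(0.01, 0.02, 0.03))
  expect_equal(bh_fdr(flat), flat)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "trajresp_value_error")
})

test_that("McNemar companion uses only the discordant cells", {
  cls <- make_classes(1424, 47, 302, 1237)
  ct <- paired_crosstab(cls$labels, cls$flags)
  res <- mcnemar_discordance(ct)
  expect_equal(res$statistic, (47 - 302)^2 / 349, tolerance = 1e-9)
  expect_lt(res$p_value, 0.001)
})

test_that("per-arm breakdown runs omnibus and FDR-adjusted pairwise tests", {
  arms <- rep(trial_arms(), each = 40)
  labels <- rep(c(rep("high", 20), rep("low", 20)), 7)
  flags <- rep(c(rep(TRUE, 22), rep(FALSE, 18)), 7)
  brk <- per_arm_breakdown(arms, labels, flags)
  expect_equal(brk$omnibus$statistic[brk$omnibus$table == "trajectory"], 0)
  expect_equal(nrow(brk$pairwise), choose(7, 2))
  expect_true(all(brk$pairwise$adjusted_p == 1))

  # omnibus invariant under permutation of patient order
  perm <- withr::with_seed(2, sample(length(arms)))
  brk2 <- per_arm_breakdown(arms[perm], labels[perm], flags[perm])
  expect_equal(brk2$omnibus$statistic, brk$omnibus$statistic)

  expect_warning(per_arm_breakdown(arms[arms != "haloperidol"],
                                   labels[arms != "haloperidol"],
                                   flags[arms != "haloperidol"]),
                 "zero patients")
})

test_that("arms with elevated response dominate the smallest adjusted p-values", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      arms <- rep(trial_arms(), each = 400)
      p_resp <- ifelse(arms %in% c("risperidone", "olanzapine"), 0.7, 0.5)
      flags <- runif(length(arms)) < p_resp
      labels <- ifelse(flags, "high", "low")
    })
    brk <- per_arm_breakdown(arms, labels, flags)
    top <- brk$pairwise[order(brk$pairwise$adjusted_p), ][1:3, ]
    all(top$arm1 %in% c("risperidone", "olanzapine") |
          top$arm2 %in% c("risperidone", "olanzapine"))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("episode split stratifies by drug class", {
  arms <- c(rep("haloperidol", 100), rep("olanzapine", 100))
  fe <- rep(c(TRUE, TRUE, FALSE, FALSE), 50)
  labels <- rep(c("high", "low"), each = 100)

  # identical trajectory rates within each episode group give statistic 0
  even <- episode_split(rep(c("high", "low"), 100), arms, fe)
  expect_true(all(even$tests$statistic[!is.na(even$tests$statistic)] == 0))

  sp <- episode_split(labels, arms, fe)
  expect_named(sp$tables, c("typical", "atypical"))
  expect_equal(sum(sp$tables$typical$counts), 100)

  # swapping the stratum definition swaps the reported tables
  swapped <- episode_split(labels, arms, fe, typical_arm_set = "olanzapine")
  expect_equal(swapped$tables$typical$counts[], sp$tables$atypical$counts[],
               ignore_attr = TRUE)

  # a stratum with no patients is skipped with a warning
  expect_warning(episode_split(labels[1:100], arms[1:100], fe[1:100]),
                 "empty")
})

test_that("an episode effect in the typical stratum is detectable", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      n_fe <- 140; n_rel <- 350
      fe <- c(rep(TRUE, n_fe), rep(FALSE, n_rel))
      p_high <- ifelse(fe, 0.6, 0.45)
      labels <- ifelse(runif(n_fe + n_rel) < p_high, "high", "low")
      arms <- rep("perphenazine", n_fe + n_rel)
    })
    sp <- suppressWarnings(episode_split(labels, arms, fe))
    sp$tests$p_value[sp$tests$stratum == "typical"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("compare_responses bundles the full comparison stage", {
  two <- make_two_class_traj(n = 300, sd = 8, seed = 21)
  sel <- cluster_trajectories(two$traj, k_range = 2:3, n_restarts = 10, seed = 4)
  data <- dplyr::left_join(sel$assignments, two$traj, by = "patient_id")
  data$arm <- withr::with_seed(1, assign_arms(300, seed = 77))
  data$first_episode <- withr::with_seed(2, runif(300) < 0.45)

  cmp <- compare_responses(data)
  expect_s3_class(cmp, "response_comparison")
  expect_equal(cmp$n, 300)
  expect_equal(sum(cmp$paired$counts), 300)
  expect_equal(cmp$discordant,
               cmp$paired$counts["high", "non_responder"] +
                 cmp$paired$counts["low", "responder"])
  expect_equal(cmp$pct_high + 100 * mean(data$label == "low"), 100,
               tolerance = 1e-9)
  gl <- generics::glance(cmp)
  expect_equal(gl$discordant, cmp$discordant)
  td <- generics::tidy(cmp)
  expect_true(all(c("composition", "mcnemar_discordance") %in% td$comparison))
  expect_true(any(grepl("^arms_", td$comparison)))
  expect_true(any(grepl("^episode_", td$comparison)))
})
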