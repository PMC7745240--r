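# Independent brute-force oracles, written loop-by-loop on purpose so they
# share no code path with the package implementation.

# Naive Lloyd's algorithm from explicit initial assignments.
oracle_lloyd <- function(X, k, init, max_iter = 200L) {
  assign <- as.integer(init)
  update_centroids <- function(a) {
    cent <- matrix(NA_real_, k, ncol(X))
    for (cl in seq_len(k)) {
      rows <- which(a == cl)
      cent[cl, ] <- colMeans(X[rows, , drop = FALSE])
    }
    cent
  }
  cent <- update_centroids(assign)
  for (it in seq_len(max_iter)) {
    d2 <- matrix(0, nrow(X), k)
    for (i in seq_len(nrow(X))) {
      for (cl in seq_len(k)) d2[i, cl] <- sum((X[i, ] - cent[cl, ])^2)
    }
    newa <- integer(nrow(X))
    for (i in seq_len(nrow(X))) newa[i] <- which.min(d2[i, ])
    repeat {
      sizes <- integer(k)
      for (i in seq_len(nrow(X))) sizes[newa[i]] <- sizes[newa[i]] + 1L
      empties <- which(sizes == 0L)
      if (length(empties) == 0L) break
      own <- numeric(nrow(X))
      for (i in seq_len(nrow(X))) own[i] <- d2[i, newa[i]]
      best <- -Inf; far <- NA_integer_
      for (i in seq_len(nrow(X))) {
        if (sizes[newa[i]] >= 2L && own[i] > best) {
          best <- own[i]; far <- i
        }
      }
      newa[far] <- empties[1]
      d2[far, ] <- 0
    }
    if (all(newa == assign)) break
    assign <- newa
    cent <- update_centroids(assign)
  }
  cent <- update_centroids(assign)
  obj <- 0
  for (i in seq_len(nrow(X))) obj <- obj + sum((X[i, ] - cent[assign[i], ])^2)
  list(assignments = assign, objective = obj)
}

# Calinski-Harabasz via the total-scatter decomposition tr(T) = tr(B) + tr(W),
# a different route from the package's direct between-scatter sum.
oracle_ch <- function(X, assign) {
  labs <- sort(unique(assign))
  k <- length(labs)
  n <- nrow(X)
  grand <- colMeans(X)
  trT <- sum(sweep(X, 2, grand)^2)
  trW <- 0
  for (lab in labs) {
    rows <- which(assign == lab)
    mu <- colMeans(X[rows, , drop = FALSE])
    trW <- trW + sum(sweep(X[rows, , drop = FALSE], 2, mu)^2)
  }
  trB <- trT - trW
  (trB / (k - 1)) / (trW / (n - k))
}

# Two-sided Fisher exact p by full enumeration of tables with fixed margins,
# probability-ordering definition.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) dhyper(x, r1, r2, c1), 0)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written out longhand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  running <- 1
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Two well-separated latent classes on the printed mean curves.
make_two_class_traj <- function(n = 200, sd = 8, seed = 1,
                                means = list(high = c(35.84, 60.51, 73.58),
                                             low = c(15.16, 28.10, 31.99)),
                                prop_high = 0.489) {
  withr::with_seed(seed, {
    cl <- sample(c("high", "low"), n, replace = TRUE,
                 prob = c(prop_high, 1 - prop_high))
    m <- t(vapply(cl, function(g) means[[g]] + rnorm(3, 0, sd), numeric(3)))
    list(
      traj = tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)),
                            pct_w2 = m[, 1], pct_w4 = m[, 2], pct_w6 = m[, 3]),
      latent = cl
    )
  })
}

random_instance <- function(seed, n_max = 50, d = 3, k_max = 4) {
  withr::with_seed(seed, {
    k <- sample(2:k_max, 1)
    n <- sample((k + 2):n_max, 1)
    X <- matrix(runif(n * d, -10, 10), n, d)
    init <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    list(X = X, k = k, init = init)
  })
}
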