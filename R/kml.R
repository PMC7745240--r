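#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

# Coerce a trajectory tibble (patient_id + pct_w* columns) or bare numeric
# matrix into the n x d matrix the engine clusters, keeping patient ids.
traj_matrix <- function(x) {
  if (is.matrix(x)) {
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(list(m = unname(x), ids = ids,
                weeks = colnames(x) %||% paste0("d", seq_len(ncol(x)))))
  }
  cols <- grep("^pct_w", names(x), value = TRUE)
  if (length(cols) == 0L) {
    rlang::abort("expected `pct_w*` trajectory columns or a numeric matrix.",
                 class = "trajresp_value_error")
  }
  m <- as.matrix(x[cols])
  if (anyNA(m)) {
    rlang::abort("trajectories contain missing values; impute before clustering.",
                 class = "trajresp_value_error")
  }
  ids <- if (!is.null(x$patient_id)) as.character(x$patient_id) else as.character(seq_len(nrow(m)))
  list(m = unname(m), ids = ids, weeks = cols)
}

sq_dist_to_centroids <- function(m, centroids) {
  # n x k matrix of squared Euclidean distances
  n <- nrow(m)
  k <- nrow(centroids)
  outer(rowSums(m^2), rep(1, k)) - 2 * m %*% t(centroids) +
    outer(rep(1, n), rowSums(centroids^2))
}

centroids_of <- function(m, assign, k) {
  rowsum(m, factor(assign, levels = seq_len(k))) /
    as.vector(table(factor(assign, levels = seq_len(k))))
}

#' Single k-means run from explicit initial assignments
#'
#' Lloyd's algorithm on the trajectory matrix: starting from the supplied
#' cluster assignments, alternate (a) centroid update as the cluster mean and
#' (b) reassignment of every patient to the nearest centroid in Euclidean
#' distance, until the assignments reach a fixed point or `max_iter` passes.
#' The within-cluster sum of squares never increases across iterations. A
#' cluster emptied by reassignment is re-seeded with the point farthest from
#' its current centroid.
#'
#' @param x Trajectory tibble (from [build_trajectories()]) or numeric matrix,
#'   one row per patient.
#' @param k Number of clusters, `2 <= k <= n`.
#' @param init Integer vector of initial cluster indices in `1..k`, covering
#'   every cluster.
#' @param max_iter Safety cap on Lloyd iterations.
#' @return A `kml_model`: k, `centroids` (k x weeks matrix), `assignments`,
#'   `objective` (total within-cluster sum of squared distances), `ch_index`,
#'   iteration count and convergence flag.
#' @export
kmeans_single <- function(x, k, init, max_iter = 200L) {
  tm <- traj_matrix(x)
  m <- tm$m
  n <- nrow(m)
  if (k < 1 || k > n) {
    rlang::abort("`k` must be between 1 and the number of patients.",
                 class = "trajresp_value_error")
  }
  if (length(init) != n || !all(init %in% seq_len(k)) ||
      length(unique(init)) != k) {
    rlang::abort("`init` must assign every patient to 1..k and cover all k clusters.",
                 class = "trajresp_value_error")
  }
  assign <- as.integer(init)
  converged <- FALSE
  iter <- 0L
  centroids <- centroids_of(m, assign, k)
  repeat {
    iter <- iter + 1L
    d2 <- sq_dist_to_centroids(m, centroids)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster with the farthest point whose own cluster
    # can spare it (size >= 2), so no repair empties another cluster
    repeat {
      sizes <- tabulate(new_assign, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      own <- d2[cbind(seq_len(n), new_assign)]
      eligible <- which(sizes[new_assign] >= 2)
      far <- eligible[which.max(own[eligible])]
      new_assign[far] <- empty[1]
      d2[far, ] <- 0  # pin: don't move the same point twice
    }
    if (all(new_assign == assign)) {
      converged <- TRUE
      break
    }
    assign <- new_assign
    centroids <- centroids_of(m, assign, k)
    if (iter >= max_iter) break
  }
  centroids <- centroids_of(m, assign, k)
  objective <- sum((m - centroids[assign, , drop = FALSE])^2)
  colnames(centroids) <- tm$weeks
  structure(list(
    k = k, centroids = centroids, assignments = assign,
    objective = objective,
    ch_index = if (k >= 2) ch_from_matrix(m, assign, k) else NA_real_,
    iterations = iter, converged = converged,
    patient_ids = tm$ids, weeks = tm$weeks,
    n_restarts = 1L, restart_objectives = objective, seed = NA_integer_
  ), class = "kml_model")
}

ch_from_matrix <- function(m, assign, k) {
  n <- nrow(m)
  grand <- colMeans(m)
  centroids <- centroids_of(m, assign, k)
  sizes <- as.vector(table(factor(assign, levels = seq_len(k))))
  trB <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
  trW <- sum((m - centroids[assign, , drop = FALSE])^2)
  if (trW == 0) {
    rlang::warn("zero within-cluster scatter: Calinski-Harabasz index is infinite.")
    return(Inf)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' Calinski-Harabasz index of a partition
#'
#' Ratio of between-cluster to within-cluster scatter, each normalised by its
#' degrees of freedom: `[tr(B)/(k-1)] / [tr(W)/(n-k)]`, where `tr(B)` sums
#' cluster sizes times squared centroid-to-grand-mean distances and `tr(W)`
#' the squared point-to-own-centroid distances. Larger is better-separated. A
#' perfect partition of duplicated points (`tr(W) = 0`) returns `Inf` with a
#' warning.
#'
#' @param x Trajectory tibble or numeric matrix.
#' @param assignments Cluster index per row; at least 2 non-empty clusters and
#'   `n > k` required.
#' @return Positive scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(x, assignments) {
  m <- traj_matrix(x)$m
  labs <- sort(unique(assignments))
  k <- length(labs)
  n <- nrow(m)
  if (k < 2) {
    rlang::abort("the Calinski-Harabasz index is undefined for fewer than 2 clusters.",
                 class = "trajresp_value_error")
  }
  if (n <= k) {
    rlang::abort("need more points than clusters.", class = "trajresp_value_error")
  }
  ch_from_matrix(m, match(assignments, labs), k)
}

#' Multi-restart longitudinal k-means
#'
#' Runs [kmeans_single()] from `n_restarts` independent uniformly random
#' initial assignments (each patient assigned arbitrarily to one of the k
#' trajectories, re-drawn if a cluster starts empty) and keeps the run with
#' the smallest within-cluster sum of squares; ties go to the earlier
#' restart. Restart r draws its initialisation from a RNG stream seeded
#' `seed + r`, so results are reproducible and restarts independent.
#'
#' @inheritParams kmeans_single
#' @param n_restarts Number of random restarts (default 20).
#' @param seed Integer seed.
#' @return The best `kml_model`, annotated with `n_restarts`,
#'   `restart_objectives` and `seed`.
#' @export
kml_fit <- function(x, k, n_restarts = 20L, seed = 1L, max_iter = 200L) {
  tm <- traj_matrix(x)
  n <- nrow(tm$m)
  if (k > n) rlang::abort("`k` exceeds the number of patients.", class = "trajresp_value_error")
  best <- NULL
  objectives <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- withr::with_seed(seed + r, {
      repeat {
        a <- sample.int(k, n, replace = TRUE)
        if (length(unique(a)) == k) break
      }
      a
    })
    fit <- kmeans_single(tm$m, k, init, max_iter = max_iter)
    objectives[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  best$n_restarts <- n_restarts
  best$restart_objectives <- objectives
  best$seed <- as.integer(seed)
  best$patient_ids <- tm$ids
  best$weeks <- tm$weeks
  colnames(best$centroids) <- tm$weeks
  best
}

#' Select the number of trajectories by the Calinski-Harabasz index
#'
#' Fits [kml_fit()] for every k in `k_range` and selects the k whose best
#' model maximises the Calinski-Harabasz index; exact ties break toward
#' smaller k (parsimony).
#'
#' @inheritParams kml_fit
#' @param k_range Candidate cluster counts (default 2:6).
#' @return A `kml_selection`: `models` (one `kml_model` per k), `selected_k`,
#'   `best` (the selected model), and a `criteria` tibble of k, objective and
#'   CH index.
#' @export
select_k <- function(x, k_range = 2:6, n_restarts = 20L, seed = 1L,
                     max_iter = 200L) {
  tm <- traj_matrix(x)
  if (max(k_range) >= nrow(tm$m)) {
    rlang::abort("max(k_range) must be smaller than the number of patients.",
                 class = "trajresp_value_error")
  }
  k_range <- sort(unique(as.integer(k_range)))
  models <- purrr::map(k_range, function(k) {
    kml_fit(tm$m, k, n_restarts = n_restarts, seed = seed + 1000L * k,
            max_iter = max_iter)
  })
  names(models) <- paste0("k", k_range)
  for (i in seq_along(models)) {
    models[[i]]$patient_ids <- tm$ids
    models[[i]]$weeks <- tm$weeks
    colnames(models[[i]]$centroids) <- tm$weeks
  }
  ch <- vapply(models, function(mod) mod$ch_index, 0)
  sel <- k_range[which.max(ch)]  # first max: ties favour smaller k
  structure(list(
    models = models,
    selected_k = sel,
    best = models[[paste0("k", sel)]],
    criteria = tibble(k = k_range,
                      objective = vapply(models, function(mod) mod$objective, 0),
                      ch_index = ch)
  ), class = "kml_selection")
}

#' Name clusters by their final-week response level
#'
#' For a two-cluster model the cluster with the larger centroid percent
#' reduction at the last clustered week is `"high"` and the other `"low"`,
#' matching the high-/low-trajectory nomenclature; for k > 2, clusters are
#' ranked by final-week centroid and named `"cluster_1"` (lowest) through
#' `"cluster_k"` (highest). Exact final-week ties break by the previous
#' weeks in reverse order, then by cluster index.
#'
#' @param model A fitted `kml_model`.
#' @return Named character vector mapping cluster index to label.
#' @export
label_trajectories <- function(model) {
  cen <- model$centroids
  ord_keys <- lapply(rev(seq_len(ncol(cen))), function(j) cen[, j])
  rank_order <- do.call(order, c(ord_keys, list(seq_len(model$k))))
  labels <- character(model$k)
  if (model$k == 2) {
    labels[rank_order] <- c("low", "high")
  } else {
    labels[rank_order] <- paste0("cluster_", seq_len(model$k))
  }
  stats::setNames(labels, as.character(seq_len(model$k)))
}

#' Cluster preprocessed trajectories end to end
#'
#' Convenience stage wrapper: scans k over `k_range` with [select_k()],
#' labels the selected model's clusters with [label_trajectories()], and
#' returns the per-patient assignment table.
#'
#' @param trajectories Trajectory tibble from [build_trajectories()] /
#'   [preprocess_panss()].
#' @inheritParams select_k
#' @return A `kml_selection` with an extra `assignments` tibble
#'   (`patient_id`, `cluster`, `label`).
#' @export
cluster_trajectories <- function(trajectories, k_range = 2:6, n_restarts = 20L,
                                 seed = 1L) {
  sel <- select_k(trajectories, k_range = k_range, n_restarts = n_restarts,
                  seed = seed)
  labs <- label_trajectories(sel$best)
  sel$assignments <- tibble(
    patient_id = sel$best$patient_ids,
    cluster = sel$best$assignments,
    label = unname(labs[as.character(sel$best$assignments)])
  )
  sel
}

#' @export
print.kml_model <- function(x, ...) {
  cat("<kml_model> k =", x$k, "| objective =", format(x$objective, digits = 6),
      "| CH =", format(x$ch_index, digits = 6), "\n")
  cat("centroids:\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' @export
print.kml_selection <- function(x, ...) {
  cat("<kml_selection> selected k =", x$selected_k, "\n")
  print(x$criteria)
  invisible(x)
}

#' Tidy a fitted trajectory cluster model
#'
#' One row per cluster: index, label, size, and the centroid percent
#' reduction at each clustered week.
#'
#' @param x A `kml_model`.
#' @param ... Unused.
#' @export
tidy.kml_model <- function(x, ...) {
  labs <- label_trajectories(x)
  cen <- as_tibble(x$centroids)
  dplyr::bind_cols(
    tibble(cluster = seq_len(x$k),
           label = unname(labs),
           size = as.vector(table(factor(x$assignments, levels = seq_len(x$k))))),
    cen
  )
}

#' @rdname tidy.kml_model
#' @export
glance.kml_model <- function(x, ...) {
  tibble(k = x$k, objective = x$objective, ch_index = x$ch_index,
         iterations = x$iterations, converged = x$converged,
         n_restarts = x$n_restarts)
}

#' @rdname tidy.kml_model
#' @param data Trajectory tibble the model was fitted to (defaults to ids
#'   stored in the model).
#' @export
augment.kml_model <- function(x, data = NULL, ...) {
  labs <- label_trajectories(x)
  ann <- tibble(patient_id = x$patient_ids,
                .cluster = x$assignments,
                .label = unname(labs[as.character(x$assignments)]))
  if (is.null(data)) return(ann)
  dplyr::left_join(as_tibble(data), ann, by = "patient_id")
}

#' @export
tidy.kml_selection <- function(x, ...) x$criteria

#' @export
glance.kml_selection <- function(x, ...) {
  tibble(selected_k = x$selected_k,
         ch_index = x$best$ch_index,
         objective = x$best$objective)
}

#' Plot the Calinski-Harabasz scan over cluster counts
#'
#' @param object A `kml_selection`.
#' @param ... Unused.
#' @export
autoplot.kml_selection <- function(object, ...) {
  ggplot2::ggplot(object$criteria, ggplot2::aes(x = .data$k, y = .data$ch_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = dplyr::filter(object$criteria,
                                             .data$k == object$selected_k),
                        colour = "red", size = 3) +
    ggplot2::labs(x = "number of trajectories (k)",
                  y = "Calinski-Harabasz index",
                  title = "Cluster-count selection") +
    ggplot2::theme_minimal()
}

#' Plot mean response trajectories per cluster
#'
#' Centroid percent-reduction curves over the clustered weeks, with cluster
#' labels; optionally overlays a sample of individual patient trajectories.
#'
#' @param object A `kml_model`.
#' @param data Optional trajectory tibble for the patient spaghetti layer.
#' @param max_lines Maximum individual trajectories drawn.
#' @param ... Unused.
#' @export
autoplot.kml_model <- function(object, data = NULL, max_lines = 200L, ...) {
  week_num <- as.numeric(sub("pct_w", "", object$weeks))
  cen <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("pct_w"),
                        names_to = "week", values_to = "pct") |>
    dplyr::mutate(week = as.numeric(sub("pct_w", "", .data$week)))
  p <- ggplot2::ggplot(cen, ggplot2::aes(x = .data$week, y = .data$pct,
                                         colour = .data$label)) +
    ggplot2::labs(x = "week", y = "PANSS percent reduction (%)",
                  colour = "trajectory") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    spag <- augment(object, data)
    if (nrow(spag) > max_lines) spag <- spag[seq_len(max_lines), , drop = FALSE]
    spag <- tidyr::pivot_longer(spag, dplyr::starts_with("pct_w"),
                                names_to = "week", values_to = "pct") |>
      dplyr::mutate(week = as.numeric(sub("pct_w", "", .data$week)))
    p <- p + ggplot2::geom_line(
      data = spag,
      ggplot2::aes(group = .data$patient_id, colour = .data$.label),
      alpha = 0.15)
  }
  p + ggplot2::geom_line(linewidth = 1.2) + ggplot2::geom_point(size = 2)
}
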