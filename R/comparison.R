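#' Dichotomous threshold responder classification
#'
#' The conventional responder definition: at least a 50% corrected reduction
#' of the PANSS total at week 6. The boundary is inclusive by default
#' (`>= cutoff`); set `strict = TRUE` for a strictly-greater rule.
#'
#' @param week6_pct Week-6 percent reduction(s).
#' @param cutoff Responder cutoff in percent (default 50).
#' @param strict Use `>` instead of `>=` at the boundary?
#' @return Logical vector: `TRUE` = responder.
#' @export
classify_threshold <- function(week6_pct, cutoff = 50, strict = FALSE) {
  if (any(!is.finite(week6_pct))) {
    rlang::abort("week-6 percent reductions must be finite.", class = "trajresp_value_error")
  }
  if (strict) week6_pct > cutoff else week6_pct >= cutoff
}

new_cross_tab <- function(counts, note = NULL) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, note = note), class = "cross_tab")
}

#' @export
print.cross_tab <- function(x, ...) {
  cat("<cross_tab>", if (!is.null(x$note)) x$note, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.cross_tab <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    stats::setNames(c("row", "col", "n"))
}

as_count_matrix <- function(x) {
  if (inherits(x, "cross_tab")) x$counts else as.matrix(x)
}

#' Paired trajectory-by-threshold cross-tabulation
#'
#' Cross-classifies each patient's trajectory membership (high/low) against
#' their threshold responder status; the off-diagonal cells count the
#' patients the two methods classify inconsistently.
#'
#' @param traj_labels Per-patient `"high"`/`"low"` trajectory labels.
#' @param resp_flags Per-patient logical responder flags, aligned with
#'   `traj_labels`.
#' @return A 2x2 `cross_tab` (rows trajectory, cols responder status) with a
#'   `discordant` attribute giving the off-diagonal total.
#' @export
paired_crosstab <- function(traj_labels, resp_flags) {
  if (length(traj_labels) != length(resp_flags)) {
    rlang::abort("trajectory labels and responder flags must be aligned (same length).",
                 class = "trajresp_value_error")
  }
  counts <- matrix(c(
    sum(traj_labels == "high" & resp_flags),
    sum(traj_labels == "high" & !resp_flags),
    sum(traj_labels == "low" & resp_flags),
    sum(traj_labels == "low" & !resp_flags)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(trajectory = c("high", "low"),
                  threshold = c("responder", "non_responder")))
  ct <- new_cross_tab(counts, "paired classification of the same patients")
  attr(ct, "discordant") <- counts["high", "non_responder"] +
    counts["low", "responder"]
  ct
}

#' Discordant-patient count of a paired cross-tab
#' @param crosstab Result of [paired_crosstab()].
#' @export
discordant_count <- function(crosstab) {
  as.integer(attr(crosstab, "discordant"))
}

#' Composition table of the two classification methods
#'
#' Compares the *composition ratio* of good vs poor response under the two
#' methods: row "trajectory" counts high/low members, row "threshold" counts
#' responders/non-responders. Each patient contributes once per method, so
#' the grand total is 2n; the downstream chi-squared treats the two
#' classifications as independent samples. (For a paired analysis of the
#' discordant cells use [mcnemar_discordance()].)
#'
#' @inheritParams paired_crosstab
#' @return A 2x2 `cross_tab` (rows methods, cols good/poor response).
#' @export
composition_table <- function(traj_labels, resp_flags) {
  if (length(traj_labels) != length(resp_flags)) {
    rlang::abort("trajectory labels and responder flags must be aligned (same length).",
                 class = "trajresp_value_error")
  }
  counts <- matrix(c(
    sum(traj_labels == "high"), sum(traj_labels == "low"),
    sum(resp_flags), sum(!resp_flags)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(method = c("trajectory", "threshold"),
                  response = c("good", "poor")))
  new_cross_tab(counts, "method compositions; grand total = 2n (one count per patient per method)")
}

test_result <- function(statistic, df, p_value, method, estimate = NA_real_) {
  tibble(statistic = as.numeric(statistic), df = df,
         p_value = p_value, method = method, estimate = estimate)
}

#' Pearson chi-squared test of independence
#'
#' Plain `sum((O - E)^2 / E)` without continuity correction, as used for all
#' omnibus contingency comparisons.
#'
#' @param table A `cross_tab` or count matrix with all expected counts > 0.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
pearson_chi2 <- function(table) {
  counts <- as_count_matrix(table)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    rlang::abort("zero expected cell count: use fisher_exact_2x2() instead.",
                 class = "trajresp_value_error")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result(res$statistic, unname(res$parameter), res$p.value, "pearson_chi2")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table; reports the conditional odds-ratio estimate.
#'
#' @param table A `cross_tab` or 2x2 matrix of non-negative integers.
#' @return One-row tibble with the odds ratio in `estimate` (`df` is `NA`).
#' @export
fisher_exact_2x2 <- function(table) {
  counts <- as_count_matrix(table)
  if (any(counts < 0)) {
    rlang::abort("counts must be non-negative.", class = "trajresp_value_error")
  }
  res <- stats::fisher.test(counts)
  # the exact p can exceed 1 by rounding in the hypergeometric sum
  test_result(NA_real_, NA_integer_, min(res$p.value, 1), "fisher_exact",
              estimate = unname(res$estimate))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply `p(i)` by `m/i`,
#' enforce monotonicity from the largest rank down, cap at 1, and return in
#' the original order. Idempotent.
#'
#' @param p_values Probabilities between 0 and 1.
#' @return Adjusted probabilities, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1].", class = "trajresp_value_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' McNemar test on the discordant cells of the paired cross-tab
#'
#' The statistically conventional paired companion to the composition
#' chi-squared: tests whether the two methods disagree symmetrically, using
#' only the discordant counts.
#'
#' @param crosstab Result of [paired_crosstab()].
#' @param correct Apply the continuity correction?
#' @return One-row tibble.
#' @export
mcnemar_discordance <- function(crosstab, correct = FALSE) {
  res <- stats::mcnemar.test(as_count_matrix(crosstab), correct = correct)
  test_result(res$statistic, unname(res$parameter), res$p.value,
              if (correct) "mcnemar_corrected" else "mcnemar")
}

omnibus_test <- function(counts, expected_min = 5) {
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < expected_min)) {
    res <- stats::fisher.test(counts, workspace = 2e7)
    test_result(NA_real_, NA_integer_, min(res$p.value, 1), "fisher_exact")
  } else {
    pearson_chi2(counts)
  }
}

#' Per-arm breakdown of trajectory and threshold response
#'
#' Builds the arm-by-trajectory and arm-by-responder contingency tables,
#' runs an omnibus test on each (Pearson chi-squared, or Fisher's exact when
#' any expected count falls below 5), and performs all pairwise 2x2 Fisher
#' comparisons between arms with Benjamini-Hochberg adjustment. Pairwise
#' comparisons use the threshold (responder) table by default.
#'
#' @param arms Per-patient drug labels.
#' @param traj_labels Per-patient trajectory labels (`"high"`/`"low"`).
#' @param resp_flags Per-patient responder flags.
#' @param pairwise_on `"threshold"` (default) or `"trajectory"`.
#' @return An `arm_breakdown` list: both `cross_tab`s, an `omnibus` tibble
#'   (one row per table), and a `pairwise` tibble with raw and adjusted
#'   p-values.
#' @export
per_arm_breakdown <- function(arms, traj_labels, resp_flags,
                              pairwise_on = c("threshold", "trajectory")) {
  pairwise_on <- match.arg(pairwise_on)
  if (length(arms) != length(traj_labels) || length(arms) != length(resp_flags)) {
    rlang::abort("`arms`, `traj_labels` and `resp_flags` must be aligned.",
                 class = "trajresp_value_error")
  }
  present <- intersect(trial_arms(), unique(arms))
  missing_arms <- setdiff(trial_arms(), present)
  if (length(missing_arms) > 0) {
    rlang::warn(paste("arms with zero patients dropped:",
                      paste(missing_arms, collapse = ", ")))
  }
  if (length(present) < 2) {
    rlang::abort("need at least 2 arms with patients.", class = "trajresp_value_error")
  }
  traj_tab <- t(vapply(present, function(a) {
    c(high = sum(arms == a & traj_labels == "high"),
      low = sum(arms == a & traj_labels == "low"))
  }, c(high = 0, low = 0)))
  resp_tab <- t(vapply(present, function(a) {
    c(responder = sum(arms == a & resp_flags),
      non_responder = sum(arms == a & !resp_flags))
  }, c(responder = 0, non_responder = 0)))
  names(dimnames(traj_tab)) <- c("arm", "trajectory")
  names(dimnames(resp_tab)) <- c("arm", "threshold")

  omnibus <- dplyr::bind_rows(
    dplyr::mutate(omnibus_test(traj_tab), table = "trajectory", .before = 1),
    dplyr::mutate(omnibus_test(resp_tab), table = "threshold", .before = 1)
  )

  pair_tab <- if (pairwise_on == "threshold") resp_tab else traj_tab
  pairs <- utils::combn(present, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sub <- pair_tab[pr, , drop = FALSE]
    res <- fisher_exact_2x2(sub)
    tibble(arm1 = pr[1], arm2 = pr[2],
           odds_ratio = res$estimate, p_value = res$p_value)
  })
  pairwise$adjusted_p <- bh_fdr(pairwise$p_value)

  structure(list(
    trajectory_table = new_cross_tab(traj_tab, "arm x trajectory"),
    threshold_table = new_cross_tab(resp_tab, "arm x threshold responder"),
    omnibus = omnibus,
    pairwise = pairwise,
    pairwise_on = pairwise_on
  ), class = "arm_breakdown")
}

#' @export
print.arm_breakdown <- function(x, ...) {
  cat("<arm_breakdown>\n")
  print(x$omnibus)
  cat("pairwise (", x$pairwise_on, ", BH-adjusted):\n", sep = "")
  print(dplyr::arrange(x$pairwise, .data$adjusted_p))
  invisible(x)
}

#' First-episode versus relapse split within drug classes
#'
#' Within the typical (first-generation) and atypical (second-generation)
#' strata separately, cross-tabulates episode status against trajectory
#' membership and tests the association with the Pearson chi-squared (Fisher
#' fallback for sparse tables). Empty strata are skipped with a warning.
#'
#' @param traj_labels Per-patient trajectory labels.
#' @param arms Per-patient drug labels.
#' @param first_episode Per-patient logical: first episode (vs relapse).
#' @param typical_arm_set Arms forming the typical stratum.
#' @return An `episode_split` list: per-stratum `cross_tab`s and a `tests`
#'   tibble.
#' @export
episode_split <- function(traj_labels, arms, first_episode,
                          typical_arm_set = typical_arms()) {
  if (!all(typical_arm_set %in% trial_arms())) {
    rlang::abort("`typical_arm_set` must be a subset of trial_arms().",
                 class = "trajresp_value_error")
  }
  strata <- list(typical = arms %in% typical_arm_set,
                 atypical = !(arms %in% typical_arm_set))
  tables <- list()
  tests <- tibble()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (!any(idx)) {
      rlang::warn(paste0("stratum `", s, "` is empty; skipped."))
      next
    }
    counts <- matrix(c(
      sum(idx & first_episode & traj_labels == "high"),
      sum(idx & first_episode & traj_labels == "low"),
      sum(idx & !first_episode & traj_labels == "high"),
      sum(idx & !first_episode & traj_labels == "low")
    ), nrow = 2, byrow = TRUE,
    dimnames = list(episode = c("first_episode", "relapse"),
                    trajectory = c("high", "low")))
    tables[[s]] <- new_cross_tab(counts, paste(s, "arms: episode x trajectory"))
    tests <- dplyr::bind_rows(tests,
                              dplyr::mutate(omnibus_test(counts), stratum = s, .before = 1))
  }
  structure(list(tables = tables, tests = tests), class = "episode_split")
}

#' @export
print.episode_split <- function(x, ...) {
  cat("<episode_split>\n")
  for (s in names(x$tables)) print(x$tables[[s]])
  print(x$tests)
  invisible(x)
}

#' Compare trajectory and threshold classifications on one analysis table
#'
#' The full comparison stage on a per-patient tibble carrying trajectory
#' labels, week-6 percent reductions, arms and episode status: threshold
#' classification, paired discordance table, composition table with its
#' chi-squared (and the McNemar companion), per-arm breakdown with
#' FDR-adjusted pairwise drug tests, and the episode-status split within
#' drug classes.
#'
#' @param data Tibble with columns `label` (`"high"`/`"low"`), `pct_w6`, and
#'   optionally `arm` and `first_episode` (those analyses are skipped when
#'   absent).
#' @param cutoff,strict Passed to [classify_threshold()].
#' @param typical_arm_set Passed to [episode_split()].
#' @return A `response_comparison` list bundling every table and test, plus
#'   the decisions in force (cutoff and boundary rule).
#' @export
compare_responses <- function(data, cutoff = 50, strict = FALSE,
                              typical_arm_set = typical_arms()) {
  flags <- classify_threshold(data$pct_w6, cutoff = cutoff, strict = strict)
  paired <- paired_crosstab(data$label, flags)
  comp <- composition_table(data$label, flags)
  out <- list(
    responder_flags = flags,
    paired = paired,
    discordant = discordant_count(paired),
    composition = comp,
    composition_test = pearson_chi2(comp),
    mcnemar = mcnemar_discordance(paired),
    n = nrow(data),
    pct_high = 100 * sum(data$label == "high") / nrow(data),
    pct_responder = 100 * sum(flags) / nrow(data),
    decisions = list(cutoff = cutoff,
                     boundary = if (strict) "strict (>)" else "inclusive (>=)")
  )
  if ("arm" %in% names(data) && length(unique(data$arm)) >= 2) {
    out$arms <- per_arm_breakdown(data$arm, data$label, flags)
    if ("first_episode" %in% names(data)) {
      out$episode <- episode_split(data$label, data$arm, data$first_episode,
                                   typical_arm_set = typical_arm_set)
    }
  }
  structure(out, class = "response_comparison")
}

#' @export
print.response_comparison <- function(x, ...) {
  cat("<response_comparison> n =", x$n, "\n")
  cat(sprintf("  high trajectory: %.2f%% | threshold responders: %.2f%% (cutoff %g%%, %s)\n",
              x$pct_high, x$pct_responder, x$decisions$cutoff, x$decisions$boundary))
  cat("  discordant patients:", x$discordant, "\n")
  cat(sprintf("  composition chi2 = %.2f (df %d, p = %.3g)\n",
              x$composition_test$statistic, x$composition_test$df,
              x$composition_test$p_value))
  invisible(x)
}

#' @export
glance.response_comparison <- function(x, ...) {
  tibble(n = x$n, pct_high = x$pct_high, pct_responder = x$pct_responder,
         discordant = x$discordant,
         composition_chi2 = x$composition_test$statistic,
         composition_p = x$composition_test$p_value)
}

#' @export
tidy.response_comparison <- function(x, ...) {
  res <- dplyr::bind_rows(
    dplyr::mutate(x$composition_test, comparison = "composition", .before = 1),
    dplyr::mutate(x$mcnemar, comparison = "mcnemar_discordance", .before = 1)
  )
  if (!is.null(x$arms)) {
    res <- dplyr::bind_rows(
      res, dplyr::mutate(x$arms$omnibus, comparison = paste0("arms_", .data$table),
                         .before = 1) |> dplyr::select(-"table"))
  }
  if (!is.null(x$episode)) {
    res <- dplyr::bind_rows(
      res, dplyr::mutate(x$episode$tests, comparison = paste0("episode_", .data$stratum),
                         .before = 1) |> dplyr::select(-"stratum"))
  }
  res
}
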