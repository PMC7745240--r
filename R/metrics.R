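#' Floor-corrected percent reduction of the PANSS total score
#'
#' The PANSS total cannot fall below 30 (every item scored 1), so a raw
#' percent change understates improvement. The corrected reduction rate
#' removes the floor:
#' `100 * (baseline - followup) / (baseline - 30)`, making 100% mean complete
#' symptom remission. Vectorised over both arguments.
#'
#' @param baseline Baseline total score(s); must exceed 30 strictly, since a
#'   baseline at the symptom floor makes the denominator zero.
#' @param followup Follow-up total score(s), at least 30.
#' @return Percent reduction (positive = improvement), `NA` where the
#'   follow-up is missing.
#' @export
percent_change_total <- function(baseline, followup) {
  if (any(is.na(baseline))) {
    rlang::abort("baseline scores must not be missing.", class = "trajresp_value_error")
  }
  if (any(baseline <= 30)) {
    rlang::abort("baseline PANSS total must exceed 30 (scale floor): denominator undefined.",
                 class = "trajresp_value_error")
  }
  100 * (baseline - followup) / (baseline - 30)
}

#' Percent reduction of a PANSS subscale score
#'
#' Subscales may sit exactly at their floor at baseline, so no floor
#' correction is applied: `100 * (baseline - followup) / baseline`.
#'
#' @param baseline Baseline subscale score(s), strictly positive.
#' @param followup Follow-up subscale score(s).
#' @return Percent reduction; negative values indicate worsening.
#' @export
percent_change_subscale <- function(baseline, followup) {
  if (any(is.na(baseline)) || any(baseline <= 0)) {
    rlang::abort("baseline subscale scores must be positive and non-missing.",
                 class = "trajresp_value_error")
  }
  100 * (baseline - followup) / baseline
}

#' Winsorize out-of-fence values by the 1.5 IQR rule
#'
#' Values above `Q3 + 1.5 * IQR` are replaced by the 0.99 quantile of the
#' original values and values below `Q1 - 1.5 * IQR` by the 0.01 quantile;
#' everything in-fence is untouched. Missing values pass through unchanged.
#' Fences and replacement values are always computed from the *input*, so a
#' second pass with the stored fences is a no-op.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param probs Replacement quantile pair (lower, upper).
#' @param type Quantile convention passed to [stats::quantile()]; the default
#'   7 is linear interpolation.
#' @return Vector of the same length; attributes `fences` (named lower/upper),
#'   `replacements` (the two quantile values used) and `n_replaced`.
#' @export
winsorize_iqr <- function(values, probs = c(0.01, 0.99), type = 7) {
  finite <- is.finite(values)
  if (sum(finite) < 4L) {
    rlang::abort("winsorization needs at least 4 finite values for stable quartiles.",
                 class = "trajresp_value_error")
  }
  x <- values[finite]
  q <- stats::quantile(x, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  repl <- stats::quantile(x, probs, type = type, names = FALSE)
  out <- values
  lo <- finite & values < fences["lower"]
  hi <- finite & values > fences["upper"]
  out[lo] <- repl[1]
  out[hi] <- repl[2]
  structure(out, fences = fences,
            replacements = c(lower = repl[1], upper = repl[2]),
            n_replaced = sum(lo) + sum(hi))
}

#' Chained-equation imputation with predictive mean matching
#'
#' Completes the missing cells of a wide numeric table by iterated
#' column-wise regression: each incomplete column is regressed (ordinary
#' least squares) on all other columns over its observed rows, predictions
#' are computed for every row, and each missing cell is filled with the
#' observed value of one of the `donor_pool` rows whose predictions are
#' nearest to the missing row's prediction (predictive mean matching). The
#' cycle over columns is repeated `n_iterations` times and the whole process
#' `n_imputations` times from independent random starts. Observed cells are
#' never altered, and every imputed value equals some observed value in its
#' column.
#'
#' @param data Data frame of numeric columns; non-numeric columns (ids) are
#'   carried through untouched and never used as predictors.
#' @param n_imputations Number of completed copies to return.
#' @param n_iterations Chained iterations per copy.
#' @param seed Integer seed.
#' @param donor_pool Number of nearest donors sampled from.
#' @return A list of `n_imputations` completed tibbles.
#' @export
impute_chained <- function(data, n_imputations = 5L, n_iterations = 20L,
                           seed = 1L, donor_pool = 5L) {
  data <- as_tibble(data)
  num_cols <- names(data)[vapply(data, is.numeric, TRUE)]
  miss_cols <- num_cols[vapply(data[num_cols], anyNA, TRUE)]
  for (col in miss_cols) {
    obs_frac <- mean(!is.na(data[[col]]))
    if (obs_frac == 0) {
      rlang::abort(paste0("column `", col, "` has no observed values; cannot impute."),
                   class = "trajresp_value_error")
    }
    if (obs_frac < 0.5) {
      rlang::warn(paste0("column `", col, "` is less than 50% observed; imputations may be unstable."))
    }
  }
  if (length(miss_cols) == 0L) {
    return(replicate(n_imputations, data, simplify = FALSE))
  }

  withr::with_seed(seed, {
    purrr::map(seq_len(n_imputations), function(m) {
      imp <- data
      # random-draw initialisation from each column's observed values
      for (col in miss_cols) {
        idx <- which(is.na(imp[[col]]))
        obs <- imp[[col]][!is.na(imp[[col]])]
        imp[[col]][idx] <- sample(obs, length(idx), replace = TRUE)
      }
      for (it in seq_len(n_iterations)) {
        for (col in miss_cols) {
          mis_idx <- which(is.na(data[[col]]))
          obs_idx <- which(!is.na(data[[col]]))
          predictors <- setdiff(num_cols, col)
          X <- as.matrix(imp[predictors])
          y <- data[[col]][obs_idx]
          fit <- stats::lm.fit(cbind(1, X[obs_idx, , drop = FALSE]), y)
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          pred <- drop(cbind(1, X) %*% beta)
          pool <- min(donor_pool, length(obs_idx))
          for (i in mis_idx) {
            d <- abs(pred[obs_idx] - pred[i])
            donors <- obs_idx[order(d, stats::runif(length(d)))[seq_len(pool)]]
            imp[[col]][i] <- data[[col]][sample(donors, 1L)]
          }
        }
      }
      imp
    })
  })
}

#' Build the percent-reduction trajectory matrix
#'
#' Converts a completed wide cohort table into the per-patient trajectory of
#' corrected percent reductions at the follow-up weeks, the quantity the
#' clustering engine operates on. Week 0 is identically zero and excluded.
#'
#' @param records Wide tibble with complete `panss_total_w*` columns (run
#'   [impute_chained()] first if follow-ups are missing).
#' @param weeks Follow-up weeks (default 2, 4, 6).
#' @return Tibble with `patient_id` and one `pct_w<week>` column per week,
#'   rows in input order.
#' @export
build_trajectories <- function(records, weeks = c(2L, 4L, 6L)) {
  baseline <- records$panss_total_w0
  if (is.null(baseline) || anyNA(baseline)) {
    rlang::abort("baseline totals (`panss_total_w0`) must be present and complete.",
                 class = "trajresp_value_error")
  }
  out <- tibble(patient_id = records$patient_id)
  for (w in weeks) {
    col <- paste0("panss_total_w", w)
    if (is.null(records[[col]]) || anyNA(records[[col]])) {
      rlang::abort(paste0("column `", col, "` must be present and complete; impute first."),
                   class = "trajresp_value_error")
    }
    out[[paste0("pct_w", w)]] <- percent_change_total(baseline, records[[col]])
  }
  out
}

#' Preprocess a raw cohort into clustering-ready trajectories
#'
#' The full preprocessing stage: (1) winsorize each follow-up PANSS total
#' column across patients by the 1.5 IQR rule (outlying *scores*, not
#' outlying ratios, are treated as the measurement artifact, so winsorization
#' precedes the percent-change transform); (2) complete missing follow-up
#' totals by chained-equation predictive mean matching; (3) convert to
#' corrected percent reductions at weeks 2/4/6. Records whose baseline sits
#' at the scale floor (total = 30) are dropped with a warning, since their
#' reduction rate is undefined.
#'
#' @param records Raw cohort tibble (as generated or read from CSV).
#' @param winsorize Apply the IQR rule before imputation?
#' @param n_imputations,n_iterations,donor_pool Passed to [impute_chained()].
#' @param seed Integer seed for the imputation draws.
#' @param quantile_type Quantile convention for winsorization.
#' @return A `panss_prep` list: `trajectories` (tibble from the first
#'   completed dataset, the default analysis set), `imputations` (list of all
#'   completed trajectory tibbles), and `audit` (counts of winsorized cells
#'   per column, imputed cells per column, dropped floor-baseline records).
#' @export
preprocess_panss <- function(records, winsorize = TRUE, n_imputations = 5L,
                             n_iterations = 20L, donor_pool = 5L, seed = 1L,
                             quantile_type = 7) {
  floor_rows <- !is.na(records$panss_total_w0) & records$panss_total_w0 <= 30
  if (any(floor_rows)) {
    rlang::warn(sprintf(
      "%d record(s) with baseline PANSS total at the scale floor (30) dropped: reduction rate undefined.",
      sum(floor_rows)))
    records <- records[!floor_rows, , drop = FALSE]
  }

  total_cols <- paste0("panss_total_w", c(0L, 2L, 4L, 6L))
  work <- records[c("patient_id", total_cols)]
  wins_audit <- tibble(column = character(), n_winsorized = integer())
  if (winsorize) {
    for (col in total_cols) {
      w <- winsorize_iqr(work[[col]], type = quantile_type)
      wins_audit <- dplyr::bind_rows(
        wins_audit, tibble(column = col, n_winsorized = attr(w, "n_replaced")))
      work[[col]] <- as.numeric(w)
    }
  }

  n_missing <- vapply(work[total_cols], function(x) sum(is.na(x)), 0L)
  completed <- impute_chained(work, n_imputations = n_imputations,
                              n_iterations = n_iterations, seed = seed,
                              donor_pool = donor_pool)
  trajectories <- purrr::map(completed, build_trajectories)

  structure(list(
    trajectories = trajectories[[1]],
    imputations = trajectories,
    audit = list(
      winsorized = wins_audit,
      imputed_cells = tibble(column = total_cols, n_imputed = unname(n_missing)),
      n_dropped_floor_baseline = sum(floor_rows)
    )
  ), class = "panss_prep")
}

#' @export
print.panss_prep <- function(x, ...) {
  cat("<panss_prep> ", nrow(x$trajectories), " patients, ",
      length(x$imputations), " imputation(s)\n", sep = "")
  cat("  winsorized cells:", sum(x$audit$winsorized$n_winsorized),
      "| imputed cells:", sum(x$audit$imputed_cells$n_imputed),
      "| dropped floor baselines:", x$audit$n_dropped_floor_baseline, "\n")
  invisible(x)
}
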