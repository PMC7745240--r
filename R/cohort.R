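#' @importFrom rlang .data abort warn %||%
#' @import tibble
NULL

# PANSS scale bounds: total 30-210, positive 7-49, negative 7-49, general 16-112.
# Subscale floors sum exactly to the total floor (7 + 7 + 16 = 30) and the
# ceilings to the total ceiling, so a proportional split of any admissible
# total always lands inside all three subscale ranges.
PANSS_BOUNDS <- list(
  total    = c(30L, 210L),
  positive = c(7L, 49L),
  negative = c(7L, 49L),
  general  = c(16L, 112L)
)

#' Seven antipsychotic trial arms
#'
#' Arm names in randomisation order: five second-generation (atypical) drugs
#' followed by the two first-generation (typical) drugs that receive half
#' randomisation weight.
#'
#' @export
trial_arms <- function() {
  c("risperidone", "olanzapine", "quetiapine", "aripiprazole",
    "ziprasidone", "perphenazine", "haloperidol")
}

#' Typical (first-generation) antipsychotic arms
#' @export
typical_arms <- function() c("perphenazine", "haloperidol")

#' Synthetic cohort configuration
#'
#' Bundles every parameter of the trial-cohort simulator: the unequal
#' randomisation scheme (1:1:1:1:1:1/2:1/2 over seven arms), two latent
#' response classes whose mean percent-reduction curves default to a
#' high-response class (35.84/60.51/73.58% at weeks 2/4/6) and a low-response
#' class (15.16/28.10/31.99%), baseline severity, visit-level measurement
#' noise, monotone dropout and isolated visit missingness.
#'
#' @param n_patients Number of patients to simulate.
#' @param arm_weights Seven non-negative relative randomisation weights,
#'   in [trial_arms()] order. At least one must be positive.
#' @param class_proportions Named probabilities of the latent response
#'   classes; must sum to 1.
#' @param class_mean_curves Named list, one numeric vector per class giving
#'   the mean corrected percent reduction of the PANSS total at the follow-up
#'   weeks (2, 4, 6).
#' @param within_class_sd Standard deviation, in percentage points, of the
#'   patient-by-visit noise around the class mean curve.
#' @param baseline_total_mean,baseline_total_sd Normal parameters of the
#'   baseline PANSS total before truncation to (30, 210].
#' @param dropout_rate Probability that a patient drops out after a uniformly
#'   chosen follow-up visit (all later visits missing).
#' @param missing_rate Per patient-visit probability of an isolated missed
#'   follow-up assessment (all four scores of that visit missing).
#' @param first_episode_prop Probability that a patient is in a first
#'   psychotic episode (vs relapse).
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration.
#'
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 3010L,
                          arm_weights = c(1, 1, 1, 1, 1, 0.5, 0.5),
                          class_proportions = c(high = 0.489, low = 0.511),
                          class_mean_curves = list(
                            high = c(35.84, 60.51, 73.58),
                            low = c(15.16, 28.10, 31.99)
                          ),
                          within_class_sd = 8,
                          baseline_total_mean = 90,
                          baseline_total_sd = 15,
                          dropout_rate = 0.1262,
                          missing_rate = 0.02,
                          first_episode_prop = 0.45,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    arm_weights = as.numeric(arm_weights),
    class_proportions = class_proportions,
    class_mean_curves = class_mean_curves,
    within_class_sd = within_class_sd,
    baseline_total_mean = baseline_total_mean,
    baseline_total_sd = baseline_total_sd,
    dropout_rate = dropout_rate,
    missing_rate = missing_rate,
    first_episode_prop = first_episode_prop,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    abort("`n_patients` must be a positive integer.", class = "trajresp_config_error")
  }
  if (length(cfg$arm_weights) != 7L || any(is.na(cfg$arm_weights)) ||
      any(cfg$arm_weights < 0) || sum(cfg$arm_weights) <= 0) {
    abort("`arm_weights` must be seven non-negative weights with at least one > 0.",
          class = "trajresp_config_error")
  }
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9 || any(cfg$class_proportions < 0)) {
    abort("`class_proportions` must be non-negative and sum to 1.",
          class = "trajresp_config_error")
  }
  if (is.null(names(cfg$class_proportions)) ||
      !setequal(names(cfg$class_proportions), names(cfg$class_mean_curves))) {
    abort("`class_proportions` and `class_mean_curves` must share class names.",
          class = "trajresp_config_error")
  }
  if (any(vapply(cfg$class_mean_curves, length, 0L) != 3L)) {
    abort("each class mean curve needs one value per follow-up week (2, 4, 6).",
          class = "trajresp_config_error")
  }
  if (cfg$within_class_sd < 0) {
    abort("`within_class_sd` must be non-negative.", class = "trajresp_config_error")
  }
  if (cfg$baseline_total_mean <= PANSS_BOUNDS$total[1] ||
      cfg$baseline_total_mean > PANSS_BOUNDS$total[2]) {
    abort("`baseline_total_mean` must lie in (30, 210].", class = "trajresp_config_error")
  }
  for (f in c("dropout_rate", "missing_rate", "first_episode_prop")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("`", f, "` must be a probability in [0, 1]."),
            class = "trajresp_config_error")
    }
  }
  cfg
}

#' Randomise patients to trial arms
#'
#' Draws `n` independent arm labels with probability proportional to the
#' supplied weights, reproducing the trial's unequal 1:1:1:1:1:1/2:1/2
#' allocation under the default weights.
#'
#' @param n Number of patients.
#' @param weights Seven non-negative relative weights in [trial_arms()] order.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Character vector of `n` arm labels.
#' @export
assign_arms <- function(n, weights = c(1, 1, 1, 1, 1, 0.5, 0.5), seed = 1L) {
  if (n < 1) abort("`n` must be at least 1.", class = "trajresp_config_error")
  if (length(weights) != 7L || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be seven non-negative values with at least one > 0.",
          class = "trajresp_config_error")
  }
  withr::with_seed(seed,
    sample(trial_arms(), n, replace = TRUE, prob = weights / sum(weights))
  )
}

# Split a visit total into positive/negative/general subscale scores that sum
# exactly to it and respect all subscale bounds. Proportional allocation at
# the scale's floor/ceiling proportions plus bounded integer jitter, then an
# exact repair of the remainder.
split_subscales <- function(totals, jitter_sd = 1.5) {
  n <- length(totals)
  pos <- round(totals * 49 / 210 + stats::rnorm(n, 0, jitter_sd))
  neg <- round(totals * 49 / 210 + stats::rnorm(n, 0, jitter_sd))
  pos <- pmin(pmax(pos, 7), 49)
  neg <- pmin(pmax(neg, 7), 49)
  gen <- totals - pos - neg
  # push any general-subscale overflow/deficit back into positive, then negative
  deficit <- pmax(16 - gen, 0)          # gen too small: shrink pos/neg
  take_pos <- pmin(deficit, pos - 7)
  pos <- pos - take_pos
  take_neg <- pmin(deficit - take_pos, neg - 7)
  neg <- neg - take_neg
  excess <- pmax((totals - pos - neg) - 112, 0)  # gen too large: grow pos/neg
  give_pos <- pmin(excess, 49 - pos)
  pos <- pos + give_pos
  give_neg <- pmin(excess - give_pos, 49 - neg)
  neg <- neg + give_neg
  gen <- totals - pos - neg
  data.frame(positive = as.integer(pos), negative = as.integer(neg),
             general = as.integer(gen))
}

#' Generate a synthetic trial cohort
#'
#' Simulates one patient table under a [cohort_config()]: arms are randomised
#' with the configured weights, each patient receives a latent response class,
#' a truncated-normal baseline PANSS total, and follow-up totals obtained by
#' inverting the floor-corrected percent-change formula
#' `total_w = baseline - pct/100 * (baseline - 30)` around the class mean
#' curve plus visit noise, so the configured curves are exact in
#' reduction-rate space (up to integer rounding of scores). Subscale scores
#' are a proportional split of each visit total. Monotone dropout and
#' isolated missed visits are then applied to follow-up visits only.
#'
#' @param config A [cohort_config()].
#' @param include_latent Keep the simulation ground-truth columns
#'   (`latent_class`)? They are retained in the returned tibble by default for
#'   recovery testing but excluded from files written by [write_cohort()]
#'   unless requested.
#' @return A tibble with one row per patient: `patient_id`, `arm`,
#'   `first_episode`, `latent_class`, covariates, and
#'   `panss_<scale>_w<0|2|4|6>` integer score columns (follow-up cells may be
#'   `NA`).
#' @export
generate_cohort <- function(config = cohort_config(), include_latent = TRUE) {
  cfg <- validate_cohort_config(config)
  n <- cfg$n_patients
  weeks <- c(2L, 4L, 6L)
  classes <- names(cfg$class_proportions)

  records <- withr::with_seed(cfg$seed, {
    arm <- sample(trial_arms(), n, replace = TRUE,
                  prob = cfg$arm_weights / sum(cfg$arm_weights))
    latent_class <- sample(classes, n, replace = TRUE,
                           prob = as.numeric(cfg$class_proportions))
    first_episode <- stats::runif(n) < cfg$first_episode_prop
    age_at_onset <- round(pmin(pmax(stats::rnorm(n, 24, 6), 13), 60), 1)
    illness_duration <- ifelse(first_episode,
                               round(stats::runif(n, 0, 1), 1),
                               round(pmin(stats::rexp(n, 1 / 6), 30), 1))
    dose <- round(stats::runif(n, 2, 8), 1)

    baseline <- round(stats::rnorm(n, cfg$baseline_total_mean, cfg$baseline_total_sd))
    baseline <- as.integer(pmin(pmax(baseline, 31), 210))

    totals <- matrix(NA_integer_, n, length(weeks))
    for (j in seq_along(weeks)) {
      mu <- vapply(latent_class, function(cl) cfg$class_mean_curves[[cl]][j], 0)
      pct <- mu + stats::rnorm(n, 0, cfg$within_class_sd)
      tw <- round(baseline - pct / 100 * (baseline - 30))
      totals[, j] <- as.integer(pmin(pmax(tw, 30), 210))
    }

    out <- tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      arm = arm, first_episode = first_episode, latent_class = latent_class,
      age_at_onset = age_at_onset, illness_duration = illness_duration,
      dose_risperidone_equiv = dose
    )
    sub0 <- split_subscales(baseline)
    out$panss_total_w0 <- baseline
    out$panss_positive_w0 <- sub0$positive
    out$panss_negative_w0 <- sub0$negative
    out$panss_general_w0 <- sub0$general
    for (j in seq_along(weeks)) {
      subw <- split_subscales(totals[, j])
      out[[paste0("panss_total_w", weeks[j])]] <- totals[, j]
      out[[paste0("panss_positive_w", weeks[j])]] <- subw$positive
      out[[paste0("panss_negative_w", weeks[j])]] <- subw$negative
      out[[paste0("panss_general_w", weeks[j])]] <- subw$general
    }

    out <- apply_dropout_impl(out, cfg$dropout_rate)
    out <- apply_visit_missing_impl(out, cfg$missing_rate)
    out
  })

  if (!include_latent) records$latent_class <- NULL
  records
}

score_cols_for_week <- function(week) {
  paste0("panss_", c("total", "positive", "negative", "general"), "_w", week)
}

apply_dropout_impl <- function(records, rate) {
  if (rate == 0) return(records)
  n <- nrow(records)
  dropped <- stats::runif(n) < rate
  cut_visit <- sample(c(2L, 4L, 6L), n, replace = TRUE)
  for (w in c(2L, 4L, 6L)) {
    rows <- dropped & cut_visit <= w
    for (col in score_cols_for_week(w)) records[[col]][rows] <- NA_integer_
  }
  records
}

apply_visit_missing_impl <- function(records, rate) {
  if (rate == 0) return(records)
  n <- nrow(records)
  for (w in c(2L, 4L, 6L)) {
    miss <- stats::runif(n) < rate
    for (col in score_cols_for_week(w)) records[[col]][miss] <- NA_integer_
  }
  records
}

#' Apply monotone dropout to a complete cohort
#'
#' For each patient selected with probability `dropout_rate`, a cut visit is
#' chosen uniformly from weeks 2/4/6 and every score from that visit onward
#' is set missing; baseline is never touched. Mirrors trial attrition where a
#' patient who leaves contributes nothing afterwards.
#'
#' @param records Cohort tibble from [generate_cohort()] with complete
#'   follow-up.
#' @param dropout_rate Probability between 0 and 1.
#' @param seed Integer seed.
#' @return The tibble with missing cells introduced.
#' @export
apply_dropout <- function(records, dropout_rate, seed = 1L) {
  if (is.na(dropout_rate) || dropout_rate < 0 || dropout_rate > 1) {
    abort("`dropout_rate` must be in [0, 1].", class = "trajresp_config_error")
  }
  withr::with_seed(seed, apply_dropout_impl(records, dropout_rate))
}

#' Write / read a cohort as wide-format CSV
#'
#' Missing cells are written as empty fields. The latent class column is
#' excluded unless `include_latent = TRUE`, so analysis stages never see the
#' simulation ground truth by default. A sidecar JSON with the full
#' configuration (including seed) can be written alongside.
#'
#' @param records Cohort tibble.
#' @param path Output CSV path.
#' @param include_latent Keep `latent_class` in the file?
#' @param config Optional [cohort_config()] to record as `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, include_latent = FALSE, config = NULL) {
  out <- records
  if (!include_latent) out$latent_class <- NULL
  readr::write_csv(out, path, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"), progress = FALSE)
}

#' Reshape a cohort to long format
#'
#' One row per patient, week and scale; useful for plotting raw score
#' trajectories.
#'
#' @param records Cohort tibble.
#' @return Tibble with columns `patient_id`, `week`, `scale`, `score`.
#' @export
cohort_long <- function(records) {
  records |>
    dplyr::select("patient_id", dplyr::starts_with("panss_")) |>
    tidyr::pivot_longer(-"patient_id", names_to = c("scale", "week"),
                        names_pattern = "panss_(.*)_w(\\d)", values_to = "score") |>
    dplyr::mutate(week = as.integer(.data$week))
}
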