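#' Sample-size-weighted pooled mean
#'
#' Combines per-group means into the total-column mean: `sum(n*mean)/sum(n)`.
#'
#' @param n group sizes (all positive).
#' @param mean group means.
#' @return The pooled mean.
#' @examples
#' pooled_mean(c(242, 104), c(10.4, 11.5)) # 10.73
#' @export
pooled_mean <- function(n, mean) {
  if (length(n) == 0) abort("`n` must be non-empty.")
  if (any(n <= 0)) abort("all group sizes must be positive.")
  if (length(n) != length(mean)) abort("`n` and `mean` must have equal length.")
  sum(n * mean) / sum(n)
}

#' Pooled standard deviation from group summaries
#'
#' Reconstructs the SD of the combined sample from per-group `(n, mean, sd)`
#' triples, using the n-1 denominator throughout:
#' \deqn{s^2 = \frac{\sum (n_i-1) s_i^2 + \sum n_i (\bar x_i - \bar x)^2}{\sum n_i - 1}.}
#' Used for total columns when the individual values are not available.
#'
#' @param n,mean,sd group sizes, means, and standard deviations.
#' @return The pooled SD.
#' @export
pooled_sd <- function(n, mean, sd) {
  if (any(n <= 1)) abort("pooled_sd needs every group size > 1.")
  grand <- pooled_mean(n, mean)
  sqrt((sum((n - 1) * sd^2) + sum(n * (mean - grand)^2)) / (sum(n) - 1))
}

#' Mean inter-visit interval
#'
#' The average time between two shop visits, computed as the mean follow-up
#' time divided by the mean number of measurements (both restricted to
#' visits above age 8): the ratio of the two summary values, not of
#' per-client intervals.
#'
#' @param followup_mean mean follow-up time in years.
#' @param n_measurements_mean mean number of measurements (> 0).
#' @return Interval in years.
#' @examples
#' mean_intervisit(5.4, 8.9) # 0.607 -> reported 0.61
#' @export
mean_intervisit <- function(followup_mean, n_measurements_mean) {
  if (any(n_measurements_mean <= 0)) {
    abort("`n_measurements_mean` must be positive.")
  }
  followup_mean / n_measurements_mean
}

#' Lead time of the shoe-size spurt over a reference growth spurt
#'
#' @param reference_phv_age age of the reference peak growth velocity (e.g.
#'   sitting height) in years.
#' @param peak_shoe_age age of the peak increase in shoe size in years.
#' @return `reference_phv_age - peak_shoe_age`; positive when the shoe-size
#'   spurt precedes the reference spurt.
#' @examples
#' lead_time(11.7, 10.4) # 1.3
#' @export
lead_time <- function(reference_phv_age, peak_shoe_age) {
  reference_phv_age - peak_shoe_age
}

#' Reference sitting-height peak-growth-velocity ages
#'
#' Dutch reference values for the age of peak growth velocity of sitting
#' height (Gerver & de Bruin): 11.7 (SD 0.8) years in girls and 14.0
#' (SD 0.9) years in boys. Override to compare against another reference
#' population.
#'
#' @param phv_age_mean,phv_age_sd named per-sex means and SDs (years).
#' @return A tibble with columns `sex`, `phv_age_mean`, `phv_age_sd`.
#' @export
reference_growth <- function(phv_age_mean = c(F = 11.7, M = 14.0),
                             phv_age_sd = c(F = 0.8, M = 0.9)) {
  if (any(phv_age_mean <= 8) || any(phv_age_mean >= 18)) {
    abort("reference PHV ages must lie in (8, 18) years.")
  }
  if (any(phv_age_sd <= 0)) abort("reference SDs must be positive.")
  sexes <- names(phv_age_mean)
  tibble::tibble(
    sex = sexes,
    phv_age_mean = unname(phv_age_mean),
    phv_age_sd = unname(phv_age_sd[sexes])
  )
}

#' Literature foot-length growth milestones
#'
#' Reference constants from earlier foot-length studies (peak-growth-velocity
#' and cessation ages in years), kept for side-by-side display only; no
#' computation uses them.
#'
#' @return A tibble with columns `study`, `n_f`, `n_m`, `pgv_f`, `pgv_m`,
#'   `cessation_f`, `cessation_m`.
#' @export
foot_length_literature <- function() {
  tibble::tribble(
    ~study,                ~n_f, ~n_m, ~pgv_f, ~pgv_m, ~cessation_f, ~cessation_m,
    "Anderson et al 1956",   20,   20,   10.5,   12.5,         13.5,         16.0,
    "Cameron et al 1982",    20,   29,   12.3,   13.8,           NA,           NA,
    "Liu et al 1998",       198,  146,   10.4,   12.1,         13.6,         15.6,
    "Welon et al 1979",     215,  121,   10.6,   13.0,           NA,           NA
  )
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
sd_or_na <- function(x) if (length(x) > 1) sd(x) else NA_real_

summarise_group <- function(label, visits, peaks, plateaus, analysis_min_age) {
  per_client <- visits |>
    dplyr::filter(.data$age_years > analysis_min_age) |>
    dplyr::group_by(.data$client_id) |>
    dplyr::summarise(
      followup = {
        a <- .data$age_years
        if (length(a)) max(a) - min(a) else NA_real_
      },
      n_meas = dplyr::n(), .groups = "drop"
    )
  found_peaks <- dplyr::filter(peaks, .data$found)
  found_plat <- dplyr::filter(plateaus, .data$found)
  gaps <- dplyr::inner_join(
    dplyr::select(found_peaks, "client_id", "peak_age"),
    dplyr::select(found_plat, "client_id", "start_age"),
    by = "client_id"
  )
  tibble::tibble(
    group = label,
    n = nrow(per_client),
    followup_mean = mean_or_na(per_client$followup),
    followup_sd = sd_or_na(per_client$followup),
    n_meas_mean = mean_or_na(per_client$n_meas),
    n_meas_sd = sd_or_na(per_client$n_meas),
    intervisit = ifelse(nrow(per_client) > 0,
                        mean_intervisit(mean(per_client$followup),
                                        mean(per_client$n_meas)), NA_real_),
    peak_n = nrow(found_peaks),
    peak_age_mean = mean_or_na(found_peaks$peak_age),
    peak_age_sd = sd_or_na(found_peaks$peak_age),
    velocity_mean = mean_or_na(found_peaks$velocity),
    velocity_sd = sd_or_na(found_peaks$velocity),
    plateau_n = nrow(found_plat),
    plateau_age_mean = mean_or_na(found_plat$start_age),
    plateau_age_sd = sd_or_na(found_plat$start_age),
    plateau_size_mean = mean_or_na(found_plat$plateau_size),
    plateau_size_sd = sd_or_na(found_plat$plateau_size),
    gap_n = nrow(gaps),
    gap_mean = mean_or_na(gaps$start_age - gaps$peak_age),
    gap_sd = sd_or_na(gaps$start_age - gaps$peak_age)
  )
}

#' Cohort summary by sex with pooled totals
#'
#' Aggregates a selected cohort and its detection results into the standard
#' per-sex demographic and outcome table: follow-up and measurement counts
#' above age 8, mean inter-visit interval, peak-increase age and velocity,
#' and plateau age/size (over plateau-found clients only) plus the
#' peak-to-plateau gap (over clients having both). The `total` row pools the
#' individual values across sexes, so its means equal the
#' sample-size-weighted combination of the sex-specific means; SDs use the
#' n-1 denominator. All values are full precision; rounding to the reported
#' number of decimals happens only in the print method.
#'
#' @param cohort the selected visit tibble.
#' @param peaks,plateaus results of [detect_peak()] and [detect_plateau()]
#'   on that cohort.
#' @param analysis_min_age visits at or below this age are excluded from the
#'   follow-up and count columns (default 8).
#' @return A tibble of class `spurt_summary`, one row per sex present plus a
#'   `total` row.
#' @export
summarize_cohort <- function(cohort, peaks, plateaus, analysis_min_age = 8) {
  sexes <- intersect(c("F", "M"), unique(cohort$sex))
  rows <- purrr::map(sexes, function(s) {
    summarise_group(
      s,
      dplyr::filter(cohort, .data$sex == s),
      dplyr::filter(peaks, .data$sex == s),
      dplyr::filter(plateaus, .data$sex == s),
      analysis_min_age
    )
  })
  total <- summarise_group("total", dplyr::filter(cohort, .data$sex %in% sexes),
                           dplyr::filter(peaks, .data$sex %in% sexes),
                           dplyr::filter(plateaus, .data$sex %in% sexes),
                           analysis_min_age)
  out <- dplyr::bind_rows(c(rows, list(total)))
  class(out) <- c("spurt_summary", class(out))
  out
}

#' @export
print.spurt_summary <- function(x, ...) {
  shown <- tibble::as_tibble(x)
  one_dec <- c("followup_mean", "followup_sd", "n_meas_mean", "n_meas_sd",
               "peak_age_mean", "peak_age_sd", "velocity_mean", "velocity_sd",
               "plateau_age_mean", "plateau_age_sd", "plateau_size_mean",
               "plateau_size_sd", "gap_mean", "gap_sd")
  for (col in one_dec) shown[[col]] <- round_half_up(shown[[col]], 1)
  shown$intervisit <- round_half_up(shown$intervisit, 2)
  cat("Cohort summary (reported precision)\n")
  print(shown, width = Inf)
  invisible(x)
}

#' Sensitivity of the peak age to the last-measurement age cutoff
#'
#' Re-runs selection and peak detection for one sex at a series of
#' increasingly strict last-visit age cutoffs, reporting the selected count
#' and the mean detected peak age at each. Because each stricter cutoff
#' selects a subset, `n_selected` is non-increasing in the cutoff; a stable
#' mean peak age across cutoffs indicates the estimate is not driven by the
#' inclusion boundary.
#'
#' @param cohort a full (pre-selection) visit tibble.
#' @param sex `"F"` or `"M"`.
#' @param cutoffs numeric vector of last-age cutoffs (years), each at least
#'   the base cutoff for that sex.
#' @param criteria base [selection_criteria()]; only `min_last_age[sex]` is
#'   varied.
#' @param min_increase,min_age passed to [detect_peak()].
#' @return A tibble with one row per cutoff: `cutoff`, `n_selected`,
#'   `mean_peak_age` (`NA` when no client is selected).
#' @export
sensitivity_analysis <- function(cohort, sex, cutoffs,
                                 criteria = selection_criteria(),
                                 min_increase = 2, min_age = 8) {
  cohort <- dplyr::filter(cohort, .data$sex == .env$sex)
  purrr::map_dfr(cutoffs, function(cutoff) {
    crit <- criteria
    crit$min_last_age[[sex]] <- cutoff
    sel <- select_clients(cohort, crit)
    peaks <- dplyr::filter(detect_peak(sel$cohort, min_increase, min_age),
                           .data$found)
    tibble::tibble(
      cutoff = cutoff,
      n_selected = sum(sel$clients$selected),
      mean_peak_age = mean_or_na(peaks$peak_age)
    )
  })
}
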