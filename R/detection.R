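# Core statistic of the analysis: the "peak increase" is the shortest window
# between two visits in which the recorded shoe size rises by at least
# `min_increase` whole sizes; its midpoint age estimates the age of peak foot
# growth velocity.

peak_one <- function(age, size, min_increase, min_age) {
  empty <- tibble::tibble(
    found = FALSE, reason = NA_character_,
    window_start_age = NA_real_, window_end_age = NA_real_,
    peak_age = NA_real_, size_increase = NA_real_,
    duration = NA_real_, velocity = NA_real_
  )
  keep <- age > min_age
  age <- age[keep]; size <- size[keep]
  n <- length(age)
  if (n < 2) {
    empty$reason <- "insufficient_data"
    return(empty)
  }
  # all ordered pairs i < j with the required increase
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1, from = 2:n)
  inc <- size[j] - size[i]
  ok <- inc >= min_increase
  if (!any(ok)) {
    empty$reason <- "no_qualifying_window"
    return(empty)
  }
  i <- i[ok]; j <- j[ok]; inc <- inc[ok]
  dur <- age[j] - age[i]
  # shortest window; ties -> earliest start age, then largest increase
  best <- order(dur, age[i], -inc)[1]
  tibble::tibble(
    found = TRUE, reason = NA_character_,
    window_start_age = age[i[best]], window_end_age = age[j[best]],
    peak_age = (age[i[best]] + age[j[best]]) / 2,
    size_increase = inc[best], duration = dur[best],
    velocity = inc[best] / dur[best]
  )
}

#' Detect the peak increase in shoe size
#'
#' For each client, searches all ordered visit pairs with both ages strictly
#' above `min_age` for those whose size difference reaches `min_increase`
#' (two whole sizes by default; the threshold is inclusive, since the
#' half-size grid makes exactly 2.0 attainable) and returns the pair with the
#' shortest duration. Ties are broken by the earliest start age, then by the
#' largest increase. The peak age is the midpoint of the window and the
#' velocity is the *observed* increase divided by the duration (so it can
#' exceed `min_increase` per year).
#'
#' @param cohort a visit tibble in the [read_cohort()] schema (one or many
#'   clients).
#' @param min_increase required size increase within the window (EU sizes).
#' @param min_age visits at or below this age are excluded from the search
#'   (default 8, guarding against "false" pre-pubertal spurts).
#' @return A tibble with one row per client: `client_id`, `sex`, `found`,
#'   `reason`, `window_start_age`, `window_end_age`, `peak_age`,
#'   `size_increase`, `duration`, `velocity`.
#' @export
detect_peak <- function(cohort, min_increase = 2, min_age = 8) {
  if (nrow(cohort) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(client_id = character(), sex = character()),
      peak_one(numeric(), numeric(), min_increase, min_age)[0, ]
    ))
  }
  cohort |>
    dplyr::arrange(.data$client_id, .data$age_years) |>
    dplyr::group_by(.data$client_id, .data$sex) |>
    dplyr::reframe(peak_one(.data$age_years, .data$size, min_increase, min_age)) |>
    tibble::as_tibble()
}

# a series with any single-step decrease larger than `max_decrease` is
# suspect (measurement or data-entry error); stands in for a visual outlier
# check
suspect_decrease <- function(size, max_decrease = 1) {
  length(size) > 1 && any(diff(size) < -max_decrease)
}

plateau_one <- function(age, size, peak_age, min_duration, tol) {
  empty <- tibble::tibble(
    found = FALSE, reason = NA_character_,
    start_age = NA_real_, end_age = NA_real_, plateau_size = NA_real_,
    duration = NA_real_, resumed_growth = NA
  )
  if (is.na(peak_age)) {
    empty$reason <- "no_peak"
    return(empty)
  }
  keep <- age > peak_age
  age <- age[keep]; size <- size[keep]
  n <- length(age)
  if (n == 0) {
    empty$reason <- "no_post_peak_data"
    return(empty)
  }
  # maximal runs in which no size exceeds the run's first size + tol
  k <- 1L
  while (k <= n) {
    end <- k
    while (end < n && size[end + 1L] <= size[k] + tol) end <- end + 1L
    if (age[end] - age[k] >= min_duration) {
      return(tibble::tibble(
        found = TRUE, reason = NA_character_,
        start_age = age[k], end_age = age[end], plateau_size = size[k],
        duration = age[end] - age[k],
        resumed_growth = end < n && any(size[(end + 1L):n] > size[k] + tol)
      ))
    }
    k <- end + 1L
  }
  empty$reason <- "no_qualifying_plateau"
  empty
}

#' Detect the terminal plateau phase
#'
#' Scans each client's visits strictly after their peak age for the earliest
#' maximal run in which the shoe size never exceeds the run's first size
#' (plus `tol`) and which lasts at least `min_duration` years. Short or
#' pre-peak flat stretches are thereby excluded. `resumed_growth` records
#' whether any visit after the run exceeds the plateau size -- a later
#' "second" growth episode, reported rather than silently resolved.
#'
#' Series containing a single-step size *decrease* larger than
#' `max_decrease` are treated as suspect records and excluded from plateau
#' analysis by default (`reason = "suspect_series"`).
#'
#' @param cohort a visit tibble in the [read_cohort()] schema.
#' @param peaks the result of [detect_peak()] on the same cohort (supplies
#'   each client's `peak_age`).
#' @param min_duration minimum plateau length in years (default 1).
#' @param tol size tolerance defining "no further increase" (default 0 on
#'   the recorded grid; 0.25 is a reasonable choice for averaged-feet
#'   series).
#' @param exclude_suspect drop clients whose series has a step decrease
#'   larger than `max_decrease`?
#' @param max_decrease threshold for the suspect-series flag (EU sizes).
#' @return A tibble with one row per client with a found peak: `client_id`,
#'   `sex`, `found`, `reason`, `start_age`, `end_age`, `plateau_size`,
#'   `duration`, `resumed_growth`.
#' @export
detect_plateau <- function(cohort, peaks, min_duration = 1, tol = 0,
                           exclude_suspect = TRUE, max_decrease = 1) {
  if (nrow(cohort) == 0 || nrow(peaks) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(client_id = character(), sex = character()),
      plateau_one(numeric(), numeric(), NA_real_, min_duration, tol)[0, ]
    ))
  }
  cohort <- dplyr::arrange(cohort, .data$client_id, .data$age_years)
  peak_age <- setNames(peaks$peak_age, peaks$client_id)
  cohort |>
    dplyr::semi_join(peaks, by = "client_id") |>
    dplyr::group_by(.data$client_id, .data$sex) |>
    dplyr::reframe({
      res <- if (exclude_suspect && suspect_decrease(.data$size, max_decrease)) {
        tibble::tibble(
          found = FALSE, reason = "suspect_series",
          start_age = NA_real_, end_age = NA_real_, plateau_size = NA_real_,
          duration = NA_real_, resumed_growth = NA
        )
      } else {
        plateau_one(.data$age_years, .data$size,
                    peak_age[[.data$client_id[1]]], min_duration, tol)
      }
      res
    }) |>
    tibble::as_tibble()
}
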