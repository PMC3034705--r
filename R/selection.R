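#' Cohort inclusion criteria
#'
#' A client is retained when, among visits strictly above `analysis_min_age`,
#' there are at least `min_visits_after_8` measurements spanning strictly
#' more than `min_followup_years`, and the client's last visit falls strictly
#' above the per-sex `min_last_age`. All comparisons are strict: "more than 4
#' measurements above the age of 8" means a count of 5 or more, and a visit
#' at exactly age 8.0 does not qualify.
#'
#' @param min_visits_after_8 minimum number of visits above
#'   `analysis_min_age` (default 5, i.e. "more than 4").
#' @param min_followup_years minimum follow-up span in years (strict `>`).
#' @param min_last_age per-sex minimum age of the last visit,
#'   `c(F = 12, M = 13)`.
#' @param analysis_min_age visits at or below this age are ignored by the
#'   count and follow-up criteria (default 8).
#' @param followup_over whether follow-up spans visits above
#'   `analysis_min_age` (`"after_min_age"`, default) or all visits (`"all"`).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_visits_after_8 = 5L,
                               min_followup_years = 2,
                               min_last_age = c(F = 12, M = 13),
                               analysis_min_age = 8,
                               followup_over = c("after_min_age", "all")) {
  followup_over <- match.arg(followup_over)
  if (min_visits_after_8 < 2) abort("`min_visits_after_8` must be >= 2.")
  if (min_followup_years <= 0) abort("`min_followup_years` must be positive.")
  if (any(min_last_age < analysis_min_age)) {
    abort("`min_last_age` must be >= `analysis_min_age`.")
  }
  structure(
    list(min_visits_after_8 = as.integer(min_visits_after_8),
         min_followup_years = min_followup_years,
         min_last_age = min_last_age,
         analysis_min_age = analysis_min_age,
         followup_over = followup_over),
    class = "selection_criteria"
  )
}

#' Apply the inclusion criteria to a cohort
#'
#' Evaluates [selection_criteria()] client by client. Criteria are checked in
#' a fixed order (sex code, visit count, follow-up span, last-visit age) and
#' each excluded client records the *first* failing criterion, so exclusion
#' reasons partition the excluded set reproducibly.
#'
#' @param cohort a visit tibble in the [read_cohort()] schema.
#' @param criteria a [selection_criteria()] object.
#' @return A list of class `spurt_selection`:
#' \describe{
#'   \item{cohort}{visit rows of the selected clients only;}
#'   \item{clients}{one row per client with `selected` and
#'     `exclusion_reason` (`NA` for selected clients);}
#'   \item{report}{per-sex and total counts with attrition percentages.}
#' }
#' @export
select_clients <- function(cohort, criteria = selection_criteria()) {
  amin <- criteria$analysis_min_age
  per_client <- cohort |>
    dplyr::group_by(.data$client_id, .data$sex) |>
    dplyr::summarise(
      n_after_min = sum(.data$age_years > amin),
      followup = {
        a <- if (criteria$followup_over == "all") .data$age_years
             else .data$age_years[.data$age_years > amin]
        if (length(a) > 1) max(a) - min(a) else 0
      },
      last_age = max(.data$age_years),
      .groups = "drop"
    )

  reason_for <- function(sex, n_after_min, followup, last_age) {
    if (!sex %in% names(criteria$min_last_age)) return("invalid_sex")
    if (n_after_min < criteria$min_visits_after_8) return("too_few_visits")
    if (!(followup > criteria$min_followup_years)) return("short_followup")
    if (!(last_age > criteria$min_last_age[[sex]])) return("last_age_too_low")
    NA_character_
  }
  per_client$exclusion_reason <- purrr::pmap_chr(
    per_client[c("sex", "n_after_min", "followup", "last_age")], reason_for
  )
  per_client$selected <- is.na(per_client$exclusion_reason)

  report <- per_client |>
    dplyr::mutate(sex = ifelse(.data$sex %in% c("F", "M"), .data$sex, "other")) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(n_initial = dplyr::n(), n_selected = sum(.data$selected),
                     .groups = "drop") |>
    dplyr::mutate(attrition_pct = ifelse(
      .data$n_initial > 0,
      round_half_up(100 * (.data$n_initial - .data$n_selected) / .data$n_initial),
      NA_real_
    ))

  structure(
    list(
      cohort = dplyr::semi_join(cohort,
                                dplyr::filter(per_client, .data$selected),
                                by = "client_id"),
      clients = dplyr::select(per_client, "client_id", "sex", "n_after_min",
                              "followup", "last_age", "selected",
                              "exclusion_reason"),
      report = report,
      criteria = criteria
    ),
    class = "spurt_selection"
  )
}

#' Attrition of a cohort under selection
#'
#' @param n_initial,n_selected client counts before and after selection.
#' @return Percentage of the initial cohort removed, rounded half-up to an
#'   integer percent.
#' @examples
#' attrition_percent(636, 242) # 62
#' @export
attrition_percent <- function(n_initial, n_selected) {
  if (any(n_initial <= 0)) abort("`n_initial` must be positive.")
  if (any(n_selected < 0) || any(n_selected > n_initial)) {
    abort("`n_selected` must lie in [0, n_initial].")
  }
  round_half_up(100 * (n_initial - n_selected) / n_initial)
}

#' @export
print.spurt_selection <- function(x, ...) {
  cat("Cohort selection\n")
  print(x$report)
  invisible(x)
}
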