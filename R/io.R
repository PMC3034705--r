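#' Decimal age at a visit
#'
#' Age is computed as the exact number of calendar days between the birth date
#' and the visit date, divided by 365.25. No rounding is applied, so the value
#' is deterministic and leap-year-safe.
#'
#' @param birth_date,visit_date `Date` vectors (or strings coercible with
#'   [as.Date()]), recycled to a common length.
#' @return A numeric vector of ages in years.
#' @examples
#' compute_age("2000-01-01", "2010-01-01")
#' @export
compute_age <- function(birth_date, visit_date) {
  birth_date <- as.Date(birth_date)
  visit_date <- as.Date(visit_date)
  if (anyNA(birth_date) || anyNA(visit_date)) {
    abort("`birth_date` and `visit_date` must be parseable dates.")
  }
  days <- as.numeric(visit_date - birth_date)
  if (any(days < 0)) {
    abort("visit_date precedes birth_date for at least one record.")
  }
  days / 365.25
}

#' Average the two feet of one measurement
#'
#' Shoe shops record each foot to the nearest EU half-size; the analysed size
#' is the arithmetic mean of both feet, kept at quarter-size resolution
#' (never re-rounded to the half-size grid).
#'
#' @param size_left,size_right numeric vectors of EU sizes on the 0.5 grid.
#' @return The unrounded mean of the two feet (0.25-grid values possible).
#' @examples
#' average_feet(38, 38.5)
#' @export
average_feet <- function(size_left, size_right) {
  if (!all(on_grid(size_left)) || !all(on_grid(size_right))) {
    abort("foot sizes must lie on the EU half-size (0.5) grid.")
  }
  (size_left + size_right) / 2
}

cohort_columns <- c("client_id", "sex", "birth_date", "visit_date")

new_issue <- function(row, client_id, field, issue, value = NA_character_) {
  tibble::tibble(
    row = as.integer(row), client_id = as.character(client_id),
    field = field, issue = issue, value = as.character(value)
  )
}

#' Read a longitudinal shoe-size cohort file
#'
#' Reads a delimited text file of visit records (one row per shop visit) into
#' a tidy visit table, one row per retained visit, ordered by client and visit
#' date. The file must carry a header with columns
#' `client_id, sex, birth_date, visit_date` and either both `size_left` and
#' `size_right` or a single pre-averaged `size` column. Dates are ISO-8601.
#'
#' Malformed rows (unparseable dates or sizes, off-grid sizes, visits dated
#' before birth) are reported as validation issues, never silently dropped;
#' duplicate rows for the same client and date are collapsed to the one with
#' the larger size. A left/right difference above 2 EU sizes is flagged as a
#' suspect record but the row is kept. Retrieve the issue log with
#' [validation_issues()].
#'
#' @param path path to a UTF-8 delimited file (comma default, tab accepted).
#' @param delim field delimiter; `NULL` (default) sniffs `\t` vs `,` from the
#'   header line.
#' @return A tibble with columns `client_id`, `sex`, `birth_date`,
#'   `visit_date`, `size_left`, `size_right`, `size`, `age_years`, carrying
#'   the issue log in the `"issues"` attribute.
#' @seealso [write_cohort()], [validation_issues()]
#' @export
read_cohort <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE, trim_ws = TRUE
  )
  for (col in cohort_columns) {
    if (!col %in% names(raw)) {
      abort(paste0("required column `", col, "` is missing from ", path))
    }
  }
  has_feet <- all(c("size_left", "size_right") %in% names(raw))
  if (!has_feet && !"size" %in% names(raw)) {
    abort(paste0("required column `size` (or `size_left`/`size_right`) is missing from ", path))
  }

  issues <- list()
  n <- nrow(raw)
  if (n == 0L) {
    out <- tibble::tibble(
      client_id = character(), sex = character(),
      birth_date = as.Date(character()), visit_date = as.Date(character()),
      size_left = numeric(), size_right = numeric(),
      size = numeric(), age_years = numeric()
    )
    attr(out, "issues") <- new_issue(integer(), character(), character(), character())[0, ]
    return(out)
  }

  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  parse_num <- function(x) suppressWarnings(as.numeric(x))

  d <- tibble::tibble(
    row = seq_len(n),
    client_id = raw$client_id,
    sex = raw$sex,
    birth_date = parse_date(raw$birth_date),
    visit_date = parse_date(raw$visit_date)
  )
  if (has_feet) {
    d$size_left <- parse_num(raw$size_left)
    d$size_right <- parse_num(raw$size_right)
  } else {
    d$size_left <- NA_real_
    d$size_right <- NA_real_
    d$size_single <- parse_num(raw$size)
  }

  bad <- logical(n)
  flag <- function(cond, field, issue, value) {
    cond <- which(cond & !bad)
    if (length(cond)) {
      issues[[length(issues) + 1L]] <<-
        new_issue(cond, d$client_id[cond], field, issue, value[cond])
      bad[cond] <<- TRUE
    }
  }

  flag(is.na(d$birth_date), "birth_date", "unparseable_date", raw$birth_date)
  flag(is.na(d$visit_date), "visit_date", "unparseable_date", raw$visit_date)
  if (has_feet) {
    flag(is.na(d$size_left), "size_left", "unparseable_size", raw$size_left)
    flag(is.na(d$size_right), "size_right", "unparseable_size", raw$size_right)
    flag(!is.na(d$size_left) & !on_grid(d$size_left), "size_left", "size_off_grid", raw$size_left)
    flag(!is.na(d$size_right) & !on_grid(d$size_right), "size_right", "size_off_grid", raw$size_right)
  } else {
    flag(is.na(d$size_single), "size", "unparseable_size", raw$size)
    flag(!is.na(d$size_single) & !on_grid(d$size_single, step = 0.25), "size",
         "size_off_grid", raw$size)
  }
  flag(!bad & d$visit_date < d$birth_date, "visit_date", "visit_before_birth",
       raw$visit_date)

  d <- d[!bad, , drop = FALSE]

  if (has_feet) {
    asym <- which(abs(d$size_left - d$size_right) > 2)
    if (length(asym)) {
      issues[[length(issues) + 1L]] <- new_issue(
        d$row[asym], d$client_id[asym], "size_right", "foot_asymmetry_gt_2",
        paste0(d$size_left[asym], "/", d$size_right[asym])
      )
    }
    d$size <- average_feet(d$size_left, d$size_right)
  } else {
    d$size <- d$size_single
    d$size_single <- NULL
  }

  # duplicate (client, date) rows collapse to the larger size, logged
  d <- dplyr::arrange(d, .data$client_id, .data$visit_date,
                      dplyr::desc(.data$size), .data$row)
  dup <- duplicated(d[, c("client_id", "visit_date")])
  if (any(dup)) {
    issues[[length(issues) + 1L]] <- new_issue(
      d$row[dup], d$client_id[dup], "visit_date", "duplicate_visit",
      as.character(d$visit_date[dup])
    )
    d <- d[!dup, , drop = FALSE]
  }

  d$age_years <- compute_age(d$birth_date, d$visit_date)
  out <- dplyr::select(
    d, "client_id", "sex", "birth_date", "visit_date",
    "size_left", "size_right", "size", "age_years"
  )
  issue_log <- if (length(issues)) {
    dplyr::arrange(dplyr::bind_rows(issues), .data$row)
  } else {
    new_issue(integer(), character(), character(), character())[0, ]
  }
  attr(out, "issues") <- issue_log
  out
}

#' Validation issues attached to a cohort read
#'
#' @param cohort a visit table returned by [read_cohort()].
#' @return A tibble with columns `row`, `client_id`, `field`, `issue`,
#'   `value`; zero rows when the file was clean.
#' @export
validation_issues <- function(cohort) {
  iss <- attr(cohort, "issues")
  if (is.null(iss)) {
    iss <- new_issue(integer(), character(), character(), character())[0, ]
  }
  iss
}

#' Write a cohort visit table to a delimited file
#'
#' Inverse of [read_cohort()]: the file it produces reads back to the same
#' visit table (dates, sizes and ordering preserved). When per-foot columns
#' are all missing, a single pre-averaged `size` column is written instead.
#'
#' @param cohort a visit table as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  out <- dplyr::arrange(cohort, .data$client_id, .data$visit_date)
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  keep <- if (all(is.na(out$size_left))) {
    c("client_id", "sex", "birth_date", "visit_date", "size")
  } else {
    c("client_id", "sex", "birth_date", "visit_date", "size_left", "size_right")
  }
  readr::write_delim(out[keep], path, delim = delim, progress = FALSE)
  invisible(path)
}
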