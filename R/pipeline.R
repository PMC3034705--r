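#' Run the full shoe-size growth-spurt analysis on a cohort
#'
#' Composes the pipeline in memory: selection ([select_clients()]) ->
#' peak-increase detection ([detect_peak()]) -> plateau detection
#' ([detect_plateau()]) -> per-sex summary ([summarize_cohort()]) -> lead
#' times against a reference growth table ([reference_growth()]).
#'
#' @param cohort a visit tibble in the [read_cohort()] schema.
#' @param criteria a [selection_criteria()] object.
#' @param reference a [reference_growth()] tibble.
#' @param min_increase,min_age peak-detection thresholds, see
#'   [detect_peak()].
#' @param plateau_min_duration,plateau_tol plateau thresholds, see
#'   [detect_plateau()].
#' @return An object of class `spurt_analysis` with elements `selection`,
#'   `peaks`, `plateaus`, `summary`, `lead_times`, and the settings used.
#'   Use [tidy()] for per-client results, [glance()] for the one-row cohort
#'   overview, and [autoplot()] for a peak-age histogram.
#' @export
analyze_cohort <- function(cohort,
                           criteria = selection_criteria(),
                           reference = reference_growth(),
                           min_increase = 2, min_age = 8,
                           plateau_min_duration = 1, plateau_tol = 0) {
  selection <- select_clients(cohort, criteria)
  peaks <- detect_peak(selection$cohort, min_increase, min_age)
  plateaus <- detect_plateau(selection$cohort, peaks,
                             min_duration = plateau_min_duration,
                             tol = plateau_tol)
  summary <- summarize_cohort(selection$cohort, peaks, plateaus,
                              analysis_min_age = criteria$analysis_min_age)
  lead_times <- summary |>
    dplyr::filter(.data$group %in% c("F", "M")) |>
    dplyr::transmute(sex = .data$group, peak_age_mean = .data$peak_age_mean) |>
    dplyr::inner_join(reference, by = "sex") |>
    dplyr::mutate(lead_time = lead_time(.data$phv_age_mean, .data$peak_age_mean))
  structure(
    list(selection = selection, peaks = peaks, plateaus = plateaus,
         summary = summary, lead_times = lead_times,
         settings = list(criteria = criteria, min_increase = min_increase,
                         min_age = min_age,
                         plateau_min_duration = plateau_min_duration,
                         plateau_tol = plateau_tol)),
    class = "spurt_analysis"
  )
}

#' @export
print.spurt_analysis <- function(x, ...) {
  cat("Shoe-size growth-spurt analysis\n")
  rep <- x$selection$report
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %s: %d of %d clients selected (attrition %d%%)\n",
                rep$sex[i], rep$n_selected[i], rep$n_initial[i],
                as.integer(rep$attrition_pct[i])))
  }
  print(x$summary)
  cat("Lead time vs reference sitting-height PHV:\n")
  lt <- x$lead_times
  for (i in seq_len(nrow(lt))) {
    cat(sprintf("  %s: peak shoe age %.1f, reference %.1f -> lead %.1f years\n",
                lt$sex[i], round_half_up(lt$peak_age_mean[i], 1),
                lt$phv_age_mean[i], round_half_up(lt$lead_time[i], 1)))
  }
  invisible(x)
}

#' Tidy per-client results of a growth-spurt analysis
#'
#' @param x a `spurt_analysis` object.
#' @param ... unused.
#' @return A tibble with one row per selected client joining the peak and
#'   plateau results.
#' @export
tidy.spurt_analysis <- function(x, ...) {
  dplyr::full_join(
    dplyr::rename(x$peaks, peak_found = "found", peak_reason = "reason"),
    x$plateaus |>
      dplyr::select(-"sex") |>
      dplyr::rename(plateau_found = "found", plateau_reason = "reason",
                    plateau_start_age = "start_age",
                    plateau_end_age = "end_age",
                    plateau_duration = "duration"),
    by = "client_id"
  )
}

#' One-row overview of a growth-spurt analysis
#'
#' @param x a `spurt_analysis` object.
#' @param ... unused.
#' @return A one-row tibble: selected n per sex, mean peak ages and
#'   velocities, plateau counts, and lead times.
#' @export
glance.spurt_analysis <- function(x, ...) {
  g <- function(sex, col) {
    v <- x$summary[[col]][x$summary$group == sex]
    if (length(v)) v else NA_real_
  }
  lt <- function(sex) {
    v <- x$lead_times$lead_time[x$lead_times$sex == sex]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    n_f = g("F", "n"), n_m = g("M", "n"),
    peak_age_f = g("F", "peak_age_mean"), peak_age_m = g("M", "peak_age_mean"),
    velocity_f = g("F", "velocity_mean"), velocity_m = g("M", "velocity_mean"),
    plateau_n_f = g("F", "plateau_n"), plateau_n_m = g("M", "plateau_n"),
    lead_time_f = lt("F"), lead_time_m = lt("M")
  )
}

#' @export
autoplot.spurt_analysis <- function(object, binwidth = 0.5, ...) {
  found <- dplyr::filter(object$peaks, .data$found)
  ggplot2::ggplot(found, ggplot2::aes(x = .data$peak_age, fill = .data$sex)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6, boundary = 0) +
    ggplot2::geom_vline(
      data = object$lead_times,
      ggplot2::aes(xintercept = .data$phv_age_mean, colour = .data$sex),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "age at peak increase in shoe size (years)", y = "clients",
      title = "Detected peak-increase ages",
      subtitle = "dashed: reference sitting-height PHV age"
    )
}

#' Growth curve of one client with detection annotations
#'
#' Plots a client's recorded shoe size against age, marking the peak-increase
#' window (dotted), its midpoint age (solid), and the detected plateau
#' (shaded), in the style of a per-client chart review.
#'
#' @param cohort a visit tibble.
#' @param client_id the client to plot.
#' @param peaks,plateaus optional [detect_peak()]/[detect_plateau()] results;
#'   computed on the fly when missing.
#' @return A ggplot object.
#' @export
plot_client <- function(cohort, client_id, peaks = NULL, plateaus = NULL) {
  visits <- dplyr::filter(cohort, .data$client_id == .env$client_id)
  if (nrow(visits) == 0) abort(paste0("no visits for client ", client_id))
  if (is.null(peaks)) peaks <- detect_peak(visits)
  if (is.null(plateaus)) plateaus <- detect_plateau(visits, peaks)
  pk <- dplyr::filter(peaks, .data$client_id == .env$client_id, .data$found)
  pl <- dplyr::filter(plateaus, .data$client_id == .env$client_id, .data$found)
  p <- ggplot2::ggplot(visits, ggplot2::aes(x = .data$age_years, y = .data$size)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::labs(x = "age (years)", y = "shoe size (EU)",
                  title = paste("Client", client_id))
  if (nrow(pk)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(pk$window_start_age, pk$window_end_age),
                          linetype = "dotted") +
      ggplot2::geom_vline(xintercept = pk$peak_age, linewidth = 1)
  }
  if (nrow(pl)) {
    p <- p + ggplot2::annotate("rect", xmin = pl$start_age, xmax = pl$end_age,
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

# 32-bit FNV-1a hash of a string; used to stamp outputs with a config digest.
# Arithmetic stays below 2^53 by splitting the state into 16-bit halves.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_digest <- function(settings) {
  fnv1a32(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

write_stamped <- function(df, path, stamp) {
  writeLines(stamp, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline from files to files
#'
#' Reads a cohort file, applies selection and detection, and writes the
#' per-client results, the selection report, the cohort summary, the
#' sensitivity table, and a `run_info.json` with the settings, seed, and
#' per-stage counts to `output_dir`. Every CSV begins with a comment line
#' embedding the seed and a digest of the settings, so outputs are traceable
#' to their configuration; [read_cohort()] and `readr::read_csv(comment =
#' "#")` skip it. Given the same input and seed the outputs are
#' byte-identical (the analysis itself is deterministic; the seed is recorded
#' for provenance and for simulated inputs).
#'
#' @param input path to a cohort file in the [read_cohort()] schema.
#' @param output_dir directory for the result files (created if needed).
#' @param criteria,reference,min_increase,min_age,plateau_min_duration,plateau_tol
#'   passed to [analyze_cohort()].
#' @param sensitivity_cutoffs named list of last-age cutoff vectors per sex
#'   for [sensitivity_analysis()]; `NULL` skips it.
#' @param seed integer recorded in every output header.
#' @param max_issues abort when the input file produces more validation
#'   issues than this.
#' @return The `spurt_analysis` object, invisibly.
#' @export
run_pipeline <- function(input, output_dir,
                         criteria = selection_criteria(),
                         reference = reference_growth(),
                         min_increase = 2, min_age = 8,
                         plateau_min_duration = 1, plateau_tol = 0,
                         sensitivity_cutoffs = list(F = c(12, 13, 14),
                                                    M = c(13, 14, 15)),
                         seed = 1L, max_issues = 1000L) {
  cohort <- read_cohort(input)
  issues <- validation_issues(cohort)
  if (nrow(issues) > max_issues) {
    abort(paste0("input produced ", nrow(issues),
                 " validation issues (cap ", max_issues, "); aborting."))
  }
  if (nrow(cohort) == 0) abort("input contains no usable visit records.")

  ana <- analyze_cohort(cohort, criteria = criteria, reference = reference,
                        min_increase = min_increase, min_age = min_age,
                        plateau_min_duration = plateau_min_duration,
                        plateau_tol = plateau_tol)
  if (nrow(ana$selection$cohort) == 0) {
    abort("no clients pass the selection criteria; nothing to analyse.")
  }

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  settings <- c(ana$settings, list(reference = reference, seed = seed))
  stamp <- paste0("# seed=", seed, " config=", config_digest(settings))

  write_stamped(tidy(ana), file.path(output_dir, "per_client_results.csv"), stamp)
  write_stamped(ana$selection$clients,
                file.path(output_dir, "selection_clients.csv"), stamp)
  write_stamped(ana$selection$report,
                file.path(output_dir, "selection_report.csv"), stamp)
  write_stamped(tibble::as_tibble(ana$summary),
                file.path(output_dir, "cohort_summary.csv"), stamp)
  write_stamped(ana$lead_times, file.path(output_dir, "lead_times.csv"), stamp)

  sens <- NULL
  if (!is.null(sensitivity_cutoffs)) {
    sens <- purrr::imap_dfr(sensitivity_cutoffs, function(cuts, s) {
      dplyr::mutate(
        sensitivity_analysis(cohort, s, cuts, criteria, min_increase, min_age),
        sex = s, .before = 1
      )
    })
    write_stamped(sens, file.path(output_dir, "sensitivity.csv"), stamp)
  }
  if (nrow(issues)) {
    write_stamped(issues, file.path(output_dir, "validation_issues.csv"), stamp)
  }

  counts <- ana$selection$report
  info <- list(
    seed = seed, config_digest = config_digest(settings), settings = settings,
    stages = list(
      visits_read = nrow(cohort), validation_issues = nrow(issues),
      clients_initial = sum(counts$n_initial),
      clients_selected = sum(counts$n_selected),
      clients_excluded = sum(counts$n_initial) - sum(counts$n_selected),
      peaks_found = sum(ana$peaks$found),
      plateaus_found = sum(ana$plateaus$found)
    )
  )
  jsonlite::write_json(info, file.path(output_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  message(sprintf(
    "pipeline: %d visits -> %d/%d clients selected -> %d peaks, %d plateaus",
    info$stages$visits_read, info$stages$clients_selected,
    info$stages$clients_initial, info$stages$peaks_found,
    info$stages$plateaus_found
  ))
  invisible(ana)
}
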