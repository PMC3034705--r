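worked <- make_visits(
  ages = c(8.0, 8.6, 9.1, 9.8, 10.5, 11.2, 12.3),
  sizes = c(32, 32.5, 33.5, 35, 36, 36.5, 37)
)

test_that("the shortest two-size window is found with its midpoint age", {
  pk <- detect_peak(worked)
  expect_true(pk$found)
  expect_equal(pk$window_start_age, 8.6)
  expect_equal(pk$window_end_age, 9.8)
  expect_equal(pk$peak_age, 9.2)
  expect_equal(pk$size_increase, 2.5)
  expect_equal(pk$duration, 1.2)
  expect_equal(pk$velocity, 2.5 / 1.2)
})

test_that("ties go to the earliest window under uniform growth", {
  uniform <- make_visits(c(9, 10, 11, 12), c(30, 31, 32, 33))
  pk <- detect_peak(uniform)
  expect_equal(pk$window_start_age, 9)
  expect_equal(pk$window_end_age, 11)
  expect_equal(pk$peak_age, 10)
  expect_equal(pk$velocity, 1)
})

test_that("series that never rise two sizes yield no peak", {
  flat <- make_visits(c(9, 10, 11, 12), c(30, 30.5, 31, 31.5))
  pk <- detect_peak(flat)
  expect_false(pk$found)
  expect_identical(pk$reason, "no_qualifying_window")
  # fewer than two visits above the age floor
  young <- make_visits(c(5, 6, 7, 9), c(25, 27, 29, 31))
  expect_identical(detect_peak(young)$reason, "insufficient_data")
})

test_that("only visit pairs with both ages above the floor are searched", {
  # the 2-size rise from age 8.0 would be the shortest window if age 8.0
  # were eligible; it is not, so the later window wins
  v <- make_visits(c(8.0, 9.5, 10.0, 11.0), c(32, 34, 34.5, 36))
  pk <- detect_peak(v)
  expect_equal(pk$window_start_age, 9.5)
  expect_equal(pk$window_end_age, 11.0)
})

test_that("detect_peak agrees with the exhaustive oracle on random series", {
  set.seed(97)
  for (rep in 1:1000) {
    s <- random_series(sprintf("R%04d", rep))
    got <- detect_peak(s)
    want <- oracle_peak(s$age_years, s$size)
    if (is.null(want)) {
      expect_false(got$found)
    } else {
      expect_true(got$found)
      expect_equal(got$window_start_age, want$window_start_age)
      expect_equal(got$window_end_age, want$window_end_age)
      expect_equal(got$peak_age, want$peak_age)
      expect_equal(got$size_increase, want$size_increase)
      expect_equal(got$velocity, want$velocity)
      # midpoint lies strictly inside the window, at machine precision
      expect_identical(got$peak_age,
                       (got$window_start_age + got$window_end_age) / 2)
      expect_true(got$window_start_age < got$peak_age &&
                  got$peak_age < got$window_end_age)
    }
  }
})

test_that("the earliest long-enough post-peak run is the plateau", {
  v <- make_visits(c(10.5, 11.0, 11.6, 12.1, 12.8, 13.3),
                   c(38, 38.5, 39, 39, 39, 39))
  peaks <- tibble::tibble(client_id = "C1", sex = "F", found = TRUE,
                          peak_age = 10.0)
  pl <- detect_plateau(v, peaks)
  expect_true(pl$found)
  expect_equal(pl$start_age, 11.6)
  expect_equal(pl$plateau_size, 39)
  expect_equal(pl$duration, 1.7, tolerance = 1e-9)
  expect_false(pl$resumed_growth)
})

test_that("short terminal stretches do not qualify", {
  v <- make_visits(c(10.5, 11.2, 12.0, 12.4, 12.9),
                   c(38, 39, 40, 40, 40))
  peaks <- tibble::tibble(client_id = "C1", sex = "F", found = TRUE,
                          peak_age = 10.0)
  pl <- detect_plateau(v, peaks)   # terminal run spans only 0.9 years
  expect_false(pl$found)
  expect_identical(pl$reason, "no_qualifying_plateau")
})

test_that("growth resuming after a long plateau is flagged, not discarded", {
  v <- make_visits(c(12.0, 12.8, 13.5, 14.2, 15.0, 15.3, 15.8, 16.4),
                   c(38, 40, 41, 41, 41, 41, 41.5, 42), sex = "M")
  peaks <- tibble::tibble(client_id = "C1", sex = "M", found = TRUE,
                          peak_age = 12.4)
  pl <- detect_plateau(v, peaks)
  expect_true(pl$found)
  expect_equal(pl$start_age, 13.5)
  expect_equal(pl$end_age, 15.3)
  expect_true(pl$resumed_growth)
})

test_that("pre-peak flat phases are ignored", {
  # flat stretch before the peak, then growth, then a terminal plateau
  v <- make_visits(c(8.5, 9.0, 9.6, 10.4, 11.0, 11.8, 12.6, 13.8),
                   c(33, 33, 33, 35, 36.5, 37, 37, 37))
  pk <- detect_peak(v)
  pl <- detect_plateau(v, pk)
  expect_true(pl$found)
  expect_gt(pl$start_age, pk$peak_age)
  expect_equal(pl$plateau_size, 37)
})

test_that("plateau needs post-peak data and an available peak", {
  v <- make_visits(c(9, 10, 11), c(33, 34, 35))
  no_post <- tibble::tibble(client_id = "C1", sex = "F", found = TRUE,
                            peak_age = 11.5)
  expect_identical(detect_plateau(v, no_post)$reason, "no_post_peak_data")
  no_peak <- tibble::tibble(client_id = "C1", sex = "F", found = FALSE,
                            peak_age = NA_real_)
  expect_identical(detect_plateau(v, no_peak)$reason, "no_peak")
})

test_that("suspect series (step decrease > 1) skip plateau analysis only", {
  v <- make_visits(c(9, 9.7, 10.3, 11.0, 12.0, 13.2),
                   c(33, 35, 36.5, 35, 35, 35))
  pk <- detect_peak(v)
  expect_true(pk$found)   # kept for peak analysis
  pl <- detect_plateau(v, pk)
  expect_false(pl$found)
  expect_identical(pl$reason, "suspect_series")
  pl_keep <- detect_plateau(v, pk, exclude_suspect = FALSE)
  expect_true(pl_keep$found)
})

test_that("a nonzero tolerance absorbs quarter-size wobble", {
  v <- make_visits(c(10.5, 11.2, 12.0, 12.4),
                   c(38, 39, 39.25, 39))
  peaks <- tibble::tibble(client_id = "C1", sex = "F", found = TRUE,
                          peak_age = 10.8)
  expect_false(detect_plateau(v, peaks, tol = 0)$found)
  pl <- detect_plateau(v, peaks, tol = 0.25)
  expect_true(pl$found)
  expect_equal(pl$start_age, 11.2)
})

test_that("found plateaus always start strictly after the peak age", {
  sim <- default_sim()
  ana <- analyze_cohort(sim$cohort)
  both <- dplyr::inner_join(
    dplyr::filter(ana$peaks, found) |> dplyr::select(client_id, peak_age),
    dplyr::filter(ana$plateaus, found) |> dplyr::select(client_id, start_age),
    by = "client_id"
  )
  expect_gt(nrow(both), 0)
  expect_true(all(both$start_age > both$peak_age))
})

test_that("dense noise-free sampling recovers the true peak age", {
  cfg <- generator_config(n = c(F = 80, M = 40), noise_sd = 0,
                          asymmetry_sd = 0, gap_mean = c(F = 0.3, M = 0.3),
                          censor_range = c(14, 17), seed = 9)
  sim <- simulate_cohort(cfg)
  ana <- analyze_cohort(sim$cohort)
  span <- sim$cohort |>
    dplyr::filter(age_years > 8) |>
    dplyr::group_by(client_id) |>
    dplyr::summarise(first = min(age_years), last = max(age_years))
  j <- dplyr::filter(ana$peaks, found) |>
    dplyr::inner_join(sim$truth, by = c("client_id", "sex")) |>
    dplyr::inner_join(span, by = "client_id") |>
    dplyr::filter(first <= true_phv_age - 1, last >= true_phv_age + 1)
  expect_gt(nrow(j), 50)
  expect_gte(mean(abs(j$peak_age - j$true_phv_age) <= 0.7), 0.9)
})
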