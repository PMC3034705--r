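test_that("pooled means reproduce the printed total columns", {
  expect_equal(round(pooled_mean(c(242, 104), c(10.4, 11.5)), 1), 10.7)
  expect_equal(round(pooled_mean(c(138, 36), c(12.1, 13.7)), 1), 12.4)
  expect_equal(pooled_mean(c(5, 3), c(7, 7)), 7)
  expect_error(pooled_mean(numeric(), numeric()), "non-empty")
  expect_error(pooled_mean(c(0, 3), c(1, 2)), "positive")
  expect_error(pooled_mean(c(2, 3), 1), "length")
})

test_that("the pooled mean lies within the range of the group means", {
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    n <- sample(1:200, k, replace = TRUE)
    m <- runif(k, 5, 15)
    p <- pooled_mean(n, m)
    expect_true(p >= min(m) && p <= max(m))
  }
})

test_that("pooled SD matches the SD of the concatenated samples", {
  set.seed(23)
  a <- rnorm(40, 10, 1.5)
  b <- rnorm(25, 13, 2.2)
  got <- pooled_sd(c(40, 25), c(mean(a), mean(b)), c(sd(a), sd(b)))
  expect_equal(got, sd(c(a, b)))
})

test_that("the inter-visit interval is the ratio of the two summary means", {
  expect_equal(round(mean_intervisit(5.4, 8.9), 2), 0.61)
  expect_equal(round(mean_intervisit(6.2, 9.0), 2), 0.69)
  expect_equal(mean_intervisit(3, 1), 3)
  expect_error(mean_intervisit(3, 0), "positive")
})

test_that("lead time is reference minus shoe-size peak age", {
  expect_equal(lead_time(11.7, 10.4), 1.3)
  expect_equal(lead_time(14.0, 11.5), 2.5)
  expect_equal(lead_time(12, 12), 0)
})

test_that("reference growth defaults carry the sitting-height constants", {
  ref <- reference_growth()
  expect_equal(ref$phv_age_mean[ref$sex == "F"], 11.7)
  expect_equal(ref$phv_age_sd[ref$sex == "F"], 0.8)
  expect_equal(ref$phv_age_mean[ref$sex == "M"], 14.0)
  expect_equal(ref$phv_age_sd[ref$sex == "M"], 0.9)
  expect_error(reference_growth(phv_age_mean = c(F = 7, M = 14)), "8, 18")
})

empty_plateaus <- tibble::tibble(
  client_id = character(), sex = character(), found = logical(),
  reason = character(), start_age = numeric(), end_age = numeric(),
  plateau_size = numeric(), duration = numeric(), resumed_growth = logical()
)

test_that("single-client groups report a mean but no SD", {
  v <- make_visits(c(8.5, 9.1, 9.9, 10.6, 11.4, 12.4),
                   c(31, 32, 33, 34, 35, 35.5), client_id = "G1")
  pk <- detect_peak(v)
  s <- summarize_cohort(v, pk, empty_plateaus)
  g <- s[s$group == "F", ]
  expect_identical(g$n, 1L)
  expect_equal(g$peak_age_mean, pk$peak_age)
  expect_true(is.na(g$peak_age_sd))
  expect_identical(g$plateau_n, 0L)
})

test_that("two-client summaries use the n-1 denominator", {
  v1 <- make_visits(c(8.5, 9.0, 9.5, 10.0), c(31, 32, 33, 33.5), client_id = "A")
  v2 <- make_visits(c(10.0, 10.5, 11.5, 12.0), c(33, 34, 35, 35.5), client_id = "B")
  peaks <- tibble::tibble(
    client_id = c("A", "B"), sex = "F", found = TRUE, reason = NA_character_,
    window_start_age = c(8.5, 10.5), window_end_age = c(9.5, 11.5),
    peak_age = c(9, 11), size_increase = c(2, 2), duration = c(1, 1),
    velocity = c(2, 2)
  )
  s <- summarize_cohort(dplyr::bind_rows(v1, v2), peaks, empty_plateaus)
  g <- s[s$group == "F", ]
  expect_equal(g$peak_age_mean, 10)
  expect_equal(g$peak_age_sd, sqrt(2))   # hand arithmetic: sqrt(((9-10)^2+(11-10)^2)/1)
})

test_that("the total row pools the per-sex rows for every mean field", {
  sim <- default_sim()
  ana <- analyze_cohort(sim$cohort)
  s <- ana$summary
  fsex <- s[s$group %in% c("F", "M"), ]
  tot <- s[s$group == "total", ]
  expect_equal(tot$peak_age_mean, pooled_mean(fsex$peak_n, fsex$peak_age_mean))
  expect_equal(tot$velocity_mean, pooled_mean(fsex$peak_n, fsex$velocity_mean))
  expect_equal(tot$followup_mean, pooled_mean(fsex$n, fsex$followup_mean))
  expect_equal(tot$n_meas_mean, pooled_mean(fsex$n, fsex$n_meas_mean))
  expect_equal(tot$plateau_age_mean,
               pooled_mean(fsex$plateau_n, fsex$plateau_age_mean))
  expect_equal(tot$plateau_size_mean,
               pooled_mean(fsex$plateau_n, fsex$plateau_size_mean))
  expect_equal(tot$gap_mean, pooled_mean(fsex$gap_n, fsex$gap_mean))
  expect_identical(tot$n, sum(fsex$n))
  expect_true(all(s$plateau_n <= s$n))
})

test_that("sensitivity rows are idempotent and non-increasing in n", {
  sim <- default_sim()
  dup <- sensitivity_analysis(sim$cohort, "M", c(13, 13))
  expect_identical(dup[1, ], dup[2, ])
  tab <- sensitivity_analysis(sim$cohort, "M", c(13, 14, 15))
  expect_identical(tab$cutoff, c(13, 14, 15))
  expect_true(all(diff(tab$n_selected) <= 0))
  # an impossible cutoff yields an empty row, not an error
  none <- sensitivity_analysis(sim$cohort, "M", 17.5)
  expect_identical(none$n_selected, 0L)
  expect_true(is.na(none$mean_peak_age))
})
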