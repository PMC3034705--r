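# Build a visit tibble from explicit ages and sizes. Visit dates are derived
# from the ages for round-trip tests; `age_years` is set to the given ages
# exactly so detection tests are not perturbed by day rounding.
make_visits <- function(ages, sizes, client_id = "C1", sex = "F",
                        birth_date = as.Date("2000-01-01")) {
  tibble::tibble(
    client_id = client_id, sex = sex, birth_date = birth_date,
    visit_date = birth_date + round(ages * 365.25),
    size_left = NA_real_, size_right = NA_real_,
    size = sizes, age_years = ages
  )
}

# Independent brute-force oracle for the peak-increase statistic: explicit
# double loop, explicit tie-break comparisons. Also asserts the shortness
# guarantee (no qualifying pair is shorter than the winner).
oracle_peak <- function(ages, sizes, min_increase = 2, min_age = 8) {
  keep <- ages > min_age
  ages <- ages[keep]
  sizes <- sizes[keep]
  n <- length(ages)
  best <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sizes[j] - sizes[i] >= min_increase) {
          cand <- list(
            start = ages[i], end = ages[j], dur = ages[j] - ages[i],
            inc = sizes[j] - sizes[i]
          )
          if (is.null(best) ||
              cand$dur < best$dur ||
              (cand$dur == best$dur && cand$start < best$start) ||
              (cand$dur == best$dur && cand$start == best$start &&
               cand$inc > best$inc)) {
            best <- cand
          }
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  # shortness guarantee
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sizes[j] - sizes[i] >= min_increase) {
        stopifnot(ages[j] - ages[i] >= best$dur)
      }
    }
  }
  list(
    window_start_age = best$start, window_end_age = best$end,
    peak_age = (best$start + best$end) / 2,
    size_increase = best$inc, duration = best$dur,
    velocity = best$inc / best$dur
  )
}

# Random quantized series for property tests: irregular ages in [5, 18],
# arbitrary (possibly non-monotone) half-size values.
random_series <- function(id) {
  n <- sample(2:25, 1)
  ages <- sort(runif(n, 5, 18))
  while (any(diff(ages) < 1e-3)) ages <- sort(runif(n, 5, 18))
  sizes <- sample(seq(28, 44, by = 0.5), n, replace = TRUE)
  make_visits(ages, sizes, client_id = id)
}

# Memoized large simulations shared between test files (built once per run).
.sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_cohort(generator_config(seed = 1))
  }
  .sim_cache$default
}

girls500_sim <- function() {
  if (is.null(.sim_cache$girls500)) {
    .sim_cache$girls500 <- simulate_cohort(
      generator_config(n = c(F = 500, M = 0), seed = 5)
    )
  }
  .sim_cache$girls500
}

noisefree_sim <- function() {
  if (is.null(.sim_cache$noisefree)) {
    .sim_cache$noisefree <- simulate_cohort(
      generator_config(noise_sd = 0, asymmetry_sd = 0, seed = 1)
    )
  }
  .sim_cache$noisefree
}
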