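#' Latent growth-curve parameters for one simulated child
#'
#' The latent (unobserved, continuous) foot size is modelled as a
#' double-logistic curve: a slow childhood component plus a faster pubertal
#' component,
#' \deqn{s(t) = C + \frac{A_1}{1+e^{-k_1(t-m_1)}} + \frac{A_2}{1+e^{-k_2(t-m_2)}}.}
#' The pubertal midpoint `m2` is (approximately) the age of peak foot growth
#' velocity and `C + A1 + A2` is the adult shoe size.
#'
#' @param C baseline size (EU sizes).
#' @param A1,k1,m1 childhood amplitude (EU sizes), rate (1/years), midpoint
#'   (years).
#' @param A2,k2,m2 pubertal amplitude, rate, midpoint; `m2 > m1` required.
#' @return A `growth_params` list.
#' @export
growth_params <- function(C, A1, k1, m1, A2, k2, m2) {
  if (A1 <= 0 || A2 <= 0 || k1 <= 0 || k2 <= 0) {
    abort("amplitudes and rates must be positive.")
  }
  if (m2 <= m1) abort("`m2` must exceed `m1`.")
  adult <- C + A1 + A2
  if (adult < 34 || adult > 48) {
    abort("adult latent size C + A1 + A2 must lie in [34, 48].")
  }
  structure(list(C = C, A1 = A1, k1 = k1, m1 = m1, A2 = A2, k2 = k2, m2 = m2),
            class = "growth_params")
}

#' Latent foot size and velocity
#'
#' `latent_size()` evaluates the double-logistic curve of [growth_params()]
#' at ages `t`; it is strictly increasing in `t`. `latent_velocity()` is its
#' analytic first derivative (EU sizes/year).
#'
#' @param params a [growth_params()] object.
#' @param t ages in years (vectorised).
#' @return Numeric vector of sizes (or velocities) at `t`.
#' @export
latent_size <- function(params, t) {
  with(params, C + A1 / (1 + exp(-k1 * (t - m1))) + A2 / (1 + exp(-k2 * (t - m2))))
}

#' @rdname latent_size
#' @export
latent_velocity <- function(params, t) {
  with(params, {
    s1 <- 1 / (1 + exp(-k1 * (t - m1)))
    s2 <- 1 / (1 + exp(-k2 * (t - m2)))
    A1 * k1 * s1 * (1 - s1) + A2 * k2 * s2 * (1 - s2)
  })
}

#' True age of peak foot growth velocity
#'
#' The argmax of [latent_velocity()] over a 0.001-year grid on \[6, 18\] --
#' the simulation ground truth that detection is validated against. With the
#' childhood component saturated this is close to (slightly before) `m2`.
#'
#' @param params a [growth_params()] object.
#' @return Age in years.
#' @export
true_phv <- function(params) {
  grid <- seq(6, 18, by = 0.001)
  grid[which.max(latent_velocity(params, grid))]
}

# first age at which the latent curve is within 0.25 sizes of the adult size
true_cessation <- function(params) {
  adult <- params$C + params$A1 + params$A2
  f <- function(t) latent_size(params, t) - (adult - 0.25)
  uniroot(f, interval = c(0, 200), tol = 1e-8)$root
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a retail shoe-fitting
#' database: per-sex peak-increase ages N(10.4, 1.1) for girls and
#' N(11.5, 1.5) for boys, adult (plateau) sizes N(38.9, 1.5) / N(41.4, 1.8),
#' gamma-distributed inter-visit gaps with means 0.61 / 0.69 years, records
#' starting in infancy, and censoring ages spread over 10--17 years so that
#' the selection criteria produce realistic attrition.
#'
#' @param n named counts of clients per sex, `c(F = ..., M = ...)`.
#' @param phv_age_mean,phv_age_sd per-sex mean/SD (years) of the pubertal
#'   midpoint `m2`.
#' @param adult_size_mean,adult_size_sd per-sex mean/SD (EU sizes) of the
#'   adult latent size.
#' @param noise_sd per-foot, per-visit measurement noise SD (EU sizes).
#' @param asymmetry_sd SD of the per-client left/right foot difference.
#' @param first_visit_range age range (years) of the first visit, sampled
#'   uniformly.
#' @param gap_mean per-sex mean inter-visit gap (years).
#' @param gap_shape gamma shape of the gap distribution; shape 4 keeps gaps
#'   away from zero.
#' @param min_gap smallest admissible gap between visits (years).
#' @param censor_range age range (years) of the uniform censoring (last
#'   observable) age; upper bound must not exceed 18.
#' @param baseline,childhood_amplitude,childhood_rate,childhood_midpoint
#'   centre values of the childhood component (`C`, `A1`, `k1`, `m1`); tuned
#'   so size at age 8 falls around 28--31 EU.
#' @param pubertal_rate_range uniform range for the pubertal rate `k2`
#'   (1/years).
#' @param jitter_sd named SDs of the per-client jitter on `C`, `A1`, `k1`,
#'   `m1`.
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = c(F = 242, M = 104),
                             phv_age_mean = c(F = 10.4, M = 11.5),
                             phv_age_sd = c(F = 1.1, M = 1.5),
                             adult_size_mean = c(F = 38.9, M = 41.4),
                             adult_size_sd = c(F = 1.5, M = 1.8),
                             noise_sd = 0.25,
                             asymmetry_sd = 0.15,
                             first_visit_range = c(1, 3),
                             gap_mean = c(F = 0.61, M = 0.69),
                             gap_shape = 4,
                             min_gap = 0.05,
                             censor_range = c(10, 17),
                             baseline = 16,
                             childhood_amplitude = 14,
                             childhood_rate = 0.45,
                             childhood_midpoint = 3.5,
                             pubertal_rate_range = c(1.1, 1.6),
                             jitter_sd = c(C = 0.5, A1 = 0.5, k1 = 0.05, m1 = 0.3),
                             seed = 1L) {
  cfg <- list(
    n = n, phv_age_mean = phv_age_mean, phv_age_sd = phv_age_sd,
    adult_size_mean = adult_size_mean, adult_size_sd = adult_size_sd,
    noise_sd = noise_sd, asymmetry_sd = asymmetry_sd,
    first_visit_range = first_visit_range, gap_mean = gap_mean,
    gap_shape = gap_shape, min_gap = min_gap, censor_range = censor_range,
    baseline = baseline, childhood_amplitude = childhood_amplitude,
    childhood_rate = childhood_rate, childhood_midpoint = childhood_midpoint,
    pubertal_rate_range = pubertal_rate_range, jitter_sd = jitter_sd,
    seed = as.integer(seed)
  )
  if (any(c(cfg$phv_age_sd, cfg$adult_size_sd, cfg$noise_sd, cfg$asymmetry_sd,
            cfg$jitter_sd) < 0)) {
    abort("all standard deviations must be >= 0.")
  }
  if (any(cfg$gap_mean <= 0)) abort("`gap_mean` must be positive.")
  if (cfg$censor_range[2] > 18) abort("censoring upper bound must be <= 18 years.")
  structure(cfg, class = "generator_config")
}

# deterministic per-client substream: reproducible independently of how many
# draws other clients consume
client_seed <- function(seed, index) {
  (as.numeric(seed) * 1009 + 7919 * index) %% 2147483647
}

rnorm_trunc <- function(mean, sd, lower, upper) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

quantize_half <- function(x) pmin(pmax(round(x * 2) / 2, 14), 50)

draw_growth_params <- function(config, sex) {
  m2 <- rnorm_trunc(config$phv_age_mean[[sex]], config$phv_age_sd[[sex]], 6, 16)
  adult <- rnorm_trunc(config$adult_size_mean[[sex]], config$adult_size_sd[[sex]], 34, 48)
  for (i in 1:100) {
    C <- config$baseline + rnorm(1, 0, config$jitter_sd[["C"]])
    A1 <- config$childhood_amplitude + rnorm(1, 0, config$jitter_sd[["A1"]])
    A2 <- adult - C - A1
    if (A2 >= 1) break
  }
  if (A2 < 1) A2 <- 1   # degenerate draw guard; adult size takes precedence
  k1 <- max(0.2, config$childhood_rate + rnorm(1, 0, config$jitter_sd[["k1"]]))
  m1 <- max(1, config$childhood_midpoint + rnorm(1, 0, config$jitter_sd[["m1"]]))
  k2 <- runif(1, config$pubertal_rate_range[1], config$pubertal_rate_range[2])
  growth_params(C = C, A1 = A1, k1 = k1, m1 = m1, A2 = A2, k2 = k2,
                m2 = max(m2, m1 + 1))
}

generate_client <- function(config, sex, index) {
  set.seed(client_seed(config$seed, index))
  for (attempt in 1:20) {
    params <- draw_growth_params(config, sex)
    first <- runif(1, config$first_visit_range[1], config$first_visit_range[2])
    censor <- runif(1, config$censor_range[1], config$censor_range[2])
    ages <- numeric(0)
    t <- first
    while (t <= censor) {
      ages <- c(ages, t)
      gap <- max(config$min_gap,
                 rgamma(1, shape = config$gap_shape,
                        scale = config$gap_mean[[sex]] / config$gap_shape))
      t <- t + gap
    }
    if (length(ages) >= 1) break
  }
  if (length(ages) == 0) {
    abort("generator produced a client with no visits; check `censor_range`.")
  }

  birth <- as.Date("1985-01-01") + floor(runif(1) * 5113)
  visit_date <- birth + round(ages * 365.25)
  age_years <- compute_age(birth, visit_date)

  asym <- rnorm(1, 0, config$asymmetry_sd)
  latent <- latent_size(params, age_years)
  left <- quantize_half(latent + asym / 2 + rnorm(length(ages), 0, config$noise_sd))
  right <- quantize_half(latent - asym / 2 + rnorm(length(ages), 0, config$noise_sd))

  id <- sprintf("%s%04d", sex, index)
  visits <- tibble::tibble(
    client_id = id, sex = sex, birth_date = birth, visit_date = visit_date,
    size_left = left, size_right = right,
    size = average_feet(left, right), age_years = age_years
  )
  truth <- tibble::tibble(
    client_id = id, sex = sex,
    true_phv_age = true_phv(params),
    true_adult_size = params$C + params$A1 + params$A2,
    true_cessation_age = true_cessation(params)
  )
  list(visits = visits, truth = truth, params = params)
}

#' Simulate a longitudinal shoe-size cohort with ground truth
#'
#' Draws one latent double-logistic growth curve per client, samples an
#' irregular visit schedule (uniform first-visit age, gamma inter-visit gaps,
#' uniform censoring age), and observes each foot with additive noise, a
#' per-client left/right asymmetry, and rounding to the EU half-size grid.
#' Alongside the observed visit table it returns a ground-truth record per
#' client: the true peak-velocity age (grid argmax of the latent velocity),
#' the true adult size, and the true cessation age (first age within 0.25
#' sizes of the adult size).
#'
#' The generator is fully deterministic given `config$seed`; each client uses
#' a substream derived from the seed and the client index.
#'
#' @param config a [generator_config()].
#' @param cohort_file,truth_file optional paths; when supplied, the visit
#'   table and the ground-truth sidecar are also written as delimited text.
#' @return A list of class `spurt_sim` with elements `cohort` (visit tibble
#'   in the [read_cohort()] schema), `truth`, `params` (per-client
#'   [growth_params()], keyed by client id), and `config`.
#' @examples
#' sim <- simulate_cohort(generator_config(n = c(F = 5, M = 5), seed = 42))
#' sim$truth
#' @export
simulate_cohort <- function(config = generator_config(),
                            cohort_file = NULL, truth_file = NULL) {
  sexes <- c(rep("F", config$n[["F"]]), rep("M", config$n[["M"]]))
  clients <- purrr::imap(sexes, function(sex, i) generate_client(config, sex, i))
  empty_visits <- tibble::tibble(
    client_id = character(), sex = character(),
    birth_date = as.Date(character()), visit_date = as.Date(character()),
    size_left = numeric(), size_right = numeric(),
    size = numeric(), age_years = numeric()
  )
  empty_truth <- tibble::tibble(
    client_id = character(), sex = character(), true_phv_age = numeric(),
    true_adult_size = numeric(), true_cessation_age = numeric()
  )
  cohort <- dplyr::bind_rows(empty_visits, purrr::map(clients, "visits"))
  truth <- dplyr::bind_rows(empty_truth, purrr::map(clients, "truth"))
  params <- setNames(purrr::map(clients, "params"), truth$client_id)
  if (!is.null(cohort_file)) write_cohort(cohort, cohort_file)
  if (!is.null(truth_file)) readr::write_csv(truth, truth_file, progress = FALSE)
  structure(list(cohort = cohort, truth = truth, params = params,
                 config = config),
            class = "spurt_sim")
}

#' @export
print.spurt_sim <- function(x, ...) {
  cat("Simulated shoe-size cohort (seed ", x$config$seed, ")\n", sep = "")
  counts <- table(factor(x$truth$sex, levels = c("F", "M")))
  cat("  clients: ", counts[["F"]], " girls, ", counts[["M"]], " boys; ",
      nrow(x$cohort), " visits\n", sep = "")
  invisible(x)
}
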