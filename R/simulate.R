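#' Configuration for the synthetic surveillance cohort
#'
#' Defaults describe an HCV-cirrhosis surveillance population: controls
#' follow a random-intercept model for log2(AFP) with population mean
#' `theta_bar = 2.92`, between-subject variance `tau2 = 1.90` and
#' within-subject variance `sigma2 = 0.71` (intra-class correlation 0.73);
#' visits per patient fall in the categories 1 / 2 / 3-4 / >4 with
#' probabilities 28.5/23.1/26.4/22.0%; inter-visit gaps are gamma with mean
#' 11.67 and SD 11.0 months; concurrent ALT is lognormal around a mean
#' log2 level of 6.14 (SD 1.03) and platelets truncated-normal around
#' 147.97 (SD 78.88) in thousands. Case trajectories follow the control
#' model until a changepoint `d - lead` (lead uniform on
#' `[0, onset_lead_max]`) after which the mean of log2(AFP) rises linearly
#' at `slope` per month.
#'
#' @param n_controls,n_cases Patient counts.
#' @param theta_bar,tau2,sigma2 Control-model parameters for log2(AFP).
#' @param visit_count_probs Probabilities for the visit-count categories
#'   `1`, `2`, `3-4`, `>4` (normalized internally).
#' @param gap_mean,gap_sd Mean and SD (months) of inter-visit gaps.
#' @param onset_lead_max Maximum pre-diagnosis lead (months) of the case
#'   changepoint.
#' @param slope Rise of mean log2(AFP) per month after the changepoint.
#' @param dx_delay_mean,dx_delay_max Mean (exponential) and cap (months) of
#'   the delay between a case's last screening visit and clinical
#'   diagnosis; surveillance diagnoses are typically triggered by a recent
#'   screen, so most cases have a screen shortly before diagnosis.
#' @param alt_log2_mean,alt_log2_sd Marginal mean/SD of log2(ALT).
#' @param alt_within_sd Within-patient SD of log2(ALT) (the rest is
#'   between-patient).
#' @param plt_mean,plt_sd Marginal mean/SD of platelets (in 1000s).
#' @param plt_within_sd Within-patient SD of platelets.
#' @param age_mean,age_sd Baseline age distribution (years).
#' @param horizon Follow-up horizon in months (end of study).
#' @param afp_min Floor for generated AFP in ng/ml (must be > 0).
#' @param lab_prob Probability that each analyte is drawn near a visit.
#' @param lab_offset_max Maximum months a lab precedes its AFP visit.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 500, n_cases = 50,
                       theta_bar = 2.92, tau2 = 1.90, sigma2 = 0.71,
                       visit_count_probs = c(`1` = 0.2848, `2` = 0.2312,
                                             `3-4` = 0.2638, `>4` = 0.2203),
                       gap_mean = 11.67, gap_sd = 11.00,
                       onset_lead_max = 24, slope = 0.15,
                       dx_delay_mean = 3, dx_delay_max = 12,
                       alt_log2_mean = 6.14, alt_log2_sd = 1.03,
                       alt_within_sd = 0.5,
                       plt_mean = 147.97, plt_sd = 78.88, plt_within_sd = 20,
                       age_mean = 52.87, age_sd = 7.28,
                       horizon = 108, afp_min = 0.1,
                       lab_prob = 0.95, lab_offset_max = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (n_controls < 0 || n_cases < 0) abort("patient counts must be >= 0")
  if (tau2 < 0 || sigma2 <= 0) abort("need tau2 >= 0 and sigma2 > 0")
  if (any(visit_count_probs < 0) || sum(visit_count_probs) <= 0) {
    abort("visit_count_probs must be non-negative and sum to a positive value")
  }
  if (length(visit_count_probs) != 4) {
    abort("visit_count_probs needs the four categories 1, 2, 3-4, >4")
  }
  if (gap_mean <= 0 || gap_sd <= 0) abort("gap moments must be positive")
  if (onset_lead_max < 0 || slope < 0) abort("need onset_lead_max >= 0 and slope >= 0")
  if (dx_delay_mean <= 0 || dx_delay_max <= 0) abort("diagnosis delay parameters must be positive")
  if (horizon <= 12) abort("horizon must exceed 12 months")
  if (afp_min <= 0) abort("afp_min must be > 0")
  if (lab_prob < 0 || lab_prob > 1) abort("lab_prob must be in [0, 1]")
  if (alt_within_sd > alt_log2_sd) abort("alt_within_sd cannot exceed alt_log2_sd")
  if (plt_within_sd > plt_sd) abort("plt_within_sd cannot exceed plt_sd")
  cfg$visit_count_probs <- visit_count_probs / sum(visit_count_probs)
  structure(cfg, class = "sim_config")
}

draw_visit_count <- function(n, probs) {
  cat_ <- sample.int(4L, n, replace = TRUE, prob = probs)
  vapply(cat_, function(k) {
    switch(k, 1L, 2L, sample(3:4, 1L), 5L + rpois(1L, 1.5))
  }, integer(1))
}

#' Simulate log2(AFP) series for a control patient
#'
#' Values are i.i.d. normal around the patient-specific mean on the log2
#' scale; AFP is the anti-log, floored at `afp_min`.
#'
#' @param theta_i Patient-specific mean of log2(AFP).
#' @param times Visit times (months).
#' @param sigma2 Within-subject variance (> 0 required by the model;
#'   0 gives a degenerate constant series).
#' @param afp_min Floor for AFP in ng/ml.
#' @return AFP values (ng/ml), one per time.
#' @export
simulate_control_afp <- function(theta_i, times, sigma2, afp_min = 0.1) {
  y <- rnorm(length(times), mean = theta_i, sd = sqrt(sigma2))
  pmax(2^y, afp_min)
}

#' Simulate log2(AFP) series for an HCC case
#'
#' The control model holds before the changepoint at `d - lead`; from the
#' changepoint the mean rises linearly at `slope` log2 units per month,
#' noise variance unchanged.
#'
#' @inheritParams simulate_control_afp
#' @param d Months to HCC diagnosis.
#' @param lead Onset lead time before diagnosis (months, >= 0).
#' @param slope Mean rise per month after the changepoint (>= 0).
#' @return AFP values (ng/ml), one per time.
#' @export
simulate_case_afp <- function(theta_i, times, d, lead, slope, sigma2,
                              afp_min = 0.1) {
  stopifnot(lead >= 0, slope >= 0)
  onset <- d - lead
  mu <- theta_i + slope * pmax(0, times - onset)
  y <- rnorm(length(times), mean = mu, sd = sqrt(sigma2))
  pmax(2^y, afp_min)
}

#' Simulate a visit schedule and concurrent labs for one patient
#'
#' The number of visits is drawn from the configured category distribution;
#' the first visit falls uniformly within one mean gap of the index date and
#' subsequent gaps are gamma-distributed with the configured mean and SD.
#' Visits after the patient endpoint (`d` for cases, the horizon for
#' controls) are discarded. Each analyte is drawn near each retained visit
#' with probability `lab_prob`, at a uniform offset before the visit, around
#' patient-specific ALT/PLT levels.
#'
#' @param id Patient identifier.
#' @param endpoint Months to HCC diagnosis (cases) or end of study.
#' @param config A [sim_config()].
#' @return List with `times` (visit times) and `labs` (tibble of
#'   `patient_id`, `analyte`, `value`, `t`).
#' @export
simulate_visits_and_labs <- function(id, endpoint, config) {
  n_target <- draw_visit_count(1L, config$visit_count_probs)
  shape <- (config$gap_mean / config$gap_sd)^2
  scale <- config$gap_sd^2 / config$gap_mean
  t1 <- runif(1, 0, min(config$gap_mean, endpoint))
  gaps <- if (n_target > 1) rgamma(n_target - 1L, shape = shape, scale = scale) else numeric(0)
  times <- t1 + c(0, cumsum(gaps))
  times <- times[times < endpoint]
  if (!length(times)) times <- t1 * 0.99  # endpoint extremely early; keep one visit

  alt_between <- sqrt(max(config$alt_log2_sd^2 - config$alt_within_sd^2, 0))
  plt_between <- sqrt(max(config$plt_sd^2 - config$plt_within_sd^2, 0))
  alt_level <- rnorm(1, config$alt_log2_mean, alt_between)
  plt_level <- rnorm(1, config$plt_mean, plt_between)

  labs <- purrr::map_dfr(times, function(tt) {
    rows <- list()
    if (runif(1) < config$lab_prob) {
      off <- runif(1, 0, min(config$lab_offset_max, tt))
      rows$alt <- tibble::tibble(
        patient_id = id, analyte = "ALT",
        value = pmax(2^(alt_level + rnorm(1, 0, config$alt_within_sd)), 1),
        t = tt - off)
    }
    if (runif(1) < config$lab_prob) {
      off <- runif(1, 0, min(config$lab_offset_max, tt))
      rows$plt <- tibble::tibble(
        patient_id = id, analyte = "PLT",
        value = pmax(plt_level + rnorm(1, 0, config$plt_within_sd), 1),
        t = tt - off)
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(labs) == 0) {
    labs <- tibble::tibble(patient_id = character(0), analyte = character(0),
                           value = numeric(0), t = numeric(0))
  }
  list(times = times, labs = labs)
}

#' Generate a synthetic surveillance cohort
#'
#' Draws patients, visit schedules, AFP trajectories and concurrent labs
#' under a [sim_config()]. Controls follow the random-intercept model for
#' log2(AFP); cases additionally rise linearly after a changepoint before
#' diagnosis. The returned cohort carries a `truth` attribute (tibble of
#' `id`, `theta`, `onset_time`, `lead`) sufficient for oracle checks.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`. The run is fully
#'   reproducible given the seed.
#' @return An `hcc_cohort` with attribute `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_controls + config$n_cases
  delta <- rep(c(0L, 1L), c(config$n_controls, config$n_cases))
  ids <- sprintf("P%05d", seq_len(n))
  theta <- rnorm(n, config$theta_bar, sqrt(config$tau2))
  baseline_age <- pmax(rnorm(n, config$age_mean, config$age_sd), 18)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.98, 0.02))
  race <- sample(c("White", "Black", "Other/Unknown"), n, replace = TRUE,
                 prob = c(0.348, 0.111, 0.541))

  d <- rep(config$horizon, n)
  lead <- rep(NA_real_, n)
  res <- purrr::map(seq_len(n), function(i) {
    sched <- simulate_visits_and_labs(ids[i], config$horizon, config)
    if (delta[i] == 1) {
      # diagnosis is usually triggered by a recent screen: a short delay
      # after the last visit, capped, never earlier than 6 months post-index
      delay <- min(stats::rexp(1, 1 / config$dx_delay_mean), config$dx_delay_max)
      d_i <- min(max(max(sched$times) + delay, 6.1), config$horizon)
      sched$times <- sched$times[sched$times < d_i]
      sched$labs <- sched$labs[sched$labs$t < d_i, , drop = FALSE]
      lead_i <- runif(1, 0, config$onset_lead_max)
      d[i] <<- d_i
      lead[i] <<- lead_i
      afp <- simulate_case_afp(theta[i], sched$times, d_i, lead_i, config$slope,
                               config$sigma2, config$afp_min)
    } else {
      afp <- simulate_control_afp(theta[i], sched$times, config$sigma2,
                                  config$afp_min)
    }
    list(visits = tibble::tibble(patient_id = ids[i], t = sched$times, afp = afp),
         labs = sched$labs)
  })

  patients <- tibble::tibble(id = ids, delta = delta, d = d,
                             baseline_age = baseline_age, sex = sex, race = race)
  visits <- purrr::list_rbind(purrr::map(res, "visits"))
  labs <- purrr::list_rbind(purrr::map(res, "labs"))
  cohort <- new_cohort(patients, visits, if (nrow(labs)) labs else NULL)
  attr(cohort, "truth") <- tibble::tibble(
    id = ids, theta = theta,
    onset_time = ifelse(delta == 1, d - lead, NA_real_), lead = lead)
  cohort
}
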