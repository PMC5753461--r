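params <- peb_params(2.92, 0.71, 1.90)

test_that("standardization centers and scales against the control model", {
  expect_equal(peb_standardize(2^2.92, params), 0)
  expect_equal(peb_standardize(2^(2.92 + sqrt(2.61)), params), 1)
  expect_equal(params$B1, 1.90 / 2.61)
})

test_that("shrinkage weights follow B_j = tau2 / (sigma2/(j-1) + tau2)", {
  eq <- peb_params(1, sigma2 = 1, tau2 = 1)
  s1 <- peb_new_state()
  r1 <- peb_screen_positive(0.5, s1, eq, f0 = 0.1)
  expect_equal(r1$b_j, 0)
  expect_equal(r1$mu_hat, 0)
  s2 <- peb_update_state(s1, 0.5)
  r2 <- peb_screen_positive(0, s2, eq, f0 = 0.1)
  expect_equal(r2$b_j, 0.5)           # sigma2 = tau2, j = 2
  expect_equal(r2$mu_hat, 0.5 * 0.5)  # B_2 * Z_1
  # the VA-like variance ratio: B_2 = 1.90 / 2.61 = ICC
  s2v <- peb_update_state(peb_new_state(), 1)
  r2v <- peb_screen_positive(1, s2v, params, f0 = 0.1)
  expect_equal(r2v$b_j, 1.90 / 2.61, tolerance = 1e-12)
  expect_equal(round(r2v$b_j, 2), 0.73)
})

test_that("the first screen reduces exactly to the fixed population threshold", {
  st <- peb_new_state()
  z90 <- qnorm(0.90)
  just_above <- peb_screen_positive(z90 + 1e-9, st, params, f0 = 0.10)
  just_below <- peb_screen_positive(z90 - 1e-9, st, params, f0 = 0.10)
  expect_true(just_above$positive)
  expect_false(just_below$positive)
  at_median <- peb_screen_positive(1e-9, st, params, f0 = 0.5)
  expect_true(at_median$positive)  # threshold 0 at f0 = 0.5
  expect_false(peb_screen_positive(-1e-9, st, params, f0 = 0.5)$positive)
})

test_that("vectorized scoring agrees with the sequential state machine", {
  set.seed(6)
  scr <- tibble::tibble(id = "A", delta = 0, d = 100,
                        t = c(3, 10, 22, 30, 41),
                        afp = 2^rnorm(5, 3, 1))
  out <- peb_score(scr, params, f0 = 0.10)
  st <- peb_new_state()
  for (i in seq_len(5)) {
    z <- peb_standardize(scr$afp[i], params)
    r <- peb_screen_positive(z, st, params, f0 = 0.10)
    expect_equal(out$score[i], r$score)
    expect_equal(out$mu_hat[i], r$mu_hat)
    expect_equal(out$positive[i], r$positive)
    st <- peb_update_state(st, z)
  }
})

test_that("a persistently elevated patient stops triggering positives", {
  # constant Z = 2 across 6 screens: first screen positive at f0 = 0.10,
  # then the history pulls mu_hat toward 2 and later screens go negative
  z <- rep(2, 6)
  afp <- 2^(params$theta_bar + z * sqrt(params$sigma2 + params$tau2))
  scr <- tibble::tibble(id = "A", delta = 0, d = 100, t = seq(0, 60, by = 12),
                        afp = afp)
  out <- peb_score(scr, params, f0 = 0.10)
  expect_true(out$positive[1])
  expect_false(any(out$positive[3:6]))
  expect_true(all(diff(out$mu_hat) >= 0))
})

test_that("the boolean rule equals score > 1 - f0 at every screen", {
  set.seed(8)
  co <- simulate_cohort(sim_config(n_controls = 60, n_cases = 15), seed = 8)
  scr <- prepare_screens(co)
  for (f0 in c(0.05, 0.10, 0.25)) {
    out <- peb_score(scr, params, f0 = f0)
    expect_equal(out$positive, out$score > 1 - f0)
    lhs <- out$z
    rhs <- out$mu_hat + qnorm(1 - f0) * sqrt(1 - params$B1 * out$b_j)
    expect_equal(out$positive, lhs > rhs)
  }
})

test_that("as tau2 -> 0 the rule reduces to the fixed threshold at all j", {
  p0 <- peb_params(2.92, 0.71, 0)
  set.seed(9)
  scr <- tibble::tibble(id = "A", delta = 0, d = 100, t = seq(1, 50, by = 7),
                        afp = 2^rnorm(8, 3, 1))
  peb <- peb_score(scr, p0, f0 = 0.10)
  fixed <- fixed_threshold_score(scr, p0, f0 = 0.10)
  expect_equal(peb$score, fixed$score)
  expect_equal(peb$positive, fixed$positive)
  expect_true(all(peb$mu_hat == 0))
})

test_that("per-screen false positive rate is controlled at f0 under the null", {
  set.seed(14)
  n_pat <- 1200; n_scr <- 5; f0 <- 0.10
  theta <- rnorm(n_pat, params$theta_bar, sqrt(params$tau2))
  scr <- purrr::map_dfr(seq_len(n_pat), function(i) {
    tibble::tibble(id = sprintf("C%04d", i), delta = 0, d = 100,
                   t = seq(1, by = 12, length.out = n_scr),
                   j = seq_len(n_scr),
                   afp = simulate_control_afp(theta[i], seq_len(n_scr),
                                              params$sigma2, afp_min = 1e-8))
  })
  out <- peb_score(scr, params, f0 = f0)
  rate_by_j <- tapply(out$positive, out$j, mean)
  mc_sd <- sqrt(f0 * (1 - f0) / n_pat)
  for (j in seq_len(n_scr)) {
    expect_lt(abs(rate_by_j[[j]] - f0), 3 * mc_sd)
  }
})

test_that("variance components are recovered from synthetic controls", {
  co <- simulate_cohort(sim_config(n_controls = 1500, n_cases = 0), seed = 16)
  scr <- prepare_screens(co)
  est <- estimate_peb_params(scr)
  expect_equal(est$theta_bar, 2.92, tolerance = 0.05)
  expect_equal(est$sigma2, 0.71, tolerance = 0.15)
  expect_equal(est$tau2, 1.90, tolerance = 0.15)
})

test_that("degenerate training data raise the documented conditions", {
  single <- tibble::tibble(id = c("A", "B", "C"), delta = 0, d = 50,
                           t = 1, j = 1, afp = c(4, 8, 16))
  expect_error(estimate_peb_params(single), "identifiable")
  flat <- tibble::tibble(id = rep(c("A", "B", "C"), each = 3), delta = 0,
                         d = 50, t = rep(1:3, 3), j = rep(1:3, 3),
                         afp = rep(c(4, 8, 64), each = 3))
  w <- testthat::capture_warnings(est <- estimate_peb_params(flat))
  expect_true(any(grepl("within-subject variance", w)))
  f0_check <- peb_params(2, 1, 0)
  expect_equal(f0_check$B1, 0)
  expect_error(peb_params(1, sigma2 = 0, tau2 = 1), "sigma2")
})

test_that("PEB parameters survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_peb_params(params, path)
  back <- read_peb_params(path)
  expect_equal(back$theta_bar, params$theta_bar)
  expect_equal(back$sigma2, params$sigma2)
  expect_equal(back$tau2, params$tau2)
  expect_equal(back$B1, params$B1)
})

test_that("tidy and glance summarize PEB parameters", {
  td <- tidy(params)
  expect_equal(td$value[td$parameter == "B1"], 1.90 / 2.61)
  gl <- glance(params)
  expect_equal(gl$icc, 1.90 / 2.61)
})
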