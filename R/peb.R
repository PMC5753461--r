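#' Parameters of the parametric empirical Bayes screening rule
#'
#' The control population model is hierarchical on `Y = log2(AFP)`:
#' `Y_ij | theta_i ~ N(theta_i, sigma2)` with `theta_i ~ N(theta_bar, tau2)`.
#' The shrinkage weight `B1 = tau2 / (sigma2 + tau2)` equals the intra-class
#' correlation of repeated log2(AFP) measurements.
#'
#' @param theta_bar Population mean of log2(AFP) in controls.
#' @param sigma2 Within-subject variance (> 0).
#' @param tau2 Between-subject variance (>= 0).
#' @return An object of class `peb_params`.
#' @export
peb_params <- function(theta_bar, sigma2, tau2) {
  if (sigma2 <= 0) abort("sigma2 must be > 0")
  if (tau2 < 0) abort("tau2 must be >= 0")
  structure(list(theta_bar = theta_bar, sigma2 = sigma2, tau2 = tau2,
                 B1 = tau2 / (sigma2 + tau2)),
            class = "peb_params")
}

#' @export
print.peb_params <- function(x, ...) {
  cat(sprintf(
    "<peb_params> theta_bar = %.4f, sigma2 = %.4f, tau2 = %.4f (ICC/B1 = %.3f)\n",
    x$theta_bar, x$sigma2, x$tau2, x$B1))
  invisible(x)
}

#' Estimate PEB parameters from training controls
#'
#' Fits a random-intercept linear mixed model (REML, via [lme4::lmer()]) to
#' `log2(AFP)` in control patients, restricted to screens with
#' AFP < `afp_max` (the OR-rule region is never scored by the algorithm).
#' Returns the fixed intercept as `theta_bar`, the residual variance as
#' `sigma2` and the intercept variance as `tau2`. AFP enters untruncated
#' (inclusion already guarantees AFP > 0); the truncation at 1 ng/ml
#' belongs to the risk-model covariates, not the hierarchical AFP model,
#' and flooring here would bias the variance components downward.
#'
#' @param screens Screen table from [prepare_screens()]; only rows with
#'   `delta == 0` are used.
#' @param afp_max Training AFP exclusion threshold (ng/ml).
#' @return A [peb_params()] object with attribute `n` (patients, screens).
#' @export
estimate_peb_params <- function(screens, afp_max = 400) {
  ctrl <- dplyr::filter(screens, .data$delta == 0, .data$afp < afp_max)
  if (nrow(ctrl) == 0) abort("no eligible control screens")
  n_multi <- sum(table(ctrl$id) >= 2)
  if (n_multi < 2) {
    abort("variance components are not identifiable: need >= 2 control patients with >= 2 visits each")
  }
  df <- data.frame(y = log2(ctrl$afp), id = ctrl$id)
  fit <- lme4::lmer(y ~ 1 + (1 | id), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "id"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  if (sigma2 <= sqrt(.Machine$double.eps)) {
    warn("estimated within-subject variance is (near) zero; degenerate control model")
    sigma2 <- max(sigma2, .Machine$double.eps)
  }
  if (tau2 <= sqrt(.Machine$double.eps)) {
    warn("between-subject variance estimated at the boundary 0; B1 = 0 and the PEB rule reduces to the fixed threshold")
    tau2 <- 0
  }
  out <- peb_params(unname(lme4::fixef(fit)[1]), sigma2, tau2)
  attr(out, "n") <- c(patients = length(unique(ctrl$id)), screens = nrow(ctrl))
  out
}

#' Standardize AFP against the control population
#'
#' `Z = (log2(AFP) - theta_bar) / sqrt(sigma2 + tau2)`; under the control
#' model the marginal distribution of `Z` is standard normal. AFP enters
#' untruncated (it must be positive).
#'
#' @param afp AFP in ng/ml, > 0.
#' @param params A [peb_params()] object.
#' @return Standardized values.
#' @export
peb_standardize <- function(afp, params) {
  stopifnot(inherits(params, "peb_params"))
  if (any(afp <= 0, na.rm = TRUE)) abort("AFP must be positive")
  (log2(afp) - params$theta_bar) / sqrt(params$sigma2 + params$tau2)
}

#' Screening state of the sequential PEB rule
#'
#' `peb_new_state()` starts a patient at screen index `j = 1` with no
#' history; `peb_update_state()` folds one standardized value into the
#' running history mean and advances the index.
#'
#' @param state A state as returned by these functions.
#' @param z Standardized value of the screen just completed.
#' @return A list with `j` (1-based index of the next/current screen) and
#'   `z_bar` (mean of the `j - 1` prior standardized values).
#' @export
peb_new_state <- function() list(j = 1L, z_bar = 0)

#' @rdname peb_new_state
#' @export
peb_update_state <- function(state, z) {
  list(j = state$j + 1L,
       z_bar = (state$z_bar * (state$j - 1L) + z) / state$j)
}

peb_bj <- function(j, params) {
  ifelse(j <= 1L, 0, params$tau2 / (params$sigma2 / (j - 1) + params$tau2))
}

#' One-screen PEB decision
#'
#' The posterior-mean estimate of the patient's standardized level is
#' `mu_hat = B_j * z_bar` with `B_j = tau2 / (sigma2 / (j - 1) + tau2)`
#' (`B_1 = 0`, so the first screen uses the population threshold). The
#' screen is positive when `z > mu_hat + qnorm(1 - f0) * sqrt(1 - B1 B_j)`,
#' equivalently when the continuous score
#' `Phi((z - mu_hat) / sqrt(1 - B1 B_j))` exceeds `1 - f0`.
#'
#' @param z Standardized value of the current screen.
#' @param state State from [peb_new_state()] / [peb_update_state()].
#' @param params A [peb_params()] object.
#' @param f0 Target per-screen false positive rate in (0, 1).
#' @return List with `positive`, `score`, `mu_hat`, `b_j`.
#' @export
peb_screen_positive <- function(z, state, params, f0) {
  if (f0 <= 0 || f0 >= 1) abort("f0 must lie strictly in (0, 1)")
  b_j <- peb_bj(state$j, params)
  mu_hat <- b_j * if (state$j > 1L) state$z_bar else 0
  denom <- sqrt(1 - params$B1 * b_j)
  stopifnot(denom > 0)  # B1 < 1 and b_j <= 1 guarantee this
  score <- pnorm((z - mu_hat) / denom)
  list(positive = score > 1 - f0, score = score, mu_hat = mu_hat, b_j = b_j)
}

#' Score every screen of a cohort with the PEB rule
#'
#' Vectorized sequential application of [peb_screen_positive()] within each
#' patient, ordered by visit time. All prior screens enter the history mean,
#' including those already positive under the AFP >= 400 OR rule, unless
#' `exclude_or_history` is set.
#'
#' @param screens Screen table from [prepare_screens()].
#' @param params A [peb_params()] object.
#' @param f0 Optional target per-screen false positive rate; when supplied a
#'   `positive` column (`score > 1 - f0`) is added.
#' @param exclude_or_history Drop screens with AFP >= `or_cutoff` from the
#'   history mean of later screens (default `FALSE`).
#' @param or_cutoff AFP cut-off of the OR rule (ng/ml).
#' @return `screens` with columns `z`, `b_j`, `mu_hat`, `score` (and
#'   `positive` when `f0` is given) added.
#' @export
peb_score <- function(screens, params, f0 = NULL,
                      exclude_or_history = FALSE, or_cutoff = 400) {
  stopifnot(inherits(params, "peb_params"))
  out <- screens |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      z = peb_standardize(.data$afp, params),
      .hist = if (exclude_or_history) {
        dplyr::lag(cumsum(.data$z * (.data$afp < or_cutoff)), default = 0)
      } else {
        dplyr::lag(cumsum(.data$z), default = 0)
      },
      .nhist = if (exclude_or_history) {
        dplyr::lag(cumsum(.data$afp < or_cutoff), default = 0)
      } else {
        dplyr::row_number() - 1
      },
      b_j = ifelse(.data$.nhist == 0, 0,
                   params$tau2 / (params$sigma2 / pmax(.data$.nhist, 1) + params$tau2)),
      mu_hat = ifelse(.data$.nhist == 0, 0,
                      .data$b_j * .data$.hist / pmax(.data$.nhist, 1)),
      score = pnorm((.data$z - .data$mu_hat) / sqrt(1 - params$B1 * .data$b_j))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".hist", -".nhist")
  if (!is.null(f0)) {
    if (f0 <= 0 || f0 >= 1) abort("f0 must lie strictly in (0, 1)")
    out <- dplyr::mutate(out, positive = .data$score > 1 - f0)
  }
  out
}

#' Fixed population-threshold scores
#'
#' The standard single-threshold rule on the standardized scale: the score
#' is `Phi(Z)`, and the screen is positive when `Z > qnorm(1 - f0)`. This is
#' the `j = 1` special case of the PEB rule applied to every screen.
#'
#' @inheritParams peb_score
#' @return `screens` with `z` and `score` (and `positive` when `f0` is
#'   given) added.
#' @export
fixed_threshold_score <- function(screens, params, f0 = NULL) {
  out <- dplyr::mutate(screens,
                       z = peb_standardize(.data$afp, params),
                       score = pnorm(.data$z))
  if (!is.null(f0)) {
    if (f0 <= 0 || f0 >= 1) abort("f0 must lie strictly in (0, 1)")
    out <- dplyr::mutate(out, positive = .data$z > qnorm(1 - f0))
  }
  out
}

#' Serialize / restore PEB parameters as JSON
#'
#' @param params A [peb_params()] object.
#' @param path Output file.
#' @return `path` (write) or a `peb_params` (read).
#' @export
write_peb_params <- function(params, path) {
  stopifnot(inherits(params, "peb_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_peb_params
#' @export
read_peb_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  peb_params(obj$theta_bar, obj$sigma2, obj$tau2)
}
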