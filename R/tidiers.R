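#' Tidy a resampled risk model
#'
#' One row per design term, summarizing the coefficient across the `K`
#' resampled logistic fits.
#'
#' @param x A `lab_risk_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (mean over iterations),
#'   `std.error` (SD over iterations).
#' @export
tidy.lab_risk_model <- function(x, ...) {
  tibble::tibble(term = colnames(x$coefficients),
                 estimate = colMeans(x$coefficients),
                 std.error = apply(x$coefficients, 2, stats::sd))
}

#' @rdname tidy.lab_risk_model
#' @return For `glance()`: a one-row tibble with fit metadata.
#' @export
glance.lab_risk_model <- function(x, ...) {
  tibble::tibble(covariate_set = x$covariate_set, K = x$K,
                 n_patients = x$n_patients, n_screens = x$n_screens,
                 n_terms = ncol(x$coefficients),
                 n_ridge_fallback = sum(x$diagnostics$ridge_fallback))
}

#' Tidy PEB parameters
#'
#' @param x A `peb_params` object.
#' @param ... Unused.
#' @return Tibble with `parameter` and `value` rows for `theta_bar`,
#'   `sigma2`, `tau2` and `B1`.
#' @export
tidy.peb_params <- function(x, ...) {
  tibble::tibble(parameter = c("theta_bar", "sigma2", "tau2", "B1"),
                 value = c(x$theta_bar, x$sigma2, x$tau2, x$B1))
}

#' @rdname tidy.peb_params
#' @return For `glance()`: a one-row tibble including the intra-class
#'   correlation (equal to `B1`) and, when estimated from data, the
#'   training sizes.
#' @export
glance.peb_params <- function(x, ...) {
  n <- attr(x, "n")
  tibble::tibble(theta_bar = x$theta_bar, sigma2 = x$sigma2, tau2 = x$tau2,
                 icc = x$B1,
                 n_patients = if (is.null(n)) NA_integer_ else unname(n["patients"]),
                 n_screens = if (is.null(n)) NA_integer_ else unname(n["screens"]))
}
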