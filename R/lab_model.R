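#' Hinge (linear spline) term
#'
#' `(x - k) * I(x > k)` with a strict indicator, the building block of every
#' covariate basis in the six-month risk model.
#'
#' @param x Numeric vector.
#' @param k Knot.
#' @return Numeric vector.
#' @export
hinge <- function(x, k) (x - k) * (x > k)

#' Knot locations of the six-month risk model bases
#'
#' AFP knots on the log2 scale at 2, 7 and 9; ALT knots at log2 of 20, 50,
#' 100 and 200 IU/ml; a platelet knot at 35 (thousands); an age knot at 50
#' years; annualized log2-AFP-change knots at -8, 0, 2 and 9.
#'
#' @return Named list of knot vectors.
#' @export
risk_model_knots <- function() {
  list(afp = c(2, 7, 9),
       alt = log2(c(20, 50, 100, 200)),
       plt = 35,
       age = 50,
       dafp = c(-8, 0, 2, 9))
}

basis_cols <- function(x, knots, prefix, transform = identity) {
  z <- transform(x)
  m <- matrix(vapply(knots, function(k) hinge(z, k), numeric(length(z))),
              nrow = length(z))
  out <- cbind(z, m)
  colnames(out) <- c(prefix, paste0(prefix, "_k", seq_along(knots)))
  out
}

afp_basis <- function(afp) basis_cols(afp, risk_model_knots()$afp, "afp",
                                      function(x) log2(pmax(x, 1)))
alt_basis <- function(alt) basis_cols(alt, risk_model_knots()$alt, "alt",
                                      function(x) log2(pmax(x, 1)))
plt_basis <- function(plt) basis_cols(pmax(plt, 1), risk_model_knots()$plt, "plt")
age_basis <- function(age) basis_cols(age, risk_model_knots()$age, "age")

dafp_basis <- function(rate, obs) {
  r <- ifelse(obs == 1L, rate, 0)
  out <- basis_cols(r, risk_model_knots()$dafp, "dafp")
  out * obs
}

outer_block <- function(a, b, prefix) {
  out <- do.call(cbind, lapply(seq_len(ncol(a)), function(i) {
    m <- a[, i] * b
    colnames(m) <- paste0(prefix, "_", colnames(a)[i], "_x_", colnames(b))
    m
  }))
  out
}

#' Design matrix of the six-month risk model
#'
#' Builds the covariate row for each screen. The `"afp_only"` set uses the
#' four-term AFP spline basis alone. The `"full"` set adds the ALT (5),
#' platelet (2) and age (2) bases, AFP-by-ALT and AFP-by-PLT interactions,
#' the indicator that no AFP change was observed (`1 - dafp_obs`), and the
#' five-term basis of the annualized log2(AFP) change, zeroed when the
#' previous AFP is more than 12 months old. Interactions are the full outer
#' product of the two bases by default, or the product of the linear terms
#' only with `interactions = "linear"`.
#'
#' @param screens Screen table from [prepare_screens()] (or any tibble with
#'   `afp`, and for the full set `alt`, `plt`, `age`, `dafp_obs`,
#'   `dafp_rate`).
#' @param covariate_set `"full"` or `"afp_only"`.
#' @param interactions `"outer"` (default) or `"linear"`.
#' @return Numeric matrix, one row per screen (no intercept column).
#' @export
design_matrix <- function(screens, covariate_set = c("full", "afp_only"),
                          interactions = c("outer", "linear")) {
  covariate_set <- match.arg(covariate_set)
  interactions <- match.arg(interactions)
  A <- afp_basis(screens$afp)
  if (covariate_set == "afp_only") {
    return(A)
  }
  if (anyNA(screens$alt) || anyNA(screens$plt)) {
    abort("full design needs concurrent ALT and PLT on every screen; filter on `lab_eligible` first")
  }
  L <- alt_basis(screens$alt)
  P <- plt_basis(screens$plt)
  G <- age_basis(screens$age)
  obs <- as.integer(screens$dafp_obs %||% 0L)
  Dh <- dafp_basis(screens$dafp_rate %||% NA_real_, obs)
  inter <- if (interactions == "outer") {
    cbind(outer_block(A, L, "i"), outer_block(A, P, "i"))
  } else {
    m <- cbind(A[, 1] * L[, 1], A[, 1] * P[, 1])
    colnames(m) <- c("i_afp_x_alt", "i_afp_x_plt")
    m
  }
  no_dafp <- matrix(1 - obs, ncol = 1, dimnames = list(NULL, "no_dafp"))
  out <- cbind(A, L, P, G, inter, no_dafp, Dh)
  if (any(!is.finite(out))) abort("non-finite design term; check inputs")
  out
}

#' Design row for a single screen
#'
#' @param visit One-row tibble or list with the fields [design_matrix()]
#'   needs.
#' @inheritParams design_matrix
#' @return Named numeric vector.
#' @export
design_row <- function(visit, covariate_set = c("full", "afp_only"),
                       interactions = c("outer", "linear")) {
  drop(design_matrix(tibble::as_tibble(visit), covariate_set, interactions)[1, ])
}

fit_logit_once <- function(X, y, ridge_lambda) {
  Xi <- cbind(`(Intercept)` = 1, X)
  ok <- TRUE
  fit <- withCallingHandlers(
    tryCatch(glm.fit(Xi, y, family = binomial()),
             error = function(e) NULL),
    warning = function(w) {
      ok <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  beta <- if (!is.null(fit)) fit$coefficients else NULL
  converged <- !is.null(fit) && isTRUE(fit$converged)
  clean <- ok && converged && !anyNA(beta) && all(abs(beta) < 30)
  if (!clean) {
    beta <- ridge_logit(X, y, ridge_lambda, glm_beta = beta)
  }
  list(beta = beta, fallback = !clean)
}

# separation / rank-deficiency fallback: small ridge penalty fitted along a
# short decreasing lambda path, constant columns excluded; if even that
# fails, the (zero-filled, clamped) unpenalized coefficients are kept
ridge_logit <- function(X, y, ridge_lambda, glm_beta = NULL) {
  beta <- setNames(numeric(ncol(X) + 1), c("(Intercept)", colnames(X)))
  keep <- apply(X, 2, function(col) diff(range(col)) > 0)
  co <- NULL
  if (sum(keep) >= 2) {
    co <- tryCatch(suppressWarnings({
      g <- glmnet::glmnet(X[, keep, drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = ridge_lambda * 10^(3:0),
                          standardize = TRUE, maxit = 2e5)
      drop(as.matrix(coef(g, s = ridge_lambda)))
    }), error = function(e) NULL)
    if (!is.null(co) && (length(co) != sum(keep) + 1 || any(!is.finite(co)))) {
      co <- NULL
    }
  }
  if (!is.null(co)) {
    beta[c(TRUE, keep)] <- co
  } else if (!is.null(glm_beta)) {
    glm_beta[is.na(glm_beta)] <- 0
    beta[] <- pmin(pmax(glm_beta, -30), 30)
  }
  beta
}

#' Fit the six-month risk model by cross-sectional resampling
#'
#' In each of `K` iterations one screening visit is drawn (with replacement
#' across iterations) per training patient, and a logistic regression of the
#' six-month outcome `D` on the design row is fitted; the `K` coefficient
#' vectors are stored and later averaged on the probability scale by
#' [predict.lab_risk_model()]. Training screens are restricted to
#' AFP < 400 ng/ml (the algorithm is only applied below the OR-rule
#' cut-off), and for the full covariate set to lab-eligible screens.
#' Iterations with separation or non-convergence are refitted with a small
#' ridge penalty and counted in the diagnostics.
#'
#' @param screens Training screen table from [prepare_screens()] including
#'   the outcome column `D`.
#' @param covariate_set `"full"` or `"afp_only"`.
#' @param K Number of resampling iterations (default 100).
#' @param seed Seed governing all visit draws; iteration `k` uses an
#'   independent substream so earlier draws are stable when `K` changes.
#' @param interactions Interaction expansion, see [design_matrix()].
#' @param afp_max Training AFP exclusion threshold (ng/ml).
#' @param ridge_lambda Ridge penalty of the stabilization fallback.
#' @return An object of class `lab_risk_model`: coefficient matrix
#'   (`K` rows), covariate-set tag, knots, seed and per-iteration
#'   diagnostics.
#' @export
fit_lab_model <- function(screens, covariate_set = c("full", "afp_only"),
                          K = 100, seed = 1L,
                          interactions = c("outer", "linear"),
                          afp_max = 400, ridge_lambda = 1e-4) {
  covariate_set <- match.arg(covariate_set)
  interactions <- match.arg(interactions)
  if (!"D" %in% names(screens)) abort("training screens need the outcome column `D`")
  train <- dplyr::filter(screens, .data$afp < afp_max)
  if (covariate_set == "full") {
    train <- dplyr::filter(train, .data$lab_eligible)
  }
  if (nrow(train) == 0) abort("no eligible training screens")
  if (length(unique(train$D)) < 2) abort("training outcome is constant; cannot fit")
  X <- design_matrix(train, covariate_set, interactions)
  rows_by_patient <- split(seq_len(nrow(train)), train$id)

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, K, replace = TRUE)
  fits <- vector("list", K)
  for (k in seq_len(K)) {
    set.seed(iter_seeds[k])
    idx <- vapply(rows_by_patient,
                  function(r) r[sample.int(length(r), 1L)], integer(1))
    fits[[k]] <- fit_logit_once(X[idx, , drop = FALSE], train$D[idx], ridge_lambda)
  }
  beta <- do.call(rbind, lapply(fits, `[[`, "beta"))
  structure(list(
    coefficients = beta,
    covariate_set = covariate_set,
    interactions = interactions,
    knots = risk_model_knots(),
    K = K, seed = seed, afp_max = afp_max,
    n_patients = length(rows_by_patient), n_screens = nrow(train),
    diagnostics = tibble::tibble(
      iteration = seq_len(K),
      ridge_fallback = vapply(fits, `[[`, logical(1), "fallback"))
  ), class = "lab_risk_model")
}

#' @export
print.lab_risk_model <- function(x, ...) {
  cat(sprintf(
    "<lab_risk_model> %s covariates, K = %d resampled fits on %d patients (%d screens); %d ridge fallback(s)\n",
    x$covariate_set, x$K, x$n_patients, x$n_screens,
    sum(x$diagnostics$ridge_fallback)))
  invisible(x)
}

#' Predicted six-month HCC risk
#'
#' The risk of a screen is the arithmetic mean over the `K` resampled fits
#' of the per-fit logistic prediction, so it always lies strictly between 0
#' and 1 and is invariant to the order of the coefficient vectors.
#'
#' @param object A `lab_risk_model`.
#' @param newdata Screen table; for the full covariate set it must be
#'   lab-eligible throughout.
#' @param ... Unused.
#' @return Numeric vector of risks in (0, 1), one per screen.
#' @export
predict.lab_risk_model <- function(object, newdata, ...) {
  X <- design_matrix(newdata, object$covariate_set, object$interactions)
  Xi <- cbind(1, X)
  eta <- Xi %*% t(object$coefficients)
  rowMeans(plogis(eta))
}

#' Serialize / restore a fitted risk model as JSON
#'
#' @param model A `lab_risk_model`.
#' @param path Output file.
#' @return `path` (write) or the restored model (read), invisibly for write.
#' @export
write_lab_model <- function(model, path) {
  stopifnot(inherits(model, "lab_risk_model"))
  obj <- model
  obj$coefficients <- list(terms = colnames(model$coefficients),
                           values = unname(as.data.frame(t(model$coefficients))))
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lab_model
#' @export
read_lab_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- t(as.matrix(as.data.frame(obj$coefficients$values)))
  dimnames(beta) <- list(NULL, obj$coefficients$terms)
  obj$coefficients <- beta
  obj$diagnostics <- tibble::as_tibble(obj$diagnostics)
  structure(obj, class = "lab_risk_model")
}
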