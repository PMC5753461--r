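#' Performance curves over the risk percentile
#'
#' Evaluates the patient-level TPR, screening-level FPR, PPV and NPV at
#' every attainable score threshold (each unique score value), under the
#' AFP >= 400 OR rule, and indexes each threshold by its risk percentile
#' (the proportion of scored screens at or below it). On control-only data
#' with no OR-rule positives the FPR-percentile relationship is linear with
#' slope -1 by construction; the achieved curve is returned so this can be
#' inspected as a diagnostic.
#'
#' @param scores Screen table for one algorithm with columns `id`, `delta`,
#'   `d`, `t`, `afp`, `score` (`NA` score = not scorable, positive only via
#'   the OR rule).
#' @param window A [detection_window()].
#' @param include_excluded Passed to the predictive-value denominators, see
#'   [screen_ppv_npv()].
#' @param or_cutoff AFP cut-off of the OR rule.
#' @param max_thresholds When there are more unique scores than this, the
#'   threshold set is thinned to evenly spaced quantiles (default 2000,
#'   keeping the curve exact on small and modest data).
#' @return A tibble of class `hcc_curves`: `threshold`, `percentile`,
#'   `tpr`, `fpr`, `ppv`, `npv`.
#' @export
performance_curves <- function(scores, window, include_excluded = TRUE,
                               or_cutoff = 400, max_thresholds = 2000) {
  cls <- classify_screens(scores, window)
  if (!include_excluded) cls <- dplyr::filter(cls, !.data$excluded)
  s <- cls$score
  scored <- !is.na(s)
  thr <- sort(unique(s[scored]))
  if (length(thr) > max_thresholds) {
    thr <- unique(quantile(s[scored], probs = seq(0, 1, length.out = max_thresholds),
                           names = FALSE, type = 1))
  }
  thr <- c(-Inf, thr)
  is_or <- cls$afp >= or_cutoff

  n_scored <- sum(scored)
  count_le <- function(values) {
    # for each threshold: how many of `values` are <= it
    v <- sort(values)
    findInterval(thr, v)
  }
  n_at_or_below <- count_le(s[scored])
  percentile <- n_at_or_below / n_scored

  # screening-level FPR: positives among FP-eligible screens
  fp_elig <- cls$fp_eligible
  n_fp <- sum(fp_elig)
  fp_or <- sum(fp_elig & is_or)
  fp_scores <- s[fp_elig & !is_or & scored]
  fpr <- (fp_or + (length(fp_scores) - count_le(fp_scores))) / n_fp

  # positives overall and among TP-eligible screens (for PPV)
  n_or <- sum(is_or)
  all_scores <- s[!is_or & scored]
  n_pos <- n_or + (length(all_scores) - count_le(all_scores))
  tp_or <- sum(cls$tp_eligible & is_or)
  tp_scores <- s[cls$tp_eligible & !is_or & scored]
  tp_pos <- tp_or + (length(tp_scores) - count_le(tp_scores))
  ppv <- ifelse(n_pos > 0, tp_pos / n_pos, NA_real_)

  # negatives: unscorable screens without OR positivity are always negative
  n_total <- nrow(cls)
  n_neg <- n_total - n_pos
  fp_unscored_neg <- sum(fp_elig & !is_or & !scored)
  fp_neg <- fp_unscored_neg + count_le(fp_scores)
  npv <- ifelse(n_neg > 0, fp_neg / n_neg, NA_real_)

  # patient-level TPR: a case is detected iff its best window screen clears
  # the threshold (OR-rule screens always do)
  tp_case <- dplyr::filter(cls, .data$delta == 1, .data$tp_eligible)
  case_best <- if (nrow(tp_case)) {
    tp_case |>
      dplyr::mutate(best = dplyr::if_else(.data$afp >= or_cutoff, Inf,
                                          dplyr::coalesce(.data$score, -Inf))) |>
      dplyr::summarise(best = max(.data$best), .by = "id")
  } else {
    tibble::tibble(id = character(0), best = numeric(0))
  }
  n_cases <- nrow(case_best)
  finite_best <- case_best$best[is.finite(case_best$best)]
  n_inf <- sum(case_best$best == Inf)
  tpr <- if (n_cases > 0) {
    (n_inf + (length(finite_best) - count_le(finite_best))) / n_cases
  } else {
    rep(NA_real_, length(thr))
  }

  out <- tibble::tibble(threshold = thr, percentile = percentile,
                        tpr = tpr, fpr = fpr, ppv = ppv, npv = npv)
  structure(out, class = c("hcc_curves", class(out)),
            window = window, n_cases = n_cases, n_fp_screens = n_fp)
}

#' Extract the operating point at a target screening-level FPR
#'
#' Returns the curve row with the largest achieved FPR not exceeding the
#' target — the same threshold [calibrate_threshold()] selects — so
#' fixed-FPR tables can be read off percentile curves.
#'
#' @param curves An `hcc_curves` tibble from [performance_curves()].
#' @param target_fpr Target screening-level FPR.
#' @return A one-row tibble.
#' @export
curve_at_fpr <- function(curves, target_fpr) {
  ok <- dplyr::filter(curves, .data$fpr <= target_fpr)
  if (nrow(ok) == 0) abort("target FPR below the attainable floor of the curve")
  dplyr::slice_min(ok, .data$threshold, n = 1, with_ties = FALSE)
}

#' HCC risk by score decile
#'
#' Splits scored screens into equal-count deciles of the score (via
#' mid-rank percentiles) and estimates, per decile, the probability that
#' the screen is followed by HCC diagnosis within `tau1` months. A natural
#' cubic spline through the decile midpoints gives the smoothed risk curve.
#'
#' @param scores Screen table with `score`, `delta`, `d`, `t`.
#' @param window A [detection_window()]; its `tau1` is the risk horizon.
#' @param n_grid Grid size of the smoothed curve.
#' @return A list with `deciles` (tibble: `decile`, `midpoint`, `risk`,
#'   `n`) and `curve` (tibble: `percentile`, `risk`).
#' @export
decile_risk <- function(scores, window, n_grid = 101) {
  stopifnot(inherits(window, "detection_window"))
  dat <- dplyr::filter(scores, !is.na(.data$score))
  pct <- risk_percentile(dat$score)
  dec <- pmin(pmax(ceiling(pct * 10), 1L), 10L)
  event <- dat$delta == 1 & (dat$d - dat$t) <= window$tau1 & dat$t <= dat$d
  deciles <- tibble::tibble(decile = dec, event = event) |>
    dplyr::summarise(risk = mean(.data$event), n = dplyr::n(),
                     .by = "decile") |>
    dplyr::arrange(.data$decile) |>
    dplyr::mutate(midpoint = (.data$decile - 0.5) / 10)
  empty <- setdiff(1:10, deciles$decile)
  if (length(empty)) {
    warn(sprintf("empty score decile(s) omitted from the risk spline: %s",
                 paste(empty, collapse = ", ")))
  }
  curve <- if (nrow(deciles) >= 2) {
    sp <- spline(deciles$midpoint, deciles$risk, method = "natural",
                 xout = seq(0, 1, length.out = n_grid))
    tibble::tibble(percentile = sp$x, risk = sp$y)
  } else {
    tibble::tibble(percentile = numeric(0), risk = numeric(0))
  }
  list(deciles = deciles, curve = curve)
}
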