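#' OR-rule positivity
#'
#' A screen is positive when AFP >= 400 ng/ml (inclusive; a patient at the
#' cut-off is referred to imaging regardless of any algorithm) or when the
#' screening algorithm flags it.
#'
#' @param afp AFP in ng/ml.
#' @param algo_positive Logical algorithm decision; `NA` (screen not
#'   scorable by the algorithm) counts as negative.
#' @param or_cutoff AFP cut-off (default 400).
#' @return Logical vector.
#' @export
or_rule_positive <- function(afp, algo_positive, or_cutoff = 400) {
  afp >= or_cutoff | (!is.na(algo_positive) & algo_positive)
}

#' Apply a score threshold under the OR rule
#'
#' Positivity is strict in the score (`score > threshold`), matching the
#' displayed decision rules; screens the algorithm cannot score
#' (`NA` score) are positive only via the AFP cut-off.
#'
#' @param scores Tibble with `score` and `afp` columns.
#' @param threshold Score threshold.
#' @param or_cutoff AFP cut-off of the OR rule.
#' @return `scores` with a logical `positive` column added.
#' @export
apply_threshold <- function(scores, threshold, or_cutoff = 400) {
  dplyr::mutate(scores,
                positive = or_rule_positive(.data$afp,
                                            .data$score > threshold,
                                            or_cutoff))
}

#' Calibrate a score threshold to a target screening-level FPR
#'
#' Finds the smallest threshold whose achieved screening-level false
#' positive rate under the OR rule does not exceed the target. The FPR is
#' computed over false-positive-eligible screens (all control screens plus
#' case screens earlier than `d - tau1`); ties in the score can make the
#' achieved rate strictly smaller than the target, which is reported.
#'
#' @param scores Tibble with columns `score`, `afp` and a logical
#'   `fp_eligible` (e.g. from [classify_screens()]).
#' @param target_fpr Target screening-level FPR in `[0, 1]`.
#' @param or_cutoff AFP cut-off of the OR rule.
#' @return A list with `threshold`, `achieved_fpr`, `floor_fpr` (rate from
#'   AFP >= cut-off alone), and `n_screens`.
#' @export
calibrate_threshold <- function(scores, target_fpr, or_cutoff = 400) {
  if (target_fpr < 0 || target_fpr > 1) abort("target_fpr must be in [0, 1]")
  elig <- dplyr::filter(scores, .data$fp_eligible)
  n <- nrow(elig)
  if (n == 0) abort("no FP-eligible screens to calibrate on")
  is_or <- elig$afp >= or_cutoff
  floor_fpr <- mean(is_or)
  if (floor_fpr > target_fpr) {
    abort(sprintf(
      "target FPR %.4f unreachable: AFP >= %g positives alone give FPR %.4f",
      target_fpr, or_cutoff, floor_fpr))
  }
  s <- sort(elig$score[!is_or & !is.na(elig$score)])
  # candidates: every observed score (eligible or not), so the threshold is
  # the smallest attainable one and agrees with performance_curves()
  cand <- c(-Inf, sort(unique(scores$score[!is.na(scores$score)])))
  # positives at threshold c: OR screens plus non-OR screens with score > c
  n_gt <- length(s) - findInterval(cand, s)
  fpr <- (sum(is_or) + n_gt) / n
  k <- which(fpr <= target_fpr)[1]  # fpr is non-increasing in cand
  list(threshold = cand[k], achieved_fpr = fpr[k],
       floor_fpr = floor_fpr, n_screens = n)
}

#' Risk percentile of each screen's score
#'
#' The proportion of screens whose score lies below a given screen's score,
#' with ties assigned the mid-rank (fraction strictly below plus half the
#' tied mass). `NA` scores get `NA` percentiles and do not enter the
#' reference distribution.
#'
#' @param score Numeric score vector.
#' @return Percentiles in (0, 1).
#' @export
risk_percentile <- function(score) {
  if (!length(score)) abort("need at least one score")
  ok <- !is.na(score)
  out <- rep(NA_real_, length(score))
  n <- sum(ok)
  out[ok] <- (rank(score[ok], ties.method = "average") - 0.5) / n
  out
}
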