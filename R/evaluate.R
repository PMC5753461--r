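#' Detection windows for longitudinal evaluation
#'
#' A window `(tau1, tau2)` declares positive screens of an HCC case to be
#' true positives when they fall in `[d - tau1, d - tau2]` (months before
#' diagnosis, both ends inclusive). The standard labels are A1 = (6, 0),
#' B1 = (12, 0), C1 = (24, 0) and D1 = (max follow-up, 0), with A2-D2 the
#' same windows excluding the final 3 months before diagnosis, where
#' earlier detection is no longer clinically meaningful.
#'
#' @param label One of `"A1"`, `"B1"`, `"C1"`, `"D1"`, `"A2"`, `"B2"`,
#'   `"C2"`, `"D2"`; alternatively supply `tau1`/`tau2` directly with
#'   `label = NULL`.
#' @param tau_max Value used for the maximum follow-up time in D windows
#'   (default `Inf`).
#' @param tau1,tau2 Explicit window bounds in months (`tau1 > tau2 >= 0`).
#' @return A list of class `detection_window` with `label`, `tau1`, `tau2`.
#' @export
detection_window <- function(label = c("A1", "B1", "C1", "D1",
                                       "A2", "B2", "C2", "D2"),
                             tau_max = Inf, tau1 = NULL, tau2 = NULL) {
  if (is.null(tau1)) {
    label <- match.arg(label)
    tau1 <- c(A = 6, B = 12, C = 24, D = tau_max)[[substr(label, 1, 1)]]
    tau2 <- c(`1` = 0, `2` = 3)[[substr(label, 2, 2)]]
  } else {
    label <- label %||% sprintf("(%s,%s)", tau1, tau2)
  }
  if (!(tau1 > tau2 && tau2 >= 0)) abort("need tau1 > tau2 >= 0")
  structure(list(label = label, tau1 = tau1, tau2 = tau2),
            class = "detection_window")
}

#' Classify screens relative to a detection window
#'
#' For a case, a screen is TP-eligible when `d - tau1 <= t <= d - tau2`
#' (inclusive), FP-eligible when `t < d - tau1` (strict) and excluded when
#' `t > d - tau2`. Every control screen is FP-eligible.
#'
#' @param screens Screen table with `delta`, `d`, `t`.
#' @param window A [detection_window()].
#' @return `screens` with logical columns `tp_eligible`, `fp_eligible`,
#'   `excluded` added (mutually exclusive, exhaustive).
#' @export
classify_screens <- function(screens, window) {
  stopifnot(inherits(window, "detection_window"))
  dplyr::mutate(screens,
    tp_eligible = .data$delta == 1 &
      .data$t >= .data$d - window$tau1 & .data$t <= .data$d - window$tau2,
    fp_eligible = .data$delta == 0 |
      (.data$delta == 1 & .data$t < .data$d - window$tau1),
    excluded = .data$delta == 1 & .data$t > .data$d - window$tau2)
}

#' Patient-level true positive rate in a detection window
#'
#' Fraction of HCC cases with at least one positive screen inside the
#' window, among cases with at least one screen inside the window (cases
#' never screened in the window are excluded from the denominator).
#'
#' @param screens Screen table with a logical `positive` column.
#' @param window A [detection_window()].
#' @return A list with `tpr`, `n_cases` (denominator) and `n_detected`.
#' @export
patient_tpr <- function(screens, window) {
  cls <- classify_screens(screens, window)
  per_case <- cls |>
    dplyr::filter(.data$delta == 1, .data$tp_eligible) |>
    dplyr::summarise(detected = any(.data$positive), .by = "id")
  n <- nrow(per_case)
  if (n == 0) {
    warn("no case has a screen inside the detection window; TPR undefined")
    return(list(tpr = NA_real_, n_cases = 0L, n_detected = 0L))
  }
  list(tpr = mean(per_case$detected), n_cases = n,
       n_detected = sum(per_case$detected))
}

#' Screening-level false positive rate
#'
#' Fraction of positive screens among FP-eligible screens (all control
#' screens plus case screens earlier than `d - tau1`), pooled over screens
#' rather than patients.
#'
#' @inheritParams patient_tpr
#' @return A list with `fpr` and `n_screens`.
#' @export
screening_fpr <- function(screens, window) {
  cls <- dplyr::filter(classify_screens(screens, window), .data$fp_eligible)
  if (nrow(cls) == 0) {
    warn("no FP-eligible screens; FPR undefined")
    return(list(fpr = NA_real_, n_screens = 0L))
  }
  list(fpr = mean(cls$positive), n_screens = nrow(cls))
}

#' Screening-level predictive values
#'
#' PPV is the fraction of positive screens that are TP-eligible case
#' screens; NPV is the fraction of negative screens that are FP-eligible
#' (true negatives). By default screens in a case's excluded region
#' (`(d - tau2, d]`) contribute to the denominators through their
#' positivity status, exactly as the conditional definitions read; set
#' `include_excluded = FALSE` to drop them entirely.
#'
#' @inheritParams patient_tpr
#' @param include_excluded Keep excluded-region case screens in the
#'   denominators (default `TRUE`).
#' @return A list with `ppv`, `npv`, `n_positive`, `n_negative`.
#' @export
screen_ppv_npv <- function(screens, window, include_excluded = TRUE) {
  cls <- classify_screens(screens, window)
  if (!include_excluded) cls <- dplyr::filter(cls, !.data$excluded)
  pos <- dplyr::filter(cls, .data$positive)
  neg <- dplyr::filter(cls, !.data$positive)
  if (nrow(pos) == 0) warn("no positive screens; PPV undefined")
  if (nrow(neg) == 0) warn("no negative screens; NPV undefined")
  list(ppv = if (nrow(pos)) mean(pos$tp_eligible) else NA_real_,
       npv = if (nrow(neg)) mean(neg$fp_eligible) else NA_real_,
       n_positive = nrow(pos), n_negative = nrow(neg))
}

#' All four longitudinal performance measures at once
#'
#' @inheritParams screen_ppv_npv
#' @return A one-row tibble with `window`, `tpr`, `fpr`, `ppv`, `npv` and
#'   the associated counts.
#' @export
screen_performance <- function(screens, window, include_excluded = TRUE) {
  tp <- patient_tpr(screens, window)
  fp <- screening_fpr(screens, window)
  pv <- screen_ppv_npv(screens, window, include_excluded)
  win <- window
  tibble::tibble(window = win$label, tau1 = win$tau1, tau2 = win$tau2,
                 tpr = tp$tpr, fpr = fp$fpr, ppv = pv$ppv, npv = pv$npv,
                 n_cases = tp$n_cases, n_fp_screens = fp$n_screens,
                 n_positive = pv$n_positive)
}

#' Per-patient false-positive burden
#'
#' Counts each patient's positive FP-eligible screens and reports the
#' fraction of patients with more than `k` of them, among patients with at
#' least one FP-eligible screen.
#'
#' @inheritParams patient_tpr
#' @param k Burden cut-off (default 2, i.e. "more than two false
#'   positives").
#' @return A list with `fraction`, `n_patients` and the per-patient counts.
#' @export
false_positive_burden <- function(screens, window, k = 2) {
  cls <- classify_screens(screens, window)
  per_patient <- cls |>
    dplyr::filter(.data$fp_eligible) |>
    dplyr::summarise(n_fp = sum(.data$positive), .by = "id")
  if (nrow(per_patient) == 0) {
    return(list(fraction = NA_real_, n_patients = 0L, counts = per_patient))
  }
  list(fraction = mean(per_patient$n_fp > k),
       n_patients = nrow(per_patient), counts = per_patient)
}

#' Compare first-positive timing between algorithms
#'
#' For every HCC case with at least one screen in the window and at least
#' one algorithm-positive screen there, each algorithm's first positive
#' time inside the window is found; an algorithm with no positive screen in
#' the window is assigned the clinical diagnosis time `d`. Each algorithm
#' pair is then summarized by the fraction of cases flagged first by either
#' algorithm or at the same visit.
#'
#' @param scores Long tibble with one row per (algorithm, screen):
#'   columns `algorithm`, `id`, `delta`, `d`, `t`, `positive`.
#' @param window A [detection_window()].
#' @return A tibble with one row per ordered algorithm pair: `algorithm_a`,
#'   `algorithm_b`, `first_a`, `first_b`, `same` (fractions) and `n_cases`
#'   (size of the comparison set).
#' @export
first_positive_comparison <- function(scores, window) {
  cls <- classify_screens(scores, window)
  algos <- unique(cls$algorithm)
  if (length(algos) < 2) abort("need positivity streams from >= 2 algorithms")
  in_win <- dplyr::filter(cls, .data$delta == 1, .data$tp_eligible)
  case_d <- dplyr::distinct(in_win, .data$id, .data$d)
  firsts <- in_win |>
    dplyr::filter(.data$positive) |>
    dplyr::summarise(t_first = min(.data$t), .by = c("id", "algorithm"))
  first_pos <- tidyr::expand_grid(id = case_d$id, algorithm = algos) |>
    dplyr::left_join(case_d, by = "id") |>
    dplyr::left_join(firsts, by = c("id", "algorithm")) |>
    dplyr::mutate(flagged = !is.na(.data$t_first),
                  t_first = dplyr::coalesce(.data$t_first, .data$d))
  keep <- first_pos |>
    dplyr::summarise(any_pos = any(.data$flagged), .by = "id") |>
    dplyr::filter(.data$any_pos)
  first_pos <- dplyr::semi_join(first_pos, keep, by = "id")

  pairs <- utils::combn(algos, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    wide <- first_pos |>
      dplyr::filter(.data$algorithm %in% p) |>
      tidyr::pivot_wider(id_cols = "id", names_from = "algorithm",
                         values_from = "t_first")
    ta <- wide[[p[1]]]; tb <- wide[[p[2]]]
    tibble::tibble(algorithm_a = p[1], algorithm_b = p[2],
                   first_a = mean(ta < tb), first_b = mean(tb < ta),
                   same = mean(ta == tb), n_cases = nrow(wide))
  })
}
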