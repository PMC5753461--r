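ALGORITHMS <- c("afp_only", "afp_lab_dafp", "peb")

#' Stratified split-sample of a cohort
#'
#' Randomly divides HCC cases and controls into training and validation
#' halves of equal size within each stratum; with an odd stratum count the
#' extra patient goes to training.
#'
#' @param cohort An `hcc_cohort`.
#' @param seed Integer seed.
#' @return A list with `training` and `validation` cohorts.
#' @export
split_sample <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  pat <- cohort$patients
  if (sum(pat$delta == 1) < 2 || sum(pat$delta == 0) < 2) {
    abort("need at least 2 cases and 2 controls to split")
  }
  set.seed(seed)
  train_ids <- unlist(lapply(split(pat$id, pat$delta), function(ids) {
    n <- length(ids)
    sample(ids, ceiling(n / 2))
  }), use.names = FALSE)
  list(training = subset_cohort(cohort, train_ids),
       validation = subset_cohort(cohort, setdiff(pat$id, train_ids)))
}

#' Fit all requested algorithms on a training screen table
#'
#' @param train_screens Training screens from [prepare_screens()].
#' @param algorithms Subset of `"afp_only"`, `"afp_lab_dafp"`, `"peb"`.
#' @param K Resampling iterations for the risk models.
#' @param seed Seed for the resampling draws.
#' @param interactions Interaction expansion of the full model.
#' @return Named list of fitted objects (`lab_risk_model` / `peb_params`).
#' @export
fit_algorithms <- function(train_screens, algorithms = ALGORITHMS,
                           K = 100, seed = 1L,
                           interactions = c("outer", "linear")) {
  algorithms <- match_algorithms(algorithms)
  fits <- list()
  if ("afp_only" %in% algorithms) {
    fits$afp_only <- fit_lab_model(train_screens, "afp_only", K = K, seed = seed)
  }
  if ("afp_lab_dafp" %in% algorithms) {
    fits$afp_lab_dafp <- fit_lab_model(train_screens, "full", K = K,
                                       seed = seed + 1L,
                                       interactions = match.arg(interactions))
  }
  if ("peb" %in% algorithms) {
    fits$peb <- estimate_peb_params(train_screens)
  }
  fits
}

match_algorithms <- function(algorithms) {
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad)) {
    abort(sprintf("unknown algorithm tag(s): %s (choose from %s)",
                  paste(bad, collapse = ", "), paste(ALGORITHMS, collapse = ", ")))
  }
  unique(algorithms)
}

#' Score a screen table with every fitted algorithm
#'
#' Produces the long per-screen score table shared by calibration,
#' evaluation and plotting. Screens a risk model cannot score (missing
#' concurrent labs) get `NA` scores and remain positive only through the
#' OR rule.
#'
#' @param screens Screen table from [prepare_screens()].
#' @param fits Named list from [fit_algorithms()].
#' @return Tibble with `algorithm`, `id`, `delta`, `d`, `t`, `j`, `afp`,
#'   `score`.
#' @export
score_algorithms <- function(screens, fits) {
  purrr::imap_dfr(fits, function(fit, algo) {
    base <- dplyr::select(screens, "id", "delta", "d", "t", "j", "afp")
    if (inherits(fit, "peb_params")) {
      sc <- peb_score(screens, fit)$score
    } else if (fit$covariate_set == "afp_only") {
      sc <- predict(fit, screens)
    } else {
      sc <- rep(NA_real_, nrow(screens))
      ok <- screens$lab_eligible
      if (any(ok)) sc[ok] <- predict(fit, screens[ok, , drop = FALSE])
    }
    dplyr::mutate(base, algorithm = algo, score = sc, .before = 1)
  })
}

#' Out-of-bag bootstrap validation of the screening algorithms
#'
#' Per replicate, `n` patients are drawn with replacement to form the
#' bootstrap training cohort (resampled patients are re-identified so
#' duplicates count as distinct); all patients absent from the draw form
#' the validation cohort. Algorithms are fitted on the training draw,
#' thresholds calibrated to the target FPR, performance evaluated
#' out-of-bag, and the measures averaged over replicates. Replicates whose
#' out-of-bag set has no evaluable case are skipped and counted.
#'
#' @param cohort An `hcc_cohort`.
#' @param B Number of bootstrap replicates (default 300).
#' @param seed Root seed; each replicate uses an independent substream.
#' @param algorithms,windows,fpr_target,K,include_excluded As in
#'   [run_experiment()].
#' @return A list with `summary` (measures averaged over replicates),
#'   `replicates` (per-replicate measures) and `n_skipped`.
#' @export
oob_bootstrap <- function(cohort, B = 300, seed = 1L,
                          algorithms = ALGORITHMS, windows = c("C1", "D1"),
                          fpr_target = 0.10, K = 100,
                          include_excluded = TRUE) {
  stopifnot(inherits(cohort, "hcc_cohort"), nrow(cohort$patients) > 0)
  algorithms <- match_algorithms(algorithms)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B, replace = TRUE)
  reps <- vector("list", B)
  n_skipped <- 0L
  ids <- cohort$patients$id
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    draw <- sample(ids, length(ids), replace = TRUE)
    oob_ids <- setdiff(ids, draw)
    oob <- subset_cohort(cohort, oob_ids)
    if (sum(oob$patients$delta == 1) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    train <- resample_cohort(cohort, draw)
    res <- tryCatch(
      evaluate_split(prepare_screens(train), prepare_screens(oob),
                     algorithms, windows, fpr_target, K = K,
                     seed = rep_seeds[b], calibrate_on = "validation",
                     include_excluded = include_excluded),
      error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    reps[[b]] <- dplyr::mutate(res$measures, replicate = b)
  }
  replicates <- purrr::list_rbind(purrr::compact(reps))
  if (nrow(replicates) == 0) abort("every bootstrap replicate was skipped")
  summary <- replicates |>
    dplyr::summarise(dplyr::across(c("tpr", "fpr", "ppv", "npv", "burden"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_replicates = dplyr::n(),
                     .by = c("algorithm", "window"))
  list(summary = summary, replicates = replicates, n_skipped = n_skipped)
}

# duplicate-aware bootstrap resample: copy k of a patient gets a new id
resample_cohort <- function(cohort, draw) {
  counts <- table(draw)
  pieces_p <- list(); pieces_v <- list(); pieces_l <- list()
  for (k in seq_len(max(counts))) {
    ids_k <- names(counts)[counts >= k]
    sub <- subset_cohort(cohort, ids_k)
    suffix <- if (k == 1) "" else sprintf("#%d", k)
    sub$patients$id <- paste0(sub$patients$id, suffix)
    sub$visits$patient_id <- paste0(sub$visits$patient_id, suffix)
    if (!is.null(sub$labs)) sub$labs$patient_id <- paste0(sub$labs$patient_id, suffix)
    pieces_p[[k]] <- sub$patients; pieces_v[[k]] <- sub$visits
    pieces_l[[k]] <- sub$labs
  }
  new_cohort(dplyr::bind_rows(pieces_p), dplyr::bind_rows(pieces_v),
             if (!is.null(cohort$labs)) dplyr::bind_rows(purrr::compact(pieces_l)))
}

# shared fit -> calibrate -> score -> evaluate path for split-sample and
# bootstrap validation
evaluate_split <- function(train_screens, valid_screens, algorithms, windows,
                           fpr_target, K, seed, calibrate_on,
                           include_excluded = TRUE, interactions = "outer") {
  fits <- fit_algorithms(train_screens, algorithms, K = K, seed = seed,
                         interactions = interactions)
  valid_scores <- score_algorithms(valid_screens, fits)
  train_scores <- score_algorithms(train_screens, fits)
  tau_max <- max(c(train_screens$d, valid_screens$d)) + 1

  measures <- list(); thresholds <- list()
  for (w in windows) {
    win <- detection_window(w, tau_max = tau_max)
    for (algo in algorithms) {
      cal_scores <- if (calibrate_on == "training") train_scores else valid_scores
      cal <- calibrate_threshold(
        classify_screens(dplyr::filter(cal_scores, .data$algorithm == algo), win),
        fpr_target)
      sc <- apply_threshold(dplyr::filter(valid_scores, .data$algorithm == algo),
                            cal$threshold)
      perf <- screen_performance(sc, win, include_excluded)
      burden <- false_positive_burden(sc, win)
      measures[[paste(w, algo)]] <- dplyr::mutate(
        perf, algorithm = algo, threshold = cal$threshold,
        achieved_cal_fpr = cal$achieved_fpr, burden = burden$fraction,
        .before = 1)
      thresholds[[paste(w, algo)]] <- tibble::tibble(
        window = w, algorithm = algo, threshold = cal$threshold,
        achieved_fpr = cal$achieved_fpr, floor_fpr = cal$floor_fpr)
    }
  }
  list(measures = purrr::list_rbind(measures),
       thresholds = purrr::list_rbind(thresholds),
       fits = fits, valid_scores = valid_scores)
}

#' Run an end-to-end screening experiment
#'
#' Simulates (or accepts) a cohort, splits it into training and validation
#' halves, fits the requested algorithms on training data, calibrates each
#' algorithm's threshold to the target screening-level FPR, scores the
#' validation screens under the OR rule and computes the full longitudinal
#' performance table, per-patient false-positive burden and (with two or
#' more algorithms) the first-positive timing comparison.
#'
#' @param cohort An `hcc_cohort` or a [sim_config()] (simulated at
#'   `seed`).
#' @param algorithms Subset of `"afp_only"`, `"afp_lab_dafp"`, `"peb"`.
#' @param windows Detection-window labels, see [detection_window()].
#' @param fpr_target Target screening-level FPR (default 0.10).
#' @param calibrate_on `"training"` (prospective use of training-calibrated
#'   thresholds) or `"validation"` (fixes the validation FPR exactly at the
#'   target, the usual fixed-FPR reporting convention).
#' @param seed Root seed; the split, resampling fits and any simulation
#'   draw their substreams from it.
#' @param K Resampling iterations of the risk models.
#' @param include_excluded Predictive-value denominator convention, see
#'   [screen_ppv_npv()].
#' @param interactions Interaction expansion of the full risk model.
#' @return An object of class `hcc_experiment`: list with `measures`,
#'   `thresholds`, `first_positive`, `fits`, `scores` (validation),
#'   `cohort` sizes and a reproducibility `manifest`.
#' @export
run_experiment <- function(cohort = sim_config(),
                           algorithms = ALGORITHMS,
                           windows = c("C1", "D1"),
                           fpr_target = 0.10,
                           calibrate_on = c("training", "validation"),
                           seed = 1L, K = 100,
                           include_excluded = TRUE,
                           interactions = c("outer", "linear")) {
  calibrate_on <- match.arg(calibrate_on)
  interactions <- match.arg(interactions)
  algorithms <- match_algorithms(algorithms)
  if (fpr_target <= 0 || fpr_target >= 1) abort("fpr_target must be in (0, 1)")

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, 3, replace = TRUE)
  config <- NULL
  if (inherits(cohort, "sim_config")) {
    config <- cohort
    cohort <- simulate_cohort(config, seed = sub_seeds[1])
  }
  stopifnot(inherits(cohort, "hcc_cohort"))

  halves <- split_sample(cohort, seed = sub_seeds[2])
  train_screens <- prepare_screens(halves$training)
  valid_screens <- prepare_screens(halves$validation)
  res <- evaluate_split(train_screens, valid_screens, algorithms, windows,
                        fpr_target, K = K, seed = sub_seeds[3],
                        calibrate_on = calibrate_on,
                        include_excluded = include_excluded,
                        interactions = interactions)

  first_pos <- NULL
  if (length(algorithms) >= 2) {
    tau_max <- max(valid_screens$d) + 1
    win <- detection_window(windows[1], tau_max = tau_max)
    thr <- res$thresholds[res$thresholds$window == windows[1], ]
    pos <- res$valid_scores |>
      dplyr::left_join(dplyr::select(thr, "algorithm", "threshold"),
                       by = "algorithm") |>
      dplyr::mutate(positive = or_rule_positive(.data$afp,
                                                .data$score > .data$threshold))
    first_pos <- first_positive_comparison(pos, win)
  }

  manifest <- list(
    seed = seed, substreams = as.integer(sub_seeds),
    algorithms = algorithms, windows = windows,
    fpr_target = fpr_target, calibrate_on = calibrate_on, K = K,
    simulated = !is.null(config),
    config_hash = rlang::hash(config %||% "external cohort"),
    n_training = nrow(halves$training$patients),
    n_validation = nrow(halves$validation$patients),
    package_version = as.character(utils::packageVersion("hccscreen")))

  structure(list(measures = res$measures, thresholds = res$thresholds,
                 first_positive = first_pos, fits = res$fits,
                 scores = res$valid_scores, manifest = manifest),
            class = "hcc_experiment")
}

#' @export
print.hcc_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<hcc_experiment> %s on %d training / %d validation patients (FPR target %.2f, calibrated on %s)\n",
    paste(m$algorithms, collapse = " + "), m$n_training, m$n_validation,
    m$fpr_target, m$calibrate_on))
  print(dplyr::select(x$measures, "algorithm", "window", "tpr", "fpr",
                      "ppv", "npv", "burden", "n_cases"))
  invisible(x)
}
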