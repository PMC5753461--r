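#' Cohort container
#'
#' A cohort bundles three tibbles sharing patient identifiers:
#' `patients` (one row per patient: `id`, `delta`, `d`, `baseline_age`, and
#' optionally `sex`, `race`), `visits` (one row per AFP screening visit:
#' `patient_id`, `t`, `afp`) and `labs` (one row per concurrent laboratory
#' test: `patient_id`, `analyte` in `"ALT"`/`"PLT"`, `value`, `t`).
#' All times are months since the HCV index date; `delta` is the HCC case
#' indicator and `d` the months to HCC diagnosis (cases) or end of study
#' (controls).
#'
#' @param patients,visits,labs Data frames with the columns described above.
#'   `labs` may be `NULL`.
#' @return An object of class `hcc_cohort`: a named list of validated
#'   tibbles.
#' @export
new_cohort <- function(patients, visits, labs = NULL) {
  patients <- tibble::as_tibble(patients)
  visits <- tibble::as_tibble(visits)
  req_p <- c("id", "delta", "d", "baseline_age")
  req_v <- c("patient_id", "t", "afp")
  check_columns(patients, req_p, "patients")
  check_columns(visits, req_v, "visits")
  if (anyDuplicated(patients$id)) {
    abort("patient ids must be unique within a cohort")
  }
  if (!all(patients$delta %in% c(0, 1))) {
    abort("`delta` must be 0 (control) or 1 (HCC case)")
  }
  if (any(patients$d <= 0)) {
    abort("`d` (months to diagnosis / end of study) must be positive")
  }
  if (!all(visits$patient_id %in% patients$id)) {
    abort("every visit must belong to a patient in `patients`")
  }
  if (any(!is.finite(visits$t))) {
    abort("visit times must be finite numbers")
  }
  if (!is.null(labs)) {
    labs <- tibble::as_tibble(labs)
    check_columns(labs, c("patient_id", "analyte", "value", "t"), "labs")
    if (any(labs$value < 0, na.rm = TRUE)) {
      abort("laboratory values must be non-negative")
    }
    if (!all(labs$analyte %in% c("ALT", "PLT"))) {
      abort("lab `analyte` must be 'ALT' or 'PLT'")
    }
  }
  structure(list(patients = patients, visits = visits, labs = labs),
            class = "hcc_cohort")
}

#' @export
print.hcc_cohort <- function(x, ...) {
  n_case <- sum(x$patients$delta == 1)
  cat(sprintf(
    "<hcc_cohort> %d patients (%d HCC cases, %d controls), %d AFP visits, %d lab records\n",
    nrow(x$patients), n_case, nrow(x$patients) - n_case, nrow(x$visits),
    if (is.null(x$labs)) 0L else nrow(x$labs)))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read a cohort from delimited text files
#'
#' Reads the three-table cohort schema (see [new_cohort()]) from CSV files,
#' validates it, and drops visit rows whose AFP is not a valid positive
#' measurement (inclusion requires AFP > 0 ng/ml). Dropped rows are reported
#' via a message and recorded in the `dropped` attribute.
#'
#' @param patients,visits,labs Paths to UTF-8 comma-delimited files. `labs`
#'   may be `NULL` when no concurrent laboratory data exist.
#' @return An `hcc_cohort`; attribute `dropped` holds the excluded visit rows.
#' @export
read_cohort <- function(patients, visits, labs = NULL) {
  for (p in c(patients, visits, labs)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  pat <- readr::read_csv(patients, show_col_types = FALSE, progress = FALSE)
  vis <- readr::read_csv(visits, show_col_types = FALSE, progress = FALSE)
  lab <- if (!is.null(labs)) {
    readr::read_csv(labs, show_col_types = FALSE, progress = FALSE)
  }
  check_columns(vis, c("patient_id", "t", "afp"), "visits")
  if (!is.numeric(vis$t)) {
    bad <- which(is.na(suppressWarnings(as.numeric(vis$t))))
    abort(sprintf("non-numeric visit time at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad_afp <- !is.finite(vis$afp) | vis$afp <= 0
  dropped <- vis[bad_afp, , drop = FALSE]
  if (nrow(dropped)) {
    message(sprintf("read_cohort: excluded %d visit row(s) without a valid (> 0 ng/ml) AFP",
                    nrow(dropped)))
    vis <- vis[!bad_afp, , drop = FALSE]
  }
  out <- new_cohort(pat, vis, lab)
  attr(out, "dropped") <- tibble::as_tibble(dropped)
  out
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: writes `patients.csv`, `visits.csv` and (when
#' present) `labs.csv` under `dir`, plus `truth.csv` when the cohort carries
#' a simulation truth sidecar (see [simulate_cohort()]).
#'
#' @param cohort An `hcc_cohort`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"), progress = FALSE)
  if (!is.null(cohort$labs)) {
    readr::write_csv(cohort$labs, file.path(dir, "labs.csv"), progress = FALSE)
  }
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Collapse same-day measurements on the log2 scale
#'
#' Multiple measurements of the same quantity on the same day are summarized
#' as the anti-log2 of the mean of their log2 values. An optional `floor`
#' (used for ALT/PLT, which the risk model truncates at 1 anyway) guards the
#' transform; AFP is collapsed unfloored since valid AFP is already > 0.
#'
#' @param data A data frame.
#' @param value Name of the value column (string).
#' @param by Character vector of grouping columns identifying a "day"
#'   (e.g. patient and time, plus analyte for labs).
#' @param floor Optional lower bound applied before the log transform.
#' @return A tibble with one row per group, other columns dropped.
#' @export
collapse_same_day <- function(data, value = "afp", by = c("patient_id", "t"),
                              floor = NULL) {
  v <- data[[value]]
  if (is.null(floor) && any(v <= 0, na.rm = TRUE)) {
    abort(sprintf("`%s` must be positive for log2 collapsing", value))
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      "{value}" := 2^mean(log2(if (is.null(floor)) .data[[value]]
                               else pmax(.data[[value]], floor))),
      .groups = "drop"
    )
}

#' Attach most recent concurrent ALT and PLT to each AFP visit
#'
#' A laboratory test is concurrent with an AFP visit at time `t` when it was
#' drawn in the closed window `[t - 6, t]` (months). For each visit the most
#' recent concurrent value of each analyte is attached; same-day duplicate
#' labs are first collapsed on the log2 scale ([collapse_same_day()]).
#' Visits with both analytes attached are flagged `lab_eligible`; the rest
#' remain usable by AFP-only and PEB algorithms.
#'
#' @param visits Tibble with `patient_id`, `t`, `afp`.
#' @param labs Tibble with `patient_id`, `analyte`, `value`, `t`, or `NULL`.
#' @param window Lookback window in months (default 6).
#' @return `visits` with columns `alt`, `plt`, `lab_eligible` added,
#'   per-patient row order preserved.
#' @export
attach_concurrent_labs <- function(visits, labs, window = 6) {
  visits <- tibble::as_tibble(visits)
  if (is.null(labs) || nrow(labs) == 0) {
    return(dplyr::mutate(visits, alt = NA_real_, plt = NA_real_,
                         lab_eligible = FALSE))
  }
  if (any(labs$value < 0, na.rm = TRUE)) abort("laboratory values must be non-negative")
  labs <- collapse_same_day(labs, "value", by = c("patient_id", "analyte", "t"),
                            floor = 1)

  match_one <- function(visit_t, lab_t, lab_v) {
    ord <- order(lab_t)
    lab_t <- lab_t[ord]; lab_v <- lab_v[ord]
    idx <- findInterval(visit_t, lab_t)   # last lab at or before visit
    val <- ifelse(idx >= 1 & lab_t[pmax(idx, 1)] >= visit_t - window,
                  lab_v[pmax(idx, 1)], NA_real_)
    val
  }

  lab_split <- split(labs, labs$analyte)
  out <- visits |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(v, key) {
      for (an in c("ALT", "PLT")) {
        lb <- lab_split[[an]]
        lb <- lb[lb$patient_id == key$patient_id, , drop = FALSE]
        col <- tolower(an)
        v[[col]] <- if (is.null(lb) || nrow(lb) == 0) {
          NA_real_
        } else {
          match_one(v$t, lb$t, lb$value)
        }
      }
      v
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row") |>
    dplyr::mutate(lab_eligible = !is.na(.data$alt) & !is.na(.data$plt))
  out
}

#' Annualized AFP rate of change since the previous screen
#'
#' For each visit, the rate of change of log2(AFP) over the previous year is
#' `[log2(AFP_j) - log2(AFP_{j-1})] / [(t_j - t_{j-1}) / 12]`, defined only
#' when the previous AFP test was within the last 12 months
#' (`dafp_obs = 1`). The first visit of every patient has `dafp_obs = 0`.
#'
#' @param visits Tibble with `patient_id`, `t`, `afp`; same-day duplicates
#'   must already be collapsed.
#' @param max_gap Maximum gap in months for the rate to be observed
#'   (default 12).
#' @return `visits` with `dafp_obs` (0/1) and `dafp_rate` (log2 per year,
#'   `NA` when unobserved) added; rows sorted by `t` within patient.
#' @export
compute_delta_afp <- function(visits, max_gap = 12) {
  visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(
      .gap = .data$t - dplyr::lag(.data$t),
      .prev = dplyr::lag(.data$afp),
      dafp_obs = as.integer(!is.na(.data$.gap) & .data$.gap <= max_gap),
      dafp_rate = dplyr::if_else(
        .data$dafp_obs == 1L,
        (log2(pmax(.data$afp, 1)) - log2(pmax(.data$.prev, 1))) / (.data$.gap / 12),
        NA_real_
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap", -".prev") -> out
  if (any(out$dafp_obs == 1L & !is.finite(out$dafp_rate))) {
    abort("zero time gap between distinct visits; collapse same-day visits first")
  }
  out
}

#' Six-month outcome label per screening visit
#'
#' `D = 1` when the patient is an HCC case diagnosed within six months of the
#' visit: `d < t + 6` (strict) and `delta = 1`; `D = 0` otherwise.
#'
#' @param visits Tibble with `patient_id`, `t`.
#' @param patients Tibble with `id`, `delta`, `d`.
#' @param horizon Outcome horizon in months (default 6).
#' @return `visits` with an integer column `D` added.
#' @export
label_six_month_outcome <- function(visits, patients, horizon = 6) {
  visits |>
    dplyr::left_join(
      dplyr::select(patients, patient_id = "id", "delta", "d"),
      by = "patient_id"
    ) |>
    dplyr::mutate(D = as.integer(.data$delta == 1 & .data$d < .data$t + horizon)) |>
    dplyr::select(-"delta", -"d")
}

#' Build the analysis screen table from a cohort
#'
#' Runs the full preprocessing chain: same-day AFP collapsing, concurrent
#' lab matching, annualized AFP rate of change, age at visit
#' (`baseline_age + t/12`), screen index `j` and the six-month outcome
#' label. The result is the tidy per-screen table every algorithm and
#' evaluation function in the package consumes.
#'
#' @param cohort An `hcc_cohort`.
#' @return A tibble with one row per screen: `id`, `delta`, `d`,
#'   `baseline_age`, `t`, `j`, `afp`, `alt`, `plt`, `lab_eligible`, `age`,
#'   `dafp_obs`, `dafp_rate`, `D`.
#' @export
prepare_screens <- function(cohort) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  vis <- collapse_same_day(cohort$visits, "afp", by = c("patient_id", "t"))
  vis <- attach_concurrent_labs(vis, cohort$labs)
  vis <- compute_delta_afp(vis)
  vis <- label_six_month_outcome(vis, cohort$patients)
  vis |>
    dplyr::left_join(
      dplyr::select(cohort$patients, patient_id = "id", "delta", "d", "baseline_age"),
      by = "patient_id"
    ) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$t, .by_group = TRUE) |>
    dplyr::mutate(j = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(age = .data$baseline_age + .data$t / 12) |>
    dplyr::select(id = "patient_id", "delta", "d", "baseline_age", "t", "j",
                  "afp", "alt", "plt", "lab_eligible", "age",
                  "dafp_obs", "dafp_rate", "D")
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort An `hcc_cohort`.
#' @param ids Patient identifiers to keep.
#' @return An `hcc_cohort` containing only those patients, their visits and
#'   labs (truth sidecar subset accordingly).
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "hcc_cohort"))
  out <- new_cohort(
    dplyr::filter(cohort$patients, .data$id %in% ids),
    dplyr::filter(cohort$visits, .data$patient_id %in% ids),
    if (!is.null(cohort$labs)) dplyr::filter(cohort$labs, .data$patient_id %in% ids)
  )
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    attr(out, "truth") <- dplyr::filter(truth, .data$id %in% ids)
  }
  out
}
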