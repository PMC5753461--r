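# Brute-force reference implementations, kept deliberately naive (explicit
# loops over screens) and independent of the package's vectorized code
# paths.

oracle_classify <- function(delta, d, t, tau1, tau2) {
  if (delta == 0) return("fp")
  if (t < d - tau1) return("fp")
  if (t >= d - tau1 && t <= d - tau2) return("tp")
  "excluded"
}

# screens: data frame with id, delta, d, t, positive
oracle_measures <- function(screens, tau1, tau2, include_excluded = TRUE) {
  cls <- character(nrow(screens))
  for (i in seq_len(nrow(screens))) {
    cls[i] <- oracle_classify(screens$delta[i], screens$d[i], screens$t[i],
                              tau1, tau2)
  }
  # patient-level TPR
  num <- 0L; den <- 0L
  for (pid in unique(screens$id[screens$delta == 1])) {
    rows <- which(screens$id == pid & cls == "tp")
    if (length(rows) == 0) next
    den <- den + 1L
    if (any(screens$positive[rows])) num <- num + 1L
  }
  tpr <- if (den > 0) num / den else NA_real_
  # screening-level FPR
  fp_rows <- which(cls == "fp")
  fpr <- if (length(fp_rows)) mean(screens$positive[fp_rows]) else NA_real_
  # predictive values
  keep <- if (include_excluded) seq_len(nrow(screens)) else which(cls != "excluded")
  pos <- keep[screens$positive[keep]]
  neg <- keep[!screens$positive[keep]]
  ppv <- if (length(pos)) mean(cls[pos] == "tp") else NA_real_
  npv <- if (length(neg)) mean(cls[neg] == "fp") else NA_real_
  list(tpr = tpr, fpr = fpr, ppv = ppv, npv = npv, n_cases = den)
}

oracle_burden <- function(screens, tau1, tau2, k = 2) {
  frac_num <- 0L; den <- 0L
  for (pid in unique(screens$id)) {
    rows <- which(screens$id == pid)
    fp_rows <- rows[vapply(rows, function(i) {
      oracle_classify(screens$delta[i], screens$d[i], screens$t[i],
                      tau1, tau2) == "fp"
    }, logical(1))]
    if (length(fp_rows) == 0) next
    den <- den + 1L
    if (sum(screens$positive[fp_rows]) > k) frac_num <- frac_num + 1L
  }
  if (den == 0) NA_real_ else frac_num / den
}

# a small mixed cohort of cases and controls with assorted screen patterns,
# randomized under the caller's seed
random_toy_screens <- function(n_patients = 12, max_screens = 5) {
  rows <- list()
  for (p in seq_len(n_patients)) {
    delta <- rbinom(1, 1, 0.5)
    d <- runif(1, 10, 60)
    n <- sample.int(max_screens, 1)
    t <- sort(runif(n, 0, d - 0.5))
    rows[[p]] <- data.frame(id = sprintf("T%02d", p), delta = delta, d = d,
                            t = t, positive = runif(n) < 0.4,
                            afp = exp(runif(n, 0, 5)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic three-patient cohort files for I/O tests
write_toy_cohort_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patients <- data.frame(id = c("A", "B", "C"), delta = c(0L, 1L, 0L),
                         d = c(60, 40, 55), baseline_age = c(50, 61, 47))
  visits <- data.frame(patient_id = c("A", "A", "B", "B", "C"),
                       t = c(1, 10, 5, 36, 2),
                       afp = c(4, 8, 16, 300, 6))
  labs <- data.frame(patient_id = c("A", "B", "B"),
                     analyte = c("ALT", "ALT", "PLT"),
                     value = c(40, 80, 120),
                     t = c(0.5, 34, 35))
  write.csv(patients, file.path(dir, "patients.csv"), row.names = FALSE)
  write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)
  write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE)
  list(patients = file.path(dir, "patients.csv"),
       visits = file.path(dir, "visits.csv"),
       labs = file.path(dir, "labs.csv"))
}
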