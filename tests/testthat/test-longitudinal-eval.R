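test_that("window labels map to the documented (tau1, tau2) pairs", {
  expect_equal(detection_window("A1")[c("tau1", "tau2")], list(tau1 = 6, tau2 = 0))
  expect_equal(detection_window("B2")[c("tau1", "tau2")], list(tau1 = 12, tau2 = 3))
  expect_equal(detection_window("C1")$tau1, 24)
  expect_equal(detection_window("D1", tau_max = 120)$tau1, 120)
  expect_equal(detection_window("D2")$tau1, Inf)
  expect_error(detection_window(tau1 = 3, tau2 = 6, label = NULL), "tau1 > tau2")
})

test_that("screen classification pins the window boundaries", {
  win_c1 <- detection_window("C1")
  case_boundary <- tibble::tibble(id = "X", delta = 1, d = 30, t = 6)
  cls <- classify_screens(case_boundary, win_c1)
  expect_true(cls$tp_eligible)   # t = d - tau1 exactly, inclusive
  win_a2 <- detection_window("A2")
  late <- classify_screens(tibble::tibble(id = "X", delta = 1, d = 30, t = 28),
                           win_a2)
  expect_true(late$excluded)     # within 3 months of diagnosis
  ctrl <- classify_screens(tibble::tibble(id = "Y", delta = 0, d = 30, t = 28),
                           win_a2)
  expect_true(ctrl$fp_eligible)
  expect_false(ctrl$excluded)
  # partition: exactly one class per screen
  set.seed(3)
  toy <- random_toy_screens()
  cls <- classify_screens(toy, win_c1)
  expect_true(all(cls$tp_eligible + cls$fp_eligible + cls$excluded == 1))
})

test_that("cases screened only outside the window leave the TPR denominator", {
  screens <- tibble::tibble(
    id = c("A", "A", "B"), delta = 1, d = c(100, 100, 100),
    t = c(10, 20, 90), positive = c(TRUE, TRUE, TRUE))
  win <- detection_window("C1")
  res <- patient_tpr(screens, win)
  expect_equal(res$n_cases, 1)   # only B has a screen in [76, 100]
  expect_equal(res$tpr, 1)
  two_cases <- tibble::tibble(id = c("A", "B"), delta = 1, d = 100,
                              t = c(90, 95), positive = c(TRUE, FALSE))
  expect_equal(patient_tpr(two_cases, win)$tpr, 0.5)
})

test_that("screening-level FPR pools screens, not patients", {
  screens <- tibble::tibble(
    id = c(rep("A", 9), "B"), delta = 0, d = 100,
    t = 1:10, positive = c(TRUE, rep(FALSE, 9)))
  expect_equal(screening_fpr(screens, detection_window("C1"))$fpr, 0.1)
  none <- dplyr::mutate(screens, positive = FALSE)
  expect_equal(screening_fpr(none, detection_window("C1"))$fpr, 0)
})

test_that("a perfect algorithm attains PPV = NPV = 1", {
  win <- detection_window("B1")
  set.seed(10)
  toy <- random_toy_screens(20)
  cls <- classify_screens(toy, win)
  toy$positive <- cls$tp_eligible
  pv <- screen_ppv_npv(toy, win)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)
  all_pos <- dplyr::mutate(toy, positive = TRUE)
  pv_all <- suppressWarnings(screen_ppv_npv(all_pos, win))  # NPV undefined
  expect_equal(pv_all$ppv, mean(cls$tp_eligible))
  expect_true(is.na(pv_all$npv))
})

test_that("all four measures equal brute-force counting on toy cohorts", {
  set.seed(11)
  for (rep in 1:6) {
    toy <- random_toy_screens(10)
    for (lab in c("A1", "B1", "C1", "D1", "A2", "B2", "C2", "D2")) {
      win <- detection_window(lab, tau_max = 200)
      for (inc in c(TRUE, FALSE)) {
        # narrow windows can leave no evaluable case; both routes agree on NA
        got <- suppressWarnings(screen_performance(toy, win, include_excluded = inc))
        want <- oracle_measures(toy, win$tau1, win$tau2, include_excluded = inc)
        expect_equal(got$tpr, want$tpr, info = paste(lab, rep))
        expect_equal(got$fpr, want$fpr, info = paste(lab, rep))
        expect_equal(got$ppv, want$ppv, info = paste(lab, rep))
        expect_equal(got$npv, want$npv, info = paste(lab, rep))
        expect_equal(got$n_cases, want$n_cases, info = paste(lab, rep))
      }
    }
  }
})

test_that("TP-eligible sets nest across widening windows", {
  set.seed(12)
  toy <- random_toy_screens(15)
  labs <- c("A1", "B1", "C1", "D1")
  sets <- lapply(labs, function(l) {
    cls <- classify_screens(toy, detection_window(l, tau_max = 200))
    which(cls$tp_eligible)
  })
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("TPR and FPR fall together as the threshold rises", {
  set.seed(13)
  toy <- random_toy_screens(25)
  toy$score <- runif(nrow(toy))
  win <- detection_window("C1")
  thr <- seq(0, 1, by = 0.1)
  perf <- lapply(thr, function(c_) {
    sc <- apply_threshold(toy, c_)
    list(tpr = patient_tpr(sc, win)$tpr, fpr = screening_fpr(sc, win)$fpr)
  })
  tprs <- vapply(perf, `[[`, numeric(1), "tpr")
  fprs <- vapply(perf, `[[`, numeric(1), "fpr")
  expect_true(all(diff(tprs) <= 1e-12))
  expect_true(all(diff(fprs) <= 1e-12))
})

test_that("excluded screens never enter TPR numerators or FPR denominators", {
  win <- detection_window("A2")
  screens <- tibble::tibble(
    id = "A", delta = 1, d = 30,
    t = c(28, 29), positive = c(TRUE, TRUE))  # both in (d-3, d]
  expect_warning(res <- patient_tpr(screens, win), "TPR undefined")
  expect_equal(res$n_cases, 0)
  expect_true(is.na(suppressWarnings(screening_fpr(screens, win)$fpr)))
})

test_that("false-positive burden counts patients beyond k false positives", {
  win <- detection_window("C1")
  screens <- tibble::tibble(
    id = rep(sprintf("P%02d", 1:10), each = 3), delta = 0, d = 100,
    t = rep(c(1, 2, 3), 10), positive = FALSE)
  screens$positive[screens$id == "P01"] <- TRUE  # 3 FPs for one patient
  res <- false_positive_burden(screens, win)
  expect_equal(res$fraction, 0.1)
  expect_equal(false_positive_burden(dplyr::mutate(screens, positive = FALSE),
                                     win)$fraction, 0)
  # agreement with the naive loop on random data
  set.seed(14)
  toy <- random_toy_screens(15)
  expect_equal(false_positive_burden(toy, win)$fraction,
               oracle_burden(toy, win$tau1, win$tau2))
})

test_that("first-positive timing handles never-positive algorithms via d", {
  win <- detection_window("C1")
  scores <- dplyr::bind_rows(
    tibble::tibble(algorithm = "A", id = "X", delta = 1, d = 30,
                   t = c(10, 20), positive = c(FALSE, TRUE)),
    tibble::tibble(algorithm = "B", id = "X", delta = 1, d = 30,
                   t = c(10, 20), positive = c(FALSE, FALSE)))
  res <- first_positive_comparison(scores, win)
  expect_equal(res$first_a, 1)  # B imputed at d = 30 > 20
  expect_equal(res$first_b, 0)
  same <- dplyr::mutate(scores, positive = .data$t == 20)
  res_same <- first_positive_comparison(same, win)
  expect_equal(res_same$same, 1)
})

test_that("first-positive fractions match hand enumeration on six cases", {
  win <- detection_window("C1")
  # cases X1..X6, all with screens at t = 10, 20 and d = 30
  mk <- function(algo, pos) {
    purrr::map_dfr(1:6, function(i) {
      tibble::tibble(algorithm = algo, id = paste0("X", i), delta = 1, d = 30,
                     t = c(10, 20), positive = pos[[i]])
    })
  }
  a <- mk("A", list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE),
                    c(TRUE, FALSE), c(FALSE, FALSE), c(FALSE, FALSE)))
  b <- mk("B", list(c(FALSE, TRUE), c(FALSE, TRUE), c(TRUE, FALSE),
                    c(TRUE, FALSE), c(FALSE, FALSE), c(FALSE, TRUE)))
  res <- first_positive_comparison(dplyr::bind_rows(a, b), win)
  # X5 dropped (no algorithm positive); of the 5 compared:
  # X1 A first; X2 same; X3 B first; X4 same visit; X6 B first
  expect_equal(res$n_cases, 5)
  expect_equal(res$first_a, 1 / 5)
  expect_equal(res$first_b, 2 / 5)
  expect_equal(res$same, 2 / 5)
})

test_that("decile risks vanish on control-only data and warn on empty deciles", {
  set.seed(15)
  scores <- tibble::tibble(id = sprintf("C%03d", 1:100), delta = 0, d = 60,
                           t = runif(100, 0, 50), score = runif(100))
  dr <- decile_risk(scores, detection_window("C1"))
  expect_true(all(dr$deciles$risk == 0))
  tied <- dplyr::mutate(scores, score = 0.5)
  expect_warning(decile_risk(tied, detection_window("C1")), "empty")
})
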