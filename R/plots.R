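#' Plot performance curves against the risk percentile
#'
#' Mirrors the standard comparison layout: TPR/FPR and PPV/NPV panels as
#' functions of the risk percentile, optionally restricted to the upper
#' percentile range where screening decisions live.
#'
#' @param object An `hcc_curves` tibble from [performance_curves()], or a
#'   named list of them (one per algorithm).
#' @param from Lower percentile limit of the x axis (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcc_curves <- function(object, from = 0.8, ...) {
  plot_performance_curves(list(algorithm = object), from = from)
}

#' @rdname autoplot.hcc_curves
#' @param curves Named list of `hcc_curves` tibbles keyed by algorithm.
#' @export
plot_performance_curves <- function(curves, from = 0.8) {
  if (inherits(curves, "hcc_curves")) curves <- list(algorithm = curves)
  long <- purrr::imap_dfr(curves, function(cv, algo) {
    tibble::as_tibble(cv) |>
      tidyr::pivot_longer(c("tpr", "fpr", "ppv", "npv"),
                          names_to = "measure", values_to = "value") |>
      dplyr::mutate(algorithm = algo,
                    panel = dplyr::if_else(.data$measure %in% c("tpr", "fpr"),
                                           "TPR / FPR", "PPV / NPV"),
                    measure = toupper(.data$measure))
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$percentile, y = .data$value,
                                     colour = .data$algorithm,
                                     linetype = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::coord_cartesian(xlim = c(from, 1)) +
    ggplot2::labs(x = "Risk percentile", y = NULL,
                  colour = "Algorithm", linetype = "Measure") +
    ggplot2::theme_minimal()
}

#' Plot HCC risk by score decile
#'
#' Decile point estimates with the natural-cubic-spline smooth from
#' [decile_risk()].
#'
#' @param risk Result of [decile_risk()], or a named list of them keyed by
#'   algorithm.
#' @return A ggplot object.
#' @export
plot_decile_risk <- function(risk) {
  if (!is.null(risk$deciles)) risk <- list(algorithm = risk)
  pts <- purrr::imap_dfr(risk, ~ dplyr::mutate(.x$deciles, algorithm = .y))
  sm <- purrr::imap_dfr(risk, ~ dplyr::mutate(.x$curve, algorithm = .y))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = sm,
                       ggplot2::aes(x = .data$percentile, y = .data$risk,
                                    colour = .data$algorithm)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$midpoint, y = .data$risk,
                                     colour = .data$algorithm)) +
    ggplot2::labs(x = "Risk percentile (decile midpoints)",
                  y = "Risk of HCC within the window",
                  colour = "Algorithm") +
    ggplot2::theme_minimal()
}

#' Plot the first-positive timing comparison
#'
#' Stacked bars of the fraction of HCC cases flagged first by each
#' algorithm of a pair or at the same visit, from
#' [first_positive_comparison()].
#'
#' @param comparison Tibble from [first_positive_comparison()].
#' @return A ggplot object.
#' @export
plot_first_positive <- function(comparison) {
  long <- comparison |>
    dplyr::mutate(pair = paste(.data$algorithm_a, "vs", .data$algorithm_b)) |>
    tidyr::pivot_longer(c("first_a", "first_b", "same"),
                        names_to = "who", values_to = "fraction") |>
    dplyr::mutate(who = dplyr::case_when(
      .data$who == "first_a" ~ paste("First:", .data$algorithm_a),
      .data$who == "first_b" ~ paste("First:", .data$algorithm_b),
      TRUE ~ "Same visit"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$fraction,
                                     fill = .data$who)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "Fraction of compared HCC cases", fill = NULL) +
    ggplot2::theme_minimal()
}
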