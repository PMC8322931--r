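# ggplot2 visualisations for the main result types.

#' Score distributions by variant type
#'
#' Density of functionality scores for synonymous, nonsense and missense
#' variants of one map — the standard bimodality check.
#'
#' @param score_table A [build_score_table()] result.
#' @param background,folinate Map selector (defaults: first available).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(score_table, background = NULL,
                                    folinate = NULL) {
  df <- dplyr::filter(score_table, .data$well_measured)
  background <- background %||% df$background[1L]
  folinate <- folinate %||% df$folinate[1L]
  df <- dplyr::filter(df, .data$background == .env$background,
                      .data$folinate == .env$folinate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   colour = .data$type)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dotted") +
    ggplot2::labs(
      x = "functionality score", y = "density",
      title = paste0(background, " background, ", folinate,
                     " µg/mL folinate")
    ) +
    ggplot2::theme_minimal()
}

#' Dose-response fits for selected variants
#'
#' Per-replicate scores against folinate concentration with the fitted
#' linear response overlaid.
#'
#' @param records Per-replicate score records ([score_records()]).
#' @param fits A [fit_dose_response()] tibble.
#' @param variants Character vector of variant keys to show.
#' @param background Background to show.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(records, fits, variants,
                               background = "wt") {
  df <- dplyr::filter(records, .data$variant %in% variants,
                      .data$background == .env$background,
                      .data$well_measured)
  fl <- dplyr::filter(fits, .data$variant %in% variants,
                      .data$background == .env$background, .data$fit_ok)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$folinate, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fl,
      ggplot2::aes(intercept = .data$b, slope = .data$r),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant)) +
    ggplot2::labs(x = "folinate (µg/mL)", y = "functionality score") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_expectation Plot the expectation curve over its
#'   training pairs.
#' @param object An `expectation_curve`.
#' @param pairs Optional training pairs to show underneath.
#' @param ... Unused.
#' @method autoplot expectation_curve
#' @export
autoplot.expectation_curve <- function(object, pairs = NULL, ...) {
  grid <- tibble::tibble(
    s_wt = seq(object$range[1L], object$range[2L], length.out = 200L)
  )
  grid$s_av <- predict(object, grid$s_wt)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$s_wt, y = .data$s_av))
  if (!is.null(pairs)) {
    p <- p + ggplot2::geom_point(data = pairs, alpha = 0.2, size = 0.4)
  }
  p + ggplot2::geom_line(colour = "darkorange", linewidth = 1) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::labs(x = "single-mutant score",
                  y = "expected double-mutant score") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_classifier Plot the balanced precision-recall
#'   curve.
#' @param object A `bprc_eval`.
#' @param ... Unused.
#' @method autoplot bprc_eval
#' @export
autoplot.bprc_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.9, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "balanced precision",
                  title = sprintf("AUBPRC = %.3f, R90P = %.3f",
                                  object$aubprc, object$r90p)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_llrp Plot the per-domain LLRp transforms.
#' @param object An `llrp_function`.
#' @param ... Unused.
#' @method autoplot llrp_function
#' @export
autoplot.llrp_function <- function(object, ...) {
  df <- purrr::map_dfr(object$fits, function(f) {
    tibble::tibble(domain = f$domain, score = f$grid, llrp = f$llrp)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$llrp,
                                   colour = .data$domain)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "functionality score",
                  y = "log-likelihood ratio of pathogenicity") +
    ggplot2::theme_minimal()
}
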