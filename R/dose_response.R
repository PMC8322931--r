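# Per-variant linear folinate dose-response models: weighted least squares
# with known per-measurement errors, Gaussian likelihoods, and a
# likelihood-ratio test against the no-response null.

#' Fit linear dose-response models per variant
#'
#' For each (variant, background), fits the functionality score as a linear
#' function of folinate concentration, `s(c) = b + r * c`, by weighted
#' least squares with per-measurement errors treated as known
#' (closed-form normal equations, no iterative optimizer). The null model
#' fixes `r = 0`, which reduces to the inverse-variance weighted mean, and
#' `llr = logL_full - logL_null` (natural log) is the evidence for a
#' folinate response.
#'
#' @param measurements A tibble of score measurements with columns
#'   `variant`, `background`, `folinate`, `score` and `sd` — e.g. the
#'   per-replicate records ([score_records()]) restricted to well-measured
#'   rows, or a [build_score_table()] tibble.
#' @param min_concentrations Minimum distinct concentrations for a fit.
#' @return A tibble with one row per (variant, background): `b`, `r`,
#'   `se_b`, `se_r`, `cov_br`, `logl_full`, `logl_null`, `llr`, `n_obs`,
#'   `n_conc` and `fit_ok`.
#' @export
fit_dose_response <- function(measurements, min_concentrations = 2L) {
  if (inherits(measurements, "score_table")) {
    measurements <- dplyr::filter(measurements, .data$well_measured)
  }
  needed <- c("variant", "background", "folinate", "score", "sd")
  abort_if(!all(needed %in% names(measurements)),
           paste("Measurements need columns:",
                 paste(needed, collapse = ", ")))
  measurements <- dplyr::filter(measurements, is.finite(.data$score),
                                is.finite(.data$sd), .data$sd > 0)
  if (!"var_non" %in% names(measurements)) measurements$var_non <- 0
  if (!"var_shared" %in% names(measurements)) measurements$var_shared <- 0
  if (!"replicate" %in% names(measurements)) measurements$replicate <- 1L

  # closed-form WLS via grouped sufficient statistics (vectorized)
  fits <- measurements |>
    dplyr::group_by(.data$variant, .data$background) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      n_conc = dplyr::n_distinct(.data$folinate),
      n_rep_groups = dplyr::n_distinct(.data$replicate),
      vn = sum(.data$var_non / .data$sd^2) / sum(1 / .data$sd^2),
      vs = sum(.data$var_shared / .data$sd^2) / sum(1 / .data$sd^2),
      sw = sum(1 / .data$sd^2),
      swc = sum(.data$folinate / .data$sd^2),
      swc2 = sum(.data$folinate^2 / .data$sd^2),
      sws = sum(.data$score / .data$sd^2),
      swcs = sum(.data$folinate * .data$score / .data$sd^2),
      sws2 = sum(.data$score^2 / .data$sd^2),
      const = sum(dnorm(0, sd = .data$sd, log = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      det = .data$sw * .data$swc2 - .data$swc^2,
      fit_ok = .data$n_conc >= min_concentrations & .data$det > 0,
      b = ifelse(.data$fit_ok,
                 (.data$swc2 * .data$sws - .data$swc * .data$swcs) /
                   .data$det, NA_real_),
      r = ifelse(.data$fit_ok,
                 (.data$sw * .data$swcs - .data$swc * .data$sws) /
                   .data$det, NA_real_),
      # two variance components do not average out across points: the
      # nonselect library is shared across a replicate's concentration
      # maps (vn), and the library clone-composition noise is shared
      # across all points of a background (vs). Both shift the intercept
      # but cancel in the slope.
      se_b = ifelse(.data$fit_ok,
                    sqrt(.data$swc2 / .data$det +
                           pmax(.data$vn * (1 / .data$n_rep_groups -
                                              1 / .data$n_obs), 0) +
                           pmax(.data$vs * (1 - 1 / .data$n_obs), 0)),
                    NA_real_),
      se_r = ifelse(.data$fit_ok, sqrt(.data$sw / .data$det), NA_real_),
      cov_br = ifelse(.data$fit_ok, -.data$swc / .data$det, NA_real_),
      # weighted SSE via sufficient statistics
      sse_full = .data$sws2 - 2 * .data$b * .data$sws -
        2 * .data$r * .data$swcs + .data$b^2 * .data$sw +
        2 * .data$b * .data$r * .data$swc + .data$r^2 * .data$swc2,
      b0 = .data$sws / .data$sw,
      sse_null = .data$sws2 - .data$sws^2 / .data$sw,
      logl_full = .data$const - pmax(.data$sse_full, 0) / 2,
      logl_null = .data$const - pmax(.data$sse_null, 0) / 2,
      llr = pmax(.data$logl_full - .data$logl_null, 0)
    ) |>
    dplyr::select("variant", "background", "b", "r", "se_b", "se_r",
                  "cov_br", "b0", "logl_full", "logl_null", "llr",
                  "n_obs", "n_conc", "fit_ok")
  fits
}

#' Classify folinate-responsive variants
#'
#' Likelihood-ratio test of the response model against the no-response
#' null (`2 * llr` against chi-square, 1 df), Benjamini-Hochberg FDR across
#' variants, plus an effect-size floor: the fitted score change across the
#' tested concentration range must be at least `min_effect`.
#'
#' @param fits A [fit_dose_response()] tibble.
#' @param alpha FDR level.
#' @param min_effect Minimum `|r| * (c_max - c_min)`.
#' @param c_range Tested concentration range (ug/mL).
#' @return `fits` with `p`, `q`, `responsive` and `response_sign` columns.
#' @export
classify_responsive <- function(fits, alpha = 0.05, min_effect = 0.1,
                                c_range = c(12.5, 200)) {
  fits <- dplyr::mutate(fits,
    p = ifelse(.data$fit_ok,
               pchisq(2 * .data$llr, df = 1, lower.tail = FALSE), NA_real_)
  )
  fits$q <- NA_real_
  ok <- !is.na(fits$p)
  fits$q[ok] <- stats::p.adjust(fits$p[ok], method = "BH")
  dplyr::mutate(fits,
    effect = abs(.data$r) * diff(c_range),
    responsive = dplyr::coalesce(
      .data$q < alpha & .data$effect >= min_effect, FALSE),
    response_sign = dplyr::case_when(
      !.data$responsive ~ "none",
      .data$r > 0 ~ "positive",
      TRUE ~ "negative"
    )
  )
}

#' Predict scores from dose-response fits ("virtual maps")
#'
#' Evaluates `s = b + r * c` with delta-method standard errors from the
#' parameter covariance. Restricted to the tested concentration range; the
#' linear model is not extrapolated beyond it.
#'
#' @param fits A [fit_dose_response()] tibble.
#' @param c Folinate concentration (scalar, ug/mL).
#' @param c_range Allowed range.
#' @return `fits` with `c`, `s_hat` and `se_hat` columns.
#' @export
predict_score <- function(fits, c, c_range = c(0, 200)) {
  abort_if(length(c) != 1L || c < c_range[1L] || c > c_range[2L],
           "Concentration outside the tested range; not extrapolating.")
  dplyr::mutate(fits,
    c = c,
    s_hat = .data$b + .data$r * c,
    se_hat = sqrt(.data$se_b^2 + c^2 * .data$se_r^2 + 2 * c * .data$cov_br)
  )
}
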