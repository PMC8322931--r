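# Genetic interaction with the common hypomorphic polymorphism: polynomial
# double-mutant expectation, folinate-independent and -dependent deviation
# terms, nested likelihood-ratio tests and suppressor detection.

#' Fit the polynomial double-mutant expectation curve
#'
#' Weighted least-squares polynomial regression of the double-mutant
#' (variant + polymorphism) score on the single-mutant (wild-type
#' background) score, pooled over concentration-matched pairs. Predictions
#' are clipped to the training score range.
#'
#' The curve is meant to describe how *non-interacting* variants behave in
#' the second background, so genuinely interacting variants are outliers
#' with respect to it. The fit is therefore robustified by iterated
#' trimming: after each pass, pairs whose residuals exceed `trim` robust
#' SDs (median absolute deviation) are excluded and the curve refitted.
#' Set `trim = Inf` for a plain weighted fit.
#'
#' @param pairs A tibble with columns `s_wt`, `s_av` and optionally
#'   `weight` (e.g. from [expectation_pairs()]).
#' @param degree Polynomial degree (1-5; default 3).
#' @param min_pairs Minimum number of pairs.
#' @param trim Residual trimming threshold in robust SDs (default 2.5).
#' @param iterations Trimming passes (default 2).
#' @return An object of class `expectation_curve`.
#' @export
fit_expectation <- function(pairs, degree = 3L, min_pairs = 50L,
                            trim = 2.5, iterations = 2L) {
  abort_if(!all(c("s_wt", "s_av") %in% names(pairs)),
           "`pairs` needs columns s_wt and s_av.")
  abort_if(degree < 1L || degree > 5L, "Degree must be between 1 and 5.")
  pairs <- dplyr::filter(pairs, is.finite(.data$s_wt), is.finite(.data$s_av))
  abort_if(nrow(pairs) < min_pairs,
           "Too few concentration-matched pairs for the expectation curve.")
  w <- if ("weight" %in% names(pairs)) pairs$weight else rep(1, nrow(pairs))

  deg <- degree
  repeat {
    x_mat <- outer(pairs$s_wt, 0:deg, `^`)
    qr_x <- qr(sqrt(w) * x_mat)
    if (qr_x$rank == deg + 1L || deg == 1L) break
    warning("Rank-deficient expectation fit; reducing polynomial degree to ",
            deg - 1L)
    deg <- deg - 1L
  }
  keep <- rep(TRUE, nrow(pairs))
  for (it in seq_len(1L + if (is.finite(trim)) iterations else 0L)) {
    fit <- stats::lm.wfit(x_mat[keep, , drop = FALSE], pairs$s_av[keep],
                          w[keep])
    if (it > iterations || !is.finite(trim)) break
    coef_it <- fit$coefficients
    coef_it[is.na(coef_it)] <- 0
    resid_all <- pairs$s_av - drop(x_mat %*% coef_it)
    s_rob <- stats::mad(resid_all[keep])
    if (s_rob == 0) break
    keep <- abs(resid_all) <= trim * s_rob
    if (sum(keep) < max(min_pairs, deg + 2L)) break
  }
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  resid_sd <- sqrt(sum(w[keep] * fit$residuals^2) / sum(w[keep]))
  structure(
    list(coefficients = unname(coef), degree = deg,
         range = range(pairs$s_wt), n_pairs = nrow(pairs),
         n_used = sum(keep), resid_sd = resid_sd),
    class = "expectation_curve"
  )
}

#' @export
print.expectation_curve <- function(x, ...) {
  cat("<expectation_curve> degree ", x$degree, ", fitted on ", x$n_pairs,
      " pairs over [", round(x$range[1L], 3), ", ", round(x$range[2L], 3),
      "]\n", sep = "")
  invisible(x)
}

#' Evaluate an expectation curve
#'
#' @param object An [fit_expectation()] curve.
#' @param newdata Numeric vector of single-mutant scores (clipped to the
#'   training range before evaluation).
#' @param ... Unused.
#' @return Predicted double-mutant scores.
#' @export
predict.expectation_curve <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$range[1L]), object$range[2L])
  drop(outer(x, 0:object$degree, `^`) %*% object$coefficients)
}

# First derivative of the expectation polynomial (clipped input, so the
# derivative is zero outside the training range).
predict_deriv <- function(object, newdata) {
  inside <- newdata >= object$range[1L] & newdata <= object$range[2L]
  x <- pmin(pmax(newdata, object$range[1L]), object$range[2L])
  k <- seq_len(object$degree)
  d <- drop(outer(x, k - 1, `^`) %*% (k * object$coefficients[-1L]))
  d * inside
}

#' Concentration-matched score pairs for the expectation curve
#'
#' @param score_table A [build_score_table()] result containing both
#'   backgrounds.
#' @param backgrounds Names of the single- and double-mutant backgrounds.
#' @return A tibble `variant`, `folinate`, `s_wt`, `s_av`, `weight`
#'   (inverse summed variance).
#' @export
expectation_pairs <- function(score_table, backgrounds = c("wt", "av")) {
  wm <- dplyr::filter(score_table, .data$well_measured)
  wt <- wm |>
    dplyr::filter(.data$background == backgrounds[1L]) |>
    dplyr::select("variant", "folinate", s_wt = "score", sd_wt = "sd")
  av <- wm |>
    dplyr::filter(.data$background == backgrounds[2L]) |>
    dplyr::select("variant", "folinate", s_av = "score", sd_av = "sd")
  dplyr::inner_join(wt, av, by = c("variant", "folinate")) |>
    dplyr::mutate(weight = 1 / (.data$sd_wt^2 + .data$sd_av^2))
}

#' Fit genetic-interaction models
#'
#' For each variant with a wild-type-background dose-response fit, models
#' the double-mutant score as the polynomial expectation of the single
#' mutant plus deviation terms:
#' `s_av(c) = P(b + r * c) + eps_b + eps_r * c`, with `(b, r)` fixed from
#' the wild-type fit. Three nested weighted fits (both terms; `eps_b` only;
#' neither) give the interaction evidence `llr_g = logL_full - logL_null`
#' and the folinate-dependence test `llr_er = logL_full - logL_eb`.
#' Posterior probabilities of a positive deviation use the Gaussian
#' approximation `P(eps > 0) = Phi(eps_hat / se)`.
#'
#' Because `(b, r)` are estimates, the deviation
#' `y = s_av - P(b + r c)` inherits their uncertainty; it is propagated
#' into each point's variance by the delta method,
#' `var(y) = sd_av^2 + P'(b + r c)^2 * var(b + r c)`, so the nested tests
#' and posteriors are calibrated under the null.
#'
#' @param wt_fits [fit_dose_response()] results for the wild-type
#'   background (including `se_b`, `se_r`, `cov_br`).
#' @param av_measurements Double-mutant score measurements (`variant`,
#'   `folinate`, `score`, `sd`), e.g. well-measured AV-background records.
#' @param curve An [fit_expectation()] curve.
#' @param min_concentrations Minimum distinct concentrations.
#' @return A tibble per variant: `eps_b`, `eps_r`, `se_eb`, `se_er`,
#'   `logl_full`, `logl_eb`, `logl_null`, `llr_g`, `llr_er`, `p_eb_pos`,
#'   `p_er_pos`, `n_obs`, `fit_ok`.
#' @export
fit_interaction <- function(wt_fits, av_measurements, curve,
                            min_concentrations = 2L) {
  wt_ok <- dplyr::filter(wt_fits, .data$fit_ok)
  if (!"var_non" %in% names(av_measurements)) av_measurements$var_non <- 0
  if (!"var_shared" %in% names(av_measurements)) {
    av_measurements$var_shared <- 0
  }
  if (!"replicate" %in% names(av_measurements)) {
    av_measurements$replicate <- 1L
  }
  av <- av_measurements |>
    dplyr::filter(is.finite(.data$score), is.finite(.data$sd),
                  .data$sd > 0) |>
    dplyr::inner_join(dplyr::select(wt_ok, "variant", "b", "r", "se_b",
                                    "se_r", "cov_br"),
                      by = "variant") |>
    dplyr::mutate(
      x_wt = .data$b + .data$r * .data$folinate,
      expected = predict(curve, .data$x_wt),
      y = .data$score - .data$expected,
      var_wt = .data$se_b^2 + .data$folinate^2 * .data$se_r^2 +
        2 * .data$folinate * .data$cov_br,
      var_prop = predict_deriv(curve, .data$x_wt)^2 * pmax(.data$var_wt, 0),
      sd = sqrt(.data$sd^2 + .data$var_prop),
      # the single-mutant fit error and the library composition noise are
      # the same draw at every concentration: fully shared across points
      shared2 = .data$var_shared + .data$var_prop
    )

  fits <- av |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      n_conc = dplyr::n_distinct(.data$folinate),
      n_rep_groups = dplyr::n_distinct(.data$replicate),
      vn = sum(.data$var_non / .data$sd^2) / sum(1 / .data$sd^2),
      vs = sum(.data$shared2 / .data$sd^2) / sum(1 / .data$sd^2),
      sw = sum(1 / .data$sd^2),
      swc = sum(.data$folinate / .data$sd^2),
      swc2 = sum(.data$folinate^2 / .data$sd^2),
      swy = sum(.data$y / .data$sd^2),
      swcy = sum(.data$folinate * .data$y / .data$sd^2),
      swy2 = sum(.data$y^2 / .data$sd^2),
      const = sum(dnorm(0, sd = .data$sd, log = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      det = .data$sw * .data$swc2 - .data$swc^2,
      fit_ok = .data$n_conc >= min_concentrations & .data$det > 0,
      eps_b = ifelse(.data$fit_ok,
                     (.data$swc2 * .data$swy - .data$swc * .data$swcy) /
                       .data$det, NA_real_),
      eps_r = ifelse(.data$fit_ok,
                     (.data$sw * .data$swcy - .data$swc * .data$swy) /
                       .data$det, NA_real_),
      # shared variance components (see fit_dose_response) inflate the
      # folinate-independent term but cancel in the slope
      se_eb = ifelse(.data$fit_ok,
                     sqrt(.data$swc2 / .data$det +
                            pmax(.data$vn * (1 / .data$n_rep_groups -
                                               1 / .data$n_obs), 0) +
                            pmax(.data$vs * (1 - 1 / .data$n_obs), 0)),
                     NA_real_),
      se_er = ifelse(.data$fit_ok, sqrt(.data$sw / .data$det), NA_real_),
      sse_full = .data$swy2 - 2 * .data$eps_b * .data$swy -
        2 * .data$eps_r * .data$swcy + .data$eps_b^2 * .data$sw +
        2 * .data$eps_b * .data$eps_r * .data$swc +
        .data$eps_r^2 * .data$swc2,
      sse_eb = .data$swy2 - .data$swy^2 / .data$sw,
      sse_null = .data$swy2,
      logl_full = .data$const - pmax(.data$sse_full, 0) / 2,
      logl_eb = .data$const - pmax(.data$sse_eb, 0) / 2,
      logl_null = .data$const - .data$sse_null / 2,
      llr_g = pmax(.data$logl_full - .data$logl_null, 0),
      llr_er = pmax(.data$logl_full - .data$logl_eb, 0),
      llr_eb = pmax(.data$logl_eb - .data$logl_null, 0),
      p_eb_pos = pnorm(.data$eps_b / .data$se_eb),
      p_er_pos = pnorm(.data$eps_r / .data$se_er)
    ) |>
    dplyr::select("variant", "eps_b", "eps_r", "se_eb", "se_er",
                  "logl_full", "logl_eb", "logl_null", "llr_g", "llr_er",
                  "llr_eb", "p_eb_pos", "p_er_pos", "n_obs", "n_conc",
                  "fit_ok")
  fits
}

#' Classify genetic interactions
#'
#' A variant is folinate-`dependent` when the `eps_r` nested test survives
#' Benjamini-Hochberg FDR below `alpha`; otherwise `independent` when the
#' `eps_b` test survives; otherwise `none`.
#'
#' @param int_fits A [fit_interaction()] tibble.
#' @param alpha FDR level.
#' @return `int_fits` with `p_er`, `q_er`, `p_eb`, `q_eb` and
#'   `interaction_class`.
#' @export
classify_interactions <- function(int_fits, alpha = 0.05) {
  out <- dplyr::mutate(int_fits,
    p_er = ifelse(.data$fit_ok,
                  pchisq(2 * .data$llr_er, df = 1, lower.tail = FALSE),
                  NA_real_),
    # Wald form of the eps_b test (identical to the LRT when errors are
    # known) so that the shared-variance correction in se_eb carries over
    p_eb = ifelse(.data$fit_ok,
                  pchisq((.data$eps_b / .data$se_eb)^2, df = 1,
                         lower.tail = FALSE),
                  NA_real_)
  )
  out$q_er <- out$q_eb <- NA_real_
  ok <- !is.na(out$p_er)
  out$q_er[ok] <- stats::p.adjust(out$p_er[ok], method = "BH")
  ok <- !is.na(out$p_eb)
  out$q_eb[ok] <- stats::p.adjust(out$p_eb[ok], method = "BH")
  dplyr::mutate(out,
    interaction_class = dplyr::case_when(
      dplyr::coalesce(.data$q_er < alpha, FALSE) ~ "dependent",
      dplyr::coalesce(.data$q_eb < alpha, FALSE) ~ "independent",
      TRUE ~ "none"
    )
  )
}

#' Suppressor score thresholds
#'
#' Per tested concentration, the 95th percentile of synonymous-variant
#' scores in the double-mutant (polymorphism) background: the level above
#' which a double-mutant score exceeds polymorphism-like functionality at
#' empirical p < 0.05.
#'
#' @param score_table A [build_score_table()] result.
#' @param background Double-mutant background name.
#' @param probs Percentile (default 0.95).
#' @param min_n Minimum synonymous scores per concentration.
#' @return Tibble `folinate`, `threshold`, `n_syn`.
#' @export
suppressor_thresholds <- function(score_table, background = "av",
                                  probs = 0.95, min_n = 20L) {
  syn <- dplyr::filter(score_table, .data$well_measured,
                       .data$background == background,
                       .data$type == "synonymous")
  out <- syn |>
    dplyr::group_by(.data$folinate) |>
    dplyr::summarise(threshold = quantile(.data$score, probs, names = FALSE),
                     n_syn = dplyr::n(), .groups = "drop")
  abort_if(nrow(out) == 0L || any(out$n_syn < min_n),
           "Too few synonymous scores to set suppressor thresholds.")
  out
}

#' Identify suppressors of the common polymorphism
#'
#' Candidates must achieve a good interaction-model fit
#' (`logl_full > logl_min`, natural log) and a posterior probability above
#' `posterior_min` of a positive interaction (either term). Candidates are
#' then categorised from the model-predicted double-mutant scores at each
#' tested concentration: above the synonymous threshold at all
#' concentrations (folinate-independent), only at the lowest
#' (low-folinate) or only at the highest (high-folinate). Each suppressor
#' is annotated with its single-nucleotide accessibility when a coding
#' sequence is supplied.
#'
#' @param int_fits A [fit_interaction()] tibble.
#' @param wt_fits The wild-type [fit_dose_response()] fits (for predicted
#'   double-mutant scores).
#' @param curve The [fit_expectation()] curve.
#' @param thresholds A [suppressor_thresholds()] tibble.
#' @param cds Optional [coding_sequence()] for SNV-accessibility annotation.
#' @param logl_min Minimum full-model log likelihood (default -8).
#' @param posterior_min Minimum posterior probability of a positive
#'   interaction (default 0.95).
#' @return A tibble of candidates with `suppressor` flag and `category`
#'   (`independent`, `low_folinate`, `high_folinate`, or `NA`), plus
#'   `snv_accessible` when `cds` is given.
#' @export
find_suppressors <- function(int_fits, wt_fits, curve, thresholds,
                             cds = NULL, logl_min = -8,
                             posterior_min = 0.95) {
  abort_if(nrow(thresholds) < 2L, "Thresholds for at least two concentrations are required.")
  cand <- int_fits |>
    dplyr::filter(.data$fit_ok) |>
    dplyr::inner_join(dplyr::select(wt_fits, "variant", "b", "r"),
                      by = "variant") |>
    dplyr::mutate(
      flagged = .data$logl_full > logl_min &
        pmax(.data$p_eb_pos, .data$p_er_pos) > posterior_min
    )

  # model-predicted double-mutant scores vs the per-concentration threshold
  pred <- tidyr::crossing(dplyr::select(cand, "variant", "b", "r",
                                        "eps_b", "eps_r"),
                          dplyr::select(thresholds, "folinate",
                                        "threshold")) |>
    dplyr::mutate(
      s_av_hat = predict(.env$curve, .data$b + .data$r * .data$folinate) +
        .data$eps_b + .data$eps_r * .data$folinate,
      above = .data$s_av_hat > .data$threshold
    )
  c_lo <- min(thresholds$folinate)
  c_hi <- max(thresholds$folinate)
  summary <- pred |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      above_all = all(.data$above),
      above_lo = any(.data$above[.data$folinate == c_lo]),
      above_hi = any(.data$above[.data$folinate == c_hi]),
      .groups = "drop"
    )
  out <- cand |>
    dplyr::left_join(summary, by = "variant") |>
    dplyr::mutate(
      category = dplyr::case_when(
        !.data$flagged ~ NA_character_,
        .data$above_all ~ "independent",
        .data$above_lo ~ "low_folinate",
        .data$above_hi ~ "high_folinate",
        TRUE ~ NA_character_
      ),
      suppressor = .data$flagged & !is.na(.data$category)
    )
  if (!is.null(cds)) {
    parsed <- tibble::tibble(
      position = as.integer(stringr::str_extract(out$variant, "\\d+")),
      alt = stringr::str_extract(out$variant, "[A-Z*=]$")
    )
    out$snv_accessible <- is_snv_accessible(parsed, cds)
  }
  dplyr::select(out, -"b", -"r", -"above_all", -"above_lo", -"above_hi")
}
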