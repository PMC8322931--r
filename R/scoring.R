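# Enrichment-based functionality scoring: consensus variant calling from
# read pairs, frequency computation, control subtraction, enrichment
# ratios, mode-based per-region rescaling, error regularization and
# replicate aggregation.

#' Scoring configuration
#'
#' @param min_nonselect_count Minimum nonselect reads for a record to be
#'   well measured.
#' @param control_factor `k`: a record is well measured only when its
#'   nonselect frequency is at least `k` times the matched control
#'   frequency.
#' @param nu Pseudo-replicate weight of the count-propagated prior variance
#'   in the error regularization.
#' @param sigma_floor Lower bound for regularized score errors.
#' @param mode_min_n Minimum number of values required for a mode estimate.
#' @param log_phi Estimate calibration modes on `log(phi)` instead of raw
#'   `phi`.
#' @param calibrate_errors Inflate claimed errors by the excess variance of
#'   the synonymous score population (per background, map and region), so
#'   that neutral variants are statistically consistent with their error
#'   estimates. This absorbs noise shared between replicates — notably
#'   clone-composition (library) noise, which replicate scatter cannot
#'   see because replicates derive from the same transformant pool.
#' @return Named list of class `score_config`.
#' @export
score_config <- function(min_nonselect_count = 10L, control_factor = 3,
                         nu = 2, sigma_floor = 0.005, mode_min_n = 5L,
                         log_phi = FALSE, calibrate_errors = TRUE) {
  structure(as.list(environment()), class = "score_config")
}

#' Call variants from paired-read observations
#'
#' Implements the read-pair agreement rule: a variant is counted once per
#' pair only when both reads of the pair report it; pairs whose two reads
#' disagree on any call are treated as wild type for the disputed calls.
#' The per-tile agreement fraction (pairs whose two reads report identical
#' call sets) is attached as attribute `"agreement"` and reported by
#' [glance()].
#'
#' @param read_pairs Tibble with columns `pair_id`, `mate` (1 or 2) and
#'   `variant`, one row per observed call (as from
#'   [simulate_read_pairs()]).
#' @param n_pairs Total number of sequenced pairs (the depth). Defaults to
#'   the `n_pairs` attribute of `read_pairs`.
#' @return A tibble `variant`, `count`, `depth` with attribute `agreement`.
#' @export
call_variants_from_read_pairs <- function(read_pairs,
                                          n_pairs = attr(read_pairs,
                                                         "n_pairs")) {
  abort_if(is.null(n_pairs), "`n_pairs` is required.")
  abort_if(!all(read_pairs$mate %in% c(1L, 2L)),
           "`mate` must be 1 or 2.")
  calls <- dplyr::distinct(read_pairs, .data$pair_id, .data$mate,
                           .data$variant)
  concordant <- calls |>
    dplyr::count(.data$pair_id, .data$variant) |>
    dplyr::filter(.data$n == 2L)
  counts <- dplyr::count(concordant, .data$variant, name = "count")
  # agreement: fraction of pairs whose two reads report identical call sets
  per_mate <- calls |>
    dplyr::group_by(.data$pair_id, .data$mate) |>
    dplyr::summarise(
      sig = paste(sort(.data$variant), collapse = ";"), .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "mate", values_from = "sig",
                       names_prefix = "m", values_fill = "")
  if (!"m1" %in% names(per_mate)) per_mate$m1 <- ""
  if (!"m2" %in% names(per_mate)) per_mate$m2 <- ""
  n_disagree <- sum(per_mate$m1 != per_mate$m2)
  out <- dplyr::mutate(counts, depth = n_pairs)
  attr(out, "agreement") <- 1 - n_disagree / n_pairs
  class(out) <- c("consensus_counts", class(out))
  out
}

#' Error-subtracted enrichment ratio
#'
#' `phi = max(0, f_sel - f_ctrl_sel) / (f_non - f_ctrl_non)`; undefined
#' (`NA`) when the denominator is not positive. Vectorized.
#'
#' @param f_sel,f_non Selected/nonselected variant frequencies.
#' @param f_ctrl_sel,f_ctrl_non Matched wild-type-control frequencies.
#' @return Numeric vector of enrichment ratios.
#' @export
enrichment_ratio <- function(f_sel, f_non, f_ctrl_sel = 0, f_ctrl_non = 0) {
  abort_if(any(c(f_sel, f_non, f_ctrl_sel, f_ctrl_non) < 0, na.rm = TRUE) ||
             any(c(f_sel, f_non, f_ctrl_sel, f_ctrl_non) > 1, na.rm = TRUE),
           "Frequencies must lie in [0, 1].")
  den <- f_non - f_ctrl_non
  num <- pmax(0, f_sel - f_ctrl_sel)
  ifelse(is.na(den) | den <= 0, NA_real_, num / den)
}

#' Kernel-density mode estimate
#'
#' Argmax of a Gaussian kernel density (Silverman's bandwidth) evaluated on
#' a 512-point grid spanning the data range.
#'
#' @param values Numeric vector (at least `min_n` finite values).
#' @param min_n Minimum number of values.
#' @return The mode estimate (scalar).
#' @export
estimate_mode <- function(values, min_n = 5L) {
  values <- values[is.finite(values)]
  abort_if(length(values) < min_n,
           "Too few values for a mode estimate.")
  if (diff(range(values)) == 0) return(values[1L])
  d <- density(values, bw = "nrd0", n = 512L)
  d$x[which.max(d$y)]
}

#' Rescale enrichment ratios to functionality scores
#'
#' Affine per-region rescaling anchored on the calibration modes:
#' `s = (phi - m_non) / (m_syn - m_non)`, so nonsense-like enrichment maps
#' to 0 and synonymous-like enrichment to 1.
#'
#' @param phi Enrichment ratios.
#' @param m_syn,m_non Modes of the synonymous and nonsense ratios.
#' @return Rescaled scores.
#' @export
rescale_region <- function(phi, m_syn, m_non) {
  abort_if(any(!is.finite(c(m_syn, m_non))) || any(m_syn <= m_non),
           "Calibration failed: synonymous mode must exceed nonsense mode.")
  (phi - m_non) / (m_syn - m_non)
}

#' Regularized score error
#'
#' Shrinks the observed between-replicate variance toward a count-propagated
#' Poisson prior: `sigma^2 = (nu * sigma_prior^2 + (n - 1) * s_obs^2) /
#' (nu + n - 1)`, floored at `sigma_floor`.
#'
#' @param sigma_prior Count-propagated prior SD per record.
#' @param s_obs Observed SD across replicates (0 when `n = 1`).
#' @param n Number of replicates.
#' @param nu Pseudo-replicate weight of the prior.
#' @param sigma_floor Lower bound.
#' @return Regularized SD, same length as `sigma_prior`.
#' @export
regularize_error <- function(sigma_prior, s_obs, n, nu = 2,
                             sigma_floor = 0.005) {
  abort_if(any(n < 1L), "At least one replicate is required.")
  s_obs <- ifelse(n > 1L, s_obs, 0)
  sig2 <- (nu * sigma_prior^2 + (n - 1) * s_obs^2) / (nu + n - 1)
  pmax(sqrt(sig2), sigma_floor)
}

#' Build a calibrated score table from sequencing counts
#'
#' The full scoring pipeline: frequencies, control subtraction, enrichment
#' ratios, per-region mode calibration on synonymous and nonsense variants,
#' rescaling to the 0/1 functionality scale, count-propagated errors with
#' regularization, and inverse-variance replicate aggregation. Records
#' failing the well-measured filter (nonselect frequency below
#' `control_factor` times the control, or nonselect count below
#' `min_nonselect_count`) carry missing scores.
#'
#' @param counts A count table as produced by [simulate_counts()] (columns
#'   `variant`, `position`, `alt`, `type`, `background`, `condition`,
#'   `folinate`, `replicate`, `region`, `count`, `depth`, `sample`).
#' @param config A [score_config()].
#' @return An object of class `score_table`: a tibble with one row per
#'   (variant, background, folinate) holding `phi`, `score`, `sd`, `df`
#'   (replicates used) and `well_measured`, with the per-replicate records
#'   in `attr(, "records")` and per-region calibrations in
#'   `attr(, "calibration")`.
#' @export
build_score_table <- function(counts, config = score_config()) {
  needed <- c("variant", "type", "background", "condition", "folinate",
              "replicate", "region", "count", "depth", "sample")
  abort_if(!all(needed %in% names(counts)),
           paste("Count table must have columns:",
                 paste(needed, collapse = ", ")))
  abort_if(!any(counts$sample == "wt_control"),
           "Missing wild-type control condition.")
  abort_if(!any(counts$condition == "nonselect") ||
             !any(counts$condition == "select"),
           "Count table must contain nonselect and select conditions.")

  lib <- dplyr::filter(counts, .data$sample == "library")
  ctrl <- counts |>
    dplyr::filter(.data$sample == "wt_control") |>
    dplyr::transmute(.data$variant, .data$background, .data$condition,
                     .data$folinate, .data$replicate,
                     f_ctrl = .data$count / .data$depth)

  freq <- lib |>
    dplyr::mutate(f = .data$count / .data$depth) |>
    dplyr::left_join(ctrl,
                     by = c("variant", "background", "condition",
                            "folinate", "replicate")) |>
    dplyr::mutate(f_ctrl = dplyr::coalesce(.data$f_ctrl, 0))

  non <- freq |>
    dplyr::filter(.data$condition == "nonselect") |>
    dplyr::select("variant", "background", "replicate",
                  f_non = "f", ctrl_non = "f_ctrl", k_non = "count")
  sel <- dplyr::filter(freq, .data$condition == "select")

  records <- sel |>
    dplyr::inner_join(non, by = c("variant", "background", "replicate")) |>
    dplyr::mutate(
      phi = enrichment_ratio(.data$f, .data$f_non, .data$f_ctrl,
                             .data$ctrl_non),
      well_measured = .data$f_non >= config$control_factor * .data$ctrl_non &
        .data$k_non >= config$min_nonselect_count &
        !is.na(.data$phi)
    )

  # per-region calibration on synonymous and nonsense variants, pooled
  # across replicates within each (background, folinate) map
  phi_for_mode <- function(x) if (config$log_phi) log(pmax(x, 1e-12)) else x
  calibration <- records |>
    dplyr::filter(.data$well_measured,
                  .data$type %in% c("synonymous", "nonsense")) |>
    dplyr::group_by(.data$background, .data$folinate, .data$region,
                    .data$type) |>
    dplyr::summarise(
      mode = estimate_mode(phi_for_mode(.data$phi), config$mode_min_n),
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "type", values_from = c("mode", "n"))
  abort_if(!all(c("mode_synonymous", "mode_nonsense") %in%
                  names(calibration)) ||
             any(is.na(calibration$mode_synonymous)) ||
             any(is.na(calibration$mode_nonsense)),
           "Calibration failed: missing synonymous or nonsense variants in a region.")
  calibration <- dplyr::rename(calibration, m_syn = "mode_synonymous",
                               m_non = "mode_nonsense")
  abort_if(any(calibration$m_syn <= calibration$m_non),
           "Calibration failed: synonymous mode must exceed nonsense mode.")

  records <- records |>
    dplyr::left_join(
      dplyr::select(calibration, "background", "folinate", "region",
                    "m_syn", "m_non"),
      by = c("background", "folinate", "region")
    ) |>
    dplyr::mutate(
      score = rescale_region(phi_for_mode(.data$phi), .data$m_syn,
                             .data$m_non),
      # delta-method Poisson error of phi, propagated through the affine
      # rescaling; +0.5 guards zero counts
      sigma_prior = (pmax(.data$phi, .data$m_non) + 0.02) *
        sqrt(1 / (.data$count + 0.5) + 1 / (.data$k_non + 0.5)) /
        (.data$m_syn - .data$m_non),
      # nonselect-count component of the variance: one nonselect library
      # serves every select condition of a replicate, so this part is
      # shared (not independent) across concentration maps
      var_non = (pmax(.data$phi, .data$m_non) + 0.02)^2 /
        ((.data$k_non + 0.5) * (.data$m_syn - .data$m_non)^2)
    )

  wm <- records |>
    dplyr::filter(.data$well_measured) |>
    dplyr::group_by(.data$variant, .data$position, .data$alt, .data$type,
                    .data$background, .data$folinate, .data$region) |>
    dplyr::mutate(
      n_rep = dplyr::n(),
      s_obs = if (dplyr::n() > 1L) sd(.data$score) else 0
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sd_rep = regularize_error(.data$sigma_prior, .data$s_obs, .data$n_rep,
                                config$nu, config$sigma_floor)
    )
  combined <- wm |>
    dplyr::group_by(.data$variant, .data$position, .data$alt, .data$type,
                    .data$background, .data$folinate, .data$region) |>
    dplyr::summarise(
      phi = mean(.data$phi),
      score = sum(.data$score / .data$sd_rep^2) / sum(1 / .data$sd_rep^2),
      sd = sqrt(1 / sum(1 / .data$sd_rep^2)),
      var_non = mean(.data$var_non) / dplyr::n(),
      df = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(well_measured = TRUE)

  # empirical error calibration on the synonymous population: whatever
  # variance the neutral variants show beyond their claimed errors is
  # shared noise every score carries
  excess <- NULL
  if (isTRUE(config$calibrate_errors)) {
    excess <- combined |>
      dplyr::filter(.data$type == "synonymous") |>
      dplyr::group_by(.data$background, .data$folinate, .data$region) |>
      dplyr::summarise(
        excess_var = max(0, stats::var(.data$score) - mean(.data$sd^2)),
        n_syn = dplyr::n(), .groups = "drop"
      )
    # the excess is library (clone-composition) noise: one draw per
    # (variant, background), shared across replicates and concentration
    # maps; it enters each score's variance once, and downstream fitters
    # receive it in `var_shared` so that across-map averages do not treat
    # it as independent
    combined <- combined |>
      dplyr::left_join(dplyr::select(excess, "background", "folinate",
                                     "region", "excess_var"),
                       by = c("background", "folinate", "region")) |>
      dplyr::mutate(
        var_shared = dplyr::coalesce(.data$excess_var, 0),
        sd = sqrt(.data$sd^2 + .data$var_shared)
      ) |>
      dplyr::select(-"excess_var")
    records <- records |>
      dplyr::left_join(dplyr::select(excess, "background", "folinate",
                                     "region", "excess_var"),
                       by = c("background", "folinate", "region")) |>
      dplyr::mutate(
        var_shared = dplyr::coalesce(.data$excess_var, 0),
        sd = sqrt(.data$sigma_prior^2 + .data$var_shared)
      ) |>
      dplyr::select(-"excess_var")
  } else {
    records <- dplyr::mutate(records, sd = .data$sigma_prior,
                             var_shared = 0)
    combined <- dplyr::mutate(combined, var_shared = 0)
  }

  # carry filtered variants as missing scores (never as zero)
  all_keys <- records |>
    dplyr::distinct(.data$variant, .data$position, .data$alt, .data$type,
                    .data$background, .data$folinate, .data$region)
  out <- all_keys |>
    dplyr::left_join(combined,
                     by = c("variant", "position", "alt", "type",
                            "background", "folinate", "region")) |>
    dplyr::mutate(well_measured = dplyr::coalesce(.data$well_measured,
                                                  FALSE))

  structure(out,
            class = c("score_table", class(out)),
            records = dplyr::select(
              records, "variant", "position", "alt", "type", "background",
              "folinate", "replicate", "region", "count", "k_non", "phi",
              "score", "sigma_prior", "sd", "var_non", "var_shared",
              "well_measured"
            ),
            calibration = calibration,
            excess_variance = excess,
            config = config)
}

#' Per-replicate score records of a score table
#' @param score_table A [build_score_table()] result.
#' @return Tibble of per-replicate records with `score` and `sigma_prior`.
#' @export
score_records <- function(score_table) {
  attr(score_table, "records")
}

#' Map coverage report
#'
#' Fraction of the `21 x L` possible outcomes with a well-measured score,
#' per map and per background (a variant counts as covered for a background
#' when at least one folinate map measures it, matching the cross-condition
#' averaged-map convention).
#'
#' @param score_table A [build_score_table()] result.
#' @param n_outcomes Total outcomes (denominator), e.g. 13776.
#' @return A list with tibbles `per_map` and `per_background`, coverage as
#'   percentages.
#' @export
map_coverage <- function(score_table,
                         n_outcomes = 21L * max(score_table$position)) {
  per_map <- score_table |>
    dplyr::group_by(.data$background, .data$folinate) |>
    dplyr::summarise(scored = sum(.data$well_measured), .groups = "drop") |>
    dplyr::mutate(coverage_pct = 100 * .data$scored / n_outcomes)
  per_background <- score_table |>
    dplyr::filter(.data$well_measured) |>
    dplyr::distinct(.data$background, .data$variant) |>
    dplyr::count(.data$background, name = "scored") |>
    dplyr::mutate(coverage_pct = 100 * .data$scored / n_outcomes)
  list(per_map = per_map, per_background = per_background)
}
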