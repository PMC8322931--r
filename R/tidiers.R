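# broom-style tidiers for the package's fitted objects.

#' @describeIn fit_expectation Tidy the polynomial coefficients.
#' @param x An `expectation_curve`.
#' @method tidy expectation_curve
#' @export
tidy.expectation_curve <- function(x, ...) {
  tibble::tibble(
    term = paste0("s_wt^", 0:x$degree),
    estimate = x$coefficients
  )
}

#' @describeIn fit_expectation One-row model summary.
#' @method glance expectation_curve
#' @export
glance.expectation_curve <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_pairs = x$n_pairs,
                 n_used = x$n_used %||% x$n_pairs,
                 resid_sd = x$resid_sd,
                 range_lo = x$range[1L], range_hi = x$range[2L])
}

#' @describeIn evaluate_classifier Tidy the balanced PR curve points.
#' @param x A `bprc_eval`.
#' @method tidy bprc_eval
#' @export
tidy.bprc_eval <- function(x, ...) {
  x$curve
}

#' @describeIn evaluate_classifier One-row evaluation summary.
#' @method glance bprc_eval
#' @export
glance.bprc_eval <- function(x, ...) {
  tibble::tibble(aubprc = x$aubprc, r90p = x$r90p,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn fit_llrp Tidy the LLRp evaluation grids.
#' @param x An `llrp_function`.
#' @method tidy llrp_function
#' @export
tidy.llrp_function <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(domain = f$domain, score = f$grid, llrp = f$llrp)
  })
}

#' @describeIn fit_llrp One-row-per-domain summary.
#' @method glance llrp_function
#' @export
glance.llrp_function <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(domain = f$domain, n_pos = f$n_pos, n_rand = f$n_rand,
                   benign_floor = x$benign_floor)
  })
}

#' @describeIn call_variants_from_read_pairs One-row summary with the
#'   read-pair agreement fraction.
#' @param x A count table from [call_variants_from_read_pairs()].
#' @param ... Unused.
#' @method glance consensus_counts
#' @export
glance.consensus_counts <- function(x, ...) {
  tibble::tibble(n_pairs = x$depth[1L], n_variants = nrow(x),
                 agreement = attr(x, "agreement"))
}
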