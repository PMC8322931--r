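# Shared constants and small numeric helpers.

# The 20 standard amino acids, one-letter, fixed order.
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# One-letter <-> three-letter amino-acid code maps ("*" = stop).
AA_THREE <- c(
  A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
  H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
  P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
  W = "Trp", Y = "Tyr", `*` = "Ter"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

# Codon -> amino acid map (standard genetic code), "*" for stop.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), names(gc))
}

#' Run code with a fixed RNG seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Weighted least squares for s ~ b + r * c with known per-point sd.
# Closed-form normal equations; returns estimates, standard errors,
# parameter covariance and the Gaussian log-likelihood (natural log).
wls_line <- function(c_vals, s_vals, sd_vals) {
  w <- 1 / sd_vals^2
  sw <- sum(w)
  swc <- sum(w * c_vals)
  swc2 <- sum(w * c_vals^2)
  sws <- sum(w * s_vals)
  swcs <- sum(w * c_vals * s_vals)
  det <- sw * swc2 - swc^2
  if (det <= 0 || !is.finite(det)) {
    return(list(b = NA_real_, r = NA_real_, se_b = NA_real_, se_r = NA_real_,
                cov_br = NA_real_, logl = NA_real_, ok = FALSE))
  }
  b <- (swc2 * sws - swc * swcs) / det
  r <- (sw * swcs - swc * sws) / det
  resid <- s_vals - b - r * c_vals
  logl <- sum(dnorm(resid, mean = 0, sd = sd_vals, log = TRUE))
  list(
    b = b, r = r,
    se_b = sqrt(swc2 / det), se_r = sqrt(sw / det), cov_br = -swc / det,
    logl = logl, ok = TRUE
  )
}

# Gaussian log-likelihood of a constant model s ~ b0 (r fixed at 0).
wls_const <- function(c_vals, s_vals, sd_vals) {
  w <- 1 / sd_vals^2
  b0 <- sum(w * s_vals) / sum(w)
  resid <- s_vals - b0
  list(b = b0, se_b = sqrt(1 / sum(w)),
       logl = sum(dnorm(resid, mean = 0, sd = sd_vals, log = TRUE)))
}

# Welch's t test from summary statistics (mean, sd, n per group).
# Returns the t statistic, Satterthwaite df and p value. `df1`/`df2`
# override the per-group degrees of freedom (e.g. to credit prior
# pseudo-replicates when the variances are regularized estimates).
welch_summary <- function(m1, s1, n1, m2, s2, n2,
                          alternative = c("two.sided", "greater", "less"),
                          df1 = n1 - 1, df2 = n2 - 1) {
  alternative <- match.arg(alternative)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  tt <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / df1 + v2^2 / df2)
  p <- switch(alternative,
    two.sided = 2 * pt_safe(-abs(tt), df),
    greater = pt_safe(-tt, df),
    less = pt_safe(tt, df)
  )
  list(t = tt, df = df, p = p)
}

pt_safe <- function(q, df) {
  out <- stats::pt(q, df)
  out[!is.finite(df) | df <= 0] <- NA_real_
  out
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
  invisible(NULL)
}
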