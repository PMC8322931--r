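# Shared fixtures. The full-scale atlas simulation and the strict-null
# simulation are expensive, so they are built lazily once per test session
# and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_cds <- function() {
  # 30-codon synthetic sequence with a fixed seed
  ct <- Biostrings::GENETIC_CODE
  sense <- names(ct)[ct != "*"]
  withr::with_seed(11L, {
    coding_sequence(paste0("ATG", paste(sample(sense, 29, replace = TRUE),
                                        collapse = ""), "TAA"),
                    id = "tiny")
  })
}

# full-scale atlas run (defaults = study conditions), analysis chain included
atlas_fixture <- function() {
  fixture("atlas", function() {
    sim <- simulate_experiment(seed = 42L)
    st <- build_score_table(sim$counts)
    recs <- dplyr::filter(score_records(st), well_measured)
    fits <- fit_dose_response(recs)
    fw <- dplyr::filter(fits, background == "wt", fit_ok)
    curve <- fit_expectation(expectation_pairs(st))
    av_meas <- st |>
      dplyr::filter(well_measured, background == "av") |>
      dplyr::select(variant, folinate, score, sd, var_non, var_shared)
    ints <- fit_interaction(fw, av_meas, curve)
    thresholds <- suppressor_thresholds(st)
    suppressors <- find_suppressors(ints, fw, curve, thresholds,
                                    cds = sim$cds)
    list(sim = sim, st = st, fits = fits, fw = fw, curve = curve,
         ints = ints, thresholds = thresholds, suppressors = suppressors)
  })
}

# strict null atlas: every variant truly wild-type-like, no slopes or
# interactions anywhere
null_fixture <- function() {
  fixture("null", function() {
    tp <- ground_truth_params(
      mixture_weights = c(null = 0, hypomorph = 0, wt_like = 1, hyper = 0),
      wt_like_sd = 0, responsive_fraction = 0, interaction_fraction = 0,
      suppressor_fraction = 0
    )
    sim <- simulate_experiment(truth_params = tp, seed = 43L)
    st <- build_score_table(sim$counts)
    recs <- dplyr::filter(score_records(st), well_measured)
    fits <- fit_dose_response(recs)
    fw <- dplyr::filter(fits, background == "wt", fit_ok)
    curve <- fit_expectation(expectation_pairs(st))
    av_meas <- st |>
      dplyr::filter(well_measured, background == "av") |>
      dplyr::select(variant, folinate, score, sd, var_non, var_shared)
    ints <- fit_interaction(fw, av_meas, curve)
    list(sim = sim, st = st, fits = fits, fw = fw, curve = curve,
         ints = ints)
  })
}

# independent dense grid-search minimiser for weighted least squares on
# s ~ b + r * c: iterative zoom, no linear algebra shared with the
# implementation under test
grid_search_line <- function(c_vals, s_vals, sd_vals,
                             b_range = c(-3, 3), r_range = c(-0.05, 0.05),
                             rounds = 14L, n_grid = 21L) {
  # search over (a, r) with a the line's value at the weighted mean
  # concentration: this decorrelates the two axes so the zoom converges
  w <- 1 / sd_vals^2
  cw <- sum(w * c_vals) / sum(w)
  sse <- function(a, r) {
    sum(((s_vals - a - r * (c_vals - cw)) / sd_vals)^2)
  }
  c_span <- diff(range(c_vals))
  a_range <- range(s_vals) + c(-1, 1)
  r_range <- r_range * 4
  for (i in seq_len(rounds)) {
    as <- seq(a_range[1], a_range[2], length.out = n_grid)
    rs <- seq(r_range[1], r_range[2], length.out = n_grid)
    grid <- expand.grid(a = as, r = rs)
    vals <- mapply(sse, grid$a, grid$r)
    best <- grid[which.min(vals), ]
    span_a <- diff(a_range) / (n_grid - 1)
    span_r <- diff(r_range) / (n_grid - 1)
    a_range <- c(best$a - span_a, best$a + span_a)
    r_range <- c(best$r - span_r, best$r + span_r)
  }
  list(b = best$a - best$r * cw, r = best$r)
}

# brute-force balanced precision-recall area: explicit threshold sweep
bprc_oracle <- function(score, label, orientation = "lower_pathogenic") {
  x <- if (orientation == "lower_pathogenic") -score else score
  thresholds <- sort(unique(x))
  pts <- data.frame(recall = 0, precision = 1)
  for (t in thresholds) {
    pred <- x >= t
    sens <- sum(pred & label) / sum(label)
    fpr <- sum(pred & !label) / sum(!label)
    bp <- if (sens + fpr == 0) 1 else sens / (sens + fpr)
    pts <- rbind(pts, data.frame(recall = sens, precision = bp))
  }
  pts <- aggregate(precision ~ recall, data = pts, FUN = max)
  pts <- pts[order(pts$recall), ]
  sum(diff(pts$recall) *
        (head(pts$precision, -1) + tail(pts$precision, -1)) / 2)
}
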