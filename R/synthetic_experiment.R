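# Simulation of the multiplexed complementation experiment: Poisson
# mutagenesis libraries per region, growth selection across a folinate
# gradient in two genetic backgrounds, and tile-based paired-read
# sequencing counts.

#' Library and sequencing specification
#'
#' Defaults follow the scale of the published experiment: ~300,000
#' transformant clones per mutagenesis region, Poisson codon-change loads of
#' 0.93/0.86/0.80/0.71 per clone for regions 1-4, ~2 million reads per tile,
#' 5.5 doublings of selection, two replicates, and folinate at 12.5, 25,
#' 100 and 200 ug/mL in wild-type and p.Ala222Val backgrounds.
#'
#' @param clones_per_region Clones per mutagenesis region per background.
#' @param lambda Mean codon changes per clone, one value per region.
#' @param depth_per_tile Sequencing read pairs per tile.
#' @param base_error Per-base miscall probability of a single read.
#' @param doublings Selection doublings `d`.
#' @param replicates Number of replicates per condition.
#' @param backgrounds Genetic backgrounds (`"wt"`, `"av"`).
#' @param folinate Folinate concentrations (ug/mL).
#' @param overdispersion Beta-binomial overdispersion of sequencing counts
#'   (0 = plain binomial, the default).
#' @return A named list of class `library_spec`.
#' @export
library_spec <- function(clones_per_region = 300000L,
                         lambda = c(0.93, 0.86, 0.80, 0.71),
                         depth_per_tile = 2e6,
                         base_error = 0.005,
                         doublings = 5.5,
                         replicates = 2L,
                         backgrounds = c("wt", "av"),
                         folinate = c(12.5, 25, 100, 200),
                         overdispersion = 0) {
  abort_if(clones_per_region <= 0 || depth_per_tile <= 0 ||
             any(lambda < 0) || doublings < 0,
           "Library spec values must be positive.")
  structure(as.list(environment()), class = "library_spec")
}

#' Simulate a regional mutagenesis library
#'
#' Each clone carries `Poisson(lambda[region])` codon changes at uniformly
#' chosen positions within its region; each change is one of the 21
#' amino-acid-level outcomes at that position, drawn uniformly. Clone
#' composition is retained so that multi-variant clones contribute their
#' full product fitness to every constituent variant's marginal frequency
#' (the background-averaging premise of marginal scoring).
#'
#' @param truth A [sample_ground_truth()] tibble.
#' @param spec A [library_spec()].
#' @param layout A [region_layout()].
#' @param seed Integer seed.
#' @return An object of class `clone_pool`: per background and region, the
#'   clone-to-variant instance table plus clone counts.
#' @export
simulate_library <- function(truth, spec, layout, seed = 1L) {
  n_regions <- nrow(layout$regions)
  abort_if(length(spec$lambda) != n_regions,
           "One lambda per region is required.")
  pools <- list()
  with_seed(seed + 23L, {
    for (bg in spec$backgrounds) {
      for (r in seq_len(n_regions)) {
        n_clones <- spec$clones_per_region
        k <- rpois(n_clones, spec$lambda[r])
        m <- sum(k)
        clone <- rep.int(seq_len(n_clones), k)
        pos <- sample(layout$regions$start[r]:layout$regions$end[r], m,
                      replace = TRUE)
        outcome <- sample.int(21L, m, replace = TRUE)
        variant_row <- (pos - 1L) * 21L + outcome
        pools[[bg]][[r]] <- list(
          n_clones = n_clones,
          clone = clone,
          variant_row = variant_row
        )
      }
    }
  })
  structure(list(pools = pools, backgrounds = spec$backgrounds,
                 n_regions = n_regions, truth_rows = nrow(truth)),
            class = "clone_pool")
}

#' @export
print.clone_pool <- function(x, ...) {
  cat("<clone_pool> ", length(x$backgrounds), " backgrounds x ",
      x$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Clone-level growth under selection
#'
#' Frequencies after `d` doublings of selection: each clone grows by the
#' factor `G(w) = 1 + w * (2^d - 1)`, linear in its relative fitness `w`
#' (`G(0) = 1`, `G(1) = 2^d`), and frequencies are renormalized. On this
#' law the calibrated enrichment score is an unbiased estimate of `w`.
#'
#' @param f_non Nonselect frequencies (need not sum to 1; the remainder is
#'   treated as wild type with `w = 1`).
#' @param w Relative fitness per entry of `f_non`.
#' @param d Number of doublings.
#' @return Post-selection frequencies, same length as `f_non`.
#' @export
select_frequencies <- function(f_non, w, d) {
  abort_if(d < 0, "`d` must be non-negative.")
  abort_if(sum(f_non) > 1 + 1e-8, "Frequencies must sum to at most 1.")
  g <- 1 + w * (2^d - 1)
  f_wt <- 1 - sum(f_non)
  z <- sum(f_non * g) + f_wt * 2^d
  f_non * g / z
}

#' Marginal variant frequencies of a clone pool under selection
#'
#' Computes, for one background and condition, the marginal per-variant
#' frequency after selection: clone fitness is the product of its variants'
#' true scores at the given folinate level, clones grow by
#' `G(w) = 1 + w * (2^d - 1)`, and each variant's frequency sums its clones'
#' post-growth weights. `folinate = NULL` gives nonselect frequencies.
#'
#' @param pool A [simulate_library()] clone pool.
#' @param truth The matching ground-truth tibble.
#' @param background `"wt"` or `"av"`.
#' @param folinate Concentration in ug/mL, or `NULL` for nonselect.
#' @param d Doublings (ignored for nonselect).
#' @return A tibble `variant_row`, `region`, `frequency` covering variants
#'   present in the pool.
#' @export
simulate_selection <- function(pool, truth, background, folinate, d = 5.5) {
  abort_if(!background %in% names(pool$pools), "Unknown background.")
  s_all <- if (is.null(folinate)) NULL else
    true_score(truth, background, folinate)
  purrr::map_dfr(seq_len(pool$n_regions), function(r) {
    pp <- pool$pools[[background]][[r]]
    if (length(pp$variant_row) == 0L) {
      return(tibble::tibble(variant_row = integer(), region = integer(),
                            frequency = double()))
    }
    if (is.null(folinate)) {
      weight <- rep(1, pp$n_clones)
    } else {
      s_inst <- s_all[pp$variant_row]
      # clone fitness: product over its variant instances
      logw <- rowsum(log(pmax(s_inst, 0)), pp$clone)
      w_clone <- rep(1, pp$n_clones)
      w_clone[as.integer(rownames(logw))] <- exp(logw[, 1L])
      g <- 1 + w_clone * (2^d - 1)
      weight <- g / mean(g)
    }
    contrib <- rowsum(weight[pp$clone], pp$variant_row)
    tibble::tibble(
      variant_row = as.integer(rownames(contrib)),
      region = r,
      frequency = contrib[, 1L] / pp$n_clones
    )
  })
}

#' Simulate sequencing counts for all conditions
#'
#' Draws per-variant tile counts as `Binomial(depth, f + f_err)` for each
#' background, condition (nonselect and each folinate level) and replicate,
#' plus wild-type-control counts whose frequencies arise from the
#' sequencing-error model alone. The error frequency of an outcome is
#' `n_paths * (base_error / 3)^2`, the chance that both reads of a pair
#' miscall the same target base of one of its `n_paths` single-nucleotide
#' routes.
#'
#' @param pool A [simulate_library()] clone pool.
#' @param truth The matching ground-truth tibble.
#' @param cds The [coding_sequence()] used to count error paths.
#' @param layout A [region_layout()].
#' @param spec A [library_spec()].
#' @param seed Integer seed.
#' @return A count table: `variant`, `position`, `alt`, `type`, `background`,
#'   `condition` (`"nonselect"`/`"select"`), `folinate` (`NA` for
#'   nonselect), `replicate`, `region`, `tile`, `count`, `depth`, plus
#'   matching `wt_control` rows per condition (`sample = "wt_control"`).
#' @export
simulate_counts <- function(pool, truth, cds, layout, spec, seed = 1L) {
  loc <- locate_variant(truth$position, layout)
  truth_loc <- dplyr::mutate(truth, region = loc$region, tile = loc$tile,
                             row_id = dplyr::row_number())
  err_freq <- snv_path_count(truth, cds) * (spec$base_error / 3)^2

  conditions <- tibble::tibble(
    condition = c("nonselect", rep("select", length(spec$folinate))),
    folinate = c(NA_real_, spec$folinate)
  )

  draw_counts <- function(f, depth) {
    if (spec$overdispersion > 0) {
      rho <- spec$overdispersion
      a <- f * (1 - rho) / rho
      b <- (1 - f) * (1 - rho) / rho
      pr <- rbeta(length(f), pmax(a, 1e-12), pmax(b, 1e-12))
      rbinom(length(f), depth, pr)
    } else {
      rbinom(length(f), depth, pmin(f, 1))
    }
  }

  out <- vector("list", 0L)
  with_seed(seed + 31L, {
    for (bg in spec$backgrounds) {
      for (ci in seq_len(nrow(conditions))) {
        fol <- conditions$folinate[ci]
        freqs <- simulate_selection(pool, truth, bg,
                                    if (is.na(fol)) NULL else fol,
                                    d = spec$doublings)
        f_vec <- numeric(nrow(truth))
        f_vec[freqs$variant_row] <- freqs$frequency
        f_vec <- pmin(f_vec + err_freq, 1)
        for (rep_i in seq_len(spec$replicates)) {
          cnt <- draw_counts(f_vec, spec$depth_per_tile)
          ctrl <- draw_counts(pmin(err_freq, 1), spec$depth_per_tile)
          base <- dplyr::transmute(truth_loc,
            variant = .data$variant, position = .data$position,
            alt = .data$alt, type = .data$type,
            background = bg,
            condition = conditions$condition[ci],
            folinate = fol, replicate = rep_i,
            region = .data$region, tile = .data$tile,
            depth = spec$depth_per_tile
          )
          out[[length(out) + 1L]] <-
            dplyr::mutate(base, sample = "library", count = cnt)
          out[[length(out) + 1L]] <-
            dplyr::mutate(base, sample = "wt_control", count = ctrl)
        }
      }
    }
  })
  dplyr::bind_rows(out)
}

#' Simulate one full experiment
#'
#' Convenience wrapper chaining annotations, ground truth, library,
#' selection and sequencing for a coding sequence.
#'
#' @param cds A [coding_sequence()]; default synthetic MTHFR-like sequence.
#' @param layout A [region_layout()].
#' @param truth_params A [ground_truth_params()] list.
#' @param spec A [library_spec()].
#' @param seed Integer seed driving every random stage.
#' @return A list with `cds`, `layout`, `annotations`, `truth`, `pool`,
#'   `counts` and `spec`.
#' @export
simulate_experiment <- function(cds = synthetic_mthfr_cds(),
                                layout = region_layout(nchar(cds$protein)),
                                truth_params = ground_truth_params(),
                                spec = library_spec(),
                                seed = 1L) {
  annotations <- generate_residue_annotations(cds, seed = seed)
  truth <- sample_ground_truth(cds, params = truth_params, seed = seed,
                               annotations = annotations)
  pool <- simulate_library(truth, spec, layout, seed = seed)
  counts <- simulate_counts(pool, truth, cds, layout, spec, seed = seed)
  list(cds = cds, layout = layout, annotations = annotations, truth = truth,
       pool = pool, counts = counts, spec = spec)
}

#' Simulate paired-read observations for one tile
#'
#' Emits per-read-pair variant observations feeding the consensus caller:
#' each pair is templated on a variant (or wild type) drawn by frequency;
#' each read of the pair independently drops a true call with probability
#' `base_error` and adds a spurious single-nucleotide call with per-path
#' probability `base_error / 3`.
#'
#' @param tile_variants Tibble with `variant`, `position`, `frequency` for
#'   the tile (frequencies summing to at most 1).
#' @param tile_range Integer vector `c(start, end)` of codon positions.
#' @param n_pairs Number of read pairs.
#' @param cds The [coding_sequence()].
#' @param base_error Per-base miscall probability.
#' @param seed Integer seed.
#' @return A tibble `pair_id`, `mate`, `variant` (one row per observed
#'   variant call; pairs with no calls are wild type on that mate).
#' @export
simulate_read_pairs <- function(tile_variants, tile_range, n_pairs, cds,
                                base_error = 0.005, seed = 1L) {
  abort_if(sum(tile_variants$frequency) > 1 + 1e-8,
           "Tile frequencies must sum to at most 1.")
  positions <- tile_range[1L]:tile_range[2L]
  ct <- codon_table()
  with_seed(seed + 41L, {
    template <- sample.int(nrow(tile_variants) + 1L, n_pairs, replace = TRUE,
                           prob = c(tile_variants$frequency,
                                    1 - sum(tile_variants$frequency)))
    obs <- list()
    for (mate in 1:2) {
      keep <- template <= nrow(tile_variants) &
        runif(n_pairs) >= base_error
      if (any(keep)) {
        obs[[length(obs) + 1L]] <- tibble::tibble(
          pair_id = which(keep), mate = mate,
          variant = tile_variants$variant[template[keep]]
        )
      }
      # spurious single-nucleotide miscalls along the tile
      n_bases <- 3L * length(positions)
      n_spur <- rbinom(n_pairs, n_bases, base_error / 3)
      spur_pair <- rep.int(seq_len(n_pairs), n_spur)
      if (length(spur_pair) > 0L) {
        pos <- sample(positions, length(spur_pair), replace = TRUE)
        codons <- codon_at(cds, pos)
        alt_codon <- vapply(codons, function(x) sample(codon_snvs(x), 1L),
                            character(1L))
        ref_aa <- unname(ct[codons])
        alt_aa <- unname(ct[alt_codon])
        alt_lab <- ifelse(alt_aa == ref_aa, "=", alt_aa)
        obs[[length(obs) + 1L]] <- tibble::tibble(
          pair_id = spur_pair, mate = mate,
          variant = paste0(ref_aa, pos, alt_lab)
        )
      }
    }
    out <- dplyr::arrange(dplyr::bind_rows(obs), .data$pair_id, .data$mate)
    attr(out, "n_pairs") <- n_pairs
    out
  })
}
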