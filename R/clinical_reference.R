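# Benchmark reference variant sets and the per-domain score ->
# log-likelihood-ratio-of-pathogenicity transform.

#' Parse semicolon-joined allele variant strings
#'
#' Splits allele descriptors such as `"p.Ser56Leu;p.Ala222Val"` into the
#' rare missense variant and the common-polymorphism flags.
#'
#' @param x Character vector of allele strings (may be empty).
#' @return A tibble `rare_hgvs` (first non-polymorphism variant or `NA`),
#'   `a222v`, `e429a`, `n_rare`.
#' @export
parse_allele_string <- function(x) {
  parts <- stringr::str_split(dplyr::coalesce(x, ""), ";")
  purrr::map_dfr(parts, function(v) {
    v <- v[nzchar(v)]
    common_av <- v == "p.Ala222Val"
    common_ea <- v == "p.Glu429Ala"
    rare <- v[!common_av & !common_ea]
    tibble::tibble(
      rare_hgvs = if (length(rare) > 0L) rare[1L] else NA_character_,
      a222v = any(common_av),
      e429a = any(common_ea),
      n_rare = length(rare)
    )
  })
}

#' Build positive reference variant sets from a case table
#'
#' Counts, per rare missense variant, the early-onset and late-onset cases
#' carrying it; variants seen strictly more often in early-onset cases form
#' the early-onset positive set, strictly more often in late-onset cases
#' the late-onset set. Ties are excluded.
#'
#' @param case_table Tibble with `onset` (`early`/`late`/`unaffected`) and
#'   `allele1_variants`, `allele2_variants` columns.
#' @return A tibble `hgvs_p`, `n_early`, `n_late`, `set`
#'   (`early`/`late`; tied variants are dropped).
#' @export
build_positive_sets <- function(case_table) {
  abort_if(!all(case_table$onset %in% c("early", "late", "unaffected")),
           "Unknown onset class values.")
  cases <- dplyr::filter(case_table, .data$onset %in% c("early", "late"))
  alleles <- dplyr::bind_rows(
    dplyr::transmute(cases, .data$onset,
                     allele = .data$allele1_variants, id = .data$id),
    dplyr::transmute(cases, .data$onset,
                     allele = .data$allele2_variants, id = .data$id)
  )
  parsed <- dplyr::bind_cols(alleles, parse_allele_string(alleles$allele))
  counts <- parsed |>
    dplyr::filter(!is.na(.data$rare_hgvs)) |>
    dplyr::distinct(.data$id, .data$onset, .data$rare_hgvs) |>
    dplyr::count(.data$rare_hgvs, .data$onset) |>
    tidyr::pivot_wider(names_from = "onset", values_from = "n",
                       values_fill = 0L)
  if (!"early" %in% names(counts)) counts$early <- 0L
  if (!"late" %in% names(counts)) counts$late <- 0L
  counts |>
    dplyr::transmute(
      hgvs_p = .data$rare_hgvs,
      n_early = .data$early, n_late = .data$late,
      set = dplyr::case_when(
        .data$n_early > .data$n_late ~ "early",
        .data$n_late > .data$n_early ~ "late",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$set))
}

#' Build the random reference variant set from population summaries
#'
#' Keeps missense variants whose global minor-allele frequency exceeds
#' 1 in 10,000 or with at least one observed homozygote.
#'
#' @param population_table Tibble with `hgvs_p`, `af`, `n_hom`.
#' @param af_min Allele-frequency cutoff.
#' @param exclude Optional character vector of variants (e.g. the positive
#'   sets) removed from the result to keep the sets disjoint.
#' @return The filtered tibble with a `set = "random"` column.
#' @export
build_random_set <- function(population_table, af_min = 1e-4,
                             exclude = NULL) {
  abort_if(!all(c("hgvs_p", "af", "n_hom") %in% names(population_table)),
           "Population table needs hgvs_p, af, n_hom.")
  out <- population_table |>
    dplyr::filter(.data$af > af_min | .data$n_hom >= 1L) |>
    dplyr::mutate(set = "random")
  if (!is.null(exclude)) {
    out <- dplyr::filter(out, !.data$hgvs_p %in% exclude)
  }
  out
}

#' Fit per-domain score-to-LLRp transforms
#'
#' Estimates, separately for the catalytic and regulatory domains, Gaussian
#' kernel densities (Silverman bandwidth, 512-point grid) of the positive
#' and random reference score distributions, and returns the
#' log-likelihood ratio of pathogenicity `LLRp(s) = log(f_pos(s) /
#' f_rand(s))` (natural log), with densities floored at `floor_frac` of
#' their peak so the transform is finite over the evaluation range.
#'
#' @param scores Tibble `hgvs_p`, `score`, `position` — one score per
#'   variant (e.g. one map or a virtual map).
#' @param positive,random Character vectors of reference variant ids
#'   (`hgvs_p`).
#' @param domain_boundary Last catalytic position (default 356): positions
#'   at or below are catalytic, above regulatory.
#' @param min_n Minimum reference scores per class per domain.
#' @param floor_frac Density floor as a fraction of the peak.
#' @param pool_domains Fit a single pooled transform instead of per-domain
#'   fits (used when a domain has too few reference scores).
#' @return An object of class `llrp_function`.
#' @export
fit_llrp <- function(scores, positive, random, domain_boundary = 356L,
                     min_n = 10L, floor_frac = 1e-3,
                     pool_domains = FALSE) {
  abort_if(!all(c("hgvs_p", "score", "position") %in% names(scores)),
           "`scores` needs hgvs_p, score, position.")
  scores <- dplyr::filter(scores, is.finite(.data$score))
  scores$domain <- if (pool_domains) "pooled" else
    ifelse(scores$position <= domain_boundary, "catalytic", "regulatory")
  fit_one <- function(df, dom) {
    pos <- df$score[df$hgvs_p %in% positive]
    rand <- df$score[df$hgvs_p %in% random]
    abort_if(length(pos) < min_n || length(rand) < min_n,
             paste0("Too few reference scores in the ", dom,
                    " domain (need ", min_n, " per class)."))
    rng <- range(c(pos, rand))
    pad <- 0.1 * diff(rng) + 1e-6
    grid <- seq(rng[1L] - pad, rng[2L] + pad, length.out = 512L)
    d_pos <- density(pos, bw = "nrd0", n = 512L,
                     from = grid[1L], to = grid[512L])
    d_rand <- density(rand, bw = "nrd0", n = 512L,
                      from = grid[1L], to = grid[512L])
    f_pos <- pmax(d_pos$y, floor_frac * max(d_pos$y))
    f_rand <- pmax(d_rand$y, floor_frac * max(d_rand$y))
    list(domain = dom, grid = d_pos$x, llrp = log(f_pos / f_rand),
         n_pos = length(pos), n_rand = length(rand), range = rng)
  }
  domains <- unique(scores$domain)
  fits <- purrr::map(setNames(domains, domains),
                     ~ fit_one(scores[scores$domain == .x, ], .x))
  obj <- structure(
    list(fits = fits, domain_boundary = domain_boundary,
         pooled = pool_domains),
    class = "llrp_function"
  )
  # benign floor: 5th percentile of the random-reference LLRp values,
  # used as the neutral value for variant-free alleles
  rand_scores <- dplyr::filter(scores, .data$hgvs_p %in% random)
  obj$benign_floor <- quantile(
    predict(obj, rand_scores$score, rand_scores$position), 0.05,
    names = FALSE
  )
  obj
}

#' @export
print.llrp_function <- function(x, ...) {
  doms <- purrr::map_chr(x$fits, "domain")
  cat("<llrp_function> domains: ", paste(doms, collapse = ", "),
      "; benign floor ", round(x$benign_floor, 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate an LLRp transform
#'
#' @param object A [fit_llrp()] object.
#' @param score Numeric scores.
#' @param position Variant positions (to pick the domain transform).
#' @param ... Unused.
#' @return LLRp values (natural log).
#' @export
predict.llrp_function <- function(object, score, position, ...) {
  domain <- if (object$pooled) rep("pooled", length(score)) else
    ifelse(position <= object$domain_boundary, "catalytic", "regulatory")
  out <- rep(NA_real_, length(score))
  for (dom in unique(domain)) {
    fit <- object$fits[[dom]]
    if (is.null(fit)) next
    idx <- which(domain == dom)
    out[idx] <- approx(fit$grid, fit$llrp, xout = score[idx],
                       rule = 2L)$y
  }
  out
}
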