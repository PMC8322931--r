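# Synthetic recessive clinical cohort: diploid genotypes with optional
# in-cis common polymorphisms, onset classes driven by the minimum allele
# functionality, and a population allele-summary table for the
# random-reference filter.

#' Parameters for the synthetic clinical cohort
#'
#' @param n_cases Individuals drawn from the disease-enriched stream (both
#'   alleles carry a rare missense variant biased toward low function).
#' @param n_reference Individuals drawn from the population stream.
#' @param in_cis_prob Probability that a rare case allele carries the common
#'   hypomorphic polymorphism in cis (about one third, as observed for rare
#'   MTHFR variants).
#' @param av_population_prob Probability that a population allele carries the
#'   common polymorphism (its minor-allele frequency is ~0.3).
#' @param e429a_prob Probability of the second common polymorphism in cis.
#' @param reference_rare_prob Probability that each population allele carries
#'   a rare missense variant (benign-biased).
#' @param onset_c Reference folinate level (ug/mL) at which allele
#'   functionality is evaluated.
#' @param early_threshold,late_threshold Onset-class cut points on the noisy
#'   minimum-allele functionality (below early -> early onset; below late ->
#'   late onset; else unaffected).
#' @param onset_noise SD of the Gaussian noise added before thresholding.
#' @param e429a_multiplier Functionality multiplier for the in-cis second
#'   polymorphism.
#' @return Named list of parameters.
#' @export
cohort_params <- function(n_cases = 100L, n_reference = 77L,
                          in_cis_prob = 1 / 3,
                          av_population_prob = 0.3,
                          e429a_prob = 0.08,
                          reference_rare_prob = 0.6,
                          onset_c = 25,
                          early_threshold = 0.35, late_threshold = 0.7,
                          onset_noise = 0.12,
                          e429a_multiplier = 0.95) {
  as.list(environment())
}

#' Generate a synthetic clinical cohort and population table
#'
#' Builds phased diploid genotypes. Case-stream alleles carry rare missense
#' variants biased toward low true functionality; population-stream alleles
#' carry mostly benign rare variants. Each rare case allele carries the
#' common polymorphism in cis with probability `in_cis_prob`. The onset
#' class (early/late/unaffected) derives from the minimum of the two
#' alleles' true functionality (the recessive rule) plus noise. The
#' population table reports allele frequencies and homozygote counts so the
#' random-reference filter (`AF > 1e-4` or `hom >= 1`) keeps most
#' population-stream variants and excludes most case-stream variants.
#'
#' @param truth A [sample_ground_truth()] tibble.
#' @param params A [cohort_params()] list.
#' @param seed Integer seed.
#' @return A list with `cases` (tibble: `id`, `cohort`, `onset`,
#'   `allele1_variants`, `allele2_variants`, `phased`) and `population`
#'   (tibble: `hgvs_p`, `variant`, `af`, `n_hom`).
#' @export
generate_clinical_cohort <- function(truth, params = cohort_params(),
                                     seed = 1L) {
  p <- params
  miss <- dplyr::filter(truth, .data$type == "missense")
  # a variant is disease-relevant when deleterious in either genetic
  # context at the reference folinate level; variants that are benign in
  # the wild-type background but deleterious in cis with the polymorphism
  # are deliberately included (they are what background-aware genotype
  # models exist for)
  fmin <- pmin(true_score(miss, "wt", p$onset_c),
               true_score(miss, "av", p$onset_c))
  path_pool <- dplyr::filter(miss, fmin < 0.75)
  benign_pool <- dplyr::filter(miss, fmin > 0.85, fmin < 1.15)
  abort_if(nrow(path_pool) < 10L || nrow(benign_pool) < 10L,
           "Truth table too small to build a cohort.")

  with_seed(seed + 53L, {
    # limited allelic heterogeneity, as in a rare-disease cohort
    path_vars <- dplyr::slice_sample(path_pool,
                                     n = min(60L, nrow(path_pool)))
    benign_vars <- dplyr::slice_sample(benign_pool,
                                       n = min(80L, nrow(benign_pool)))

    # allele functionality for the onset model: the rare variant's true
    # score in the matching background (relative to the polymorphism-only
    # baseline, which is itself clinically benign); variant-free alleles
    # are fully functional
    allele_func <- function(rows, av, e429a) {
      f <- ifelse(is.na(rows), 1,
                  true_score(truth[pmax(rows, 1L), ], "wt", p$onset_c))
      f_av <- ifelse(is.na(rows), 1,
                     true_score(truth[pmax(rows, 1L), ], "av", p$onset_c))
      out <- ifelse(av, f_av, f)
      ifelse(e429a & !is.na(rows), out * p$e429a_multiplier, out)
    }
    allele_string <- function(rows, av, e429a) {
      base <- ifelse(is.na(rows), "",
                     format_protein_variant(truth[pmax(rows, 1L), ]))
      s <- ifelse(av, paste0(base, ";p.Ala222Val"), base)
      s <- ifelse(e429a, paste0(s, ";p.Glu429Ala"), s)
      sub("^;", "", s)
    }

    draw_stream <- function(n, pool_rows, rare_prob, av_prob) {
      a1 <- ifelse(runif(n) < rare_prob,
                   sample(pool_rows, n, replace = TRUE), NA_integer_)
      a2 <- ifelse(runif(n) < rare_prob,
                   sample(pool_rows, n, replace = TRUE), NA_integer_)
      av1 <- ifelse(is.na(a1), runif(n) < p$av_population_prob,
                    runif(n) < av_prob)
      av2 <- ifelse(is.na(a2), runif(n) < p$av_population_prob,
                    runif(n) < av_prob)
      e1 <- runif(n) < p$e429a_prob
      e2 <- runif(n) < p$e429a_prob
      # recessive disease: the more functional allele governs phenotype
      # (one working copy suffices), matching the least-pathogenic-allele
      # rule used for genotype LLRp
      func <- pmax(allele_func(a1, av1, e1), allele_func(a2, av2, e2))
      noisy <- func + rnorm(n, 0, p$onset_noise)
      tibble::tibble(
        allele1_variants = allele_string(a1, av1, e1),
        allele2_variants = allele_string(a2, av2, e2),
        onset = dplyr::case_when(
          noisy < p$early_threshold ~ "early",
          noisy < p$late_threshold ~ "late",
          TRUE ~ "unaffected"
        ),
        phased = TRUE
      )
    }

    row_ids <- function(df) match(df$variant, truth$variant)
    cases <- draw_stream(p$n_cases, row_ids(path_vars),
                         rare_prob = 1, av_prob = p$in_cis_prob)
    cases$cohort <- "case"
    refs <- draw_stream(p$n_reference, row_ids(benign_vars),
                        rare_prob = p$reference_rare_prob,
                        av_prob = p$in_cis_prob)
    refs$cohort <- "reference"
    cohort <- dplyr::bind_rows(cases, refs)
    cohort$id <- sprintf("IND%03d", seq_len(nrow(cohort)))
    cohort <- dplyr::select(cohort, "id", "cohort", "onset",
                            "allele1_variants", "allele2_variants", "phased")

    # population allele summaries: benign-pool variants are common enough
    # (or seen homozygous) to pass the random-reference filter; case-pool
    # variants are rare and never homozygous
    population <- dplyr::bind_rows(
      tibble::tibble(
        variant = benign_vars$variant,
        hgvs_p = format_protein_variant(benign_vars),
        af = 10^runif(nrow(benign_vars), -5, -2.3),
        n_hom = rbinom(nrow(benign_vars), 2L, 0.25)
      ),
      tibble::tibble(
        variant = path_vars$variant,
        hgvs_p = format_protein_variant(path_vars),
        af = 10^runif(nrow(path_vars), -6, -4.5),
        n_hom = 0L
      )
    )
    list(cases = cohort, population = population)
  })
}
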