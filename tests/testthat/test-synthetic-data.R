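test_that("ground truth anchors nonsense and synonymous outcomes", {
  cds <- tiny_cds()
  truth <- sample_ground_truth(cds, seed = 1L)
  expect_true(all(truth$w_base[truth$type == "nonsense"] == 0))
  expect_true(all(truth$w_base[truth$type == "synonymous"] == 1))
  expect_true(all(truth$rho[truth$type != "missense"] == 0))

  # deterministic given seed; different seeds decorrelate
  again <- sample_ground_truth(cds, seed = 1L)
  expect_identical(truth, again)
  other <- sample_ground_truth(cds, seed = 2L)
  expect_false(identical(truth$w_base, other$w_base))

  # no responsive slopes when the responsive fraction is zero
  none <- sample_ground_truth(cds, ground_truth_params(
    responsive_fraction = 0), seed = 1L)
  expect_true(all(none$rho == 0))

  expect_error(ground_truth_params(mixture_weights = c(
    null = 0.5, hypomorph = 0.5, wt_like = 0.5, hyper = 0)), "sum to 1")
})

test_that("responsive and interacting fractions match requested rates", {
  cds <- synthetic_mthfr_cds()
  truth <- sample_ground_truth(cds, seed = 3L)
  miss <- truth[truth$type == "missense", ]
  n <- nrow(miss)
  # binomial tolerance: ~4 sd
  expect_lt(abs(mean(miss$responsive) - 0.07), 4 * sqrt(0.07 * 0.93 / n))
  frac_int <- mean(miss$gamma_b != 0 | miss$gamma_r != 0)
  expect_gt(frac_int, 0.28)
  expect_lt(frac_int, 0.42)
})

test_that("library mutational load follows the Poisson model", {
  cds <- tiny_cds()
  lay <- region_layout(nchar(cds$protein), n_regions = 1L,
                       tiles_per_region = 1L)
  truth <- sample_ground_truth(cds, seed = 1L)

  # lambda = 0: all clones wild type
  spec0 <- library_spec(clones_per_region = 1000L, lambda = 0)
  pool0 <- simulate_library(truth, spec0, lay, seed = 1L)
  expect_equal(length(pool0$pools$wt[[1]]$variant_row), 0L)
  f0 <- simulate_selection(pool0, truth, "wt", NULL)
  expect_equal(nrow(f0), 0L)

  # lambda = 0.9: fraction of untouched clones ~ exp(-0.9)
  spec <- library_spec(clones_per_region = 10000L, lambda = 0.9)
  pool <- simulate_library(truth, spec, lay, seed = 1L)
  pp <- pool$pools$wt[[1]]
  frac0 <- 1 - length(unique(pp$clone)) / pp$n_clones
  expect_lt(abs(frac0 - exp(-0.9)), 0.02)

  # expected per-variant frequency ~ lambda / (21 * region length)
  f <- simulate_selection(pool, truth, "wt", NULL)
  expect_lt(abs(mean(f$frequency) - 0.9 / (21 * nchar(cds$protein))), 2e-4)
})

test_that("selection follows the doubling growth law", {
  # two clones, half frequency each, w = {1, 0}, d = 2 -> {0.8, 0.2}
  expect_equal(select_frequencies(c(0.5, 0.5), c(1, 0), d = 2),
               c(0.8, 0.2))
  # uniform fitness cancels exactly
  expect_equal(select_frequencies(c(0.3, 0.7), c(1, 1), d = 3.7),
               c(0.3, 0.7))
  # a dead clone's frequency is strictly decreasing in d
  f_at <- vapply(c(0, 1, 2, 5), function(d) {
    select_frequencies(c(0.5, 0.5), c(1, 0), d)[2]
  }, numeric(1))
  expect_true(all(diff(f_at) < 0))
  expect_error(select_frequencies(c(0.5, 0.5), c(1, 0), d = -1),
               "non-negative")
})

test_that("sequencing counts follow binomial sampling with an error floor", {
  cds <- tiny_cds()
  lay <- region_layout(nchar(cds$protein), n_regions = 1L,
                       tiles_per_region = 1L)
  truth <- sample_ground_truth(cds, seed = 1L)
  spec <- library_spec(clones_per_region = 5000L, lambda = 0.9,
                       depth_per_tile = 1e5, base_error = 0)
  pool <- simulate_library(truth, spec, lay, seed = 2L)
  counts <- simulate_counts(pool, truth, cds, lay, spec, seed = 2L)
  expect_true(all(counts$count <= counts$depth))
  # zero error model: control strain counts are exactly zero
  ctrl <- counts[counts$sample == "wt_control", ]
  expect_true(all(ctrl$count == 0))
  # binomial moments: count ~ depth * f within 5 sd
  non <- counts[counts$sample == "library" &
                  counts$condition == "nonselect" &
                  counts$replicate == 1L, ]
  freqs <- simulate_selection(pool, truth, "wt", NULL)
  f_vec <- numeric(nrow(truth))
  f_vec[freqs$variant_row] <- freqs$frequency
  idx <- match(non$variant[non$background == "wt"], truth$variant)
  obs <- non$count[non$background == "wt"]
  expected <- f_vec[idx] * 1e5
  ok <- expected > 20
  z <- (obs[ok] - expected[ok]) / sqrt(expected[ok])
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(sd(z), 1.3)
})

test_that("clinical cohort respects in-cis probability and onset anchors", {
  truth <- sample_ground_truth(synthetic_mthfr_cds(), seed = 4L)
  coh <- generate_clinical_cohort(truth, seed = 4L)
  alleles <- c(coh$cases$allele1_variants, coh$cases$allele2_variants)
  parsed <- parse_allele_string(alleles)
  rare_case <- parsed[!is.na(parsed$rare_hgvs) &
                        rep(coh$cases$cohort, 2) == "case", ]
  # about one third of rare case alleles carry the polymorphism in cis
  n <- nrow(rare_case)
  expect_lt(abs(mean(rare_case$a222v) - 1 / 3), 4 * sqrt(2 / 9 / n))

  # in-cis probability 0: no rare case allele carries the polymorphism
  coh0 <- generate_clinical_cohort(truth, cohort_params(in_cis_prob = 0),
                                   seed = 4L)
  p0 <- parse_allele_string(c(coh0$cases$allele1_variants,
                              coh0$cases$allele2_variants))
  p0 <- p0[!is.na(p0$rare_hgvs) & rep(coh0$cases$cohort, 2) == "case", ]
  expect_true(all(!p0$a222v))

  # extreme thresholds: genotypes built from two null alleles are always
  # early onset (null-only disease pool, no interactions)
  tnull <- sample_ground_truth(synthetic_mthfr_cds(), ground_truth_params(
    mixture_weights = c(null = 0.5, hypomorph = 0, wt_like = 0.5,
                        hyper = 0),
    responsive_fraction = 0, interaction_fraction = 0,
    suppressor_fraction = 0), seed = 4L)
  cohx <- generate_clinical_cohort(tnull, cohort_params(
    early_threshold = 1 - 1e-9, late_threshold = 1 - 1e-9,
    onset_noise = 0), seed = 4L)
  cases <- cohx$cases[cohx$cases$cohort == "case", ]
  expect_true(all(cases$onset == "early"))
})

test_that("residue annotations are deterministic and complete", {
  cds <- synthetic_mthfr_cds()
  ann <- generate_residue_annotations(cds, seed = 9L)
  expect_equal(nrow(ann), 656L)
  expect_true(all(ann$domain %in% c("serine_rich", "catalytic", "linker",
                                    "regulatory")))
  expect_identical(ann, generate_residue_annotations(cds, seed = 9L))
  expect_true(all(ann$asa_pct >= 0 & ann$asa_pct <= 100))
  # ligand flags sit in the expected domains
  expect_true(all(ann$domain[ann$near_mthf] == "catalytic"))
  expect_true(all(ann$domain[ann$near_sah] == "regulatory"))
})

test_that("read-pair simulation and consensus calling agree on the rules", {
  cds <- tiny_cds()
  tile_vars <- tibble::tibble(
    variant = c("A2C", "A2*"), position = c(2L, 2L),
    frequency = c(0.2, 0.1)
  )
  rp <- simulate_read_pairs(tile_vars, c(1L, 30L), n_pairs = 4000L, cds,
                            base_error = 0, seed = 3L)
  called <- call_variants_from_read_pairs(rp)
  expect_equal(called$depth[1], 4000L)
  expect_lt(abs(called$count[called$variant == "A2C"] / 4000 - 0.2), 0.03)
  expect_equal(glance(called)$agreement, 1)

  # with base errors, spurious pair-consensus calls are rare (~(e/3)^2 per
  # path) while one-mate dropouts lower the agreement fraction
  rp2 <- simulate_read_pairs(tile_vars, c(1L, 30L), n_pairs = 4000L, cds,
                             base_error = 0.02, seed = 3L)
  called2 <- call_variants_from_read_pairs(rp2)
  expect_lt(glance(called2)$agreement, 1)
  spurious <- setdiff(called2$variant, tile_vars$variant)
  expect_lt(sum(called2$count[called2$variant %in% spurious]),
            0.01 * 4000)
})
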