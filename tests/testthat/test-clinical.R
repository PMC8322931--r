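test_that("positive reference sets use strict onset majorities", {
  cases <- tibble::tibble(
    id = sprintf("I%02d", 1:6),
    onset = c("early", "early", "late", "early", "late", "unaffected"),
    allele1_variants = c("p.Ala5Cys", "p.Ala5Cys;p.Ala222Val", "p.Ala5Cys",
                         "p.Gly7Arg", "p.Gly7Arg", "p.Trp9Ser"),
    allele2_variants = c("p.Leu6Pro", "p.Leu6Pro", "",
                         "p.Leu6Pro", "", ""),
    phased = TRUE
  )
  sets <- build_positive_sets(cases)
  # Ala5Cys: 2 early vs 1 late -> early set
  expect_equal(sets$set[sets$hgvs_p == "p.Ala5Cys"], "early")
  # Gly7Arg: 1 early vs 1 late -> tie, excluded
  expect_false("p.Gly7Arg" %in% sets$hgvs_p)
  # Leu6Pro: 3 early vs 0 late -> early
  expect_equal(sets$set[sets$hgvs_p == "p.Leu6Pro"], "early")
  # unaffected carriers contribute to neither count
  expect_false("p.Trp9Ser" %in% sets$hgvs_p)
  expect_error(build_positive_sets(dplyr::mutate(cases,
    onset = "sometime")), "onset")
})

test_that("random reference filter keeps common or homozygous variants", {
  pop <- tibble::tibble(
    hgvs_p = c("p.Ala5Cys", "p.Leu6Pro", "p.Gly7Arg", "p.Trp9Ser"),
    af = c(5e-5, 5e-5, 2e-4, 1e-3),
    n_hom = c(0L, 1L, 0L, 2L)
  )
  rnd <- build_random_set(pop)
  expect_false("p.Ala5Cys" %in% rnd$hgvs_p)   # rare, never homozygous
  expect_true("p.Leu6Pro" %in% rnd$hgvs_p)    # rare but homozygous
  expect_true("p.Gly7Arg" %in% rnd$hgvs_p)    # above 1 in 10,000
  # positive-set overlap removed on request
  rnd2 <- build_random_set(pop, exclude = "p.Trp9Ser")
  expect_false("p.Trp9Ser" %in% rnd2$hgvs_p)
})

test_that("LLRp transform matches the Gaussian closed form", {
  withr::with_seed(19, {
    n <- 50000
    # overlapping references so the density floor never binds over the
    # evaluation range
    scores <- tibble::tibble(
      hgvs_p = sprintf("p.X%d", 1:(2 * n)),
      score = c(rnorm(n, 0, 0.3), rnorm(n, 1, 0.3)),
      position = 100L
    )
    pos_ids <- scores$hgvs_p[1:n]
    rand_ids <- scores$hgvs_p[(n + 1):(2 * n)]
    llrp <- fit_llrp(scores, pos_ids, rand_ids, pool_domains = TRUE,
                     floor_frac = 1e-9)
    # closed form: log N(s; 0, .3) - log N(s; 1, .3) = (1 - 2 s) / 0.18,
    # linear and decreasing in the score
    s_eval <- seq(0.2, 0.8, by = 0.05)
    est <- predict(llrp, s_eval, rep(100L, length(s_eval)))
    analytic <- (1 - 2 * s_eval) / (2 * 0.3^2)
    expect_lt(max(abs(est - analytic)), 0.2)
    expect_true(all(diff(est) < 0))
    # equal densities cross at LLRp zero
    expect_lt(abs(predict(llrp, 0.5, 100L)), 0.1)
  })
  # identical reference distributions: LLRp flat at zero
  same <- tibble::tibble(hgvs_p = sprintf("p.Y%d", 1:40),
                         score = rep(seq(0, 1, length.out = 20), 2),
                         position = 10L)
  l0 <- fit_llrp(same, same$hgvs_p[1:20], same$hgvs_p[1:20],
                 pool_domains = TRUE)
  expect_lt(max(abs(predict(l0, seq(0.1, 0.9, 0.1), rep(10L, 9)))), 1e-9)

  expect_error(fit_llrp(same, same$hgvs_p[1:5], same$hgvs_p[1:20],
                        pool_domains = TRUE), "Too few")
})

test_that("balanced precision-recall evaluation matches its definitions", {
  # perfectly separated classes
  sep <- evaluate_classifier(c(0.1, 0.2, 0.8, 0.9),
                             c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$aubprc, 1)
  expect_equal(sep$r90p, 1)

  # any threshold between the classes has balanced precision 1
  expect_true(all(sep$curve$precision == 1))

  # labels independent of scores: area near one half
  withr::with_seed(20, {
    big <- evaluate_classifier(runif(4000), runif(4000) < 0.3)
    expect_lt(abs(big$aubprc - 0.5), 0.05)
  })

  # brute-force threshold-sweep oracle on small instances
  withr::with_seed(24, {
    for (i in 1:25) {
      n <- sample(10:50, 1)
      sc <- round(runif(n), 2)  # ties likely
      lb <- runif(n) < 0.4
      if (!any(lb) || all(lb)) next
      ours <- evaluate_classifier(sc, lb)$aubprc
      expect_equal(ours, bprc_oracle(sc, lb), tolerance = 1e-12)
    }
  })
  expect_error(evaluate_classifier(1:3, c(TRUE, TRUE, TRUE)), "classes")
})

test_that("paired bootstrap comparison detects a dominated classifier", {
  withr::with_seed(25, {
    lb <- rep(c(TRUE, FALSE), each = 60)
    good <- ifelse(lb, rnorm(120, 0.2, 0.1), rnorm(120, 0.8, 0.1))
    noisy <- ifelse(lb, rnorm(120, 0.45, 0.2), rnorm(120, 0.55, 0.2))
    cmp <- compare_classifiers(good, noisy, lb, n_boot = 500L, seed = 1L)
    expect_gt(cmp$delta, 0)
    expect_lt(cmp$p, 0.05)
    # comparing a classifier with itself: null difference
    self <- compare_classifiers(good, good, lb, n_boot = 200L, seed = 1L)
    expect_equal(self$delta, 0)
    expect_equal(self$p, 1)
  })
})

test_that("allele and genotype scoring follow the M1-M3 model definitions", {
  # minimal deterministic setup: identity expectation, linear LLRp
  scores <- tibble::tibble(
    hgvs_p = c("p.Ala5Cys", "p.Leu6Pro", "p.Gly400Arg"),
    score = c(0.1, 0.8, 0.2),
    position = c(5L, 6L, 400L)
  )
  ref_scores <- tibble::tibble(
    hgvs_p = sprintf("p.Z%d", 1:40),
    score = c(seq(0, 0.4, length.out = 20), seq(0.6, 1.2, length.out = 20)),
    position = rep(c(50L, 400L), 20)
  )
  llrp <- fit_llrp(dplyr::bind_rows(scores, ref_scores),
                   positive = ref_scores$hgvs_p[1:20],
                   random = ref_scores$hgvs_p[21:40],
                   pool_domains = TRUE)
  wt_fits <- tibble::tibble(
    variant = c("A5C", "L6P", "G400R"), background = "wt",
    b = c(0.1, 0.8, 0.2), r = 0, se_b = 0.01, se_r = 1e-4, cov_br = 0,
    fit_ok = TRUE
  )
  int_fits <- tibble::tibble(
    variant = c("A5C", "L6P", "G400R"),
    eps_b = c(0, -0.6, 0), eps_r = 0, fit_ok = TRUE
  )
  curve <- fit_expectation(tibble::tibble(s_wt = seq(0, 1.2, length.out = 100),
                                          s_av = seq(0, 1.2, length.out = 100)),
                           degree = 1L)
  geno <- tibble::tibble(
    id = c("G1", "G2", "G3"),
    allele1_variants = c("p.Ala5Cys", "p.Leu6Pro;p.Ala222Val",
                         "p.Gly400Arg;p.Glu429Ala"),
    allele2_variants = c("p.Leu6Pro", "p.Leu6Pro", "")
  )
  m1 <- score_genotypes(geno, scores, wt_fits, int_fits, curve, llrp,
                        model = "M1")
  m2 <- score_genotypes(geno, scores, wt_fits, int_fits, curve, llrp,
                        model = "M2")
  m3 <- score_genotypes(geno, scores, wt_fits, int_fits, curve, llrp,
                        model = "M3")

  # M1 and M2 agree except for alleles with the polymorphism in cis
  expect_equal(m1$genotype_llrp[1], m2$genotype_llrp[1])
  expect_equal(m1$allele1_func[2], 0.8)
  expect_equal(m2$allele1_func[2], 0.2, tolerance = 1e-6)  # 0.8 - 0.6
  # M3 applies the product rule for the second polymorphism
  expect_equal(m3$allele1_func[3], 0.2 * 0.95, tolerance = 1e-6)
  # variant-free alleles sit at the benign floor
  expect_equal(m1$allele2_llrp[3], llrp$benign_floor)
  # the genotype takes the minimum (least pathogenic) allele LLRp
  expect_equal(m1$genotype_llrp, pmin(m1$allele1_llrp, m1$allele2_llrp))
  # allele order invariance
  swapped <- geno
  swapped$allele1_variants <- geno$allele2_variants
  swapped$allele2_variants <- geno$allele1_variants
  m1s <- score_genotypes(swapped, scores, wt_fits, int_fits, curve, llrp,
                         model = "M1")
  expect_equal(m1s$genotype_llrp, m1$genotype_llrp)
  # homozygous genotype scores as its single allele
  hom <- score_genotypes(tibble::tibble(
    id = "H", allele1_variants = "p.Ala5Cys",
    allele2_variants = "p.Ala5Cys"), scores, wt_fits, int_fits, curve,
    llrp, model = "M1")
  expect_equal(hom$genotype_llrp, hom$allele1_llrp)
  # unscorable rare variants propagate as missing
  uns <- score_genotypes(tibble::tibble(
    id = "U", allele1_variants = "p.Trp9Ser",
    allele2_variants = "p.Ala5Cys"), scores, wt_fits, int_fits, curve,
    llrp, model = "M1")
  expect_true(is.na(uns$genotype_llrp))
  expect_equal(uns$n_unscored, 1L)
})
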