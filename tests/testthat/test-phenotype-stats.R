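test_that("summary-statistic Welch test matches t.test on raw data", {
  withr::with_seed(14, {
    for (i in 1:25) {
      x <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
      y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
      w <- welch_summary(mean(x), sd(x), length(x),
                         mean(y), sd(y), length(y))
      ref <- t.test(x, y)
      expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(w$p, ref$p.value, tolerance = 1e-9)
      w1 <- welch_summary(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y),
                          alternative = "greater")
      ref1 <- t.test(x, y, alternative = "greater")
      expect_equal(w1$p, ref1$p.value, tolerance = 1e-9)
    }
  })
})

test_that("background comparisons flag planted shifts and spare nulls", {
  make_st <- function(delta_fun) {
    n <- 300
    withr::with_seed(15, {
      purrr::map_dfr(c("wt", "av"), function(bg) {
        purrr::map_dfr(c(12.5, 25, 100, 200), function(fol) {
          mu <- 0.8 + if (bg == "av") delta_fun(seq_len(n)) else 0
          tibble::tibble(
            variant = sprintf("V%03d", seq_len(n)), type = "missense",
            background = bg, folinate = fol,
            score = rnorm(n, mu, 0.05 / sqrt(2)), sd = 0.05 / sqrt(2),
            df = 2L, well_measured = TRUE
          )
        })
      })
    })
  }
  # identical distributions: nothing flagged
  null_st <- make_st(function(i) 0)
  cmp0 <- compare_backgrounds(null_st)
  expect_lte(mean(cmp0$flagged), 0.05)

  # a planted -0.4 shift with sigma 0.05 and two replicates is flagged in
  # every concentration
  shift_st <- make_st(function(i) ifelse(i <= 50, -0.4, 0))
  cmp <- compare_backgrounds(shift_st)
  hit <- cmp[cmp$variant %in% sprintf("V%03d", 1:50), ]
  expect_gte(mean(hit$flagged), 0.95)
  expect_true(all(hit$direction[hit$flagged] == "less_functional"))
  summ <- summarize_background_shifts(cmp)
  expect_gte(summ$less_functional_all, 40)
  expect_lte(summ$more_functional_any, 15)
})

test_that("hypercomplementation screen tests candidates above 1 one-sided", {
  withr::with_seed(16, {
    n_syn <- 200
    syn <- tibble::tibble(
      variant = sprintf("S%03d", 1:n_syn), type = "synonymous",
      background = "wt", b = rnorm(n_syn, 1, 0.1),
      se_b = 0.05, n_obs = 8L, fit_ok = TRUE
    )
    mis <- tibble::tibble(
      variant = sprintf("M%03d", 1:3), type = "missense",
      background = "wt", b = c(1.0, 1.02, 1.4),
      se_b = 0.05 / sqrt(8), n_obs = 8L, fit_ok = TRUE
    )
    res <- find_hypercomplementers(dplyr::bind_rows(syn, mis))
    # b = 1 fails the strict candidate inequality
    expect_false("M001" %in% res$variant)
    res <- res[order(res$variant), ]
    # at the synonymous mean: not significant; planted 1.4: flagged
    expect_false(res$hypercomplementing[res$variant == "M002"])
    expect_true(res$hypercomplementing[res$variant == "M003"])
    expect_true(all(res$q >= res$p - 1e-12))
  })
  expect_error(find_hypercomplementers(tibble::tibble(
    variant = "M1", type = "missense", b = 1.2, se_b = 0.01,
    n_obs = 4L, fit_ok = TRUE)), "synonymous")
})

test_that("rank-sum comparisons match exact enumeration for small groups", {
  res <- rank_sum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$delta_median, -3)
  # exhaustive oracle: all C(6,3) assignments of ranks to group A
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(idx) {
    sum(outer(idx, setdiff(1:6, idx), ">"))
  })
  p_exact <- mean(u_all <= 0) * 2
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  expect_equal(res$p, 0.1, tolerance = 1e-12)

  # identical groups: no median difference, p near 1
  same <- rank_sum_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$delta_median, 0)
  expect_gt(same$p, 0.9)

  # random small instances against enumeration of the U null distribution
  withr::with_seed(17, {
    for (i in 1:10) {
      pool <- sample(1000, 9)
      a <- pool[1:4]
      b <- pool[5:9]
      res <- rank_sum_compare(a, b)
      pooled <- c(a, b)
      combos <- combn(9, 4)
      u_all <- apply(combos, 2, function(idx) {
        sum(outer(pooled[order(pooled)][idx],
                  pooled[order(pooled)][setdiff(1:9, idx)], ">"))
      })
      p_two <- min(1, 2 * min(mean(u_all <= res$u), mean(u_all >= res$u)))
      expect_equal(res$p, p_two, tolerance = 1e-9)
    }
  })
  expect_error(rank_sum_compare(numeric(0), 1:3), "non-empty")
})

test_that("structural-group comparisons recover the planted severity", {
  atlas <- atlas_fixture()
  pos_med <- position_median_scores(atlas$st)
  res <- compare_structural_groups(pos_med, atlas$sim$annotations)
  buried <- res[res$comparison == "buried_vs_exposed_catalytic", ]
  # buried catalytic positions were planted less functional
  expect_lt(buried$delta_median, 0)
  expect_lt(buried$p, 0.01)
  fad <- res[res$comparison == "near_fad_vs_exposed", ]
  expect_lt(fad$delta_median, 0)
})

test_that("Fisher enrichment reports both odds ratios and exact p values", {
  even <- fisher_enrichment(rep(c(TRUE, FALSE), each = 20),
                            rep(c(TRUE, FALSE), 20))
  expect_equal(even$or_sample, 1)
  expect_gt(even$p, 0.99)

  x <- c(rep(TRUE, 10), rep(FALSE, 10))
  y <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  res <- fisher_enrichment(x, y)
  expect_equal(res$or_sample, 16)
  ref <- fisher.test(table(factor(x, c(TRUE, FALSE)),
                           factor(y, c(TRUE, FALSE))))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$or_cmle, unname(ref$estimate), tolerance = 1e-9)

  # hypergeometric tail against brute-force enumeration (n <= 20)
  withr::with_seed(18, {
    for (i in 1:10) {
      n <- sample(8:20, 1)
      a <- sample(c(TRUE, FALSE), n, replace = TRUE)
      b <- sample(c(TRUE, FALSE), n, replace = TRUE)
      res <- fisher_enrichment(a, b)
      # enumerate all tables with the observed margins
      m1 <- sum(a); m2 <- sum(b)
      ks <- max(0, m1 + m2 - n):min(m1, m2)
      probs <- choose(m2, ks) * choose(n - m2, m1 - ks) / choose(n, m1)
      obs <- sum(a & b)
      p_enum <- sum(probs[probs <= probs[ks == obs] * (1 + 1e-7)])
      expect_equal(res$p, p_enum, tolerance = 1e-7)
    }
  })

  # zero margin: degenerate flag with an extreme sample odds ratio
  deg <- fisher_enrichment(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  expect_true(deg$degenerate)
})

test_that("screens are invariant to row order", {
  atlas <- atlas_fixture()
  cmp <- compare_backgrounds(atlas$st)
  shuffled <- atlas$st[sample(nrow(atlas$st)), ]
  attributes(shuffled)$records <- attr(atlas$st, "records")
  cmp2 <- compare_backgrounds(shuffled)
  cmp2 <- cmp2[match(paste(cmp$variant, cmp$folinate),
                     paste(cmp2$variant, cmp2$folinate)), ]
  expect_equal(cmp2$p, cmp$p)
  expect_equal(cmp2$flagged, cmp$flagged)
})
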