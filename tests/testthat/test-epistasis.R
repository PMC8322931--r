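make_av <- function(c_vals, scores, sds, variant = "V1") {
  tibble::tibble(variant = variant, folinate = c_vals, score = scores,
                 sd = sds)
}

make_wt_fit <- function(b, r, variant = "V1", se = 1e-6) {
  tibble::tibble(variant = variant, background = "wt", b = b, r = r,
                 se_b = se, se_r = se / 100, cov_br = 0, fit_ok = TRUE)
}

identity_curve <- function() {
  pairs <- tibble::tibble(s_wt = seq(-0.2, 1.6, length.out = 200),
                          s_av = seq(-0.2, 1.6, length.out = 200))
  fit_expectation(pairs, degree = 1L)
}

test_that("expectation curve recovers identity and linear relations", {
  withr::with_seed(12, {
    s <- runif(500, 0, 1.2)
    ident <- fit_expectation(tibble::tibble(s_wt = s,
                                            s_av = s + rnorm(500, 0, 0.02)))
    expect_lt(abs(predict(ident, 0.5) - 0.5), 0.01)

    # exact weighted linear recovery at degree 1 (vs lm as cross-check)
    sav <- 0.8 * s
    w <- runif(500, 0.5, 2)
    lin <- fit_expectation(tibble::tibble(s_wt = s, s_av = sav, weight = w),
                           degree = 1L, trim = Inf)
    lmf <- stats::lm(sav ~ s, weights = w)
    expect_equal(lin$coefficients, unname(coef(lmf)), tolerance = 1e-9)
    expect_equal(predict(lin, 0.5), 0.4, tolerance = 1e-9)

    # clipping: out-of-range inputs return the boundary value
    expect_equal(predict(lin, 10), predict(lin, max(s)))
    expect_equal(predict(lin, -10), predict(lin, min(s)))
  })
  expect_error(fit_expectation(tibble::tibble(s_wt = 1:10 / 10,
                                              s_av = 1:10 / 10)),
               "Too few")
})

test_that("robust trimming keeps the curve on the non-interacting majority", {
  withr::with_seed(13, {
    s <- runif(2000, 0, 1.2)
    s_av <- s + rnorm(2000, 0, 0.03)
    # a third of variants interact negatively
    hit <- seq_len(2000) <= 660
    s_av[hit] <- s_av[hit] - runif(660, 0.2, 0.5)
    robust <- fit_expectation(tibble::tibble(s_wt = s, s_av = s_av))
    plain <- fit_expectation(tibble::tibble(s_wt = s, s_av = s_av),
                             trim = Inf)
    # the trimmed curve tracks the majority; the plain fit is dragged down
    expect_lt(abs(predict(robust, 0.8) - 0.8), 0.03)
    expect_gt(0.8 - predict(plain, 0.8), 0.05)
  })
})

test_that("interaction terms are exact on constructed data", {
  cc <- c(12.5, 25, 100, 200)
  curve <- identity_curve()

  # AV scores exactly on the expectation: both terms zero
  wt <- make_wt_fit(b = 0.8, r = 0)
  av0 <- make_av(cc, rep(0.8, 4), rep(0.05, 4))
  f0 <- fit_interaction(wt, av0, curve)
  expect_equal(f0$eps_b, 0, tolerance = 1e-9)
  expect_equal(f0$eps_r, 0, tolerance = 1e-9)
  expect_equal(f0$llr_g, 0, tolerance = 1e-9)

  # constant offset: eps_b = -0.3
  f1 <- fit_interaction(wt, make_av(cc, rep(0.5, 4), rep(0.05, 4)), curve)
  expect_equal(f1$eps_b, -0.3, tolerance = 1e-9)
  expect_equal(f1$eps_r, 0, tolerance = 1e-9)

  # offset plus slope: eps_b = -0.4, eps_r = 0.001
  f2 <- fit_interaction(wt, make_av(cc, 0.4 + 0.001 * cc, rep(0.05, 4)),
                        curve)
  expect_equal(f2$eps_b, -0.4, tolerance = 1e-8)
  expect_equal(f2$eps_r, 0.001, tolerance = 1e-10)

  # nested likelihood ordering holds
  expect_true(all(f2$logl_full >= f2$logl_eb - 1e-9))
  expect_true(all(f2$logl_eb >= f2$logl_null - 1e-9))
})

test_that("interaction fits match a 2-D grid-search oracle", {
  curve <- identity_curve()
  withr::with_seed(22, {
    for (i in 1:100) {
      cc <- sample(c(12.5, 25, 100, 200), 6, replace = TRUE)
      if (length(unique(cc)) < 2) cc[1:2] <- c(12.5, 200)
      b <- runif(1, 0, 1)
      y <- b + runif(1, -0.4, 0.4) + runif(1, -0.002, 0.002) * cc +
        rnorm(6, 0, 0.05)
      sd_v <- runif(6, 0.02, 0.1)
      fit <- fit_interaction(make_wt_fit(b, 0),
                             make_av(cc, y, sd_v), curve)
      ref <- grid_search_line(cc, y - b, sd_v, b_range = c(-1, 1),
                              r_range = c(-0.01, 0.01))
      expect_lt(abs(fit$eps_b - ref$b), 1e-6)
      expect_lt(abs(fit$eps_r - ref$r), 1e-6)
    }
  })
})

test_that("posterior probabilities follow the Gaussian closed form", {
  cc <- c(12.5, 25, 100, 200)
  curve <- identity_curve()
  f <- fit_interaction(make_wt_fit(0.8, 0),
                       make_av(cc, rep(0.8, 4), rep(0.05, 4)), curve)
  expect_equal(f$p_eb_pos, 0.5, tolerance = 1e-6)
  # an estimate at exactly 1.645 standard errors: posterior ~ 0.95
  f2 <- fit_interaction(make_wt_fit(0.8, 0),
                        make_av(cc, rep(0.8, 4) + 1.645 * f$se_eb,
                                rep(0.05, 4)), curve)
  expect_equal(f2$p_eb_pos, pnorm(1.645), tolerance = 1e-6)
  expect_equal(pnorm(1.645), 0.95, tolerance = 5e-4)
})

test_that("interaction classes separate planted effects under FDR", {
  curve <- identity_curve()
  cc <- rep(c(12.5, 25, 100, 200), 2)
  withr::with_seed(23, {
    n_each <- 80
    wt <- make_wt_fit(0.8, 0, variant = sprintf("V%03d", 1:(3 * n_each)))
    av <- purrr::map_dfr(1:(3 * n_each), function(i) {
      mu <- if (i <= n_each) 0.8            # no interaction
      else if (i <= 2 * n_each) 0.5         # eps_b = -0.3
      else 0.8 + 0.002 * cc                 # eps_r only
      make_av(cc, mu + rnorm(8, 0, 0.05), rep(0.05, 8),
              variant = sprintf("V%03d", i))
    })
    cl <- classify_interactions(fit_interaction(wt, av, curve))
    cl <- cl[order(cl$variant), ]
    grp <- rep(c("none", "eb", "er"), each = n_each)
    # null fraction flagged stays at the FDR level (2x Monte Carlo slack)
    expect_lte(mean(cl$interaction_class[grp == "none"] != "none"), 0.1)
    # planted folinate-independent effects are recovered as independent
    expect_gte(mean(cl$interaction_class[grp == "eb"] == "independent"),
               0.9)
    # planted folinate-dependent effects are recovered as dependent, and
    # not mislabeled independent
    expect_gte(mean(cl$interaction_class[grp == "er"] == "dependent"), 0.8)
    expect_lte(mean(cl$interaction_class[grp == "er"] == "independent"),
               0.1)
  })
})

test_that("suppressor detection applies the fit, posterior and threshold rules", {
  curve <- identity_curve()
  cc <- c(12.5, 25, 100, 200)
  thresholds <- tibble::tibble(folinate = cc, threshold = 1.15, n_syn = 50L)

  wt <- make_wt_fit(0.4, 0, variant = c("A1C", "A1D", "A1E"))
  wt$variant <- c("A1C", "A1D", "A1E")
  av <- dplyr::bind_rows(
    make_av(cc, rep(1.4, 4), rep(0.03, 4), variant = "A1C"),      # flat high
    make_av(cc, 1.45 - 0.003 * cc, rep(0.03, 4), variant = "A1D"), # low only
    make_av(cc, rep(0.4, 4), rep(0.03, 4), variant = "A1E")        # none
  )
  ints <- fit_interaction(wt, av, curve)
  sup <- find_suppressors(ints, wt, curve, thresholds)
  sup <- sup[order(sup$variant), ]
  expect_equal(sup$suppressor, c(TRUE, TRUE, FALSE))
  expect_equal(sup$category[1:2], c("independent", "low_folinate"))
  # zero-deviation variants have posterior 1/2 and are never candidates
  expect_equal(sup$p_eb_pos[3], 0.5, tolerance = 1e-6)

  # categories are mutually exclusive over flagged candidates
  expect_true(all(table(sup$variant[sup$suppressor]) == 1))
})

test_that("planted atlas interactions are recovered quantitatively", {
  atlas <- atlas_fixture()
  tr <- atlas$sim$truth[match(atlas$ints$variant,
                              atlas$sim$truth$variant), ]
  ok <- atlas$ints$fit_ok
  expect_gte(cor(atlas$ints$eps_b[ok], tr$gamma_b[ok]), 0.8)
  expect_gte(cor(atlas$ints$eps_r[ok], tr$gamma_r[ok]), 0.8)
})
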