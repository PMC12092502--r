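test_that("t-test Bayes factors reproduce the published worked examples", {
  # one-sample N = 80, default Cauchy r = 1
  expect_equal(bf_ttest(2.03, one_sample(80), cauchy_prior(1))$b10, 0.64,
               tolerance = 0.02)
  # effect-size prior focused on small effects
  expect_equal(bf_ttest(2.24, one_sample(80), es_prior(0.2))$b10, 3.70,
               tolerance = 0.02)
  # moment prior focused on large effects
  expect_equal(bf_ttest(2.03, one_sample(80), moment_prior(0.8))$b10, 0.19,
               tolerance = 0.02)
})

test_that("quadrature matches the Monte-Carlo prior-draw oracle (t tests)", {
  n_draw <- 1e6
  # one-sample, effect-size prior
  pr <- es_prior(0.5)
  mc <- mc_bf(2.1, "t", df = 49, effect_draws = sample_prior(pr, n_draw, 3),
              ncp_of = function(d) sqrt(50) * d)
  expect_mc_agreement(bf_ttest(2.1, one_sample(50), pr)$b10, mc)
  # two-sample, moment prior
  pr2 <- moment_prior(0.5)
  lay <- two_sample(30, 40)
  mc2 <- mc_bf(1.7, "t", df = 68, effect_draws = sample_prior(pr2, n_draw, 4),
               ncp_of = function(d) sqrt(lay$m) * d)
  expect_mc_agreement(bf_ttest(1.7, lay, pr2)$b10, mc2)
  # Cauchy default
  pr3 <- cauchy_prior(1)
  mc3 <- mc_bf(2.5, "t", df = 39, effect_draws = sample_prior(pr3, n_draw, 5),
               ncp_of = function(d) sqrt(40) * d)
  expect_mc_agreement(bf_ttest(2.5, one_sample(40), pr3)$b10, mc3)
})

test_that("the nu = 1, d_e = 0 effect-size path recovers an independently coded Cauchy quadrature", {
  for (cfg in list(c(t = 2.03, n = 80, r = 1), c(t = -1.2, n = 25, r = 0.5),
                   c(t = 0, n = 12, r = 0.707))) {
    tv <- cfg[["t"]]; n <- cfg[["n"]]; r <- cfg[["r"]]
    direct <- integrate(function(d)
      suppressWarnings(exp(dt(tv, n - 1, ncp = sqrt(n) * d, log = TRUE) -
                             dt(tv, n - 1, log = TRUE))) * dcauchy(d, 0, r),
      -Inf, Inf, rel.tol = 1e-12)$value
    via_es <- bf_ttest(tv, one_sample(n), es_prior(0, nu = 1, r = r))$b10
    via_cauchy <- bf_ttest(tv, one_sample(n), cauchy_prior(r))$b10
    expect_equal(via_es, direct, tolerance = 1e-10)
    expect_equal(via_cauchy, direct, tolerance = 1e-10)
  }
})

test_that("linear-model Bayes factors reproduce the published regression table rows", {
  # full-vs-reduced comparisons at N = 175, statistics recovered from
  # partial R^2; the table prints B01 (preference for the reduced model)
  b <- bf_linear(linear_layout(175, 3, 2), lambda2_es_prior(2, sqrt(0.35)),
                 r2p = 0.0136)
  expect_equal(b$b01, 41.07, tolerance = 0.05)
  b2 <- bf_linear(linear_layout(175, 4, 1),
                  lambda2_moment_prior(1, sqrt(0.35)), r2p = 0.0002)
  expect_equal(b2$b01, 218.63, tolerance = 0.05)
})

test_that("quadrature matches the Monte-Carlo oracle (linear models)", {
  n_draw <- 1e6
  lay <- linear_layout(60, 2, 2)
  # the lambda^2 effect-size sampler is construction-based (multivariate t
  # around the Cohen's-f sphere), independent of the hypergeometric density
  pr <- lambda2_es_prior(2, 0.5)
  mc <- mc_bf(2.4, "f", df1 = 2, df2 = lay$m - 2,
              effect_draws = sample_prior(pr, n_draw, 6),
              ncp_of = function(l2) lay$m * l2)
  expect_mc_agreement(bf_linear(lay, pr, f_stat = 2.4)$b10, mc)
  pr2 <- lambda2_moment_prior(2, 0.5)
  mc2 <- mc_bf(2.4, "f", df1 = 2, df2 = lay$m - 2,
               effect_draws = sample_prior(pr2, n_draw, 7),
               ncp_of = function(l2) lay$m * l2)
  expect_mc_agreement(bf_linear(lay, pr2, f_stat = 2.4)$b10, mc2)
})

test_that("the chi-squared worked example and its Monte-Carlo oracle agree", {
  fam <- stat_family("chisq", df = 5, effect_map = function(w2) 100 * w2)
  pr <- wsq_gamma_prior(0.3)
  b <- bf_teststat(12.72, fam, pr)
  expect_equal(b$b10, 5.14, tolerance = 0.005)
  mc <- mc_bf(12.72, "chisq", df = 5,
              effect_draws = sample_prior(pr, 1e6, 8),
              ncp_of = function(w2) 100 * w2)
  expect_mc_agreement(b$b10, mc)
})

test_that("the generic engine reduces to the t-test path and to point masses", {
  pr <- es_prior(0.2)
  fam <- stat_family("t", df = 79, effect_map = function(d) sqrt(80) * d)
  expect_equal(bf_teststat(2.03, fam, pr)$b10,
               bf_ttest(2.03, one_sample(80), pr)$b10, tolerance = 1e-8)
  # near-degenerate prior at xi0: BF -> f(x | xi0) / f(x | 0)
  xi0 <- 0.4
  spike <- function(e) dnorm(e, xi0, 0.005)
  b <- suppressWarnings(bf_teststat(2.03, fam, spike))
  expect_equal(b$b10, exp(log_density_ratio(fam, 2.03, sqrt(80) * xi0)),
               tolerance = 0.01)
  # a non-normalized prior triggers a warning reporting the normalization
  expect_warning(bf_teststat(2.03, fam, function(e) 2 * dnorm(e)),
                 "integrates to 2")
})

test_that("framing invariance: the same hypothesis gives the same Bayes factor in every guise", {
  # (i) one-sample t vs p = 0, q = 1 linear comparison with f = d
  n <- 40; tv <- 2.2; de <- 0.5
  for (mk in list(
    function() list(bf_ttest(tv, one_sample(n), es_prior(de)),
                    bf_linear(linear_layout(n, 0, 1),
                              lambda2_es_prior(1, de), t_stat = tv)),
    function() list(bf_ttest(tv, one_sample(n), moment_prior(de)),
                    bf_linear(linear_layout(n, 0, 1),
                              lambda2_moment_prior(1, de, nu = 5),
                              t_stat = tv)))) {
    pair <- mk()
    expect_equal(pair[[1]]$b10, pair[[2]]$b10, tolerance = 1e-6)
  }
  # (ii) two-sample t vs p = 1, q = 1 linear with d = sqrt((N-1)/M) f
  lay2 <- two_sample(40, 60)
  f <- 0.25
  d <- convert_effect_size(f, "f", "d", lay2)
  k <- d / f
  b_t <- bf_ttest(1.9, lay2, es_prior(d, nu = 3, r = sqrt(1 / 3) * d))
  b_l <- bf_linear(linear_layout(100, 1, 1),
                   lambda2_es_prior(1, f, nu = 3, r = sqrt(1 / 3) * f),
                   t_stat = 1.9)
  expect_equal(b_t$b10, b_l$b10, tolerance = 1e-6)
  b_tm <- bf_ttest(1.9, lay2, moment_prior(d, nu = 5))
  b_lm <- bf_linear(linear_layout(100, 1, 1),
                    lambda2_moment_prior(1, f, nu = 5), t_stat = 1.9)
  expect_equal(b_tm$b10, b_lm$b10, tolerance = 1e-6)
})

test_that("statistic conversions are exact and round-trip", {
  expect_equal(F_from_r2p(0, 100, 2, 1), 0)
  expect_equal(F_from_r2p(0.0136, 175, 3, 2), 1.172, tolerance = 1e-3)
  expect_equal(eta2p_from_F(16.73, 1, 36), 0.32, tolerance = 0.01)
  for (r2 in c(0.01, 0.3, 0.85)) {
    expect_equal(r2p_from_F(F_from_r2p(r2, 50, 3, 2), 50, 3, 2), r2,
                 tolerance = 1e-12)
  }
  for (fv in c(0.3, 4.2)) {
    expect_equal(F_from_eta2p(eta2p_from_F(fv, 2, 30), 2, 30), fv,
                 tolerance = 1e-12)
  }
  expect_error(F_from_r2p(1, 100, 2, 1), "\\[0, 1\\)")

  expect_equal(convert_effect_size(0.5, "d", "f"), 0.5)
  expect_equal(convert_effect_size(0.5, "d", "f2"), 0.25)
  expect_equal(convert_effect_size(1, "f", "d", two_sample(50, 50)),
               sqrt(99 / 25), tolerance = 1e-12)
  d0 <- 0.37
  expect_equal(convert_effect_size(
    convert_effect_size(d0, "d", "f", two_sample(30, 50)),
    "f", "d", two_sample(30, 50)), d0, tolerance = 1e-12)
})

test_that("consistency-in-information thresholds follow the prior family", {
  expect_equal(consistency_threshold("one_sample", "es", nu = 3), 4)
  expect_equal(consistency_threshold("two_sample", "es", nu = 3), 5)
  expect_equal(consistency_threshold("linear", "es", nu = 3, p = 1, q = 1), 5)
  expect_equal(consistency_threshold("one_sample", "moment", nu = 5), 4)
  expect_equal(consistency_threshold("two_sample", "moment", nu = 5), 5)
  expect_equal(consistency_threshold("linear", "moment", nu = 5, p = 2,
                                     q = 1), 6)
})

test_that("above the threshold B10 is increasing and unbounded in t", {
  grid <- c(2, 5, 10, 20, 40, 70, 100)
  for (pr in list(es_prior(0.5), moment_prior(0.5), cauchy_prior(1))) {
    b <- vapply(grid, function(tv) bf_ttest(tv, one_sample(50), pr)$b10, 0)
    expect_true(all(diff(b) > 0))
    expect_gt(b[length(b)], 1e6)
  }
  # at the minimal N the Bayes factor still increases (slowly)
  b_edge <- vapply(grid, function(tv)
    bf_ttest(tv, one_sample(4), es_prior(0.5))$b10, 0)
  expect_true(all(diff(b_edge) > 0))
  # below the threshold a note flags the bounded regime
  res <- bf_ttest(2, one_sample(3), es_prior(0.5))
  expect_match(res$notes, "consistency")
})

test_that("results keep their internal invariants and inputs are validated", {
  r <- bf_ttest(2.03, one_sample(80), es_prior(0.2))
  expect_equal(r$b10 * r$b01, 1, tolerance = 1e-14)
  expect_lt(r$abs_error_estimate / r$b10, 1e-6)
  expect_equal(r$log10_b10, log10(r$b10))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$b10, r$b10)

  expect_error(bf_ttest(Inf, one_sample(80), es_prior(0.2)), "finite")
  expect_error(bf_ttest(NaN, one_sample(80), es_prior(0.2)), "finite")
  expect_error(bf_ttest(2, one_sample(80), lambda2_es_prior(1, 0.3)),
               "prior")
  expect_error(bf_linear(linear_layout(175, 3, 2),
                         lambda2_es_prior(1, 0.3), f_stat = 2), "q = ")
  expect_error(bf_linear(linear_layout(175, 3, 2),
                         lambda2_es_prior(2, 0.3)), "exactly one")
  expect_error(bf_linear(linear_layout(175, 3, 2), lambda2_es_prior(2, 0.3),
                         f_stat = 1, r2p = 0.1), "exactly one")
  # t = 0 is a valid input
  expect_gt(bf_ttest(0, one_sample(20), es_prior(0.5))$b10, 0)
})
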