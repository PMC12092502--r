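# Independent oracles used across the suite.

# Monte-Carlo Bayes factor: average the noncentral/central density ratio
# over prior draws.  Shares nothing with the quadrature engine beyond the
# density functions of base R.
mc_bf <- function(x, kind, df, df1 = NULL, df2 = NULL, effect_draws,
                  ncp_of, seed_unused = NULL) {
  ncp <- ncp_of(effect_draws)
  lr <- switch(kind,
    t = suppressWarnings(dt(x, df, ncp = ncp, log = TRUE) -
                           dt(x, df, log = TRUE)),
    f = suppressWarnings(stats::df(x, df1, df2, ncp = ncp, log = TRUE) -
                           stats::df(x, df1, df2, log = TRUE)),
    chisq = suppressWarnings(dchisq(x, df, ncp = ncp, log = TRUE) -
                               dchisq(x, df, log = TRUE)))
  r <- exp(lr)
  r[!is.finite(r)] <- 0
  list(mean = mean(r), se = sd(r) / sqrt(length(r)))
}

expect_mc_agreement <- function(bf_value, mc, n_se = 3) {
  expect_lt(abs(bf_value - mc$mean), n_se * mc$se)
}

# quadrature CDF of a prior, independent of the closed forms used in the
# package (plain stats::integrate of the density)
quad_cdf <- function(prior, q, lower = -Inf) {
  integrate(function(x) prior_density(prior, x), lower, q,
            rel.tol = 1e-10)$value
}
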