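## Design evaluation: Bayes factors from significance-test outcomes,
## required-t curves, expected Bayes-factor-ratio curves, and a raw-data
## fixture generator for end-to-end and framing-invariance checks.

#' Bayes factor implied by a significance-test outcome
#'
#' If all that is retained from the data is whether a Neyman-Pearson test at
#' level `alpha` with power `1 - beta` was significant, then a significant
#' outcome carries a Bayes factor of \eqn{(1-\beta)/\alpha} for the
#' alternative and a nonsignificant one \eqn{\beta/(1-\alpha)}.  When the
#' alternative is a prior `f` over effect sizes rather than a point, the
#' power is averaged over the prior: \eqn{B_{10} = \int \Phi(\theta) f(\theta)
#' d\theta / \alpha} (significant), with `power` then a power *function*
#' \eqn{\Phi}.
#'
#' @param alpha Type-I error rate, strictly inside (0, 1).
#' @param power Scalar power `1 - beta`, or a power function of the effect
#'   size when `prior` is given.
#' @param outcome `"significant"` or `"nonsignificant"`.
#' @param prior Optional effect-size prior object (or density function on
#'   the real line).
#' @return A `bf_result`.
#' @examples
#' significance_outcome_bf(0.05, 0.80)$b10                      # 16
#' significance_outcome_bf(0.05, 0.80, "nonsignificant")$b01    # 4.75
#' @export
significance_outcome_bf <- function(alpha, power,
                                    outcome = c("significant",
                                                "nonsignificant"),
                                    prior = NULL) {
  outcome <- match.arg(outcome)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  err <- 0
  if (is.null(prior)) {
    if (!is.numeric(power) || length(power) != 1 || power < 0 || power > 1)
      stop("scalar `power` must lie in [0, 1]", call. = FALSE)
    avg_power <- power
  } else {
    if (!is.function(power))
      stop("with a prior, `power` must be a power function of the effect ",
           "size", call. = FALSE)
    dens <- if (inherits(prior, "bf_prior"))
      function(e) prior_density(prior, e) else prior
    lims <- if (inherits(prior, "bf_prior") && prior$support == "positive")
      c(0, Inf) else c(-Inf, Inf)
    brk <- if (inherits(prior, "bf_prior")) prior_breaks(prior) else numeric()
    res <- quad_panels(function(e) power(e) * dens(e), lims[1], lims[2],
                       breaks = brk, rel_tol = 1e-9)
    avg_power <- res$value
    err <- res$abs_error
  }
  b10 <- if (outcome == "significant") avg_power / alpha
         else (1 - avg_power) / (1 - alpha)
  new_bf_result(b10, err / if (outcome == "significant") alpha else 1 - alpha,
                method = "significance_outcome",
                settings = list(alpha = alpha, outcome = outcome))
}

#' t value required to reach a target Bayes factor
#'
#' Finds the nonnegative t with `bf_ttest(t, layout, prior)$b10 ==
#' target_bf`, by bracketing and root solving on the monotone region
#' `t >= 0`.
#'
#' @param layout A [one_sample()] or [two_sample()] layout.
#' @param prior A prior accepted by [bf_ttest()].
#' @param target_bf Target \eqn{B_{10}} (> value at t = 0).
#' @param t_max Upper limit for the bracket search.
#' @return The required t value.
#' @examples
#' t10 <- t_for_target_bf(one_sample(100), es_prior(0.5), 10)
#' bf_ttest(t10, one_sample(100), es_prior(0.5))$b10        # ~= 10
#' @export
t_for_target_bf <- function(layout, prior, target_bf, t_max = 1000) {
  if (!is.numeric(target_bf) || length(target_bf) != 1 || target_bf <= 0)
    stop("`target_bf` must be a single positive number", call. = FALSE)
  bf_at <- function(t) bf_ttest(t, layout, prior, rel_tol = 1e-9)$b10
  b0 <- bf_at(0)
  if (target_bf <= b0)
    stop("target B10 (", format(target_bf), ") is not above the value at ",
         "t = 0 (", format(b0, digits = 4), "); no nonnegative root exists",
         call. = FALSE)
  hi <- 5
  while (bf_at(hi) < target_bf && hi < t_max) hi <- hi * 2
  if (bf_at(hi) < target_bf)
    stop("target B10 not attained by t = ", hi, "; the sample size may be ",
         "below the consistency-in-information threshold", call. = FALSE)
  stats::uniroot(function(t) bf_at(t) - target_bf, c(0, hi),
                 tol = 1e-8)$root
}

#' Expected ratio of two Bayes factors over the sampling distribution of t
#'
#' For a one- or two-sample t design with true standardized effect
#' `true_effect`, computes \eqn{E[\mathrm{BF}_a(T)/\mathrm{BF}_b(T)]} where
#' `T` follows the noncentral t distribution implied by the layout
#' (noncentrality `sqrt(N) d` or `sqrt(M) d`; set `true_effect = 0` for the
#' behaviour under the null).  `mode = "b01"` compares the evidence for the
#' null instead, i.e. the ratio of the reciprocal Bayes factors.
#'
#' @param true_effect True Cohen's d generating the data.
#' @param layout A [one_sample()] or [two_sample()] layout.
#' @param prior_a,prior_b Priors accepted by [bf_ttest()].
#' @param mode `"b10"` or `"b01"`.
#' @param average `"arithmetic"` (the expectation of the ratio) or
#'   `"geometric"` (`exp(E[log ratio])`).
#' @param rel_tol Quadrature tolerance for the outer integral.
#' @return The expected ratio (scalar).
#' @export
expected_bf_ratio <- function(true_effect, layout, prior_a, prior_b,
                              mode = c("b10", "b01"),
                              average = c("arithmetic", "geometric"),
                              rel_tol = 1e-6) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  fam <- family_for_layout(layout)
  ncp <- fam$effect_map(true_effect)
  log_ratio <- function(t) {
    vapply(t, function(ti) {
      la <- log(bf_ttest(ti, layout, prior_a, rel_tol = 1e-8)$b10)
      lb <- log(bf_ttest(ti, layout, prior_b, rel_tol = 1e-8)$b10)
      if (mode == "b10") la - lb else lb - la
    }, 0)
  }
  integrand <- function(t) {
    w <- exp(log_density(fam, t, ncp))
    lr <- log_ratio(t)
    if (average == "arithmetic") w * exp(lr) else w * lr
  }
  ## truncate where the sampling density of t has dropped ~35 log units
  ## below its peak (the Bayes-factor ratio grows at most polynomially)
  half <- max(10, 2 * abs(stats::qt(1e-13, fam$df)))
  probe <- seq(ncp - half, ncp + half, length.out = 321L)
  lw <- log_density(fam, probe, ncp)
  keep <- which(lw > max(lw) - 35)
  lo <- probe[max(1, min(keep) - 1)]
  hi <- probe[min(length(probe), max(keep) + 1)]
  res <- quad_panels(integrand, lo, hi,
                     breaks = ncp + c(-6, -2, 0, 2, 6), rel_tol = rel_tol)
  if (average == "arithmetic") res$value else exp(res$value)
}

## ---- raw-data fixtures ------------------------------------------------------

#' Describe a synthetic-data design
#'
#' Designs for the fixture generator: `"one_sample"` (n observations with
#' true standardized effect d), `"two_sample"` (n1/n2 observations, group
#' mean difference `sigma * d`), or `"linear"` (design matrices `X1`
#' (retained) and `X2` (tested), coefficients and residual SD; the true
#' multivariate effect is \eqn{f^2 = \mu^t \Omega \mu} with
#' \eqn{\mu = \beta_2/\sigma},
#' \eqn{\Omega = X_2^t(I - X_1(X_1^tX_1)^{-1}X_1^t)X_2 / (N - p)}).
#'
#' @param kind `"one_sample"`, `"two_sample"` or `"linear"`.
#' @param n,n1,n2 Sample sizes.
#' @param d True standardized effect (t designs).
#' @param sigma Residual/observation standard deviation.
#' @param X1 Retained design matrix (may have zero columns for `p = 0`).
#' @param X2 Tested design matrix.
#' @param beta1,beta2 True coefficients of the retained/tested blocks.
#' @return A `fixture_design` object.
#' @export
fixture_design <- function(kind = c("one_sample", "two_sample", "linear"),
                           n = NULL, n1 = NULL, n2 = NULL, d = 0, sigma = 1,
                           X1 = NULL, X2 = NULL, beta1 = NULL, beta2 = NULL) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  des <- switch(kind,
    one_sample = {
      check_count(n, "n", min = 2)
      list(kind = kind, n = n, d = d, sigma = sigma)
    },
    two_sample = {
      check_count(n1, "n1"); check_count(n2, "n2")
      list(kind = kind, n1 = n1, n2 = n2, d = d, sigma = sigma)
    },
    linear = {
      X2 <- as.matrix(X2)
      n <- nrow(X2)
      if (is.null(X1)) X1 <- matrix(numeric(0), n, 0) else X1 <- as.matrix(X1)
      p <- ncol(X1); q <- ncol(X2)
      if (nrow(X1) != n) stop("X1 and X2 need equal row counts", call. = FALSE)
      if (is.null(beta1)) beta1 <- rep(0, p)
      if (is.null(beta2)) beta2 <- rep(0, q)
      if (length(beta1) != p || length(beta2) != q)
        stop("coefficient lengths must match the design matrices",
             call. = FALSE)
      if (n <= p + q)
        stop("need more observations than coefficients (zero residual ",
             "degrees of freedom otherwise)", call. = FALSE)
      list(kind = kind, n = n, p = p, q = q, X1 = X1, X2 = X2,
           beta1 = beta1, beta2 = beta2, sigma = sigma)
    })
  structure(des, class = "fixture_design")
}

## residual-maker projection of y on the columns of X
proj_resid <- function(X, y) {
  if (ncol(X) == 0) return(y)
  y - X %*% solve(crossprod(X), crossprod(X, y))
}

#' Simulate raw data for a design and compute its test statistics
#'
#' Generates normal data under the design's true parameters, computes the
#' usual least-squares statistics (t, or F with partial R-squared and
#' partial eta-squared), and reports the true effect size on the relevant
#' scale.  Statistics are scale invariant: multiplying the data by any
#' nonzero constant leaves t, F and hence every Bayes factor unchanged.
#'
#' @param design A [fixture_design()].
#' @param seed Integer seed for reproducibility.
#' @return A list with `data` (data frame), `statistics` (named list),
#'   `truth` (true effect sizes) and `layout` (the matching layout object).
#' @examples
#' fx <- simulate_fixture(fixture_design("one_sample", n = 20, d = 0.5), 1)
#' fx$statistics$t
#' @export
simulate_fixture <- function(design, seed = NULL) {
  stopifnot(inherits(design, "fixture_design"))
  with_seed(seed, {
    if (design$kind == "one_sample") {
      y <- stats::rnorm(design$n, mean = design$sigma * design$d,
                        sd = design$sigma)
      fixture_stats_one(y, design)
    } else if (design$kind == "two_sample") {
      x <- stats::rnorm(design$n1, mean = -design$sigma * design$d / 2,
                        sd = design$sigma)
      y <- stats::rnorm(design$n2, mean = design$sigma * design$d / 2,
                        sd = design$sigma)
      fixture_stats_two(x, y, design)
    } else {
      mu <- drop(design$X1 %*% design$beta1 + design$X2 %*% design$beta2)
      y <- stats::rnorm(design$n, mean = mu, sd = design$sigma)
      fixture_stats_linear(y, design)
    }
  })
}

#' Compute fixture statistics from raw vectors
#'
#' The deterministic half of [simulate_fixture()]: given raw data laid out
#' per the design, compute the statistics.  Exposed so that externally
#' supplied vectors (e.g. read from CSV) run through the same code path.
#'
#' @param design A [fixture_design()].
#' @param y Response vector (one-sample/linear) or second group.
#' @param x First group (two-sample only).
#' @return As [simulate_fixture()].
#' @export
fixture_statistics <- function(design, y, x = NULL) {
  stopifnot(inherits(design, "fixture_design"))
  switch(design$kind,
         one_sample = fixture_stats_one(y, design),
         two_sample = fixture_stats_two(x, y, design),
         linear = fixture_stats_linear(y, design))
}

fixture_stats_one <- function(y, design) {
  n <- length(y)
  s <- stats::sd(y)
  if (s == 0) stop("zero residual variance: the t statistic is undefined",
                   call. = FALSE)
  t <- mean(y) / (s / sqrt(n))
  list(data = data.frame(y = y),
       statistics = list(t = t, df = n - 1),
       truth = list(d = design$d),
       layout = one_sample(n))
}

fixture_stats_two <- function(x, y, design) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n - 2)
  if (sp2 == 0) stop("zero residual variance: the t statistic is undefined",
                     call. = FALSE)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(data = data.frame(group = rep(c(1, 2), c(n1, n2)), y = c(x, y)),
       statistics = list(t = t, df = n - 2),
       truth = list(d = design$d),
       layout = two_sample(n1, n2))
}

fixture_stats_linear <- function(y, design) {
  X1 <- design$X1; X2 <- design$X2
  n <- design$n; p <- design$p; q <- design$q
  X <- cbind(X1, X2)
  rss0 <- sum(proj_resid(X1, y)^2)
  rss1 <- sum(proj_resid(X, y)^2)
  if (rss1 <= 0)
    stop("zero residual variance under the full model", call. = FALSE)
  f_stat <- ((rss0 - rss1) / q) / (rss1 / (n - p - q))
  r2p <- (rss0 - rss1) / rss0
  ## true multivariate effect: f^2 = mu^t Omega mu
  Sigma <- crossprod(proj_resid(X1, X2))
  Omega <- Sigma / (n - p)
  mu <- design$beta2 / design$sigma
  f2 <- drop(t(mu) %*% Omega %*% mu)
  list(data = data.frame(y = y, X),
       statistics = list(f_stat = f_stat, df1 = q, df2 = n - p - q,
                         r2p = r2p,
                         eta2p = eta2p_from_F(f_stat, q, n - p - q)),
       truth = list(f2 = f2, f = sqrt(f2)),
       layout = linear_layout(n, p, q))
}

#' Write a fixture to disk
#'
#' Data go to `<stem>.csv` (one column per variable) and the true
#' parameters plus computed statistics to a `<stem>.json` sidecar.
#'
#' @param fixture Result of [simulate_fixture()].
#' @param stem Path stem (without extension).
#' @return `stem`, invisibly.
#' @export
fixture_write <- function(fixture, stem) {
  utils::write.csv(fixture$data, paste0(stem, ".csv"), row.names = FALSE)
  side <- list(statistics = fixture$statistics, truth = fixture$truth,
               layout = unclass(fixture$layout))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}
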