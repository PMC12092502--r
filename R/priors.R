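#' @importFrom stats dt pt rt dcauchy pcauchy rcauchy dgamma pgamma rgamma
#'   df pf rf dchisq rchisq integrate rnorm runif optimize uniroot setNames
NULL

## ---- shifted / scaled t helpers -------------------------------------------

dt_scaled <- function(x, df, mean = 0, scale = 1, log = FALSE) {
  out <- stats::dt((x - mean) / scale, df = df, log = log)
  if (log) out - log(scale) else out / scale
}

pt_scaled <- function(q, df, mean = 0, scale = 1) {
  stats::pt((q - mean) / scale, df = df)
}

## run an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_prior <- function(subclass, fields, support) {
  structure(c(fields, list(support = support)),
            class = c(subclass, "bf_prior"))
}

#' Effect-size prior on a standardized effect
#'
#' An equal-weight mixture of two scaled and shifted t distributions centered
#' at `-effect_size` and `+effect_size` (Cohen's d scale).  With the
#' recommended scale `r = sqrt((nu - 2)/nu) * effect_size` the spread between
#' the two mixture components and the spread within each component contribute
#' equally to the total prior variance `nu/(nu - 2) * r^2 + effect_size^2`.
#'
#' `effect_size = 0` with `nu = 1` recovers the scaled-Cauchy (JZS) default
#' prior with scale `r`.
#'
#' @param effect_size Prespecified effect size \eqn{d_e \ge 0} (Cohen's d).
#' @param nu Degrees of freedom of each t component (integer \eqn{\ge 1}).
#' @param r Scale factor of each component (> 0).  `NULL` fills in the
#'   recommended value `sqrt((nu - 2)/nu) * effect_size` (requires `nu > 2`).
#' @return An object of class `es_prior`.
#' @examples
#' p <- es_prior(0.5)
#' interval_mass(p, -0.5, 0.5)
#' @export
es_prior <- function(effect_size, nu = 3, r = NULL) {
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0)
    stop("`effect_size` must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1 || nu < 1 || nu != round(nu))
    stop("`nu` must be a positive integer", call. = FALSE)
  if (is.null(r)) {
    if (nu <= 2)
      stop("the recommended scale r = sqrt((nu-2)/nu)*d_e needs nu > 2; ",
           "supply `r` explicitly", call. = FALSE)
    r <- sqrt((nu - 2) / nu) * effect_size
  }
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  new_prior("es_prior",
            list(effect_size = effect_size, nu = nu, r = r),
            support = "real")
}

#' Moment prior on a standardized effect
#'
#' A nonlocal prior: the scaled t density multiplied by \eqn{d^2} and
#' renormalized, so the density is exactly zero at the null value and the two
#' modes sit exactly at `-effect_size` and `+effect_size`.  The component
#' scale is fixed by the mode constraint at
#' `c = sqrt((nu - 1) * effect_size^2 / (2 * nu))`.
#'
#' @param effect_size Prespecified effect size \eqn{d_e > 0} (Cohen's d).
#' @param nu Degrees of freedom (integer \eqn{\ge 3}; the quadratic weight
#'   needs two extra moments of the t kernel to normalize).
#' @return An object of class `moment_prior`.
#' @examples
#' prior_density(moment_prior(0.5), 0) # exactly zero
#' @export
moment_prior <- function(effect_size, nu = 5) {
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size <= 0)
    stop("`effect_size` must be a single positive number for moment priors",
         call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1 || nu < 3 || nu != round(nu))
    stop("`nu` must be an integer >= 3 for moment priors", call. = FALSE)
  new_prior("moment_prior",
            list(effect_size = effect_size, nu = nu,
                 scale = sqrt((nu - 1) * effect_size^2 / (2 * nu))),
            support = "real")
}

#' Scaled Cauchy (JZS default) prior
#'
#' The default prior on the standardized effect: a Cauchy distribution with
#' scale `r`.  Equivalent to [es_prior()] with `nu = 1`, `effect_size = 0`.
#' The median absolute effect equals `r`.
#'
#' @param r Scale factor (> 0).
#' @return An object of class `cauchy_prior`.
#' @export
cauchy_prior <- function(r = 1) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  new_prior("cauchy_prior", list(r = r), support = "real")
}

#' Induced effect-size prior on the squared multivariate effect
#'
#' The prior on \eqn{\lambda^2}, the squared multivariate standardized effect
#' in a regression/ANOVA model comparison testing `q` coefficients, induced by
#' a multivariate t prior on the standardized coefficients focused uniformly
#' on the ellipsoid of Cohen's f equal to `effect_size`.  Its density involves
#' the Gauss hypergeometric function.
#'
#' @param q Number of tested coefficients (integer \eqn{\ge 1}).
#' @param effect_size Prespecified Cohen's f (\eqn{\ge 0}).
#' @param nu Degrees of freedom of the t kernel.
#' @param r Scale; `NULL` fills in the recommended
#'   `sqrt((nu - 2)/(nu * q)) * effect_size`.
#' @return An object of class `lambda2_es_prior`.
#' @export
lambda2_es_prior <- function(q, effect_size, nu = 3, r = NULL) {
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("`q` must be a positive integer", call. = FALSE)
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0)
    stop("`effect_size` (Cohen's f) must be a single nonnegative number",
         call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1 || nu < 1)
    stop("`nu` must be >= 1", call. = FALSE)
  if (is.null(r)) {
    if (nu <= 2)
      stop("the recommended scale needs nu > 2; supply `r` explicitly",
           call. = FALSE)
    r <- sqrt((nu - 2) / (nu * q)) * effect_size
  }
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  new_prior("lambda2_es_prior",
            list(q = q, effect_size = effect_size, nu = nu, r = r),
            support = "positive")
}

#' Induced moment prior on the squared multivariate effect
#'
#' The prior on \eqn{\lambda^2} induced by the multivariate moment prior on
#' standardized coefficients in a regression/ANOVA comparison of `q` tested
#' coefficients.  After rescaling it is a beta-prime (scaled F) distribution,
#' which normalizes exactly.
#'
#' @param q Number of tested coefficients (integer \eqn{\ge 1}).
#' @param effect_size Prespecified Cohen's f (> 0).
#' @param nu Degrees of freedom (> 2); defaults to the recommended
#'   `5 + (q - 1)`.
#' @return An object of class `lambda2_moment_prior`.
#' @export
lambda2_moment_prior <- function(q, effect_size, nu = 5 + (q - 1)) {
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("`q` must be a positive integer", call. = FALSE)
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size <= 0)
    stop("`effect_size` (Cohen's f) must be a single positive number",
         call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1 || nu <= 2)
    stop("`nu` must be > 2 for moment priors", call. = FALSE)
  new_prior("lambda2_moment_prior",
            list(q = q, effect_size = effect_size, nu = nu,
                 rate = 2 / ((q + nu - 2) * effect_size^2)),
            support = "positive")
}

#' Gamma prior on squared Cohen's w
#'
#' A Gamma (shape-rate) prior on \eqn{w^2} for chi-squared model comparisons.
#' With the default `rate = (2 * shape - 1) / (2 * effect_size^2)` the induced
#' density of \eqn{w} has its mode exactly at `effect_size` (analytically:
#' the induced density is proportional to
#' \eqn{w^{2\,\mathrm{shape}-1} e^{-\mathrm{rate}\, w^2}}, so the squared mode
#' is \eqn{(2\,\mathrm{shape}-1)/(2\,\mathrm{rate})}) and, at `shape = 6.6`,
#' a standard deviation of about `0.2 * effect_size`.  Supply `rate` to use
#' any other calibration.
#'
#' @param effect_size Prespecified Cohen's w (> 0).
#' @param shape Gamma shape (> 0.5 so the induced w density is unimodal away
#'   from zero).
#' @param rate Gamma rate; defaults to `(2 * shape - 1) / (2 * effect_size^2)`.
#' @return An object of class `wsq_gamma_prior`.
#' @export
wsq_gamma_prior <- function(effect_size, shape = 6.6,
                            rate = (2 * shape - 1) / (2 * effect_size^2)) {
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size <= 0)
    stop("`effect_size` (Cohen's w) must be a single positive number",
         call. = FALSE)
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0.5)
    stop("`shape` must be > 0.5", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  new_prior("wsq_gamma_prior",
            list(effect_size = effect_size, shape = shape, rate = rate),
            support = "positive")
}

## ---- generics --------------------------------------------------------------

#' Prior density
#'
#' Evaluate the density of a prior at `x` (an effect-size value for priors on
#' the real line, a \eqn{\lambda^2} or \eqn{w^2} value for priors on the
#' positive half-line).
#'
#' @param prior A prior object (see [es_prior()] and friends).
#' @param x Numeric vector of evaluation points.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @export
prior_density <- function(prior, x, log = FALSE) UseMethod("prior_density")

#' Probability mass of an interval under a prior
#'
#' @param prior A prior object.
#' @param lower,upper Interval endpoints (`lower <= upper`); infinite
#'   endpoints are allowed.
#' @return The probability of `[lower, upper]`.
#' @export
interval_mass <- function(prior, lower, upper) {
  if (any(lower > upper))
    stop("`lower` must not exceed `upper`", call. = FALSE)
  UseMethod("interval_mass")
}

#' Two-sided tail mass of a prior
#'
#' Probability of an absolute effect exceeding `threshold`:
#' `P(|X| > threshold)` for priors on the real line, `P(X > threshold)` for
#' priors on the positive half-line.
#'
#' @param prior A prior object.
#' @param threshold Nonnegative threshold.
#' @return A probability.
#' @export
tail_mass <- function(prior, threshold) {
  if (any(threshold < 0))
    stop("`threshold` must be nonnegative", call. = FALSE)
  UseMethod("tail_mass")
}

#' Draw samples from a prior
#'
#' @param prior A prior object.
#' @param n Number of draws (\eqn{\ge 1}).
#' @param seed Optional integer; when given, draws are reproducible and the
#'   caller's RNG state is left untouched.
#' @return Numeric vector of `n` draws.
#' @export
sample_prior <- function(prior, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a positive count", call. = FALSE)
  UseMethod("sample_prior")
}

prior_cdf <- function(prior, q) UseMethod("prior_cdf")

## ---- effect-size prior methods --------------------------------------------

#' @export
prior_density.es_prior <- function(prior, x, log = FALSE) {
  d <- 0.5 * (dt_scaled(x, prior$nu, -prior$effect_size, prior$r) +
              dt_scaled(x, prior$nu,  prior$effect_size, prior$r))
  if (log) log(d) else d
}

#' @export
prior_cdf.es_prior <- function(prior, q) {
  0.5 * (pt_scaled(q, prior$nu, -prior$effect_size, prior$r) +
         pt_scaled(q, prior$nu,  prior$effect_size, prior$r))
}

#' @export
sample_prior.es_prior <- function(prior, n, seed = NULL) {
  with_seed(seed, {
    center <- sample(c(-1, 1), n, replace = TRUE) * prior$effect_size
    center + prior$r * stats::rt(n, prior$nu)
  })
}

## ---- moment prior methods --------------------------------------------------

#' @export
prior_density.moment_prior <- function(prior, x, log = FALSE) {
  nu <- prior$nu
  ld <- log(2 * (nu - 2) / (nu - 1)) + 2 * log(abs(x)) -
    2 * log(prior$effect_size) +
    dt_scaled(x, nu, 0, prior$scale, log = TRUE)
  ld[x == 0] <- -Inf
  if (log) ld else exp(ld)
}

## |X|^2 = (3 nu c^2 / (nu - 2)) * F(3, nu - 2): the d^2-weighted t kernel
## is a chi(3)/chi(nu-2) scale mixture, which gives an exact CDF via pf().
#' @export
prior_cdf.moment_prior <- function(prior, q) {
  k <- 3 * prior$nu * prior$scale^2 / (prior$nu - 2)
  half <- stats::pf(q^2 / k, 3, prior$nu - 2)
  ifelse(q >= 0, 0.5 + 0.5 * half, 0.5 - 0.5 * half)
}

#' @export
sample_prior.moment_prior <- function(prior, n, seed = NULL) {
  k <- 3 * prior$nu * prior$scale^2 / (prior$nu - 2)
  with_seed(seed, {
    sample(c(-1, 1), n, replace = TRUE) * sqrt(k * stats::rf(n, 3, prior$nu - 2))
  })
}

## ---- Cauchy prior methods --------------------------------------------------

#' @export
prior_density.cauchy_prior <- function(prior, x, log = FALSE) {
  stats::dcauchy(x, 0, prior$r, log = log)
}

#' @export
prior_cdf.cauchy_prior <- function(prior, q) stats::pcauchy(q, 0, prior$r)

#' @export
sample_prior.cauchy_prior <- function(prior, n, seed = NULL) {
  with_seed(seed, stats::rcauchy(n, 0, prior$r))
}

## ---- lambda^2 effect-size prior methods ------------------------------------

#' @export
prior_density.lambda2_es_prior <- function(prior, x, log = FALSE) {
  q <- prior$q; nu <- prior$nu; r <- prior$r; f <- prior$effect_size
  out <- rep(-Inf, length(x))
  pos <- which(x > 0)
  if (length(pos)) {
    l2 <- x[pos]
    a <- l2 + f^2 + nu * r^2
    z <- 4 * f^2 * l2 / a^2
    lh <- vapply(z, function(zz)
      log_gauss_2F1((nu + q) / 4, (2 + nu + q) / 4, q / 2, zz), 0)
    out[pos] <- lgamma((nu + q) / 2) - lgamma(nu / 2) - lgamma(q / 2) +
      (nu / 2) * log(nu * r^2) + (q / 2 - 1) * log(l2) -
      ((nu + q) / 2) * log(a) + lh
  }
  if (log) out else exp(out)
}

#' @export
prior_cdf.lambda2_es_prior <- function(prior, q) {
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    stats::integrate(function(u) prior_density(prior, u), 0, qq,
                     rel.tol = 1e-9, stop.on.error = FALSE)$value
  }, 0)
}

## Construction-based sampler: standardized coefficients are multivariate t
## around a uniformly random point on the Cohen's-f sphere; lambda^2 is the
## squared norm.  Independent of the hypergeometric density formula.
#' @export
sample_prior.lambda2_es_prior <- function(prior, n, seed = NULL) {
  q <- prior$q; nu <- prior$nu; r <- prior$r; f <- prior$effect_size
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * q), n, q)
    dir <- z / sqrt(rowSums(z^2))
    w <- stats::rchisq(n, nu)
    t_noise <- matrix(stats::rnorm(n * q), n, q) * sqrt(nu / w)
    u <- f * dir + r * t_noise
    rowSums(u^2)
  })
}

## ---- lambda^2 moment prior methods -----------------------------------------

#' @export
prior_density.lambda2_moment_prior <- function(prior, x, log = FALSE) {
  q <- prior$q; nu <- prior$nu; s <- prior$rate; f <- prior$effect_size
  out <- rep(-Inf, length(x))
  pos <- which(x > 0)
  if (length(pos)) {
    l2 <- x[pos]
    out[pos] <- log(2 * (nu - 2) / (q * (nu + q - 2) * f^2)) +
      lgamma((nu + q) / 2) - lgamma(nu / 2) - lgamma(q / 2) +
      (q / 2) * log(s * l2) - ((nu + q) / 2) * log1p(s * l2)
  }
  if (log) out else exp(out)
}

## s * lambda^2 is beta-prime(q/2 + 1, (nu-2)/2) = ((q+2)/(nu-2)) F(q+2, nu-2)
#' @export
prior_cdf.lambda2_moment_prior <- function(prior, q) {
  s <- prior$rate
  k <- (prior$q + 2) / (prior$nu - 2)
  ifelse(q <= 0, 0, stats::pf(s * q / k, prior$q + 2, prior$nu - 2))
}

#' @export
sample_prior.lambda2_moment_prior <- function(prior, n, seed = NULL) {
  s <- prior$rate
  k <- (prior$q + 2) / (prior$nu - 2)
  with_seed(seed, (k / s) * stats::rf(n, prior$q + 2, prior$nu - 2))
}

## ---- w^2 Gamma prior methods -----------------------------------------------

#' @export
prior_density.wsq_gamma_prior <- function(prior, x, log = FALSE) {
  stats::dgamma(x, shape = prior$shape, rate = prior$rate, log = log)
}

#' @export
prior_cdf.wsq_gamma_prior <- function(prior, q) {
  stats::pgamma(q, shape = prior$shape, rate = prior$rate)
}

#' @export
sample_prior.wsq_gamma_prior <- function(prior, n, seed = NULL) {
  with_seed(seed, stats::rgamma(n, shape = prior$shape, rate = prior$rate))
}

## ---- shared mass methods ----------------------------------------------------

#' @export
interval_mass.bf_prior <- function(prior, lower, upper) {
  lo <- if (prior$support == "positive") pmax(lower, 0) else lower
  cdf_hi <- ifelse(is.infinite(upper) & upper > 0, 1, prior_cdf(prior, upper))
  cdf_lo <- ifelse(is.infinite(lo) & lo < 0, 0, prior_cdf(prior, lo))
  pmin(pmax(cdf_hi - cdf_lo, 0), 1)
}

#' @export
tail_mass.bf_prior <- function(prior, threshold) {
  if (prior$support == "real") {
    ## symmetric about 0
    2 * (1 - prior_cdf(prior, threshold))
  } else {
    1 - prior_cdf(prior, threshold)
  }
}

#' @export
print.bf_prior <- function(x, ...) {
  pars <- x[!names(x) %in% "support"]
  cat(class(x)[1], ": ",
      paste(names(pars), vapply(pars, function(v) format(v, digits = 4), ""),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

## ---- recommended hyperparameters -------------------------------------------

#' Recommended prior degrees of freedom and scale
#'
#' Default hyperparameters for the effect-size and moment prior families.
#' Effect-size priors: `nu = 3` with `r = sqrt((nu - 2)/nu) * d_e` for t
#' tests and `r = sqrt((nu - 2)/(nu q)) * f` for regression/ANOVA, so that
#' the between-mode and within-component contributions to the prior variance
#' are equal.  Moment priors: `nu = 5` for t tests and `nu = 5 + (q - 1)` for
#' regression/ANOVA, counteracting the heavier tails induced by the quadratic
#' weight as the number of tested coefficients `q` grows.
#'
#' @param family `"es"` or `"moment"`.
#' @param effect_size Prespecified effect size (d for t tests, Cohen's f for
#'   linear-model comparisons); must be positive.
#' @param q Number of tested coefficients (linear comparisons only).
#' @param test_kind `"t"` or `"linear"`.
#' @return A list with elements `nu` and (for the effect-size family) `r`.
#' @examples
#' recommend_hyperparameters("es", 0.3)           # nu 3, r ~= 0.173
#' recommend_hyperparameters("moment", 0.25, q = 4, test_kind = "linear")
#' @export
recommend_hyperparameters <- function(family = c("es", "moment"),
                                      effect_size, q = 1,
                                      test_kind = c("t", "linear")) {
  family <- match.arg(family)
  test_kind <- match.arg(test_kind)
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size <= 0)
    stop("`effect_size` must be a single positive number", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1 || q < 1 || q != round(q))
    stop("`q` must be a positive integer", call. = FALSE)
  if (q > 20)
    warning("with q > 20 tested coefficients, even larger prior degrees of ",
            "freedom than the rule 5 + (q - 1) should be considered; check ",
            "the implied tail probabilities", call. = FALSE)
  if (family == "es") {
    nu <- 3
    r <- if (test_kind == "t") sqrt((nu - 2) / nu) * effect_size
         else sqrt((nu - 2) / (nu * q)) * effect_size
    list(nu = nu, r = r)
  } else {
    list(nu = if (test_kind == "t") 5 else 5 + (q - 1), r = NULL)
  }
}

## conventional small/medium/large effect sizes per statistic scale
effect_size_label <- function(label, scale = c("d", "f", "f2", "w")) {
  scale <- match.arg(scale)
  tab <- list(d  = c(small = 0.2,  medium = 0.5,  large = 0.8),
              f  = c(small = 0.10, medium = 0.25, large = 0.40),
              f2 = c(small = 0.02, medium = 0.15, large = 0.35),
              w  = c(small = 0.10, medium = 0.30, large = 0.50))
  v <- tab[[scale]][label]
  if (any(is.na(v)))
    stop("unknown effect-size label; use 'small', 'medium' or 'large'",
         call. = FALSE)
  unname(v)
}

#' Build a prior from a plain configuration list
#'
#' Constructs a prior from a mapping such as parsed YAML/JSON:
#' `list(family = "es", effect_size = 0.3)`.  Omitted `nu`/`r` are filled in
#' by [recommend_hyperparameters()]; `effect_size` may be a conventional
#' label (`"small"`, `"medium"`, `"large"`), resolved on the d scale for
#' `es`/`moment`/`cauchy` families, the f scale for `lambda2_*` families and
#' the w scale for `wsq_gamma`.
#'
#' @param config A named list with at least `family`; recognised families are
#'   `es`, `moment`, `cauchy`, `lambda2_es`, `lambda2_moment`, `wsq_gamma`.
#' @return A prior object.
#' @export
prior_from_config <- function(config) {
  if (is.null(config$family))
    stop("prior config needs a `family` entry", call. = FALSE)
  fam <- config$family
  es <- config$effect_size
  if (is.character(es)) {
    scale <- switch(fam,
                    lambda2_es = , lambda2_moment = "f",
                    wsq_gamma = "w", "d")
    es <- effect_size_label(es, scale)
  }
  switch(fam,
    es = {
      nu <- config$nu %||% 3
      es_prior(es, nu = nu, r = config$r)
    },
    moment = moment_prior(es, nu = config$nu %||% 5),
    cauchy = cauchy_prior(r = config$r %||% 1),
    lambda2_es = {
      q <- config$q %||% 1
      lambda2_es_prior(q, es, nu = config$nu %||% 3, r = config$r)
    },
    lambda2_moment = {
      q <- config$q %||% 1
      nu <- config$nu %||% (5 + (q - 1))
      lambda2_moment_prior(q, es, nu = nu)
    },
    wsq_gamma = {
      if (is.null(config$rate)) wsq_gamma_prior(es, shape = config$shape %||% 6.6)
      else wsq_gamma_prior(es, shape = config$shape %||% 6.6, rate = config$rate)
    },
    stop("unknown prior family: ", fam, call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
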