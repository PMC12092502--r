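## The Bayes-factor integrals: 1-D adaptive quadrature of
## (noncentral / central density ratio) x (effect-size prior density).

## piecewise adaptive quadrature with panel splits at the prior modes and at
## the effect size implied by the observed statistic, so each panel's
## integrand is unimodal
quad_panels <- function(f, lower, upper, breaks = numeric(),
                        rel_tol = 1e-9) {
  pts <- sort(unique(c(lower, breaks[breaks > lower & breaks < upper], upper)))
  one_panel <- function(a, b, depth) {
    piece <- stats::integrate(f, a, b, rel.tol = rel_tol,
                              abs.tol = 1e-12, subdivisions = 400L,
                              stop.on.error = FALSE)
    ## "roundoff error" on a tail panel means the panel is negligible
    ## relative to machine precision; its abs.error still enters the total
    if (piece$message %in% c("OK", "roundoff error was detected"))
      return(c(piece$value, piece$abs.error))
    ## steeply decaying panels can defeat the extrapolation; bisect
    if (depth < 8 && is.finite(a) && is.finite(b)) {
      mid <- (a + b) / 2
      return(one_panel(a, mid, depth + 1) + one_panel(mid, b, depth + 1))
    }
    ## residual sub-panels at this depth are dominated by floating-point
    ## noise of the noncentral densities; keep the estimate, whose
    ## abs.error flows into the reported integration error
    c(piece$value, piece$abs.error)
  }
  total <- c(0, 0)
  for (i in seq_len(length(pts) - 1))
    total <- total + one_panel(pts[i], pts[i + 1], 0)
  list(value = total[1], abs_error = total[2])
}

## Generic kernel: integrate ratio x prior over the prior's support.
##
## The integrand is first probed on a grid in log space; the integration
## range is truncated where the log integrand falls `drop` units below its
## peak (the far noncentral-t/F tails underflow noisily and carry no mass),
## and the adaptive quadrature then runs on the peak-rescaled integrand so
## relative tolerances are meaningful whatever the magnitude of B10.
bf_integral <- function(x, family, log_prior_fun, support, breaks,
                        rel_tol = 1e-9, drop = 45) {
  li <- function(e) {
    out <- log_density_ratio(family, x, family$effect_map(e)) +
      log_prior_fun(e)
    out[is.nan(out)] <- -Inf
    out
  }
  centers <- breaks[is.finite(breaks)]
  if (support == "real") {
    if (length(centers) == 0) centers <- 0
    w <- max(diff(range(centers)), 1)
    lo <- min(centers) - 4 * w
    hi <- max(centers) + 4 * w
    grid <- seq(lo, hi, length.out = 481L)
    lg <- li(grid)
    m <- max(lg)
    ## expand outward while the boundary still carries mass
    for (it in 1:60) {
      grew <- FALSE
      if (lg[1] > m - drop) {
        add <- seq(grid[1] - 4 * w, grid[1], length.out = 81L)[-81L]
        grid <- c(add, grid); lg <- c(li(add), lg); grew <- TRUE
      }
      nlast <- length(grid)
      if (lg[nlast] > m - drop) {
        add <- seq(grid[nlast], grid[nlast] + 4 * w, length.out = 81L)[-1L]
        grid <- c(grid, add); lg <- c(lg, li(add)); grew <- TRUE
      }
      m <- max(lg)
      if (!grew) break
    }
    keep <- which(lg > m - drop)
    lo_t <- grid[max(1, min(keep) - 1)]
    hi_t <- grid[min(length(grid), max(keep) + 1)]
  } else {
    if (length(centers) == 0 || all(centers <= 0)) centers <- 1
    hi <- 4 * max(centers)
    repeat {
      grid <- hi * exp(seq(log(1e-8), 0, length.out = 321L))
      lg <- li(grid)
      m <- max(lg, na.rm = TRUE)
      if (lg[length(grid)] <= m - drop || hi > 1e8) break
      hi <- hi * 4
    }
    keep <- which(lg > m - drop)
    lo_t <- 0  # keep the (integrable) lambda^2 -> 0 singularity
    hi_t <- grid[min(length(grid), max(keep) + 1)]
  }
  if (!is.finite(m))
    stop("the Bayes-factor integrand vanished everywhere; check inputs",
         call. = FALSE)
  f_scaled <- function(e) exp(li(e) - m)
  res <- quad_panels(f_scaled, lo_t, hi_t,
                     breaks = centers[centers > lo_t & centers < hi_t],
                     rel_tol = rel_tol)
  list(value = exp(m) * res$value, abs_error = exp(m) * res$abs_error,
       log_value = m + log(res$value))
}

prior_breaks <- function(prior) {
  switch(class(prior)[1],
    es_prior = c(-prior$effect_size, 0, prior$effect_size),
    moment_prior = c(-prior$effect_size, 0, prior$effect_size),
    cauchy_prior = c(-prior$r, 0, prior$r),
    lambda2_es_prior = prior$effect_size^2,
    lambda2_moment_prior = prior$effect_size^2,
    wsq_gamma_prior = prior$effect_size^2,
    numeric()
  )
}

## ---- t tests ----------------------------------------------------------------

#' Bayes factor for a t test from the t statistic
#'
#' Computes \eqn{B_{10}} for a one- or two-sample t test by integrating the
#' noncentral-t / central-t density ratio at the observed statistic against
#' a prior on the standardized effect size d.  The noncentrality is
#' \eqn{\sqrt{N} d} (one-sample) or \eqn{\sqrt{M} d} with
#' \eqn{M = N_1 N_2 / N} (two-sample).  With a [cauchy_prior()] this is the
#' JZS default Bayes factor.
#'
#' @param t Observed t statistic (finite; `t = 0` is valid).
#' @param layout A [one_sample()] or [two_sample()] layout.
#' @param prior An [es_prior()], [moment_prior()] or [cauchy_prior()].
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bf_result` with elements `b10`, `b01`, `log10_b10` and an
#'   integration error estimate.  When the sample size is below the
#'   consistency-in-information threshold a note is attached (not an error):
#'   such Bayes factors remain bounded as `t` grows.
#' @examples
#' bf_ttest(2.03, one_sample(80), cauchy_prior(1))       # B10 ~= 0.64
#' bf_ttest(2.03, one_sample(80), es_prior(0.2))         # B10 ~= 2.52
#' @export
bf_ttest <- function(t, layout, prior, rel_tol = 1e-9) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t))
    stop("`t` must be a single finite number", call. = FALSE)
  if (!inherits(layout, "bf_layout") ||
      !layout$kind %in% c("one_sample", "two_sample"))
    stop("`layout` must be a one_sample() or two_sample() layout",
         call. = FALSE)
  if (!inherits(prior, c("es_prior", "moment_prior", "cauchy_prior")))
    stop("`prior` must be an es_prior, moment_prior or cauchy_prior",
         call. = FALSE)
  fam <- family_for_layout(layout)
  mult <- if (layout$kind == "one_sample") sqrt(layout$n) else sqrt(layout$m)
  breaks <- sort(unique(c(prior_breaks(prior), t / mult)))
  res <- bf_integral(t, fam, function(d) prior_density(prior, d, log = TRUE),
                     "real", breaks, rel_tol)
  notes <- consistency_note(layout, prior)
  new_bf_result(res$value, res$abs_error, method = "ttest",
                settings = list(t = t, layout = layout, prior = prior),
                notes = notes)
}

consistency_note <- function(layout, prior) {
  fam <- switch(class(prior)[1],
                es_prior = , cauchy_prior = , lambda2_es_prior = "es",
                moment_prior = , lambda2_moment_prior = "moment",
                return(character()))
  nu <- switch(class(prior)[1], cauchy_prior = 1, prior$nu)
  thr <- consistency_threshold(layout$kind, fam, nu,
                               p = layout$p %||% 0, q = layout$q %||% 1)
  if (layout$n < thr)
    paste0("N = ", layout$n, " is below the consistency-in-information ",
           "threshold (", thr, "): B10 stays bounded as the statistic grows")
  else character()
}

## ---- regression / ANOVA -----------------------------------------------------

#' Bayes factor for a linear-model comparison
#'
#' Computes \eqn{B_{10}} for testing `q` coefficients of a regression or
#' ANOVA model against the reduced model with `p` retained coefficients,
#' by integrating the noncentral-F / central-F density ratio against the
#' induced prior on the squared multivariate effect size \eqn{\lambda^2}
#' (noncentrality \eqn{M\lambda^2}, effective sample size `m = n - p`).
#' Exactly one of `f_stat`, `r2p`, `eta2p` or `t_stat` must be supplied;
#' partial R-squared, partial eta-squared and (for `q = 1`) t statistics are
#' converted to the equivalent F value.
#'
#' @param layout A [linear_layout()].
#' @param prior A [lambda2_es_prior()] or [lambda2_moment_prior()] whose `q`
#'   matches the layout.
#' @param f_stat Observed F statistic.
#' @param r2p Observed partial R-squared.
#' @param eta2p Observed partial eta-squared.
#' @param t_stat Observed t statistic (allowed only when `q = 1`;
#'   `f_stat = t_stat^2`).
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bf_result`.  `b01` gives the preference for the reduced model.
#' @examples
#' lay <- linear_layout(175, p = 3, q = 2)
#' pr <- lambda2_es_prior(2, effect_size = sqrt(0.35))
#' bf_linear(lay, pr, r2p = 0.0136)$b01   # ~= 41
#' @export
bf_linear <- function(layout, prior, f_stat = NULL, r2p = NULL,
                      eta2p = NULL, t_stat = NULL, rel_tol = 1e-9) {
  if (!inherits(layout, "bf_layout") || layout$kind != "linear")
    stop("`layout` must be a linear_layout()", call. = FALSE)
  if (!inherits(prior, c("lambda2_es_prior", "lambda2_moment_prior")))
    stop("`prior` must be a lambda2_es_prior or lambda2_moment_prior",
         call. = FALSE)
  if (prior$q != layout$q)
    stop("the prior was built for q = ", prior$q,
         " tested coefficients but the layout has q = ", layout$q,
         call. = FALSE)
  given <- !c(is.null(f_stat), is.null(r2p), is.null(eta2p), is.null(t_stat))
  if (sum(given) != 1)
    stop("supply exactly one of `f_stat`, `r2p`, `eta2p`, `t_stat`",
         call. = FALSE)
  if (!is.null(t_stat)) {
    if (layout$q != 1)
      stop("a t statistic determines F only for q = 1", call. = FALSE)
    f_stat <- t_stat^2
  }
  if (!is.null(r2p))
    f_stat <- F_from_r2p(r2p, layout$n, layout$p, layout$q)
  if (!is.null(eta2p))
    f_stat <- F_from_eta2p(eta2p, layout$q, layout$m - layout$q)
  if (!is.numeric(f_stat) || length(f_stat) != 1 || !is.finite(f_stat) ||
      f_stat < 0)
    stop("the F statistic must be a single finite nonnegative number",
         call. = FALSE)
  fam <- family_for_layout(layout)
  breaks <- sort(unique(c(prior_breaks(prior), f_stat * layout$q / layout$m)))
  res <- bf_integral(f_stat, fam,
                     function(l2) prior_density(prior, l2, log = TRUE),
                     "positive", breaks, rel_tol)
  new_bf_result(res$value, res$abs_error, method = "linear",
                settings = list(f_stat = f_stat, layout = layout,
                                prior = prior),
                notes = consistency_note(layout, prior))
}

## ---- generic test-statistic engine -----------------------------------------

#' Test-statistic-based Bayes factor
#'
#' The generic engine: for any test statistic whose sampling distribution
#' under the alternative is a known noncentral family indexed by a
#' one-dimensional effect size \eqn{\xi} (with \eqn{\xi = 0} under the null),
#' \deqn{B_{10} = \int f(x \mid \xi)\, f(\xi)\, d\xi \; / \; f(x \mid 0).}
#' With the t family and an effect-size or moment prior this reproduces
#' [bf_ttest()] exactly; with the chi-squared family and a
#' [wsq_gamma_prior()] it gives Bayes factors for likelihood-ratio /
#' chi-squared tests (noncentrality \eqn{N w^2}).
#'
#' @param x Observed statistic value.
#' @param family A [stat_family()] whose `effect_map` sends the effect size
#'   to the noncentrality parameter.
#' @param effect_prior A prior object, or a plain density function on the
#'   effect size (then `support` gives its domain).
#' @param support `"real"` or `"positive"`; taken from prior objects
#'   automatically.
#' @param breaks Optional interior quadrature split points.
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bf_result`.  If a plain-function prior integrates to something
#'   other than 1 (beyond 1e-3) a warning reports the computed normalization.
#' @examples
#' fam <- stat_family("chisq", df = 5, effect_map = function(w2) 100 * w2)
#' bf_teststat(12.72, fam, wsq_gamma_prior(0.3))$b10   # ~= 5.14
#' @export
bf_teststat <- function(x, family, effect_prior, support = NULL,
                        breaks = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(family, "stat_family"))
  if (inherits(effect_prior, "bf_prior")) {
    support <- effect_prior$support
    log_prior_fun <- function(e) prior_density(effect_prior, e, log = TRUE)
    if (is.null(breaks)) breaks <- prior_breaks(effect_prior)
  } else if (is.function(effect_prior)) {
    if (is.null(support)) support <- "real"
    log_prior_fun <- function(e) log(effect_prior(e))
    prior_fun <- effect_prior
    lims <- if (support == "real") c(-Inf, Inf) else c(0, Inf)
    norm <- quad_panels(prior_fun, lims[1], lims[2],
                        breaks = breaks %||% numeric(), rel_tol = 1e-8)
    if (abs(norm$value - 1) > 1e-3)
      warning("the supplied effect prior integrates to ",
              format(norm$value, digits = 6),
              ", not 1; the Bayes factor is scaled accordingly",
              call. = FALSE)
    if (is.null(breaks)) breaks <- numeric()
  } else {
    stop("`effect_prior` must be a prior object or a density function",
         call. = FALSE)
  }
  res <- bf_integral(x, family, log_prior_fun, support, breaks, rel_tol)
  new_bf_result(res$value, res$abs_error, method = "teststat",
                settings = list(x = x, family = family$kind,
                                prior = effect_prior))
}

## ---- consistency in information --------------------------------------------

#' Minimal sample size for consistency in information
#'
#' The smallest `N` at which the Bayes factor grows without bound as the
#' test statistic tends to infinity (N fixed).  Effect-size priors:
#' `1 + nu` (one-sample t), `2 + nu` (two-sample t), `p + q + nu` (linear).
#' Moment priors: `nu - 1`, `nu`, `p + q + nu - 2`.
#'
#' @param test_kind `"one_sample"`, `"two_sample"` or `"linear"`.
#' @param prior_family `"es"` (includes the Cauchy default) or `"moment"`.
#' @param nu Prior degrees of freedom.
#' @param p,q Linear-model dimensions (linear only).
#' @return The minimal `N` (integer).
#' @examples
#' consistency_threshold("one_sample", "es", nu = 3)   # 4
#' @export
consistency_threshold <- function(test_kind = c("one_sample", "two_sample",
                                                "linear"),
                                  prior_family = c("es", "moment"),
                                  nu, p = 0, q = 1) {
  test_kind <- match.arg(test_kind)
  prior_family <- match.arg(prior_family)
  if (prior_family == "es")
    switch(test_kind,
           one_sample = 1 + nu,
           two_sample = 2 + nu,
           linear = p + q + nu)
  else
    switch(test_kind,
           one_sample = nu - 1,
           two_sample = nu,
           linear = p + q + nu - 2)
}
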