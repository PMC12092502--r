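## Noncentral sampling-distribution families of t, F and chi-squared test
## statistics, with the effect-size -> noncentrality maps used throughout:
## one-sample t: sqrt(N) d; two-sample t: sqrt(M) d, M = N1 N2 / N;
## linear models: M lambda^2, M = N - p; chi-squared: N w^2.

#' Sample layouts
#'
#' Describe how the observations that produced a test statistic were
#' organised.  `one_sample(n)` and `two_sample(n1, n2)` cover t tests;
#' `linear_layout(n, p, q)` covers regression/ANOVA model comparisons with
#' `p` coefficients retained under the reduced model and `q` tested ones
#' (effective sample size `m = n - p`).
#'
#' @param n,n1,n2 Positive integer sample sizes.
#' @param p Number of coefficients in the reduced model (\eqn{\ge 0}).
#' @param q Number of tested coefficients (\eqn{\ge 1}).
#' @return A classed list with derived quantities (`n`, `m`).
#' @export
one_sample <- function(n) {
  check_count(n, "n", min = 2)
  structure(list(kind = "one_sample", n = n), class = "bf_layout")
}

#' @rdname one_sample
#' @export
two_sample <- function(n1, n2) {
  check_count(n1, "n1", min = 1)
  check_count(n2, "n2", min = 1)
  n <- n1 + n2
  if (n < 3)
    stop("a two-sample t test needs at least 3 observations in total",
         call. = FALSE)
  structure(list(kind = "two_sample", n1 = n1, n2 = n2, n = n,
                 m = n1 * n2 / n), class = "bf_layout")
}

#' @rdname one_sample
#' @export
linear_layout <- function(n, p, q) {
  check_count(n, "n", min = 1)
  check_count(p, "p", min = 0)
  check_count(q, "q", min = 1)
  if (n <= p + q)
    stop("the F statistic is uninformative unless n > p + q", call. = FALSE)
  structure(list(kind = "linear", n = n, p = p, q = q, m = n - p),
            class = "bf_layout")
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
    stop("`", name, "` must be an integer >= ", min, call. = FALSE)
  invisible(x)
}

#' Noncentral statistic family
#'
#' Bundle a test statistic's sampling-distribution family with the map from
#' the effect-size parameter to the noncentrality parameter.
#'
#' @param kind `"t"`, `"f"` or `"chisq"`.
#' @param df Degrees of freedom (t, chisq).
#' @param df1,df2 Numerator/denominator degrees of freedom (F).
#' @param effect_map Function mapping the effect-size parameter to the
#'   noncentrality parameter; must map 0 to 0.  Defaults to the identity.
#' @return An object of class `stat_family`.
#' @examples
#' fam <- stat_family("t", df = 79, effect_map = function(d) sqrt(80) * d)
#' log_density_ratio(fam, x = 2.03, ncp = fam$effect_map(0.227))
#' @export
stat_family <- function(kind = c("t", "f", "chisq"), df = NULL,
                        df1 = NULL, df2 = NULL, effect_map = identity) {
  kind <- match.arg(kind)
  if (kind == "f") {
    if (is.null(df1) || is.null(df2) || df1 <= 0 || df2 <= 0)
      stop("the F family needs positive `df1` and `df2`", call. = FALSE)
  } else {
    if (is.null(df) || df <= 0)
      stop("the ", kind, " family needs positive `df`", call. = FALSE)
  }
  if (!is.function(effect_map))
    stop("`effect_map` must be a function", call. = FALSE)
  structure(list(kind = kind, df = df, df1 = df1, df2 = df2,
                 effect_map = effect_map),
            class = "stat_family")
}

## layout -> statistic family for the t and F paths
family_for_layout <- function(layout) {
  switch(layout$kind,
    one_sample = stat_family("t", df = layout$n - 1,
                             effect_map = local({
                               n <- layout$n
                               function(d) sqrt(n) * d
                             })),
    two_sample = stat_family("t", df = layout$n - 2,
                             effect_map = local({
                               m <- layout$m
                               function(d) sqrt(m) * d
                             })),
    linear = stat_family("f", df1 = layout$q, df2 = layout$m - layout$q,
                         effect_map = local({
                           m <- layout$m
                           function(lambda2) m * lambda2
                         }))
  )
}

#' Log density of a noncentral statistic family
#'
#' Evaluated in log space so ratios for extreme statistic values do not
#' overflow.  Noncentrality must be nonnegative for the F and chi-squared
#' families; the t noncentrality is signed.
#'
#' @param family A [stat_family()].
#' @param x Statistic value(s) (F and chi-squared require `x >= 0`).
#' @param ncp Noncentrality parameter.
#' @return Log density values.
#' @export
log_density <- function(family, x, ncp = 0) {
  stopifnot(inherits(family, "stat_family"))
  if (family$kind != "t" && any(ncp < 0))
    stop("noncentrality must be nonnegative for the ", family$kind,
         " family", call. = FALSE)
  if (family$kind != "t" && any(x < 0))
    stop("the ", family$kind, " statistic is nonnegative", call. = FALSE)
  ld <- suppressWarnings(switch(family$kind,
    t = if (all(ncp == 0)) stats::dt(x, family$df, log = TRUE)
        else stats::dt(x, family$df, ncp = ncp, log = TRUE),
    f = if (all(ncp == 0)) stats::df(x, family$df1, family$df2, log = TRUE)
        else stats::df(x, family$df1, family$df2, ncp = ncp, log = TRUE),
    chisq = if (all(ncp == 0)) stats::dchisq(x, family$df, log = TRUE)
            else stats::dchisq(x, family$df, ncp = ncp, log = TRUE)
  ))
  ## numeric underflow in the noncentral series surfaces as NaN/-Inf:
  ## such points carry no mass, so map them to -Inf rather than propagate NaN
  ld[is.nan(ld)] <- -Inf
  ld
}

#' Log density ratio against the central case
#'
#' `log f(x | ncp) - log f(x | 0)`, the integrand kernel of every Bayes
#' factor in the package.  Zero when `ncp = 0`.
#'
#' @inheritParams log_density
#' @return Log density-ratio values.
#' @export
log_density_ratio <- function(family, x, ncp) {
  log_density(family, x, ncp) - log_density(family, x, 0)
}
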