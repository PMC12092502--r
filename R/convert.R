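## Conversions among the F statistic, partial R^2, partial eta^2, and among
## the effect-size scales d, f, f^2.

#' Convert between F, partial R-squared and partial eta-squared
#'
#' `F` and partial \eqn{R^2} stand in a one-to-one relationship for a
#' comparison of a full model (p + q coefficients) against a reduced model
#' (p coefficients) on `n` observations:
#' \eqn{F = \frac{R^2_p}{1 - R^2_p}\cdot\frac{n - p - q}{q}}.  Partial
#' \eqn{\eta^2} relates to F through its degrees of freedom:
#' \eqn{\eta^2_p = F\,\mathrm{df1} / (F\,\mathrm{df1} + \mathrm{df2})}.
#'
#' @param r2p Partial R-squared in `[0, 1)`.
#' @param f_stat F statistic (\eqn{\ge 0}).
#' @param eta2p Partial eta-squared in `[0, 1)`.
#' @param n,p,q Observations, retained and tested coefficients (`n > p + q`).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return The converted value.
#' @examples
#' F_from_r2p(0.0136, n = 175, p = 3, q = 2)   # ~= 1.172
#' eta2p_from_F(16.73, df1 = 1, df2 = 36)      # ~= 0.32
#' @export
F_from_r2p <- function(r2p, n, p, q) {
  if (any(r2p < 0) || any(r2p >= 1))
    stop("`r2p` must lie in [0, 1)", call. = FALSE)
  if (n <= p + q) stop("need n > p + q", call. = FALSE)
  r2p / (1 - r2p) * (n - p - q) / q
}

#' @rdname F_from_r2p
#' @export
r2p_from_F <- function(f_stat, n, p, q) {
  if (any(f_stat < 0)) stop("`f_stat` must be nonnegative", call. = FALSE)
  if (n <= p + q) stop("need n > p + q", call. = FALSE)
  u <- f_stat * q / (n - p - q)
  u / (1 + u)
}

#' @rdname F_from_r2p
#' @export
eta2p_from_F <- function(f_stat, df1, df2) {
  if (any(f_stat < 0)) stop("`f_stat` must be nonnegative", call. = FALSE)
  f_stat * df1 / (f_stat * df1 + df2)
}

#' @rdname F_from_r2p
#' @export
F_from_eta2p <- function(eta2p, df1, df2) {
  if (any(eta2p < 0) || any(eta2p >= 1))
    stop("`eta2p` must lie in [0, 1)", call. = FALSE)
  eta2p / (1 - eta2p) * df2 / df1
}

#' Convert an effect size between the d, f and f-squared scales
#'
#' For a one-sample t test (or an equivalent single-group linear comparison)
#' `f = d` and `f^2 = d^2`.  For a two-sample t test against the equivalent
#' `q = 1` linear comparison the scales differ because the linear framing
#' standardizes by the effective sample size `N - 1` while the t framing
#' uses `M = N1 N2 / N`: `d = sqrt((N - 1)/M) * f`.
#'
#' @param value Effect-size value.
#' @param from,to One of `"d"`, `"f"`, `"f2"`.
#' @param layout `NULL` (one-sample rules) or a [two_sample()] layout.
#' @return The converted value.
#' @examples
#' convert_effect_size(0.5, "d", "f")                         # 0.5
#' convert_effect_size(1, "f", "d", two_sample(50, 50))       # ~= 1.99
#' @export
convert_effect_size <- function(value, from = c("d", "f", "f2"),
                                to = c("d", "f", "f2"), layout = NULL) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(value)
  two <- !is.null(layout)
  if (two && (!inherits(layout, "bf_layout") || layout$kind != "two_sample"))
    stop("`layout` must be NULL (one-sample) or a two_sample() layout",
         call. = FALSE)
  scale_d_per_f <- if (two) sqrt((layout$n - 1) / layout$m) else 1
  f <- switch(from,
              d = value / scale_d_per_f,
              f = value,
              f2 = sqrt(value))
  switch(to,
         d = f * scale_d_per_f,
         f = f,
         f2 = f^2)
}
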