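## Gauss hypergeometric function 2F1(a, b; c; z) for 0 <= z < 1, c > 0.
##
## Direct power series for z <= 0.8; for larger z the Euler transformation
## 2F1(a,b;c;z) = (1-z)^(c-a-b) 2F1(c-a, c-b; c; z) is used, whose series
## converges at z = 1 whenever a + b - c > 0 (always the case for the
## lambda^2 effect-size prior, where a + b - c = (nu + 1)/2).

hyp2f1_series <- function(a, b, c, z, max_terms = 100000L,
                          rel_tol = 1e-15) {
  term <- 1
  s <- 1
  for (k in 0:max_terms) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    if (term == 0) return(s)
    s_new <- s + term
    if (is.finite(s_new) && abs(term) <= rel_tol * abs(s_new)) return(s_new)
    s <- s_new
  }
  warning("2F1 series did not reach the requested tolerance", call. = FALSE)
  s
}

#' Gauss hypergeometric function
#'
#' Evaluates \eqn{{}_2F_1(a, b; c; z)} for real arguments with
#' \eqn{0 \le z < 1} and \eqn{c > 0}, the regime needed by the induced
#' effect-size prior on \eqn{\lambda^2}.  Near the singular point the Euler
#' linear transformation is applied to preserve accuracy.
#'
#' @param a,b,c Parameters (`c > 0`).
#' @param z Argument in `[0, 1)`.
#' @return The function value (scalar).
#' @export
gauss_2F1 <- function(a, b, c, z) {
  exp(log_gauss_2F1(a, b, c, z))
}

log_gauss_2F1 <- function(a, b, c, z) {
  if (!is.finite(z) || z < 0 || z >= 1)
    stop("2F1 argument must lie in [0, 1); got ", z, call. = FALSE)
  if (c <= 0) stop("2F1 parameter c must be positive", call. = FALSE)
  if (z <= 0.8) {
    log(hyp2f1_series(a, b, c, z))
  } else {
    (c - a - b) * log1p(-z) + log(hyp2f1_series(c - a, c - b, c, z))
  }
}
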