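## Result container shared by all Bayes-factor operations.

new_bf_result <- function(b10, abs_error, method, settings = list(),
                          notes = character()) {
  stopifnot(is.numeric(b10), b10 > 0)
  structure(list(b10 = b10,
                 b01 = 1 / b10,
                 log10_b10 = log10(b10),
                 abs_error_estimate = abs_error,
                 method = method,
                 settings = settings,
                 notes = notes),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, digits = 6, ...) {
  cat("Bayes factor (", x$method, ")\n", sep = "")
  cat("  B10       = ", format(x$b10, digits = digits), "\n", sep = "")
  cat("  B01       = ", format(x$b01, digits = digits), "\n", sep = "")
  cat("  log10 B10 = ", format(x$log10_b10, digits = digits), "\n", sep = "")
  if (is.finite(x$abs_error_estimate))
    cat("  abs. error estimate = ",
        format(x$abs_error_estimate, digits = 3), "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bayes-factor result
#'
#' @param x A `bf_result`.
#' @param ... Unused.
#' @return A one-row tibble with columns `method`, `b10`, `b01`,
#'   `log10_b10`, `abs_error_estimate`.
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, ...) {
  tibble::tibble(method = x$method, b10 = x$b10, b01 = x$b01,
                 log10_b10 = x$log10_b10,
                 abs_error_estimate = x$abs_error_estimate)
}

#' @rdname tidy.bf_result
#' @method glance bf_result
#' @export
glance.bf_result <- function(x, ...) tidy(x, ...)

## flatten a result plus its settings for serialization
bf_result_record <- function(x) {
  flat <- function(v) if (inherits(v, "bf_prior") || inherits(v, "bf_layout"))
    unclass(v)[!names(unclass(v)) %in% "support"] else v
  list(b10 = x$b10, b01 = x$b01, log10_b10 = x$log10_b10,
       error_estimate = x$abs_error_estimate, method = x$method,
       settings = lapply(x$settings, flat), notes = x$notes)
}
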