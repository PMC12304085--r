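#' Effective-size estimate container
#'
#' A light container for a single effective population size estimate:
#' a point value (possibly infinite or `NA` when the drift signal is
#' undetectable), an optional confidence interval, a method tag and a named
#' list of auxiliary diagnostics (e.g. harmonic-mean sample size, number of
#' loci or pairs, mean r-squared, lifetime variance in reproductive
#' success). Use [tidy()] / [glance()] to get tibbles.
#'
#' @param point Point estimate (individuals). `Inf` flags an estimate whose
#'   drift signal is indistinguishable from sampling noise; negative raw
#'   values are kept in `aux` rather than reported as points.
#' @param ci_low,ci_high Confidence bounds (may be infinite or `NA`).
#' @param method One of `"theoretical"`, `"realized"`, `"ld"`, `"sfs"`.
#' @param aux Named list of numeric diagnostics.
#' @return An object of class `ne_estimate`.
#' @export
ne_estimate <- function(point, ci_low = NA_real_, ci_high = NA_real_,
                        method = c("theoretical", "realized", "ld", "sfs"),
                        aux = list()) {
  method <- match.arg(method)
  if (is.finite(point) && point <= 0) {
    stop("`point` must be positive; flag undetectable signal with Inf and ",
         "keep raw values in `aux`", call. = FALSE)
  }
  if (is.finite(ci_low) && is.finite(point) && is.finite(ci_high) &&
      !(ci_low <= point && point <= ci_high)) {
    stop("confidence interval must bracket the point estimate", call. = FALSE)
  }
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 method = method, aux = aux),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  pt <- if (is.finite(x$point)) format(x$point, digits = 6) else as.character(x$point)
  cat("<ne_estimate> method =", x$method, "\n")
  cat("  Ne =", pt)
  if (!is.na(x$ci_low) || !is.na(x$ci_high)) {
    cat("  [", format(x$ci_low, digits = 6), ", ",
        format(x$ci_high, digits = 6), "]", sep = "")
  }
  cat("\n")
  if (length(x$aux)) {
    keep <- vapply(x$aux, function(v) is.numeric(v) && length(v) == 1, logical(1))
    if (any(keep)) {
      cat("  aux:", paste(names(x$aux)[keep],
                          vapply(x$aux[keep], function(v) format(v, digits = 5),
                                 character(1)),
                          sep = " = ", collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Ne estimate
#'
#' @param x An [ne_estimate] object.
#' @param ... Unused.
#' @return `tidy()` gives a one-row tibble with `method`, `estimate`,
#'   `conf.low`, `conf.high`; `glance()` additionally spreads scalar
#'   auxiliary diagnostics into columns.
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$point,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.ne_estimate
#' @export
glance.ne_estimate <- function(x, ...) {
  out <- tidy(x)
  keep <- vapply(x$aux, function(v) is.numeric(v) && length(v) == 1, logical(1))
  if (any(keep)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(x$aux[keep]))
  }
  out
}
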