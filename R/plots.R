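#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an equilibrium age structure
#'
#' @param object An `age_structure` tibble.
#' @param ... Unused.
#' @return A ggplot: expected count per age class (log scale).
#' @export
autoplot.age_structure <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "expected individuals",
                  title = paste0("Equilibrium age structure (K = ",
                                 attr(object, "total"), ")")) +
    ggplot2::theme_minimal()
}

#' Plot a site-frequency spectrum
#'
#' Observed counts per allele-frequency class, with the constant-size
#' neutral expectation (proportional to `1/i`, scaled to the observed number
#' of segregating sites) overlaid for unfolded spectra.
#'
#' @param object An `sfs` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfs <- function(object, ...) {
  df <- tibble::tibble(i = seq_along(object$counts), xi = object$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$xi)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = if (object$folded) "minor-allele count" else
      "derived-allele count",
      y = "number of sites") +
    ggplot2::theme_minimal()
  if (!object$folded && sum(object$counts) > 0) {
    s <- sum(object$counts)
    expd <- tibble::tibble(
      i = df$i, xi = s * (1 / df$i) / sum(1 / df$i)
    )
    p <- p + ggplot2::geom_line(data = expd, colour = "firebrick",
                                linewidth = 0.7) +
      ggplot2::labs(subtitle = "red: neutral constant-size expectation (1/i)")
  }
  p
}

#' Plot benchmark results
#'
#' One panel per migration rate: every subset's per-deme Ne estimate against
#' the factor on the x axis, with the per-class mean marked and an optional
#' horizontal reference at the target effective size. Infinite and failed
#' estimates are dropped (they are reported in the result table's `flag`
#' column).
#'
#' @param object A `bench_result` tibble from [run_benchmark()].
#' @param x_var `"sample_size"` or `"n_loci"`.
#' @param target Optional reference Ne (dashed line).
#' @param estimator Which estimator to show (default `"ld"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bench_result <- function(object, x_var = c("sample_size", "n_loci"),
                                  target = NULL, estimator = "ld", ...) {
  x_var <- match.arg(x_var)
  df <- dplyr::filter(object, .data$estimator == !!estimator,
                      .data$flag == "ok")
  df$x <- factor(df[[x_var]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ne)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4,
                          colour = "red", size = 3, stroke = 1.2) +
    ggplot2::facet_wrap(~migration, labeller = ggplot2::label_both) +
    ggplot2::labs(x = x_var, y = "estimated Ne") +
    ggplot2::theme_minimal()
  if (!is.null(target)) {
    p <- p + ggplot2::geom_hline(yintercept = target, linetype = "dashed")
  }
  p
}
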