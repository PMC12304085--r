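#' Burrows composite disequilibrium between two loci
#'
#' The Burrows composite disequilibrium is estimated from unphased diploid
#' dosages as half the sample covariance of the two allele counts,
#' `delta = cov(X, Y) / 2`; it sums the gametic and non-gametic components
#' of disequilibrium and requires no phase or Hardy-Weinberg assumption.
#' The squared correlation is obtained by normalizing with the
#' heterozygote-excess-adjusted allele variances,
#' `r2 = delta^2 / (D_A D_B)` with `D_A = p(1-p) + (P_AA - p^2)`, where
#' `P_AA` is the observed frequency of the counted-allele homozygote. Only
#' individuals non-missing at both loci are used.
#'
#' @param x A [genotype_matrix()].
#' @param locus_a,locus_b Column indices (or names from the locus id) of
#'   the two loci.
#' @return A one-row tibble: `locus_a`, `locus_b`, `delta`, `r2`, `s_pair`,
#'   and `excluded` (TRUE when either locus is monomorphic among the
#'   complete cases, in which case `r2` is `NA`).
#' @export
burrows_r2 <- function(x, locus_a, locus_b) {
  stopifnot(inherits(x, "genotype_matrix"))
  ga <- x$g[, locus_a]; gb <- x$g[, locus_b]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- ga[ok]; gb <- gb[ok]
  s <- length(ga)
  if (s < 2) {
    return(tibble::tibble(locus_a = locus_a, locus_b = locus_b,
                          delta = NA_real_, r2 = NA_real_, s_pair = s,
                          excluded = TRUE))
  }
  da <- comp_denom(ga); db <- comp_denom(gb)
  if (da <= 0 || db <= 0) {
    return(tibble::tibble(locus_a = locus_a, locus_b = locus_b,
                          delta = NA_real_, r2 = NA_real_, s_pair = s,
                          excluded = TRUE))
  }
  delta <- (mean(ga * gb) - mean(ga) * mean(gb)) / 2
  tibble::tibble(locus_a = locus_a, locus_b = locus_b, delta = delta,
                 r2 = delta^2 / (da * db), s_pair = s, excluded = FALSE)
}

comp_denom <- function(g) {
  p <- mean(g) / 2
  p * (1 - p) + (mean(g == 2L) - p^2)
}

# r2 and delta matrices for a complete-case genotype matrix (no NA);
# maximum-likelihood (1/n) moments throughout, so r2 is bounded by 1
burrows_matrices <- function(g) {
  n <- nrow(g)
  gc <- g - rep(colMeans(g), each = n)
  cv <- crossprod(gc) / n
  p <- colMeans(g) / 2
  d <- p * (1 - p) + (colMeans(g == 2L) - p^2)
  delta <- cv / 2
  r2 <- delta^2 / outer(d, d)
  list(delta = delta, r2 = r2, d = d, s = n)
}

#' Aggregate pairwise linkage disequilibrium over a locus panel
#'
#' Screens loci by minor-allele frequency, forms all locus pairs under the
#' chosen pairing policy and averages the Burrows composite r-squared
#' ([burrows_r2()]) over them. Pairs are built either from all loci
#' (`"all"`) or only between loci on different chromosomes
#' (`"between-chrom"`, which removes physical linkage at the price of
#' fewer pairs). With missing genotypes each pair uses its complete cases
#' and the summary reports the harmonic mean of the per-pair sample sizes.
#'
#' @param x A [genotype_matrix()].
#' @param maf_min Minimum minor-allele frequency for a locus to enter the
#'   pair set.
#' @param policy `"all"` or `"between-chrom"`.
#' @return An object of class `ld_summary`: `n_loci`, `n_pairs`, `mean_r2`,
#'   `harmonic_s`, `policy`, `maf_min`.
#' @export
ld_summary <- function(x, maf_min = 0.05, policy = c("all", "between-chrom")) {
  stopifnot(inherits(x, "genotype_matrix"))
  policy <- match.arg(policy)
  keep <- which(maf(x) >= maf_min & maf(x) > 0)
  if (length(keep) < 2) {
    stop("fewer than 2 loci pass the MAF screen (maf_min = ", maf_min, ")",
         call. = FALSE)
  }
  g <- x$g[, keep, drop = FALSE]
  chrom <- x$loci$chrom[keep]
  L <- ncol(g)
  pair_ok <- upper.tri(matrix(0, L, L))
  if (policy == "between-chrom") {
    pair_ok <- pair_ok & outer(chrom, chrom, `!=`)
    if (!any(pair_ok)) {
      stop("no between-chromosome pairs available", call. = FALSE)
    }
  }
  if (!anyNA(g)) {
    bm <- burrows_matrices(g)
    r2v <- bm$r2[pair_ok]
    n_pairs <- sum(!is.na(r2v))
    mean_r2 <- mean(r2v, na.rm = TRUE)
    harm_s <- bm$s
  } else {
    stats_m <- burrows_matrices_masked(g)
    r2v <- stats_m$r2[pair_ok]
    sv <- stats_m$s[pair_ok]
    ok <- !is.na(r2v) & sv >= 2
    n_pairs <- sum(ok)
    mean_r2 <- mean(r2v[ok])
    harm_s <- n_pairs / sum(1 / sv[ok])
  }
  structure(list(n_loci = L, n_pairs = n_pairs, mean_r2 = mean_r2,
                 harmonic_s = harm_s, policy = policy, maf_min = maf_min),
            class = "ld_summary")
}

# per-pair complete-case version (missing data); returns r2 and s matrices
burrows_matrices_masked <- function(g) {
  m <- !is.na(g)
  g0 <- g; g0[!m] <- 0L
  storage.mode(g0) <- "double"
  mm <- matrix(as.double(m), nrow(g))
  n <- crossprod(mm)
  sx <- crossprod(g0, mm)           # [a, b] = sum of x_a over pairs complete at both
  sxy <- crossprod(g0)
  cv <- (sxy - sx * t(sx) / n) / n
  hom <- matrix(as.double(g0 == 2 & m), nrow(g))
  sh <- crossprod(hom, mm)
  p <- sx / (2 * n)
  dx <- p * (1 - p) + (sh / n - p^2)
  r2 <- (cv / 2)^2 / (dx * t(dx))
  r2[dx <= 0 | t(dx) <= 0] <- NA
  list(r2 = r2, s = n)
}

#' @export
print.ld_summary <- function(x, ...) {
  cat("<ld_summary>", x$n_loci, "loci,", x$n_pairs, "pairs (", x$policy,
      "), mean r2 =", signif(x$mean_r2, 5), ", harmonic S =",
      signif(x$harmonic_s, 5), "\n")
  invisible(x)
}

#' Contemporary Ne from a linkage-disequilibrium summary
#'
#' Inverts the drift-plus-sampling decomposition of the mean squared
#' correlation: under random mating, `E[r2] = 1/(3 Ne) + 1/S`, so
#' `Ne = 1 / (3 (mean_r2 - 1/S))`; under lifetime monogamy the drift term
#' is `1/(2 Ne)`. When the observed mean r-squared does not exceed the
#' sampling expectation, the drift signal is undetectable and the estimate
#' is flagged infinite (the raw, possibly negative, inversion is kept in
#' the auxiliary slot). An optional refined mode uses the published
#' second-order sampling expectations and quadratic inversion for random
#' mating (`E[r2] = 1/S + 3.19/S^2` for `S >= 30`,
#' `0.0018 + 0.907/S + 4.44/S^2` below); its constants are configuration,
#' not re-derived here.
#'
#' @param summary An [ld_summary()].
#' @param mating `"random"` (default) or `"monogamy"`.
#' @param refined Use the published second-order sampling expectation and
#'   quadratic inversion (random mating only).
#' @return A [ne_estimate] with `method = "ld"`.
#' @export
ld_ne_estimate <- function(summary, mating = c("random", "monogamy"),
                           refined = FALSE) {
  stopifnot(inherits(summary, "ld_summary"))
  mating <- match.arg(mating)
  s <- summary$harmonic_s
  if (!is.finite(s) || s < 2) stop("degenerate harmonic sample size", call. = FALSE)
  drift_div <- if (mating == "random") 3 else 2
  if (refined && mating == "random") {
    # the published expectations and inversion are for the bias-corrected
    # (n/(n-1)) composite; rescale our ML-moment r2 accordingly
    r2_use <- summary$mean_r2 * (s / (s - 1))^2
    exp_samp <- if (s >= 30) 1 / s + 3.19 / s^2 else
      0.0018 + 0.907 / s + 4.44 / s^2
  } else {
    r2_use <- summary$mean_r2
    exp_samp <- 1 / s
  }
  r2d <- r2_use - exp_samp
  aux <- list(mean_r2 = summary$mean_r2, r2_drift = r2d, S = s,
              n_loci = summary$n_loci, n_pairs = summary$n_pairs,
              sampling_expectation = exp_samp)
  if (!is.finite(r2d) || r2d <= 0) {
    aux$raw_ne <- if (r2d < 0) 1 / (drift_div * r2d) else NA_real_
    return(ne_estimate(point = Inf, method = "ld", aux = aux))
  }
  if (refined && mating == "random") {
    disc <- if (s >= 30) 1 / 9 - 2.76 * r2d else 0.308^2 - 2.08 * r2d
    if (disc >= 0) {
      point <- if (s >= 30) (1 / 3 + sqrt(disc)) / (2 * r2d) else
        (0.308 + sqrt(disc)) / (2 * r2d)
    } else {
      point <- 1 / (drift_div * r2d)
      aux$refined_fallback <- 1
    }
  } else {
    point <- 1 / (drift_div * r2d)
  }
  ne_estimate(point = point, method = "ld", aux = aux)
}

#' Jackknife confidence interval for the LD-based Ne estimate
#'
#' Delete-one jackknife over the whole estimation pipeline, on the scale of
#' the drift signal `mean_r2 - 1/S` (where the estimator is a smooth
#' monotone transform). Units are either individuals (default) or loci.
#' The locus panel is fixed once on the full data so that every
#' pseudo-replicate uses the same pair set.
#'
#' @param x A [genotype_matrix()].
#' @param maf_min,policy As in [ld_summary()].
#' @param confidence Coverage of the interval (default 0.95).
#' @param unit `"individual"` or `"locus"`.
#' @param mating Passed to [ld_ne_estimate()].
#' @return Named numeric `c(low, high)` (Ne scale; `high` may be `Inf`),
#'   with attributes `se` (jackknife standard error of the drift signal)
#'   and `degenerate` (TRUE when the pseudo-values carry no variation).
#' @export
jackknife_ci <- function(x, maf_min = 0.05, policy = "all",
                         confidence = 0.95,
                         unit = c("individual", "locus"),
                         mating = "random") {
  stopifnot(inherits(x, "genotype_matrix"))
  unit <- match.arg(unit)
  n_ind <- nrow(x$g)
  if (unit == "individual" && n_ind < 10) {
    stop("need at least 10 individuals for the delete-one jackknife",
         call. = FALSE)
  }
  keep <- which(maf(x) >= maf_min & maf(x) > 0)
  if (length(keep) < 2) stop("fewer than 2 loci pass the MAF screen", call. = FALSE)
  xs <- genotype_matrix(x$g[, keep, drop = FALSE],
                        x$loci[keep, , drop = FALSE], x$samples)
  full <- ld_summary(xs, maf_min = 0, policy = policy)
  theta_hat <- full$mean_r2 - 1 / full$harmonic_s
  drift_div <- if (mating == "random") 3 else 2
  if (unit == "individual") {
    theta_i <- vapply(seq_len(n_ind), function(i) {
      xi <- genotype_matrix(xs$g[-i, , drop = FALSE], xs$loci,
                            xs$samples[-i, , drop = FALSE])
      sm <- tryCatch(ld_summary(xi, maf_min = 0, policy = policy),
                     error = function(e) NULL)
      if (is.null(sm)) return(NA_real_)
      sm$mean_r2 - 1 / sm$harmonic_s
    }, numeric(1))
  } else {
    # delete-one-locus pseudo-values from the pair sums
    g <- xs$g
    if (anyNA(g)) {
      mm <- burrows_matrices_masked(g)
      r2m <- mm$r2
    } else {
      r2m <- burrows_matrices(g)$r2
    }
    L <- ncol(g)
    pair_ok <- upper.tri(r2m)
    if (policy == "between-chrom") {
      pair_ok <- pair_ok & outer(xs$loci$chrom, xs$loci$chrom, `!=`)
    }
    r2m[!pair_ok & !t(pair_ok)] <- NA
    tot <- sum(r2m, na.rm = TRUE) / 2
    npair <- sum(!is.na(r2m)) / 2
    row_sum <- rowSums(r2m, na.rm = TRUE)
    row_n <- rowSums(!is.na(r2m))
    theta_i <- (tot - row_sum) / (npair - row_n) - 1 / full$harmonic_s
  }
  theta_i <- theta_i[is.finite(theta_i)]
  m <- length(theta_i)
  if (m < 3 || stats::sd(theta_i) == 0 || !is.finite(theta_hat)) {
    out <- c(low = NA_real_, high = NA_real_)
    attr(out, "degenerate") <- TRUE
    attr(out, "se") <- NA_real_
    return(out)
  }
  se <- sqrt((m - 1) / m * sum((theta_i - mean(theta_i))^2))
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  th_lo <- theta_hat - z * se
  th_hi <- theta_hat + z * se
  inv <- function(th) if (th <= 0) Inf else 1 / (drift_div * th)
  out <- c(low = inv(th_hi), high = inv(th_lo))
  attr(out, "se") <- se
  attr(out, "degenerate") <- FALSE
  out
}

#' Physical-linkage correction for LD-based Ne estimates
#'
#' When all locus pairs are used (including pairs on the same chromosome),
#' physical linkage inflates the mean r-squared and biases the Ne estimate
#' downward. In the absence of a recombination map, an empirical correction
#' divides the raw estimate by a predicted ratio
#' `Ne_hat / Ne_true = a + b * log(n_chromosomes)`, a published regression
#' whose coefficients are treated here as configuration, with the genome
#' size in centimorgans convertible at 100 cM per chromosome unit. The
#' ratio is capped at 1, so the correction vanishes for large genomes.
#'
#' @param ne_hat Raw (uncorrected) Ne estimate; must be finite and positive.
#' @param n_chromosomes Haploid chromosome number.
#' @param genome_cM Total genome map length in centimorgans (alternative to
#'   `n_chromosomes`).
#' @param coef Regression coefficients `c(a, b)`.
#' @return The upward-adjusted Ne, with the applied `factor` as an
#'   attribute.
#' @export
linkage_correction <- function(ne_hat, n_chromosomes = NULL, genome_cM = NULL,
                               coef = c(0.098, 0.219)) {
  if (!is.finite(ne_hat) || ne_hat <= 0) {
    stop("`ne_hat` must be finite and positive (flagged estimates cannot be ",
         "corrected)", call. = FALSE)
  }
  if (is.null(n_chromosomes) && is.null(genome_cM)) {
    stop("cannot correct: supply `n_chromosomes` or `genome_cM`", call. = FALSE)
  }
  chr <- if (!is.null(n_chromosomes)) n_chromosomes else genome_cM / 100
  if (chr < 1) stop("`n_chromosomes` must be >= 1", call. = FALSE)
  ratio <- coef[1] + coef[2] * log(chr)
  ratio <- min(1, max(ratio, 0.05))
  out <- ne_hat / ratio
  attr(out, "factor") <- ratio
  out
}

#' One-call LD-based Ne estimation
#'
#' Convenience wrapper: [ld_summary()] then [ld_ne_estimate()], optionally
#' with a jackknife confidence interval and the chromosome-number
#' correction.
#'
#' @inheritParams jackknife_ci
#' @param refined Passed to [ld_ne_estimate()].
#' @param ci `"none"`, `"jackknife-ind"` or `"jackknife-locus"`.
#' @param n_chromosomes Apply [linkage_correction()] when not `NULL`.
#' @return A [ne_estimate] with `method = "ld"`.
#' @export
ld_ne <- function(x, maf_min = 0.05, policy = "all", mating = "random",
                  refined = FALSE, ci = c("none", "jackknife-ind",
                                          "jackknife-locus"),
                  confidence = 0.95, n_chromosomes = NULL) {
  ci <- match.arg(ci)
  sm <- ld_summary(x, maf_min = maf_min, policy = policy)
  est <- ld_ne_estimate(sm, mating = mating, refined = refined)
  if (ci != "none") {
    jk <- jackknife_ci(x, maf_min = maf_min, policy = policy,
                       confidence = confidence,
                       unit = if (ci == "jackknife-ind") "individual" else "locus",
                       mating = mating)
    est$ci_low <- unname(jk["low"])
    est$ci_high <- unname(jk["high"])
  }
  if (!is.null(n_chromosomes) && is.finite(est$point)) {
    corrected <- linkage_correction(est$point, n_chromosomes)
    est$aux$uncorrected <- est$point
    est$aux$linkage_factor <- attr(corrected, "factor")
    est$point <- as.numeric(corrected)
    if (is.finite(est$ci_low)) est$ci_low <- est$ci_low / est$aux$linkage_factor
    if (is.finite(est$ci_high)) est$ci_high <- est$ci_high / est$aux$linkage_factor
  }
  est
}
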