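#' Site-frequency spectrum of a sample
#'
#' Tallies, for every segregating site, the number of copies of the derived
#' allele (unfolded) or of the minor allele (folded) among the sampled
#' haplotypes. Input can be a [genotype_matrix()] (2 haplotypes per
#' individual; the counted allele is the derived one by construction of the
#' simulator) or a `haplotype_set`. With `by_deme = TRUE` and two demes, a
#' joint SFS matrix of dimension `(n1 + 1) x (n2 + 1)` is returned instead.
#'
#' @param x A [genotype_matrix()] or `haplotype_set`.
#' @param fold Return the folded (minor-allele) spectrum.
#' @param by_deme Build the two-population joint SFS from the `deme` column
#'   of the sample table.
#' @return An object of class `sfs`: a list with `counts` (`xi[i]`, `i =
#'   1 .. n-1` unfolded or `1 .. floor(n/2)` folded), sample size `n`
#'   (haplotypes) and `folded`; or class `joint_sfs` (a counts matrix with
#'   `n1`, `n2`).
#' @export
compute_sfs <- function(x, fold = FALSE, by_deme = FALSE) {
  if (inherits(x, "genotype_matrix")) {
    dac <- colSums(x$g, na.rm = TRUE)
    n <- 2L * nrow(x$g)
    deme <- if ("deme" %in% names(x$samples)) x$samples$deme else NULL
  } else if (inherits(x, "haplotype_set")) {
    dac <- colSums(x$hap)
    n <- nrow(x$hap)
    deme <- NULL
  } else {
    stop("`x` must be a genotype_matrix or haplotype_set", call. = FALSE)
  }
  if (by_deme) {
    if (is.null(deme) || length(unique(deme)) != 2) {
      stop("joint SFS needs a genotype matrix with exactly two demes",
           call. = FALSE)
    }
    ds <- sort(unique(deme))
    g1 <- x$g[deme == ds[1], , drop = FALSE]
    g2 <- x$g[deme == ds[2], , drop = FALSE]
    n1 <- 2L * nrow(g1); n2 <- 2L * nrow(g2)
    d1 <- colSums(g1, na.rm = TRUE); d2 <- colSums(g2, na.rm = TRUE)
    m <- matrix(0L, n1 + 1L, n2 + 1L)
    tt <- table(factor(d1, levels = 0:n1), factor(d2, levels = 0:n2))
    m[] <- as.integer(tt)
    return(structure(list(counts = m, n1 = n1, n2 = n2,
                          demes = ds), class = "joint_sfs"))
  }
  seg <- dac > 0 & dac < n
  xi <- tabulate(dac[seg], nbins = n - 1L)
  if (fold) {
    half <- floor(n / 2)
    folded <- xi[seq_len(half)]
    upper <- rev(xi)[seq_len(half)]          # xi[n-1], xi[n-2], ...
    add <- which(seq_len(half) != n - seq_len(half))
    folded[add] <- folded[add] + upper[add]
    xi <- folded
  }
  structure(list(counts = xi, n = n, folded = fold), class = "sfs")
}

#' Fold an unfolded site-frequency spectrum
#'
#' Pools `xi[i]` with `xi[n - i]`; the central class of an even-sized sample
#' is not doubled.
#'
#' @param sfs An unfolded `sfs` object.
#' @return A folded `sfs` object.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs"))
  if (sfs$folded) return(sfs)
  n <- sfs$n
  half <- floor(n / 2)
  xi <- sfs$counts[seq_len(half)]
  upper <- rev(sfs$counts)[seq_len(half)]
  add <- which(seq_len(half) != n - seq_len(half))
  xi[add] <- xi[add] + upper[add]
  structure(list(counts = xi, n = n, folded = TRUE), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("<sfs>", if (x$folded) "folded," else "unfolded,", "n =", x$n,
      "haplotypes, S =", sum(x$counts), "segregating sites\n")
  invisible(x)
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs>", x$n1, "x", x$n2, "haplotypes,",
      sum(x$counts), "sites (corners included)\n")
  invisible(x)
}

#' Watterson estimate of long-term Ne from segregating sites
#'
#' `theta_W = S / a_n` with `a_n = sum_{i=1}^{n-1} 1/i`, converted to an
#' effective size with `Ne = theta_W / (4 mu l)` where `mu l` is the total
#' per-generation mutation target of the surveyed sequence.
#'
#' @param sfs An `sfs` object (folded or unfolded; only the total number of
#'   segregating sites is used).
#' @param mu Mutation rate per bp per generation.
#' @param seq_length Total surveyed sequence length in bp.
#' @return A [ne_estimate] with `method = "sfs"` and `aux` containing
#'   `theta_w`, `S` and `a_n`. `S = 0` yields a zero/undefined flag
#'   (`point = Inf` is not used here; the estimate is `NA`-flagged via
#'   `aux$zero_theta`).
#' @export
watterson_ne <- function(sfs, mu, seq_length) {
  stopifnot(inherits(sfs, "sfs"))
  if (mu * seq_length <= 0) {
    stop("mutation target `mu * seq_length` must be positive", call. = FALSE)
  }
  if (sfs$n < 2) stop("need at least 2 haplotypes", call. = FALSE)
  s <- sum(sfs$counts)
  a_n <- sum(1 / seq_len(sfs$n - 1L))
  theta <- s / a_n
  aux <- list(theta_w = theta, S = s, a_n = a_n)
  if (s == 0) {
    aux$zero_theta <- 1
    return(ne_estimate(point = Inf, method = "sfs", aux = aux))
  }
  ne_estimate(point = theta / (4 * mu * seq_length), method = "sfs",
              aux = aux)
}

#' Write / read a site-frequency spectrum in dadi text format
#'
#' Standard three-line dadi/moments format. For a single population of `n`
#' haplotypes: a header `"<n+1> <unfolded|folded>"`, a line of `n + 1`
#' entries (counts for derived-allele frequencies `0 .. n`; the invariant
#' corner classes are written as 0), and a mask line of `n + 1` 0/1 entries
#' (1 = masked; the corners are masked). A joint SFS is written as a
#' `"<n1+1> <n2+1> <unfolded|folded>"` header with the matrix serialized
#' row-major, both corners (cell `[0, 0]` and `[n1, n2]`) masked.
#'
#' @param sfs An `sfs` or `joint_sfs` object.
#' @param path File path.
#' @return `write_dadi_sfs()` returns `path` invisibly; `read_dadi_sfs()`
#'   the reconstructed `sfs`/`joint_sfs` object.
#' @export
write_dadi_sfs <- function(sfs, path) {
  if (inherits(sfs, "sfs")) {
    n <- sfs$n
    full <- numeric(n + 1L)
    if (sfs$folded) {
      full[1L + seq_along(sfs$counts)] <- sfs$counts
    } else {
      full[2:n] <- sfs$counts
    }
    mask <- integer(n + 1L)
    mask[c(1L, n + 1L)] <- 1L
    if (sfs$folded) mask[(floor(n / 2) + 2L):(n + 1L)] <- 1L
    lines <- c(paste(n + 1L, if (sfs$folded) "folded" else "unfolded"),
               paste(format(full, trim = TRUE, scientific = FALSE),
                     collapse = " "),
               paste(mask, collapse = " "))
  } else if (inherits(sfs, "joint_sfs")) {
    m <- sfs$counts
    mask <- matrix(0L, nrow(m), ncol(m))
    mask[1, 1] <- 1L
    mask[nrow(m), ncol(m)] <- 1L
    lines <- c(paste(nrow(m), ncol(m), "unfolded"),
               paste(format(as.vector(t(m)), trim = TRUE,
                            scientific = FALSE), collapse = " "),
               paste(as.vector(t(mask)), collapse = " "))
  } else {
    stop("`sfs` must be an sfs or joint_sfs object", call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dadi_sfs
#' @export
read_dadi_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  dims <- suppressWarnings(as.integer(hdr))
  dims <- dims[!is.na(dims)]
  folded <- any(hdr == "folded")
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(dims) == 1L) {
    n <- dims - 1L
    if (length(vals) != dims) stop("dadi SFS: dimension mismatch", call. = FALSE)
    counts <- if (folded) vals[1L + seq_len(floor(n / 2))] else vals[2:n]
    structure(list(counts = counts, n = n, folded = folded), class = "sfs")
  } else if (length(dims) == 2L) {
    if (length(vals) != prod(dims)) stop("dadi SFS: dimension mismatch", call. = FALSE)
    m <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    structure(list(counts = m, n1 = dims[1] - 1L, n2 = dims[2] - 1L,
                   demes = c(1L, 2L)), class = "joint_sfs")
  } else {
    stop("dadi SFS: unsupported header", call. = FALSE)
  }
}
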