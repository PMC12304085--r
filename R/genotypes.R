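#' Genotype matrix with locus and sample metadata
#'
#' Diploid genotypes coded 0/1/2 (count of the derived or alternate
#' allele), individuals in rows and biallelic loci in columns, with a locus
#' table (`chrom`, `pos`, `ancestral`, `derived`) and a sample table
#' (`id` plus any extra columns such as `deme`). `NA` marks missing
#' genotypes.
#'
#' @param g Integer matrix (individuals x loci) with values 0, 1, 2 or NA.
#' @param loci Tibble with one row per locus: `chrom`, `pos` and optionally
#'   allele labels.
#' @param samples Tibble with one row per individual; must contain `id`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(g, loci, samples) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  loci <- tibble::as_tibble(loci)
  samples <- tibble::as_tibble(samples)
  if (nrow(loci) != ncol(g)) {
    stop("`loci` must have one row per column of `g`", call. = FALSE)
  }
  if (nrow(samples) != nrow(g)) {
    stop("`samples` must have one row per row of `g`", call. = FALSE)
  }
  if (!all(c("chrom", "pos") %in% names(loci))) {
    stop("`loci` needs columns `chrom` and `pos`", call. = FALSE)
  }
  if (!"id" %in% names(samples)) stop("`samples` needs column `id`", call. = FALSE)
  if (!"ancestral" %in% names(loci)) loci$ancestral <- "A"
  if (!"derived" %in% names(loci)) loci$derived <- "T"
  bad <- g[!is.na(g)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  }
  structure(list(g = g, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", nrow(x$g), "individuals x", ncol(x$g), "loci (",
      length(unique(x$loci$chrom)), "chromosome(s) )\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$g)

#' Minor- and derived-allele frequencies of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @return `allele_freq()`: per-locus frequency of the counted (derived)
#'   allele among non-missing genotypes; `maf()`: the corresponding minor
#'   allele frequency `pmin(p, 1 - p)`.
#' @export
allele_freq <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  colMeans(x$g, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

#' Subset individuals and loci of a genotype matrix
#'
#' Draws a random subset of loci among those whose minor-allele frequency
#' (computed in the retained individuals) is at least `maf_min`, optionally
#' keeping at most one locus per chromosome (so that retained loci are
#' physically independent). Individuals can be restricted first, so that
#' the frequency screen reflects the exported sample.
#'
#' @param x A [genotype_matrix()].
#' @param n_loci Number of loci to draw (uniformly, without replacement).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param sample_ids Optional individual ids to retain.
#' @param max_per_chrom Maximum number of retained loci per chromosome
#'   (`Inf` to disable; `1` enforces full physical independence).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] with `n_loci` columns.
#' @export
subset_loci <- function(x, n_loci, maf_min = 0.05, sample_ids = NULL,
                        max_per_chrom = Inf, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, x$samples$id)
    if (anyNA(idx)) {
      stop("sample id(s) not present: ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    x <- genotype_matrix(x$g[idx, , drop = FALSE], x$loci,
                         x$samples[idx, , drop = FALSE])
  }
  eligible <- which(maf(x) >= maf_min)
  if (is.finite(max_per_chrom)) {
    keep <- unlist(lapply(split(eligible, x$loci$chrom[eligible]),
                          function(ii) {
                            if (length(ii) <= max_per_chrom) ii else
                              sample(ii, max_per_chrom)
                          }), use.names = FALSE)
    eligible <- sort(keep)
  }
  if (length(eligible) < n_loci) {
    stop("locus shortfall: ", n_loci, " requested but only ",
         length(eligible), " eligible after MAF >= ", maf_min,
         if (is.finite(max_per_chrom))
           paste0(" and <= ", max_per_chrom, " per chromosome"),
         call. = FALSE)
  }
  pick <- sort(sample(eligible, n_loci))
  genotype_matrix(x$g[, pick, drop = FALSE], x$loci[pick, , drop = FALSE],
                  x$samples)
}

#' Collapse a haplotype set into diploid genotypes
#'
#' Adds the two haplotypes of every individual; requires the haplotype set
#' to carry the standard leaf table (two lineages per individual, as
#' produced by [simulate_genomes()]).
#'
#' @param hs A `haplotype_set` from [overlay_mutations()].
#' @param samples Optional sample table (`id`, ...) to attach.
#' @return A [genotype_matrix()].
#' @export
haplotypes_to_genotypes <- function(hs, samples = NULL) {
  stopifnot(inherits(hs, "haplotype_set"))
  lv <- hs$leaves
  if (!"individual" %in% names(lv)) {
    stop("haplotype set has no individual mapping (recap-only forest?)",
         call. = FALSE)
  }
  ids <- unique(lv$individual)
  first <- match(ids, lv$individual)
  g <- hs$hap[first, , drop = FALSE] + hs$hap[first + 1L, , drop = FALSE]
  loci <- dplyr::mutate(hs$sites, id = paste0("chr", .data$chrom, "_", .data$pos))
  if (is.null(samples)) samples <- tibble::tibble(id = ids)
  genotype_matrix(g, loci, samples)
}

#' Simulate genomes for the sampled individuals of a forward run
#'
#' End-to-end neutral genome generation: exact per-locus transmission
#' through the recorded pedigree (Mendelian inheritance with free
#' recombination between loci), Kingman recapitation of the remaining
#' founder lineages in a single merged ancestral population, and
#' infinite-sites mutation overlay. Returns diploid genotypes for the
#' sampled individuals together with their sampling metadata.
#'
#' @param sim A `sim_result` from [run_simulation()].
#' @param spec A [genome_spec()] with `linkage = "unlinked"`.
#' @param ancestral_ne Diploid size of the merged ancestral population;
#'   defaults to `n_demes` times the realized per-deme effective size
#'   computed from the recorded pedigree (the sum of the demes' effective
#'   sizes).
#' @param sample_ids Individuals to genotype (default: all sampled).
#' @param seed Integer seed for transmission, recapitation and mutations.
#' @return A [genotype_matrix()]; the sample table carries `deme`,
#'   `step_sampled` and `age_at_sampling`.
#' @export
simulate_genomes <- function(sim, spec, ancestral_ne = NULL,
                             sample_ids = NULL, seed = 1) {
  stopifnot(inherits(sim, "sim_result"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sim$samples$id
  if (is.null(ancestral_ne)) {
    ancestral_ne <- sim$config$n_demes * realized_ne(sim)$point
  }
  forest <- build_sample_forest(sim, spec, ancestral_ne, sample_ids)
  hs <- overlay_mutations(forest, spec)
  meta <- sim$samples[match(sample_ids, sim$samples$id), ]
  haplotypes_to_genotypes(hs, samples = meta)
}
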