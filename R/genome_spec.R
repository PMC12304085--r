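#' Genome specification
#'
#' Describes the simulated genome: chromosome lengths in bp, per-bp
#' recombination and mutation rates, and the linkage mode used when genomes
#' are generated for sampled individuals.
#'
#' * `linkage = "linked"`: chromosomes are transmitted with crossovers
#'   (Poisson along each chromosome at `recombination_rate` per bp per
#'   meiosis) and assort independently of one another.
#' * `linkage = "unlinked"`: every chromosome is a short, independently
#'   segregating locus (no internal recombination); this is the natural
#'   mode for estimators that assume fully independent loci.
#'
#' @param chromosomes Numeric vector of chromosome lengths in bp.
#' @param recombination_rate Per-bp, per-meiosis crossover rate.
#' @param mutation_rate Per-bp, per-generation mutation rate.
#' @param linkage `"linked"` or `"unlinked"`.
#' @return An object of class `genome_spec`.
#' @seealso [unlinked_genome()]
#' @export
genome_spec <- function(chromosomes = rep(5e7, 20), recombination_rate = 1e-8,
                        mutation_rate = 1e-8,
                        linkage = c("linked", "unlinked")) {
  linkage <- match.arg(linkage)
  if (any(chromosomes < 1)) stop("chromosome lengths must be >= 1 bp", call. = FALSE)
  if (recombination_rate < 0 || mutation_rate < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(chromosomes = as.numeric(chromosomes),
                 recombination_rate = recombination_rate,
                 mutation_rate = mutation_rate, linkage = linkage),
            class = "genome_spec")
}

#' @rdname genome_spec
#' @param n_loci Number of independent loci.
#' @param locus_length Length of each locus in bp (the mutation target per
#'   locus is `mutation_rate * locus_length`).
#' @export
unlinked_genome <- function(n_loci, locus_length = 5000,
                            mutation_rate = 1e-8) {
  genome_spec(chromosomes = rep(locus_length, n_loci),
              recombination_rate = 0, mutation_rate = mutation_rate,
              linkage = "unlinked")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chromosomes), " chromosome(s), total ",
      format(sum(x$chromosomes), big.mark = ","), " bp, r = ",
      x$recombination_rate, "/bp, mu = ", x$mutation_rate, "/bp/gen, ",
      x$linkage, "\n", sep = "")
  invisible(x)
}
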