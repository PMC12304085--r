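#' Crossover positions for one meiosis
#'
#' Crossover count per chromosome is Poisson(`rate * length`), positions
#' uniform along the chromosome.
#'
#' @param n Number of meioses to draw.
#' @param length Chromosome length in bp.
#' @param rate Per-bp crossover rate.
#' @return A list of `n` sorted numeric vectors of crossover positions.
#' @export
sim_crossovers <- function(n, length, rate) {
  k <- stats::rpois(n, rate * length)
  pos <- stats::runif(sum(k)) * length
  split_idx <- rep.int(seq_len(n), k)
  out <- rep(list(numeric(0)), n)
  if (sum(k) > 0) {
    sp <- split(pos, factor(split_idx, levels = seq_len(n)))
    out <- lapply(sp, sort)
  }
  out
}

#' Gene dropping: trace sampled genomes to founder haplotypes
#'
#' Transmits genome segments backwards through the recorded pedigree: at
#' every meiosis, crossovers are placed as a Poisson process along each
#' chromosome (see [sim_crossovers()]) and chromosomes assort
#' independently; the segments carried by each sampled haplotype are traced
#' until they reach a founder (an individual with no recorded parents). All
#' lineages that pass through the same meiosis share the same crossover
#' realization, so identity-by-descent sharing among relatives is exact.
#'
#' @param sim A `sim_result` from [run_simulation()] (or a pedigree tibble).
#' @param spec A [genome_spec()].
#' @param sample_ids Individuals whose genomes to trace (default: all
#'   sampled individuals).
#' @param seed Optional integer seed.
#' @return A tibble of class `gene_drop` with one row per ancestry segment:
#'   `individual`, `haplotype` (1 = maternal, 2 = paternal), `chrom`,
#'   `start`, `end` (0-based, half-open, bp) and `founder_hap` (global
#'   haplotype id `2 * founder - 1` or `2 * founder`). Segments of one
#'   haplotype tile each chromosome exactly.
#' @export
drop_genomes <- function(sim, spec, sample_ids = NULL, seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (inherits(sim, "sim_result")) {
    pedigree <- sim$pedigree
    if (is.null(sample_ids)) sample_ids <- sim$samples$id
  } else {
    pedigree <- sim
    if (is.null(sample_ids)) {
      stop("with a bare pedigree, supply `sample_ids`", call. = FALSE)
    }
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  pa <- ped_arrays(pedigree)
  n_chrom <- length(spec$chromosomes)
  H <- 2L * length(sample_ids)
  glob_hap <- as.integer(rbind(2L * sample_ids - 1L, 2L * sample_ids))
  # entry vectors: one per (sample haplotype, segment)
  e_sh <- rep(seq_len(H), each = n_chrom)
  e_chr <- rep(seq_len(n_chrom), H)
  e_start <- rep(0, H * n_chrom)
  e_end <- rep(spec$chromosomes, H)
  e_hap <- rep(glob_hap, each = n_chrom)
  e_birth <- pa$birth[(e_hap + 1L) %/% 2L]
  FOUNDER <- -.Machine$integer.max %/% 2L
  repeat {
    todo <- which(e_birth > 0L)
    if (!length(todo)) break
    t <- max(e_birth[todo])
    sel <- todo[e_birth[todo] == t]
    haps <- unique(e_hap[sel])
    ns_sh <- list(); ns_chr <- list(); ns_s <- list(); ns_e <- list()
    ns_hap <- list(); ci <- 0L
    for (h in haps) {
      owner <- (h + 1L) %/% 2L
      par <- if (h %% 2L == 1L) pa$mom[owner] else pa$dad[owner]
      if (is.na(par)) {
        stop("pedigree integrity error: non-founder ", owner,
             " lacks a recorded parent", call. = FALSE)
      }
      rows <- sel[e_hap[sel] == h]
      chrs <- unique(e_chr[rows])
      phase <- stats::rbinom(n_chrom, 1L, 0.5)
      bps <- sim_crossovers(length(chrs), spec$chromosomes[chrs],
                            spec$recombination_rate)
      for (k in seq_along(chrs)) {
        cc <- chrs[k]
        rws <- rows[e_chr[rows] == cc]
        bp <- bps[[k]]
        for (r in rws) {
          s <- e_start[r]; e <- e_end[r]
          cuts <- bp[bp > s & bp < e]
          bounds <- c(s, cuts, e)
          ph <- (phase[cc] + findInterval(bounds[-length(bounds)], bp)) %% 2L
          target <- 2L * par - 1L + ph
          # first piece stays in place, extra pieces become new entries
          e_end[r] <- bounds[2]
          e_hap[r] <- target[1]
          e_birth[r] <- if (pa$birth[par] > 0L) pa$birth[par] else FOUNDER
          if (length(bounds) > 2) {
            ci <- ci + 1L
            npc <- length(bounds) - 2L
            ns_sh[[ci]] <- rep(e_sh[r], npc)
            ns_chr[[ci]] <- rep(cc, npc)
            ns_s[[ci]] <- bounds[2:(length(bounds) - 1)]
            ns_e[[ci]] <- bounds[3:length(bounds)]
            ns_hap[[ci]] <- target[-1]
          }
        }
      }
    }
    if (ci > 0L) {
      new_hap <- unlist(ns_hap)
      e_sh <- c(e_sh, unlist(ns_sh)); e_chr <- c(e_chr, unlist(ns_chr))
      e_start <- c(e_start, unlist(ns_s)); e_end <- c(e_end, unlist(ns_e))
      e_hap <- c(e_hap, new_hap)
      nb <- pa$birth[(new_hap + 1L) %/% 2L]
      nb[nb <= 0L] <- FOUNDER
      e_birth <- c(e_birth, nb)
    }
  }
  out <- tibble::tibble(
    individual = sample_ids[(e_sh + 1L) %/% 2L],
    haplotype = 2L - (e_sh %% 2L),
    chrom = e_chr, start = e_start, end = e_end, founder_hap = e_hap
  )
  out <- dplyr::arrange(out, .data$individual, .data$haplotype, .data$chrom,
                        .data$start)
  class(out) <- c("gene_drop", class(out))
  out
}
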