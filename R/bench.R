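#' Factorial benchmark design
#'
#' The reference benchmark crosses migration rates {0.01, 0.05, 0.10} (3
#' replicate simulations each) with 12 post-processing subsets per
#' simulation: locus counts {1000, 10000, 30000} x per-deme sample sizes
#' {14, 50, 56, 140}, sampled at the final time step only -- 108 subsets in
#' total. Every simulation and every subset carries its own seed derived
#' deterministically from `base_seed`.
#'
#' @param migration Migration rates to simulate.
#' @param replicates Replicate simulations per migration rate.
#' @param loci Locus counts per subset.
#' @param sample_sizes Individuals per deme per subset.
#' @param base_seed Integer from which all seeds are derived.
#' @return A list of class `bench_design`.
#' @export
bench_design <- function(migration = c(0.01, 0.05, 0.10), replicates = 3,
                         loci = c(1000, 10000, 30000),
                         sample_sizes = c(14, 50, 56, 140),
                         base_seed = 2024) {
  structure(list(migration = migration, replicates = as.integer(replicates),
                 loci = as.integer(loci), sample_sizes = as.integer(sample_sizes),
                 base_seed = as.integer(base_seed)),
            class = "bench_design")
}

#' Enumerate the subsets of a benchmark design
#'
#' @param design A [bench_design()].
#' @return A tibble with one row per subset: `sim` (simulation index),
#'   `migration`, `replicate`, `n_loci`, `sample_size`, `sim_seed`,
#'   `subset_seed`. The row count is
#'   `length(migration) * replicates * length(loci) * length(sample_sizes)`.
#' @export
enumerate_design <- function(design) {
  stopifnot(inherits(design, "bench_design"))
  sims <- tidyr::expand_grid(migration = design$migration,
                             replicate = seq_len(design$replicates))
  sims$sim <- seq_len(nrow(sims))
  sims$sim_seed <- design$base_seed + 1000L * sims$sim
  out <- tidyr::expand_grid(sims, n_loci = design$loci,
                            sample_size = design$sample_sizes)
  out$subset <- seq_len(nrow(out))
  out$subset_seed <- out$sim_seed + match(out$n_loci, design$loci) * 100L +
    match(out$sample_size, design$sample_sizes)
  dplyr::select(out, "subset", "sim", "migration", "replicate", "n_loci",
                "sample_size", "sim_seed", "subset_seed")
}

#' Run the simulation benchmark
#'
#' Executes, for every simulation of the design: the forward demographic
#' simulation, genome generation for the final-step samples (unlinked
#' loci, recapitated in a merged ancestral population of size equal to the
#' summed realized per-deme effective sizes), then for every subset the
#' individual/locus subsetting and the requested estimators, separately per
#' deme. Failures of individual subsets are recorded as flagged rows and do
#' not abort the sweep.
#'
#' `scale` shrinks the scenario for desk-scale work: the cohort size is
#' `round(5000 * scale)` and the subset locus counts are
#' `round(n_loci * scale)`; requested sample sizes are capped at the number
#' of final-step samples available per deme (the actual size is reported).
#'
#' @param design A [bench_design()].
#' @param estimators Subset of `c("ld", "sfs-watterson")`.
#' @param scale Scenario scale in `(0, 1]`.
#' @param rates Vital rates (default [default_vital_rates()]).
#' @param locus_length Per-locus sequence length in bp for the simulated
#'   genomes (the number of candidate loci is chosen automatically so that
#'   enough polymorphic loci pass the MAF screen).
#' @param maf_min MAF screen applied when subsetting loci.
#' @param ld_refined Use the refined LD inversion (see [ld_ne_estimate()]).
#' @param cache_dir Optional directory; per-simulation intermediate results
#'   are stored there and reused on re-runs (making long sweeps resumable).
#' @param progress Print per-simulation progress.
#' @return A tibble of class `bench_result`: one row per (subset, deme,
#'   estimator) with the design coordinates, actual sizes, `ne`, `ci_low`,
#'   `ci_high`, `flag` (`"ok"`, `"infinite"` or `"error"`), `note` and
#'   `runtime_s`.
#' @export
run_benchmark <- function(design, estimators = c("ld", "sfs-watterson"),
                          scale = 1, rates = default_vital_rates(),
                          locus_length = NULL, maf_min = 0.05,
                          ld_refined = TRUE, cache_dir = NULL,
                          progress = FALSE) {
  stopifnot(inherits(design, "bench_design"))
  if (scale <= 0 || scale > 1) stop("`scale` must be in (0, 1]", call. = FALSE)
  estimators <- match.arg(estimators, c("ld", "sfs-watterson"),
                          several.ok = TRUE)
  subsets <- enumerate_design(design)
  subsets$n_loci_scaled <- pmax(2L, as.integer(round(subsets$n_loci * scale)))
  cohort <- max(20L, as.integer(round(5000 * scale)))
  rows <- list()
  for (s in unique(subsets$sim)) {
    sub_s <- subsets[subsets$sim == s, ]
    m <- sub_s$migration[1]
    if (progress) {
      message("simulation ", s, " (m = ", m, ", seed = ", sub_s$sim_seed[1], ")")
    }
    sim_data <- bench_sim_data(
      migration = m, seed = sub_s$sim_seed[1], cohort = cohort,
      rates = rates, max_loci = max(sub_s$n_loci_scaled),
      locus_length = locus_length, maf_min = maf_min, cache_dir = cache_dir
    )
    for (i in seq_len(nrow(sub_s))) {
      rows[[length(rows) + 1L]] <-
        bench_one_subset(sub_s[i, ], sim_data, estimators, maf_min,
                         ld_refined)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bench_result", class(out))
  out
}

# simulate one benchmark scenario and genotype the final-step samples
bench_sim_data <- function(migration, seed, cohort, rates, max_loci,
                           locus_length, maf_min, cache_dir) {
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(cache_dir,
                       sprintf("sim_m%s_seed%d_c%d.rds", migration, seed,
                               cohort))
    if (file.exists(cache)) return(readRDS(cache))
  }
  cfg <- sim_config(rates = rates, cohort_size = cohort, migration = migration,
                    n_steps = 100, sampling_steps = 90:100,
                    sampling_rate = 0.10, seed = seed)
  sim <- run_simulation(cfg)
  rne <- realized_ne(sim)
  anc_ne <- cfg$n_demes * rne$point
  # choose the per-locus mutation target so that roughly E[S] = 1 segregating
  # site per candidate locus, then take 3x more candidates than needed to
  # absorb the polymorphism and MAF screens
  final_ids <- sim$samples$id[sim$samples$step_sampled == 100]
  n_hap <- 2 * length(final_ids)
  a_n <- sum(1 / seq_len(max(n_hap - 1, 1)))
  mu <- 1e-8
  if (is.null(locus_length)) {
    locus_length <- max(1000, round(1 / (4 * anc_ne * mu * a_n)))
  }
  n_candidates <- max(4L * max_loci, 200L)
  spec <- unlinked_genome(n_candidates, locus_length, mu)
  geno <- simulate_genomes(sim, spec, ancestral_ne = anc_ne,
                           sample_ids = final_ids, seed = seed + 7L)
  out <- list(sim = sim, geno = geno, realized = rne, ancestral_ne = anc_ne,
              spec = spec, mu = mu, locus_length = locus_length,
              n_candidates = n_candidates)
  if (!is.null(cache_dir)) saveRDS(out, cache)
  out
}

bench_one_subset <- function(spec_row, sim_data, estimators, maf_min,
                             ld_refined) {
  geno <- sim_data$geno
  demes <- sort(unique(geno$samples$deme))
  out <- list()
  for (d in demes) {
    pool <- geno$samples$id[geno$samples$deme == d]
    n_take <- min(spec_row$sample_size, length(pool))
    withr_seed <- spec_row$subset_seed + d
    old <- get_rng_state(); set.seed(withr_seed)
    ids <- sample(pool, n_take)
    restore_rng_state(old)
    for (est in estimators) {
      t0 <- Sys.time()
      res <- tryCatch({
        if (est == "ld") {
          sub <- subset_loci(geno, spec_row$n_loci_scaled, maf_min = maf_min,
                             sample_ids = ids, max_per_chrom = 1L,
                             seed = withr_seed + 13L)
          ne <- ld_ne_estimate(ld_summary(sub, maf_min = maf_min),
                               refined = ld_refined)
          list(ne = ne, n_loci_actual = ncol(sub$g))
        } else {
          idx <- match(ids, geno$samples$id)
          gsub <- genotype_matrix(geno$g[idx, , drop = FALSE], geno$loci,
                                  geno$samples[idx, , drop = FALSE])
          sf <- compute_sfs(gsub)
          ne <- watterson_ne(sf, sim_data$mu,
                             sim_data$n_candidates * sim_data$locus_length)
          list(ne = ne, n_loci_actual = sum(sf$counts))
        }
      }, error = function(e) e)
      dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      if (inherits(res, "error")) {
        row <- tibble::tibble(ne = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, flag = "error",
                              note = conditionMessage(res),
                              n_loci_actual = NA_integer_)
      } else {
        fit <- res$ne
        row <- tibble::tibble(
          ne = fit$point, ci_low = fit$ci_low, ci_high = fit$ci_high,
          flag = if (is.finite(fit$point)) "ok" else "infinite",
          note = NA_character_, n_loci_actual = res$n_loci_actual
        )
      }
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        spec_row[, c("subset", "sim", "migration", "replicate", "n_loci",
                     "sample_size", "sim_seed", "subset_seed")],
        tibble::tibble(deme = d, sample_size_actual = n_take,
                       estimator = est),
        row,
        tibble::tibble(runtime_s = dt)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Seeded fixtures with known truth
#'
#' Small synthetic data sets used as estimator oracles:
#'
#' * `"wf-ideal"`: an ideal Wright-Fisher population (discrete generations,
#'   random mating with replacement) of `n` diploids evolved for `gens`
#'   generations from linkage equilibrium; returns a [genotype_matrix()] of
#'   a sample of `s` individuals whose metadata records the true `ne = n`.
#'   Loci are unlinked by default; passing `n_chrom` and `chrom_cM` places
#'   `n_loci / n_chrom` loci evenly on each chromosome and recombines with
#'   the Haldane map, giving physically linked panels.
#' * `"toy-pedigree"`: tiny pedigrees with known reproductive-success
#'   variance (`variant = "equal-rs"`: 4 parents with 2 offspring each,
#'   `Vk = 0`; `variant = "skewed"`: one parent with all 8 offspring).
#' * `"two-deme-small"`: a small two-deme forward simulation (`m`
#'   configurable) for migration/structure checks.
#'
#' @param kind Fixture type.
#' @param seed Integer seed.
#' @param ... Parameters of the chosen kind (see Details above): `n`, `s`,
#'   `n_loci`, `gens`, `p0`, `n_chrom`, `chrom_cM`, `variant`, `m`,
#'   `cohort`.
#' @return See above; the true parameter values are attached as attributes
#'   (`true_ne`, `true_vk`, ...).
#' @export
make_fixtures <- function(kind = c("wf-ideal", "toy-pedigree",
                                   "two-deme-small"), seed = 1, ...) {
  kind <- match.arg(kind)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  dots <- list(...)
  switch(kind,
    "wf-ideal" = do.call(fixture_wf, dots),
    "toy-pedigree" = do.call(fixture_toy_pedigree, dots),
    "two-deme-small" = do.call(fixture_two_deme, dots)
  )
}

fixture_wf <- function(n = 200, s = 100, n_loci = 500, gens = 15,
                       p0 = NULL, n_chrom = NULL, chrom_cM = NULL) {
  if (is.null(p0)) p0 <- stats::runif(n_loci, 0.2, 0.8)
  unlinked <- is.null(n_chrom)
  if (!unlinked) {
    per <- n_loci / n_chrom
    if (per != floor(per)) stop("`n_loci` must be a multiple of `n_chrom`",
                                call. = FALSE)
    chrom <- rep(seq_len(n_chrom), each = per)
    pos_cM <- rep(seq(0, chrom_cM, length.out = per), n_chrom)
    # Haldane recombination fraction between adjacent loci
    rfrac <- (1 - exp(-2 * diff(pos_cM) / 100)) / 2
    rfrac[diff(chrom) != 0] <- 0.5
  } else {
    chrom <- seq_len(n_loci)
    pos_cM <- rep(0, n_loci)
  }
  # haplotype population, 2n x L
  hap <- matrix(stats::rbinom(2 * n * n_loci, 1, rep(p0, each = 2 * n)),
                2 * n, n_loci)
  gamete <- function(parents) {
    h1 <- hap[2 * parents - 1, , drop = FALSE]
    h2 <- hap[2 * parents, , drop = FALSE]
    if (unlinked) {
      pick <- matrix(stats::runif(n * n_loci) < 0.5, n, n_loci)
    } else {
      sw <- matrix(stats::runif(n * (n_loci - 1)) <
                     rep(rfrac, each = n), n, n_loci - 1)
      cum <- t(apply(cbind(stats::runif(n) < 0.5, sw), 1, cumsum)) %% 2
      pick <- cum == 1
    }
    ifelse(pick, h1, h2)
  }
  for (g in seq_len(gens)) {
    mom <- sample.int(n, n, replace = TRUE)
    dad <- sample.int(n, n, replace = TRUE)
    hap <- rbind(gamete(mom), gamete(dad))[order(rep(seq_len(n), 2)), ]
  }
  take <- sample.int(n, s)
  g <- hap[2 * take - 1, , drop = FALSE] + hap[2 * take, , drop = FALSE]
  out <- genotype_matrix(
    g,
    tibble::tibble(chrom = chrom,
                   pos = if (unlinked) 1L else as.integer(pos_cM * 1e4 + 1)),
    tibble::tibble(id = seq_len(s), deme = 1L)
  )
  attr(out, "true_ne") <- n
  attr(out, "n_chrom") <- if (unlinked) n_loci else n_chrom
  out
}

fixture_toy_pedigree <- function(variant = c("equal-rs", "skewed")) {
  variant <- match.arg(variant)
  parents <- tibble::tibble(
    id = 1:4, sex = c("F", "M", "F", "M"), birth_step = 0L,
    deme_birth = 1L, mother_id = NA_integer_, father_id = NA_integer_,
    death_step = NA_integer_
  )
  # equal-rs: every parent of the birth-0 cohort has exactly 2 offspring;
  # skewed: one cohort member has all 8 offspring (the other parent sits
  # outside the cohort), giving lifetime counts {8, 0, 0, 0}
  if (variant == "equal-rs") {
    kids <- tibble::tibble(
      id = 5:8, sex = c("F", "M", "F", "M"), birth_step = 1L,
      deme_birth = 1L, mother_id = c(1L, 1L, 3L, 3L),
      father_id = c(2L, 2L, 4L, 4L), death_step = NA_integer_
    )
    extra <- NULL
    vk <- 0
  } else {
    extra <- tibble::tibble(
      id = 13L, sex = "M", birth_step = -1L, deme_birth = 1L,
      mother_id = NA_integer_, father_id = NA_integer_,
      death_step = NA_integer_
    )
    kids <- tibble::tibble(
      id = 5:12, sex = rep(c("F", "M"), 4), birth_step = 1L,
      deme_birth = 1L, mother_id = rep(1L, 8),
      father_id = rep(13L, 8), death_step = NA_integer_
    )
    vk <- 12
  }
  ped <- dplyr::bind_rows(parents, extra, kids)
  attr(ped, "true_vk") <- vk
  attr(ped, "parent_cohort") <- 0L
  ped
}

fixture_two_deme <- function(m = 0.5, cohort = 100, n_steps = 40,
                             seed = NULL) {
  a <- 3L
  rates <- vital_rates(survival = c(1, 0.6, 0.4),
                       fertility = c(0, 0, 0, 1),
                       maturity_age = 3)
  cfg <- sim_config(rates = rates, cohort_size = cohort, migration = m,
                    n_steps = n_steps,
                    sampling_steps = (n_steps - 2):n_steps,
                    sampling_rate = 0.2,
                    seed = if (is.null(seed)) 1L else seed)
  run_simulation(cfg)
}
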