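# Shared fixtures, built once per test run.

# Wright-Fisher-like schedule: one age class, everyone breeds at age 1.
wf_rates <- function() {
  vital_rates(survival = 1, fertility = c(0, 1), maturity_age = 1,
              label = "wf-toy")
}

# three-age toy schedule used across forward-simulation tests
toy_rates <- function() {
  vital_rates(survival = c(1, 0.6, 0.4), fertility = c(0, 0, 1, 2),
              maturity_age = 2, label = "toy")
}

# memoised moderate two-deme simulation reused by several test files
.cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.cache$sim)) {
    cfg <- sim_config(rates = default_vital_rates(), cohort_size = 300,
                      n_steps = 70, migration = 0.05,
                      sampling_steps = 60:70, sampling_rate = 0.10,
                      seed = 424242)
    .cache$sim <- run_simulation(cfg)
  }
  .cache$sim
}

# small genotype matrix with two demes for format round-trips
toy_genotypes <- function(missing = FALSE) {
  g <- matrix(c(0L, 1L, 2L, 1L,
                2L, 0L, 1L, 1L,
                1L, 1L, 0L, 2L,
                0L, 2L, 2L, 0L,
                1L, 0L, 1L, 2L,
                2L, 2L, 0L, 0L), nrow = 6, byrow = TRUE)
  if (missing) g[2, 3] <- NA
  genotype_matrix(
    g,
    tibble::tibble(chrom = c(1L, 1L, 2L, 2L), pos = c(10L, 500L, 7L, 99L)),
    tibble::tibble(id = paste0("ind", 1:6), deme = rep(1:2, each = 3))
  )
}

# genotype-level Wright-Fisher population with unlinked loci; returns the
# sampled genotype matrix (independent of the packaged wf-ideal fixture,
# which is haplotype-based -- this one serves as a second route)
wf_sample <- function(n, s, loci, gens = 15, p0 = NULL) {
  if (is.null(p0)) p0 <- stats::runif(loci, 0.2, 0.8)
  g <- matrix(stats::rbinom(n * loci, 2, rep(p0, each = n)), n, loci)
  for (t in seq_len(gens)) {
    mom <- sample.int(n, n, TRUE)
    dad <- sample.int(n, n, TRUE)
    gm <- matrix(stats::rbinom(n * loci, 1, g[mom, ] / 2), n, loci)
    gp <- matrix(stats::rbinom(n * loci, 1, g[dad, ] / 2), n, loci)
    g <- gm + gp
  }
  idx <- sample.int(n, s)
  genotype_matrix(g[idx, , drop = FALSE],
                  tibble::tibble(chrom = seq_len(loci), pos = 1L),
                  tibble::tibble(id = seq_len(s), deme = 1L))
}
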