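test_that("recapitation matches neutral coalescent expectations", {
  # a single lineage gains no coalescent branch length
  f1 <- recapitate(1, unlinked_genome(5), ancestral_ne = 100, seed = 1)
  expect_equal(total_branch_length(f1), rep(0, 5))

  # pairwise coalescence time averages 2N generations
  n_anc <- 150
  f2 <- recapitate(1:2, unlinked_genome(2500), ancestral_ne = n_anc, seed = 2)
  t2 <- root_time(f2)
  se <- 2 * n_anc / sqrt(2500)
  expect_lt(abs(mean(t2) - 2 * n_anc), 3.5 * se)

  # total tree length for n lineages averages 4N * sum(1/i)
  f3 <- recapitate(1:20, unlinked_genome(2000), ancestral_ne = n_anc, seed = 3)
  expected <- 4 * n_anc * sum(1 / (1:19))
  expect_lt(abs(mean(total_branch_length(f3)) - expected) / expected, 0.05)
})

test_that("mutation overlay is Poisson in the mutation target", {
  f <- recapitate(1:20, unlinked_genome(400, 1e5, 1e-7), 400, seed = 4)
  # zero rate, zero variants
  hs0 <- overlay_mutations(f, 0, seed = 5)
  expect_equal(ncol(hs0$hap), 0)
  # Watterson expectation for the segregating-site count
  theta <- 4 * 400 * 1e-7 * 1e5
  expected_s <- theta * sum(1 / (1:19)) * 400
  hs <- overlay_mutations(f, 1e-7, seed = 6)
  expect_lt(abs(ncol(hs$hap) - expected_s) / expected_s, 0.05)
  # doubling the rate doubles the variant count
  hs2 <- overlay_mutations(f, 2e-7, seed = 7)
  expect_lt(abs(ncol(hs2$hap) / ncol(hs$hap) - 2), 0.1)
})

test_that("crossover counts per meiosis are Poisson", {
  set.seed(8)
  xs <- sim_crossovers(10000, 1e8, 1e-8)
  k <- lengths(xs)
  expect_lt(abs(mean(k) - 1), 0.05)
  obs <- c(sum(k == 0), sum(k == 1), sum(k == 2), sum(k >= 3))
  p <- c(dpois(0:2, 1), 1 - ppois(2, 1))
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("gene dropping reaches only the parents' founder haplotypes", {
  ped <- tibble::tibble(
    id = 1:3, sex = c("F", "M", "F"), birth_step = c(0L, 0L, 5L),
    deme_birth = 1L, mother_id = c(NA, NA, 1L), father_id = c(NA, NA, 2L),
    death_step = NA_integer_
  )
  spec <- genome_spec(chromosomes = 1e6, recombination_rate = 1e-7)
  segs <- drop_genomes(ped, spec, sample_ids = 3L, seed = 9)
  mat <- segs[segs$haplotype == 1, ]
  pat <- segs[segs$haplotype == 2, ]
  expect_true(all(mat$founder_hap %in% c(1, 2)))  # mother's two haplotypes
  expect_true(all(pat$founder_hap %in% c(3, 4)))  # father's two haplotypes

  # zero recombination: one segment per haplotype per chromosome
  spec0 <- genome_spec(chromosomes = c(5e5, 5e5), recombination_rate = 0)
  segs0 <- drop_genomes(ped, spec0, sample_ids = 3L, seed = 10)
  expect_equal(nrow(segs0), 4)  # 2 haplotypes x 2 chromosomes
  expect_true(all(segs0$start == 0 & segs0$end == 5e5))
})

test_that("ancestry segments tile every chromosome without gaps or overlaps", {
  res <- shared_sim()
  set.seed(12)
  ids <- sample(res$samples$id, 12)
  spec <- genome_spec(chromosomes = c(2e7, 1e7), recombination_rate = 1e-8)
  segs <- drop_genomes(res, spec, sample_ids = ids, seed = 13)
  by_hap <- split(segs, list(segs$individual, segs$haplotype, segs$chrom),
                  drop = TRUE)
  for (b in by_hap) {
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], spec$chromosomes[b$chrom[1]])
    if (nrow(b) > 1) {
      expect_equal(b$start[-1], b$end[-nrow(b)])
    }
  }
  # founder haplotypes belong to founders
  founders <- res$pedigree$id[is.na(res$pedigree$mother_id)]
  expect_true(all((segs$founder_hap + 1) %/% 2 %in% founders))
})

test_that("recapitation-only samples show the 1/i frequency spectrum", {
  n <- 50
  f <- recapitate(seq_len(n), unlinked_genome(1200, 5e4, 1e-8), 500,
                  seed = 14)
  hs <- overlay_mutations(f, 1e-8, seed = 15)
  sf <- compute_sfs(hs)
  expect_equal(sum(sf$counts), ncol(hs$hap))
  xi <- sf$counts
  p <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  # pool the rare upper tail for a stable chi-square
  cut <- 25
  obs <- c(xi[1:cut], sum(xi[(cut + 1):(n - 1)]))
  pp <- c(p[1:cut], sum(p[(cut + 1):(n - 1)]))
  expect_gt(stats::chisq.test(obs, p = pp)$p.value, 0.01)
})

test_that("pedigree-phase coalescences respect relatedness", {
  # full sibs share a parental haplotype at ~half their loci; unrelated
  # founder pairs share none inside the pedigree
  ped <- tibble::tibble(
    id = 1:4, sex = c("F", "M", "F", "M"),
    birth_step = c(0L, 0L, 5L, 5L), deme_birth = 1L,
    mother_id = c(NA, NA, 1L, 1L), father_id = c(NA, NA, 2L, 2L),
    death_step = NA_integer_
  )
  sim <- structure(list(
    pedigree = ped,
    samples = tibble::tibble(id = 3:4, step_sampled = 5L,
                             age_at_sampling = 0L, deme = 1L),
    census = NULL, migrations = NULL,
    config = sim_config(rates = wf_rates(), cohort_size = 2, n_steps = 5,
                        seed = 1)
  ), class = "sim_result")
  g <- simulate_genomes(sim, unlinked_genome(800, 2e4, 1e-7),
                        ancestral_ne = 50, seed = 16)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(nrow(g$g), 2)
  # additivity: dosage built from two haplotypes
  expect_true(all(g$g %in% 0:2))
})

test_that("subsetting loci honours the MAF screen and shortfall contract", {
  set.seed(17)
  x <- wf_sample(100, 60, 300, gens = 8)
  eligible <- which(maf(x) >= 0.1)
  sub <- subset_loci(x, min(50, length(eligible)), maf_min = 0.1, seed = 18)
  expect_equal(ncol(sub$g), min(50, length(eligible)))
  expect_true(all(maf(sub) >= 0.1))
  # the eligible set equals a brute-force frequency filter
  p <- colMeans(x$g) / 2
  expect_equal(eligible, which(pmin(p, 1 - p) >= 0.1))
  expect_error(subset_loci(x, 1e6, maf_min = 0.1), "shortfall")
  # per-chromosome thinning caps retained loci per chromosome
  sub1 <- subset_loci(x, 20, maf_min = 0.1, max_per_chrom = 1, seed = 19)
  expect_true(all(table(sub1$loci$chrom) == 1))
})

test_that("same seed reproduces the whole genome pipeline", {
  res <- shared_sim()
  ids <- utils::head(res$samples$id[res$samples$step_sampled == 70], 20)
  spec <- unlinked_genome(150, 2000, 1e-8)
  g1 <- simulate_genomes(res, spec, ancestral_ne = 1000, sample_ids = ids,
                         seed = 20)
  g2 <- simulate_genomes(res, spec, ancestral_ne = 1000, sample_ids = ids,
                         seed = 20)
  expect_identical(g1$g, g2$g)
  expect_identical(g1$loci, g2$loci)
})
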