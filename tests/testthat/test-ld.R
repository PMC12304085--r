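test_that("Burrows r2 detects perfect association regardless of coding", {
  g <- cbind(a = c(0L, 1L, 2L, 1L, 0L, 2L), b = c(0L, 1L, 2L, 1L, 0L, 2L))
  x <- genotype_matrix(g, tibble::tibble(chrom = 1:2, pos = 1L),
                       tibble::tibble(id = 1:6))
  out <- burrows_r2(x, 1, 2)
  expect_equal(out$r2, 1)
  expect_gt(out$delta, 0)

  # complement coding flips the sign of delta but not r2
  x2 <- genotype_matrix(cbind(g[, 1], 2L - g[, 1]),
                        tibble::tibble(chrom = 1:2, pos = 1L),
                        tibble::tibble(id = 1:6))
  out2 <- burrows_r2(x2, 1, 2)
  expect_equal(out2$r2, 1)
  expect_lt(out2$delta, 0)
})

test_that("Burrows statistics equal a direct evaluation of the formula", {
  # printed toy table: six diploid genotypes at two loci
  ga <- c(0L, 1L, 2L, 1L, 0L, 1L)
  gb <- c(1L, 1L, 2L, 0L, 0L, 2L)
  x <- genotype_matrix(cbind(ga, gb), tibble::tibble(chrom = 1:2, pos = 1L),
                       tibble::tibble(id = 1:6))
  out <- burrows_r2(x, 1, 2)
  # independent brute-force evaluation
  n <- 6
  delta <- (sum(ga * gb) / n - (sum(ga) / n) * (sum(gb) / n)) / 2
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  da <- pa * (1 - pa) + (mean(ga == 2) - pa^2)
  db <- pb * (1 - pb) + (mean(gb == 2) - pb^2)
  expect_equal(out$delta, delta)
  expect_equal(out$r2, delta^2 / (da * db))
  expect_equal(out$s_pair, 6)

  # invariance to individual ordering
  perm <- c(4, 2, 6, 1, 5, 3)
  xp <- genotype_matrix(cbind(ga, gb)[perm, ],
                        tibble::tibble(chrom = 1:2, pos = 1L),
                        tibble::tibble(id = 1:6))
  expect_equal(burrows_r2(xp, 1, 2)$r2, out$r2)
})

test_that("pair sets follow the pairing policy", {
  g <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L, 0L, 2L, 2L, 0L,
                2L, 0L, 1L, 1L, 2L, 0L, 0L, 2L, 1L, 0L, 1L, 2L), 6)
  x3 <- genotype_matrix(g[, 1:3], tibble::tibble(chrom = 1:3, pos = 1L),
                        tibble::tibble(id = 1:6))
  expect_equal(ld_summary(x3, maf_min = 0)$n_pairs, 3)
  x4 <- genotype_matrix(g, tibble::tibble(chrom = c(1, 1, 2, 2), pos = 1:4),
                        tibble::tibble(id = 1:6))
  expect_equal(ld_summary(x4, maf_min = 0, policy = "between-chrom")$n_pairs, 4)
  expect_error(ld_summary(x3, maf_min = 0.51), "MAF screen")
})

test_that("missing genotypes use per-pair complete cases", {
  x <- toy_genotypes(missing = TRUE)
  sm <- ld_summary(x, maf_min = 0)
  expect_lt(sm$harmonic_s, 6)
  pair <- burrows_r2(x, 1, 3)
  expect_equal(pair$s_pair, 5)
})

test_that("the estimator inverts the drift-plus-sampling expectation", {
  mk <- function(r2, s) structure(
    list(n_loci = 100, n_pairs = 4950, mean_r2 = r2, harmonic_s = s,
         policy = "all", maf_min = 0.05), class = "ld_summary")
  # exact inversion identity
  est <- ld_ne_estimate(mk(1 / (3 * 500) + 1 / 80, 80))
  expect_equal(est$point, 500, tolerance = 1e-9)
  # no drift signal: flagged infinite
  est_inf <- ld_ne_estimate(mk(1 / 80, 80))
  expect_identical(est_inf$point, Inf)
  # negative signal keeps the raw inversion in aux
  est_neg <- ld_ne_estimate(mk(0.9 / 80, 80))
  expect_identical(est_neg$point, Inf)
  expect_lt(est_neg$aux$raw_ne, 0)
  # monotonicity: more LD, smaller Ne
  e1 <- ld_ne_estimate(mk(0.013, 100))$point
  e2 <- ld_ne_estimate(mk(0.015, 100))$point
  expect_gt(e1, e2)
})

test_that("mean r2 on an ideal population matches drift plus sampling", {
  set.seed(31)
  ne <- 150; s <- 75
  r2s <- vapply(1:25, function(r) {
    x <- wf_sample(ne, s, 300, gens = 12)
    ld_summary(x, maf_min = 0.05)$mean_r2
  }, numeric(1))
  expected <- 1 / (3 * ne) + 1 / s
  expect_lt(abs(mean(r2s) - expected) / expected, 0.05)
})

test_that("the LD estimator recovers a known Ne", {
  set.seed(32)
  ne <- 150; s <- 75
  est <- vapply(1:25, function(r) {
    x <- wf_sample(ne, s, 400, gens = 12)
    ld_ne_estimate(ld_summary(x, maf_min = 0.05), refined = TRUE)$point
  }, numeric(1))
  expect_lt(abs(stats::median(est) - ne) / ne, 0.15)
})

test_that("jackknife intervals behave sensibly", {
  # degenerate input: identical (all-heterozygote) individuals carry no
  # covariance signal, so the pseudo-values cannot vary
  g <- matrix(1L, 12, 3)
  x <- genotype_matrix(g, tibble::tibble(chrom = 1:3, pos = 1L),
                       tibble::tibble(id = 1:12))
  jk <- suppressWarnings(jackknife_ci(x, maf_min = 0, policy = "all"))
  expect_true(attr(jk, "degenerate"))

  expect_error(jackknife_ci(toy_genotypes(), maf_min = 0), "at least 10")

  # width shrinks as individuals are added (fixed locus panel)
  set.seed(33)
  widths <- vapply(c(30, 60, 120), function(n) {
    mean(vapply(1:4, function(r) {
      x <- wf_sample(200, n, 200, gens = 10)
      jk <- jackknife_ci(x, maf_min = 0.05)
      th <- 1 / pmax(jk, 1e-12)  # width on the drift-signal scale
      th["low"] - th["high"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # nominal 95% interval covers the truth most of the time
  set.seed(34)
  cover <- mean(vapply(1:20, function(r) {
    x <- wf_sample(150, 60, 250, gens = 12)
    jk <- jackknife_ci(x, maf_min = 0.05)
    is.finite(jk["low"]) && jk["low"] <= 150 &&
      (is.infinite(jk["high"]) || jk["high"] >= 150)
  }, logical(1)))
  expect_gte(cover, 0.6)
})

test_that("physical-linkage correction adjusts upward and vanishes in the limit", {
  expect_equal(linkage_correction(1000, n_chromosomes = 1e6), 1000,
               ignore_attr = TRUE)
  c4 <- linkage_correction(1000, n_chromosomes = 4)
  c20 <- linkage_correction(1000, n_chromosomes = 20)
  expect_gt(c4, c20)
  expect_gt(c20, 1000)
  expect_error(linkage_correction(1000), "cannot correct")
  expect_error(linkage_correction(Inf, n_chromosomes = 4), "finite")
  # genome size in cM is accepted as an alternative
  expect_equal(linkage_correction(1000, genome_cM = 400),
               linkage_correction(1000, n_chromosomes = 4))
})

test_that("linked panels bias the raw estimate low; the correction helps", {
  set.seed(35)
  ne <- 200
  raw <- corr <- betw <- numeric(3)
  for (r in 1:3) {
    x <- make_fixtures("wf-ideal", seed = 35 + r, n = ne, s = 100,
                       n_loci = 600, gens = 20, n_chrom = 4, chrom_cM = 100)
    sm_all <- ld_summary(x, maf_min = 0.05, policy = "all")
    raw[r] <- ld_ne_estimate(sm_all, refined = TRUE)$point
    corr[r] <- linkage_correction(raw[r], n_chromosomes = 4)
    sm_b <- ld_summary(x, maf_min = 0.05, policy = "between-chrom")
    betw[r] <- ld_ne_estimate(sm_b, refined = TRUE)$point
  }
  # physical linkage biases the all-pairs estimate below the truth
  expect_lt(mean(raw), ne)
  # the correction moves it closer
  expect_lt(abs(mean(corr) - ne), abs(mean(raw) - ne))
  # between-chromosome pairs are nearly unbiased without any correction
  expect_lt(abs(mean(betw) - ne) / ne, 0.35)
})
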