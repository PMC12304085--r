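test_that("the SFS tallies derived-allele counts exactly", {
  hap <- matrix(c(1, 0, 0,   # site 1: count 1
                  0, 1, 0,   # site 2: count 1
                  1, 1, 0,   # site 3: count 2
                  0, 0, 1),  # site 4: count 1
                nrow = 3)
  hs <- structure(list(hap = hap,
                       sites = tibble::tibble(chrom = 1:4, pos = 1L,
                                              locus = 1:4),
                       leaves = NULL), class = "haplotype_set")
  sf <- compute_sfs(hs)
  expect_equal(sf$counts, c(3, 1))
  expect_equal(sf$n, 3)

  # monomorphic input: all-zero spectrum
  x0 <- genotype_matrix(matrix(2L, 4, 3),
                        tibble::tibble(chrom = 1:3, pos = 1L),
                        tibble::tibble(id = 1:4))
  expect_true(all(compute_sfs(x0)$counts == 0))

  # total equals the segregating-site count of a genotype matrix
  set.seed(41)
  x <- wf_sample(80, 40, 200, gens = 6)
  sf2 <- compute_sfs(x)
  expect_equal(sum(sf2$counts), sum(maf(x) > 0))
})

test_that("folding pools complementary classes", {
  set.seed(42)
  x <- wf_sample(60, 30, 150, gens = 6)
  unf <- compute_sfs(x)
  fol <- compute_sfs(x, fold = TRUE)
  expect_equal(fold_sfs(unf)$counts, fol$counts)
  n <- unf$n
  expect_equal(fol$counts[1], unf$counts[1] + unf$counts[n - 1])
  # the central class of an even sample is not doubled
  expect_equal(fol$counts[n / 2], unf$counts[n / 2])
  expect_equal(sum(fol$counts), sum(unf$counts))
})

test_that("Watterson estimator matches the closed form", {
  sf <- structure(list(counts = c(5, 4, 2), n = 4, folded = FALSE),
                  class = "sfs")
  est <- watterson_ne(sf, mu = 1e-8, seq_length = 1e6)
  expect_equal(est$aux$theta_w, 11 / (1 + 1 / 2 + 1 / 3))
  expect_equal(est$aux$theta_w, 6)
  expect_equal(est$point, 6 / (4 * 1e-8 * 1e6))

  sf0 <- structure(list(counts = c(0, 0, 0), n = 4, folded = FALSE),
                   class = "sfs")
  est0 <- watterson_ne(sf0, 1e-8, 1e6)
  expect_equal(est0$aux$theta_w, 0)
  expect_equal(est0$aux$zero_theta, 1)
  expect_error(watterson_ne(sf, mu = 0, seq_length = 1e6), "positive")
})

test_that("Watterson Ne recovers a constant population size", {
  n_anc <- 300
  nes <- vapply(1:40, function(r) {
    f <- recapitate(1:30, unlinked_genome(120, 2e4, 1e-8), n_anc,
                    seed = 100 + r)
    hs <- overlay_mutations(f, 1e-8, seed = 200 + r)
    watterson_ne(compute_sfs(hs), 1e-8, 120 * 2e4)$point
  }, numeric(1))
  expect_lt(abs(mean(nes) - n_anc) / n_anc, 0.1)
})

test_that("dadi export writes the documented format and round-trips", {
  sf <- structure(list(counts = c(3, 1), n = 3, folded = FALSE),
                  class = "sfs")
  path <- withr::local_tempfile(fileext = ".fs")
  write_dadi_sfs(sf, path)
  lines <- readLines(path)
  expect_equal(lines[1], "4 unfolded")
  expect_equal(lines[2], "0 3 1 0")
  expect_equal(lines[3], "1 0 0 1")
  back <- read_dadi_sfs(path)
  expect_equal(back$counts, sf$counts)
  expect_equal(back$n, 3)

  # folded export pools by the fold definition
  set.seed(43)
  x <- wf_sample(60, 25, 100, gens = 6)
  fol <- compute_sfs(x, fold = TRUE)
  write_dadi_sfs(fol, path)
  expect_equal(read_dadi_sfs(path)$counts, fol$counts)
})

test_that("the joint SFS has the documented dimensions and round-trips", {
  set.seed(44)
  g <- matrix(rbinom(10 * 40, 2, 0.3), 10, 40)
  x <- genotype_matrix(g, tibble::tibble(chrom = seq_len(40), pos = 1L),
                       tibble::tibble(id = 1:10, deme = rep(1:2, each = 5)))
  js <- compute_sfs(x, by_deme = TRUE)
  expect_equal(dim(js$counts), c(11, 11))
  expect_equal(sum(js$counts), 40)
  path <- withr::local_tempfile(fileext = ".fs")
  write_dadi_sfs(js, path)
  back <- read_dadi_sfs(path)
  expect_equal(back$counts, unname(js$counts))
  expect_equal(c(back$n1, back$n2), c(10, 10))
})
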