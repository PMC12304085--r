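test_that("equilibrium age structure follows cumulative survivorship", {
  # identity survival: every class equals the cohort
  r <- vital_rates(survival = c(1, 1, 1), fertility = c(0, 0, 1, 1),
                   maturity_age = 2)
  st <- equilibrium_age_structure(r, 100)
  expect_equal(st$count, rep(100, 4))
  expect_equal(attr(st, "total"), 400)

  # powers of one half
  r2 <- vital_rates(survival = c(1, 0.5, 0.5), fertility = c(0, 0, 1, 1),
                    maturity_age = 2)
  st2 <- equilibrium_age_structure(r2, 8)
  expect_equal(st2$count, c(8, 8, 4, 2))
  expect_equal(attr(st2, "total"), 22)

  # scale equivariance of the real-valued counts
  st3 <- equilibrium_age_structure(r2, 16)
  expect_equal(st3$count, 2 * st2$count)
  expect_equal(sum(st3$count), 2 * sum(st2$count))
})

test_that("vital-rates validation rejects malformed schedules", {
  expect_error(vital_rates(survival = c(1, 1.2), fertility = c(0, 0, 1),
                           maturity_age = 2), "\\[0, 1\\]")
  expect_error(vital_rates(survival = c(1, 1), fertility = c(0, 1, 1),
                           maturity_age = 2), "below `maturity_age`")
  expect_error(vital_rates(survival = c(1, 1), fertility = c(0, 0, 0),
                           maturity_age = 2), "positive fertility")
})

test_that("generation length is the mean age of parents", {
  # semelparous: all reproduction at age 1
  expect_equal(generation_length(wf_rates()), 1)

  # two reproductive ages with equal weight average to their midpoint
  r <- vital_rates(survival = rep(1, 6),
                   fertility = c(0, 0, 0, 0, 1, 0, 1), maturity_age = 4)
  expect_equal(generation_length(r), 5)
})

test_that("theoretical Ne reduces to census size for discrete generations", {
  est <- theoretical_ne(wf_rates(), 500)
  expect_s3_class(est, "ne_estimate")
  expect_lt(abs(est$point - 500) / 500, 0.01)
  expect_equal(est$aux$T, 1)
})

test_that("theoretical Ne is invariant to rescaling fertility weights", {
  r1 <- toy_rates()
  r2 <- vital_rates(survival = r1$survival, fertility = r1$fertility * 7.3,
                    maturity_age = r1$maturity_age)
  expect_equal(theoretical_ne(r1, 1000)$point, theoretical_ne(r2, 1000)$point)
})

test_that("analytic lifetime RS variance matches the Monte-Carlo cohort oracle", {
  r <- default_vital_rates()
  ana <- lifetime_rs_moments(r, 5000, method = "analytic")
  mc <- lifetime_rs_moments(r, 5000, method = "montecarlo", nrep = 60,
                            seed = 7)
  expect_equal(ana$mean_k, 2, tolerance = 1e-10)
  expect_lt(abs(mc$mean_k - 2), 0.02)
  expect_lt(abs(ana$var_k - mc$var_k) / ana$var_k, 0.01)
})

test_that("reconstructed schedule keeps Ne below census abundance", {
  r <- default_vital_rates()
  st <- equilibrium_age_structure(r, 5000)
  ne <- theoretical_ne(r, 5000)$point
  expect_lt(ne / attr(st, "total"), 1)
  expect_equal(ne / attr(st, "total"), 3314 / 17710, tolerance = 0.001)
  # survival probabilities are a proper schedule
  expect_true(all(r$survival >= 0 & r$survival <= 1))
  expect_identical(r$label, "reconstructed")
})

test_that("vital-rates config files round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".txt")
  r <- default_vital_rates()
  write_vital_rates(r, path)
  r2 <- read_vital_rates(path)
  expect_identical(r2$survival, r$survival)
  expect_identical(r2$fertility, r$fertility)
  expect_identical(r2$maturity_age, r$maturity_age)
  expect_identical(r2$sex_ratio, r$sex_ratio)

  # packaged config agrees with the in-code reconstruction
  pkg <- read_vital_rates(system.file("extdata",
                                      "vital_rates_reconstructed.txt",
                                      package = "nesim"))
  expect_equal(pkg$survival, r$survival)

  # schema violations are rejected
  lines <- readLines(path)
  writeLines(lines[-2], path)  # drop max_age
  expect_error(read_vital_rates(path), "missing keys")
})
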