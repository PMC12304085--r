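test_that("initial population matches equilibrium counts", {
  r <- vital_rates(survival = c(1, 1), fertility = c(0, 0, 1),
                   maturity_age = 2)
  cfg <- sim_config(rates = r, cohort_size = 10, n_demes = 1, n_steps = 5,
                    seed = 3)
  set.seed(3)
  st <- init_population(cfg)
  expect_length(st$id, 30)  # 10 per age class 0..2
  expect_true(all(st$deme == 1L))
})

test_that("runs are reproducible and seed-dependent", {
  cfg <- sim_config(rates = toy_rates(), cohort_size = 60, n_steps = 15,
                    sampling_steps = 12:15, sampling_rate = 0.2, seed = 9)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$samples, b$samples)
  expect_identical(a$census, b$census)
  cfg2 <- cfg; cfg2$seed <- 10L
  c2 <- run_simulation(cfg2)
  expect_false(identical(a$pedigree$mother_id, c2$pedigree$mother_id))
})

test_that("zero migration keeps the demes' pedigrees closed", {
  cfg <- sim_config(rates = toy_rates(), cohort_size = 80, n_steps = 20,
                    migration = 0, seed = 5, sampling_steps = integer(0))
  res <- run_simulation(cfg)
  expect_equal(nrow(res$migrations), 0)
  ped <- res$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  expect_true(all(ped$deme_birth[kids$mother_id] == kids$deme_birth))
  expect_true(all(ped$deme_birth[kids$father_id] == kids$deme_birth))
})

test_that("pedigree is acyclic with legal parental ages", {
  res <- shared_sim()
  ped <- res$pedigree
  kids <- ped[!is.na(ped$mother_id), ]
  alpha <- res$config$rates$maturity_age
  expect_true(all(ped$birth_step[kids$mother_id] <= kids$birth_step - alpha))
  expect_true(all(ped$birth_step[kids$father_id] <= kids$birth_step - alpha))
  # exact recruitment: every deme gains cohort_size newborns per step
  born <- dplyr::count(kids, .data$birth_step, .data$deme_birth)
  expect_true(all(born$n == res$config$cohort_size))
})

test_that("census stays near the equilibrium abundance after burn-in", {
  res <- shared_sim()
  k <- attr(equilibrium_age_structure(res$config$rates,
                                      res$config$cohort_size), "total")
  late <- res$census[res$census$step >= 20, ]
  per_deme <- tapply(late$count, late$deme, mean)
  expect_true(all(abs(per_deme - k) / k < 0.01))
})

test_that("sampling respects the per-class rate and never recaptures", {
  res <- shared_sim()
  expect_false(any(duplicated(res$samples$id)))
  expect_true(all(res$samples$age_at_sampling >= 1))
  expect_true(all(res$samples$step_sampled %in% 60:70))

  # rate 0 gives empty samples
  cfg0 <- sim_config(rates = toy_rates(), cohort_size = 50, n_steps = 6,
                     sampling_steps = 5:6, sampling_rate = 0, seed = 2)
  expect_equal(nrow(run_simulation(cfg0)$samples), 0)

  # rate 1 samples every individual aged >= 1 exactly once over the window
  cfg1 <- sim_config(rates = toy_rates(), cohort_size = 40, n_demes = 1,
                     n_steps = 8, sampling_steps = 6:8, sampling_rate = 1,
                     seed = 2)
  res1 <- run_simulation(cfg1)
  expect_false(any(duplicated(res1$samples$id)))
  alive_at_6 <- with(res1$pedigree,
                     id[birth_step <= 5 &
                          (is.na(death_step) | death_step > 6)])
  # everyone alive and aged 1+ at the first sampling step must be captured
  ages6 <- 6 - res1$pedigree$birth_step[alive_at_6]
  expect_true(all(alive_at_6[ages6 >= 1] %in% res1$samples$id))
})

test_that("Poisson recruitment varies the cohort size around its mean", {
  cfg <- sim_config(rates = toy_rates(), cohort_size = 50, n_demes = 1,
                    n_steps = 25, recruitment = "poisson",
                    sampling_steps = integer(0), seed = 6)
  res <- run_simulation(cfg)
  born <- dplyr::count(dplyr::filter(res$pedigree, .data$birth_step > 0),
                       .data$birth_step)
  expect_gt(stats::var(born$n), 0)
  expect_lt(abs(mean(born$n) - 50), 3 * sqrt(50 / 25))
})

test_that("a deme without mature mates raises an extinction error", {
  r <- toy_rates()
  cfg <- sim_config(rates = r, cohort_size = 20, n_demes = 1, n_steps = 2,
                    seed = 1)
  cfg$rates$sex_ratio <- 0  # all newborns female
  set.seed(1)
  st <- init_population(cfg)
  st$sex[] <- 0L  # no males anywhere
  expect_error(sim_step(st, cfg), "no mature males")
})

test_that("zero steps yield a founders-only pedigree and no samples", {
  cfg <- sim_config(rates = toy_rates(), cohort_size = 30, n_steps = 0,
                    seed = 4)
  res <- run_simulation(cfg)
  expect_true(all(is.na(res$pedigree$mother_id)))
  expect_equal(nrow(res$samples), 0)
})

test_that("pedigree export round-trips", {
  res <- run_simulation(sim_config(rates = toy_rates(), cohort_size = 30,
                                   n_steps = 5, seed = 8,
                                   sampling_steps = 4:5,
                                   sampling_rate = 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(res$pedigree, path)
  back <- read_pedigree(path)
  expect_equal(as.data.frame(back), as.data.frame(res$pedigree))
})
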