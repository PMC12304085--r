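test_that("lifetime reproductive success on toy pedigrees", {
  ped <- make_fixtures("toy-pedigree", variant = "equal-rs")
  rs <- lifetime_rs(ped, birth_step = 0, allow_incomplete = TRUE)
  expect_equal(rs$mean_k, 2)
  expect_equal(rs$var_k, 0)

  ped2 <- make_fixtures("toy-pedigree", variant = "skewed")
  rs2 <- lifetime_rs(ped2, birth_step = 0, allow_incomplete = TRUE)
  expect_equal(sort(rs2$k, decreasing = TRUE), c(8, 0, 0, 0))
  expect_equal(rs2$mean_k, 2)
  expect_equal(rs2$var_k, 12)  # population variance of {8,0,0,0}

  expect_error(lifetime_rs(ped, birth_step = 1, max_age = 15, n_steps = 1),
               "truncated")
  expect_error(lifetime_rs(ped, birth_step = 99), "no individuals")
})

test_that("realized Ne evaluates the hybrid formula on cohort variance", {
  # Vk = 0, N1 = 4, T = 1 gives Ne = 4 * 4 * 1 / 2 = 8
  ped <- make_fixtures("toy-pedigree", variant = "equal-rs")
  est <- realized_ne(ped, cohorts = 0, rates = wf_rates(), cohort_size = 4,
                     n_steps = 2)
  expect_equal(est$point, 8)
  expect_equal(est$method, "realized")
})

test_that("realized Ne of a discrete-generation population equals census", {
  cfg <- sim_config(rates = wf_rates(), cohort_size = 500, n_demes = 1,
                    migration = 0, n_steps = 30,
                    sampling_steps = integer(0), seed = 77)
  res <- run_simulation(cfg)
  est <- realized_ne(res, cohorts = 2:29)
  expect_lt(abs(est$point - 500) / 500, 0.05)
})

test_that("cohort mean offspring number converges to two", {
  res <- shared_sim()
  per <- realized_ne(res, cohorts = 30:45)$aux$per_cohort
  expect_lt(abs(mean(per$mean_k) - 2), 0.05)
})

test_that("kin-pair census classifies by precedence and matches brute force", {
  ped <- make_fixtures("toy-pedigree", variant = "equal-rs")
  # two full sibs
  expect_equal(kin_pair_census(ped, c(5, 6))$full_sib, 1)
  # parent and offspring
  kc <- kin_pair_census(ped, c(1, 5))
  expect_equal(kc$parent_offspring, 1)
  expect_equal(kc$total_pairs, 1)
  expect_error(kin_pair_census(ped, c(1, 999)), "unknown")

  # brute-force all-pairs oracle on a random sample of a real pedigree
  res <- shared_sim()
  set.seed(11)
  ids <- sample(res$samples$id, 80)
  kc2 <- kin_pair_census(res$pedigree, ids)
  lut <- res$pedigree[match(ids, res$pedigree$id), ]
  po <- fs <- hs <- 0
  for (i in 1:79) {
    for (j in (i + 1):80) {
      mi <- lut$mother_id[i]; fi <- lut$father_id[i]
      mj <- lut$mother_id[j]; fj <- lut$father_id[j]
      if ((!is.na(mj) && ids[i] == mj) || (!is.na(fj) && ids[i] == fj) ||
          (!is.na(mi) && ids[j] == mi) || (!is.na(fi) && ids[j] == fi)) {
        po <- po + 1
      } else if (!is.na(mi) && !is.na(mj) && mi == mj &&
                 !is.na(fi) && !is.na(fj) && fi == fj) {
        fs <- fs + 1
      } else if ((!is.na(mi) && !is.na(mj) && mi == mj) ||
                 (!is.na(fi) && !is.na(fj) && fi == fj)) {
        hs <- hs + 1
      }
    }
  }
  expect_equal(kc2$parent_offspring, po)
  expect_equal(kc2$full_sib, fs)
  expect_equal(kc2$half_sib, hs)
  expect_equal(kc2$total_pairs, choose(80, 2))
})

test_that("related-pair counts increase with the sampling fraction", {
  res <- shared_sim()
  pool <- res$samples$id
  set.seed(21)
  mean_po <- vapply(c(0.1, 0.4, 1), function(f) {
    mean(vapply(1:5, function(r) {
      ids <- sample(pool, round(f * length(pool)))
      kc <- kin_pair_census(res$pedigree, ids)
      kc$parent_offspring + kc$full_sib + kc$half_sib
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_po) > 0))
})
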