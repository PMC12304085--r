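#' Configuration for the forward demographic simulation
#'
#' Describes a set of identical, migration-connected sub-populations
#' (demes), each governed by the same [vital_rates()] schedule and a fixed
#' annual recruitment. Defaults reproduce the packaged two-deme reference
#' scenario: cohort size 5000 per deme (equilibrium census 17,710), 5%
#' symmetric migration, 100 time steps with serial sampling of 10% of every
#' age class 1..max_age over steps 90-100.
#'
#' @param rates A [vital_rates()] object.
#' @param cohort_size Newborns recruited per deme per time step.
#' @param n_demes Number of demes (>= 1).
#' @param migration Per-individual, per-step probability of moving to
#'   another deme (uniformly chosen among the others), in `[0, 1]`.
#' @param n_steps Number of time steps to simulate.
#' @param sampling_steps Integer vector of steps at which samples are drawn.
#' @param sampling_rate Fraction of each age class sampled per step.
#' @param recruitment `"fixed"` (exactly `cohort_size` newborns per deme per
#'   step, the default) or `"poisson"` (Poisson with mean `cohort_size`).
#' @param seed Integer seed making the whole run reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(rates = default_vital_rates(), cohort_size = 5000,
                       n_demes = 2, migration = 0.05, n_steps = 100,
                       sampling_steps = 90:100, sampling_rate = 0.10,
                       recruitment = c("fixed", "poisson"), seed = 1) {
  stopifnot(inherits(rates, "vital_rates"))
  recruitment <- match.arg(recruitment)
  if (migration < 0 || migration > 1) {
    stop("`migration` must lie in [0, 1]", call. = FALSE)
  }
  if (sampling_rate < 0 || sampling_rate > 1) {
    stop("`sampling_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (n_demes < 1) stop("`n_demes` must be >= 1", call. = FALSE)
  if (n_steps < 0) stop("`n_steps` must be >= 0", call. = FALSE)
  sampling_steps <- as.integer(sampling_steps)
  sampling_steps <- sampling_steps[sampling_steps >= 1 & sampling_steps <= n_steps]
  structure(
    list(rates = rates, cohort_size = as.integer(cohort_size),
         n_demes = as.integer(n_demes), migration = migration,
         n_steps = as.integer(n_steps), sampling_steps = sampling_steps,
         sampling_rate = sampling_rate, recruitment = recruitment,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Mutable per-run accumulator (pedigree, events, sampling memory). An
# environment so that per-step updates do not copy million-element vectors.
new_ped_store <- function(capacity, n_demes) {
  ped <- new.env(parent = emptyenv())
  ped$birth <- integer(capacity)
  ped$deme_birth <- integer(capacity)
  ped$mom <- rep(NA_integer_, capacity)
  ped$dad <- rep(NA_integer_, capacity)
  ped$sex <- integer(capacity)           # 0 = female, 1 = male
  ped$death <- rep(NA_integer_, capacity)
  ped$sampled_step <- rep(NA_integer_, capacity)
  ped$sampled_age <- rep(NA_integer_, capacity)
  ped$sampled_deme <- rep(NA_integer_, capacity)
  ped$n <- 0L
  ped$mig_id <- integer(0); ped$mig_step <- integer(0)
  ped$mig_from <- integer(0); ped$mig_to <- integer(0)
  ped$census <- list()
  ped
}

#' Initialize a population at demographic equilibrium
#'
#' Populates every deme with the rounded [equilibrium_age_structure()]
#' counts; ages, balanced sexes and founder status are assigned at random.
#' Founders carry `birth_step = -age` and no parents. Uses the current RNG
#' state (seed it, or use [run_simulation()] which seeds from the config).
#'
#' @param config A [sim_config()].
#' @return A population state: a list with vectors `id`, `age`, `sex`,
#'   `deme`, the current `step`, and the pedigree accumulator.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  struct <- equilibrium_age_structure(config$rates, config$cohort_size)
  counts <- struct$count_rounded
  per_deme <- sum(counts)
  n0 <- per_deme * config$n_demes
  capacity <- n0 + config$n_demes * config$cohort_size * (config$n_steps + 1L)
  ped <- new_ped_store(capacity, config$n_demes)
  age <- rep(rep(struct$age, counts), config$n_demes)
  deme <- rep(seq_len(config$n_demes), each = per_deme)
  id <- seq_len(n0)
  sex <- ifelse(stats::runif(n0) < config$rates$sex_ratio, 0L, 1L)
  ped$birth[id] <- -age
  ped$deme_birth[id] <- deme
  ped$sex[id] <- sex
  ped$n <- n0
  list(step = 0L, id = id, age = age, sex = sex, deme = deme, ped = ped)
}

#' Advance the population by one time step
#'
#' Applies, in order: (1) age-dependent survival (independent Bernoulli from
#' the survival schedule; survival beyond the maximum age is zero), (2)
#' aging by one year, (3) migration (each survivor moves to another deme
#' with the configured probability), (4) reproduction (each deme recruits
#' exactly `cohort_size` newborns; every newborn draws its mother among the
#' deme's mature females and its father among its mature males,
#' independently and with replacement, with probability proportional to the
#' age-specific fertility weight). Parents and deaths are recorded in the
#' pedigree.
#'
#' @param state A population state from [init_population()] or a previous
#'   step.
#' @param config The [sim_config()].
#' @return The updated state (step advanced by one).
#' @export
sim_step <- function(state, config) {
  rates <- config$rates
  t <- state$step + 1L
  ped <- state$ped
  # (1) survival
  s_full <- c(rates$survival, 0)
  live <- stats::runif(length(state$age)) < s_full[state$age + 1L]
  ped$death[state$id[!live]] <- t
  id <- state$id[live]; age <- state$age[live]
  sex <- state$sex[live]; deme <- state$deme[live]
  # (2) aging
  age <- age + 1L
  # (3) migration
  if (config$migration > 0 && config$n_demes > 1) {
    mig <- stats::runif(length(id)) < config$migration
    if (any(mig)) {
      from <- deme[mig]
      if (config$n_demes == 2L) {
        to <- 3L - from
      } else {
        shift <- sample.int(config$n_demes - 1L, sum(mig), replace = TRUE)
        to <- 1L + (from - 1L + shift) %% config$n_demes
      }
      deme[mig] <- to
      ped$mig_id <- c(ped$mig_id, id[mig])
      ped$mig_step <- c(ped$mig_step, rep(t, sum(mig)))
      ped$mig_from <- c(ped$mig_from, from)
      ped$mig_to <- c(ped$mig_to, to)
    }
  }
  # (4) reproduction
  bx <- rates$fertility
  new_id <- integer(0); new_deme <- integer(0); new_sex <- integer(0)
  for (d in seq_len(config$n_demes)) {
    ncs <- if (identical(config$recruitment, "poisson"))
      stats::rpois(1L, config$cohort_size) else config$cohort_size
    mature <- which(deme == d & age >= rates$maturity_age)
    fem <- mature[sex[mature] == 0L]
    mal <- mature[sex[mature] == 1L]
    if (length(fem) == 0L || length(mal) == 0L) {
      stop(sprintf("extinction: deme %d has no mature %s at step %d", d,
                   if (length(fem) == 0L) "females" else "males", t),
           call. = FALSE)
    }
    moms <- fem[sample.int(length(fem), ncs, replace = TRUE,
                           prob = bx[age[fem] + 1L])]
    dads <- mal[sample.int(length(mal), ncs, replace = TRUE,
                           prob = bx[age[mal] + 1L])]
    nid <- ped$n + seq_len(ncs)
    ped$birth[nid] <- t
    ped$deme_birth[nid] <- d
    ped$mom[nid] <- id[moms]
    ped$dad[nid] <- id[dads]
    kid_sex <- ifelse(stats::runif(ncs) < rates$sex_ratio, 0L, 1L)
    ped$sex[nid] <- kid_sex
    ped$n <- ped$n + ncs
    new_id <- c(new_id, nid); new_deme <- c(new_deme, rep(d, ncs))
    new_sex <- c(new_sex, kid_sex)
  }
  id <- c(id, new_id); age <- c(age, integer(length(new_id)))
  sex <- c(sex, new_sex); deme <- c(deme, new_deme)
  ped$census[[t]] <- tabulate(deme, nbins = config$n_demes)
  list(step = t, id = id, age = age, sex = sex, deme = deme, ped = ped)
}

#' Draw a serial sample from the current population
#'
#' For every deme and every age class `1..max_age`, samples
#' `floor(sampling_rate * N_age_deme)` live individuals uniformly without
#' replacement, never re-capturing an individual sampled at an earlier step.
#' Sampled ids, ages and demes are recorded in the run accumulator.
#'
#' @inheritParams sim_step
#' @return A tibble with columns `id`, `step_sampled`, `age_at_sampling`,
#'   `deme` (also retrievable for the whole run from [run_simulation()]).
#' @export
draw_samples <- function(state, config) {
  ped <- state$ped
  rates <- config$rates
  out_id <- integer(0); out_age <- integer(0); out_deme <- integer(0)
  for (d in seq_len(config$n_demes)) {
    for (a in seq_len(rates$max_age)) {
      in_class <- state$id[state$deme == d & state$age == a]
      target <- floor(config$sampling_rate * length(in_class))
      if (target < 1) next
      avail <- in_class[is.na(ped$sampled_step[in_class])]
      take <- min(target, length(avail))
      if (take < 1) next
      pick <- avail[sample.int(length(avail), take)]
      out_id <- c(out_id, pick)
      out_age <- c(out_age, rep(a, take))
      out_deme <- c(out_deme, rep(d, take))
    }
  }
  ped$sampled_step[out_id] <- state$step
  ped$sampled_age[out_id] <- out_age
  ped$sampled_deme[out_id] <- out_deme
  tibble::tibble(id = out_id, step_sampled = state$step,
                 age_at_sampling = out_age, deme = out_deme)
}

#' Run a forward simulation
#'
#' Seeds the RNG from the config, initializes all demes at demographic
#' equilibrium, advances `n_steps` steps and draws serial samples at the
#' configured steps. The same config always yields an identical result.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: a list with
#'   * `pedigree`: tibble of every individual ever alive (`id`, `sex`,
#'     `birth_step`, `deme_birth`, `mother_id`, `father_id`, `death_step`,
#'     `sampled_step`, `sampled_age`, `sampled_deme`),
#'   * `samples`: tibble of sample records,
#'   * `census`: tibble (`step`, `deme`, `count`),
#'   * `migrations`: tibble of individual deme changes,
#'   * `config`: the input configuration.
#' @export
#' @examples
#' cfg <- sim_config(cohort_size = 50, n_steps = 10, seed = 42,
#'                   sampling_steps = 8:10)
#' res <- run_simulation(cfg)
#' dplyr::count(res$pedigree, birth_step > 0)
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  state <- init_population(config)
  samples <- vector("list", length(config$sampling_steps))
  for (t in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    if (t %in% config$sampling_steps) {
      samples[[match(t, config$sampling_steps)]] <- draw_samples(state, config)
    }
  }
  ped <- state$ped
  n <- ped$n
  pedigree <- tibble::tibble(
    id = seq_len(n),
    sex = ifelse(ped$sex[1:n] == 0L, "F", "M"),
    birth_step = ped$birth[1:n],
    deme_birth = ped$deme_birth[1:n],
    mother_id = ped$mom[1:n],
    father_id = ped$dad[1:n],
    death_step = ped$death[1:n],
    sampled_step = ped$sampled_step[1:n],
    sampled_age = ped$sampled_age[1:n],
    sampled_deme = ped$sampled_deme[1:n]
  )
  census <- if (length(ped$census)) {
    tibble::tibble(
      step = rep(seq_along(ped$census), each = config$n_demes),
      deme = rep(seq_len(config$n_demes), length(ped$census)),
      count = unlist(ped$census)
    )
  } else {
    tibble::tibble(step = integer(0), deme = integer(0), count = integer(0))
  }
  migrations <- tibble::tibble(id = ped$mig_id, step = ped$mig_step,
                               from = ped$mig_from, to = ped$mig_to)
  samples <- if (length(samples)) dplyr::bind_rows(samples) else
    tibble::tibble(id = integer(0), step_sampled = integer(0),
                   age_at_sampling = integer(0), deme = integer(0))
  structure(list(pedigree = pedigree, samples = samples, census = census,
                 migrations = migrations, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", nrow(x$pedigree), "individuals,",
      nrow(x$samples), "sample records,", x$config$n_demes, "demes,",
      x$config$n_steps, "steps (m =", x$config$migration, ")\n")
  invisible(x)
}

#' Export and import a recorded pedigree
#'
#' Tab-separated, one row per individual, with the column set documented in
#' [run_simulation()]; missing parents (founders) and missing death or
#' sampling records are written as `NA`.
#'
#' @param pedigree A pedigree tibble.
#' @param path File path.
#' @return `write_pedigree()` returns `path` invisibly; `read_pedigree()`
#'   the pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
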