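#' Lifetime reproductive success of a birth cohort
#'
#' Counts, for every member of the cohort born in `birth_step` (optionally
#' restricted to one deme of birth), the number of offspring it produced
#' over its whole life, wherever those offspring were born, and returns the
#' cohort mean and (population) variance of that count. At demographic
#' equilibrium with fully observed lifetimes the mean is close to 2 (every
#' newborn has exactly one mother and one father).
#'
#' @param pedigree A pedigree tibble from [run_simulation()].
#' @param birth_step Birth step of the cohort.
#' @param deme Optional deme of birth; all demes when `NULL`.
#' @param n_steps Total number of simulated steps (used to verify that the
#'   cohort's lifetimes are complete); taken from the maximum birth step
#'   when omitted.
#' @param max_age Longevity used for the completeness check.
#' @param allow_incomplete Set `TRUE` to skip the completeness check.
#' @return A list of class `cohort_rs` with elements `birth_step`, `deme`,
#'   `k` (per-individual lifetime offspring counts), `mean_k`, `var_k`, `n`.
#' @export
lifetime_rs <- function(pedigree, birth_step, deme = NULL, n_steps = NULL,
                        max_age = NULL, allow_incomplete = FALSE) {
  if (is.null(n_steps)) n_steps <- max(pedigree$birth_step)
  if (!allow_incomplete && !is.null(max_age) &&
      birth_step > n_steps - max_age) {
    stop("cohort born at step ", birth_step, " may be truncated by the end ",
         "of the simulation; pass `allow_incomplete = TRUE` to override",
         call. = FALSE)
  }
  in_cohort <- pedigree$birth_step == birth_step
  if (!is.null(deme)) in_cohort <- in_cohort & pedigree$deme_birth == deme
  members <- pedigree$id[in_cohort]
  if (length(members) == 0L) {
    stop("no individuals born at step ", birth_step, call. = FALSE)
  }
  links <- c(pedigree$mother_id, pedigree$father_id)
  links <- links[!is.na(links)]
  k <- tabulate(match(links, members), nbins = length(members))
  structure(
    list(birth_step = birth_step, deme = deme, k = k, mean_k = mean(k),
         var_k = stats::var(k) * (length(k) - 1) / length(k),
         n = length(k)),
    class = "cohort_rs"
  )
}

#' @export
print.cohort_rs <- function(x, ...) {
  cat("<cohort_rs> step", x$birth_step,
      if (!is.null(x$deme)) paste("deme", x$deme) else "(all demes)",
      "- n =", x$n, ", mean k =", round(x$mean_k, 4),
      ", Vk =", round(x$var_k, 4), "\n")
  invisible(x)
}

#' Realized (pedigree-based) effective size per generation
#'
#' For each requested birth cohort and deme, computes the lifetime variance
#' in reproductive success `Vk` from the recorded pedigree ([lifetime_rs()])
#' and converts it to a per-generation effective size with the hybrid
#' Felsenstein-Hill formula `Ne = 4 N1 T / (Vk + 2)`, where `N1` is the
#' cohort size at age 1 and `T` the generation length implied by the vital
#' rates. The reported point estimate is the mean over cohorts (pooled over
#' demes); per-deme and per-cohort values are kept in the auxiliary table.
#'
#' @param sim A `sim_result` from [run_simulation()], or a pedigree tibble
#'   (in which case `rates`, `cohort_size` and `n_steps` must be supplied).
#' @param cohorts Birth steps of the cohorts to use. Defaults to all steps
#'   in `[2 * max_age, n_steps - max_age]`, i.e. cohorts born after the age
#'   structure has equilibrated whose lifetimes are complete.
#' @param rates,cohort_size,n_steps Overrides when `sim` is a bare pedigree.
#' @return A [ne_estimate] with `method = "realized"`; `aux$per_cohort` is a
#'   tibble with one row per (deme, cohort) and `aux$per_deme` the per-deme
#'   mean Ne.
#' @export
#' @examples
#' \donttest{
#' res <- run_simulation(sim_config(cohort_size = 200, n_steps = 60, seed = 7))
#' realized_ne(res)
#' }
realized_ne <- function(sim, cohorts = NULL, rates = NULL,
                        cohort_size = NULL, n_steps = NULL) {
  if (inherits(sim, "sim_result")) {
    pedigree <- sim$pedigree
    rates <- sim$config$rates
    cohort_size <- sim$config$cohort_size
    n_steps <- sim$config$n_steps
  } else {
    pedigree <- sim
    if (is.null(rates) || is.null(cohort_size) || is.null(n_steps)) {
      stop("with a bare pedigree, supply `rates`, `cohort_size` and `n_steps`",
           call. = FALSE)
    }
  }
  a <- rates$max_age
  if (is.null(cohorts)) {
    cohorts <- seq(min(2L * a, max(0L, n_steps - a)), max(0L, n_steps - a))
  }
  cohorts <- cohorts[cohorts <= n_steps - a]
  if (length(cohorts) == 0L) {
    stop("no complete cohorts available: need birth steps <= n_steps - max_age",
         call. = FALSE)
  }
  n1 <- cohort_size * survivorship(rates)[2]
  tg <- generation_length(rates)
  demes <- sort(unique(pedigree$deme_birth))
  per <- tidyr::expand_grid(deme = demes, cohort = cohorts)
  stats_list <- purrr::pmap(per, function(deme, cohort) {
    rs <- lifetime_rs(pedigree, cohort, deme = deme, n_steps = n_steps)
    tibble::tibble(vk = rs$var_k, mean_k = rs$mean_k, n = rs$n,
                   ne = 4 * n1 * tg / (rs$var_k + 2))
  })
  per <- dplyr::bind_cols(per, dplyr::bind_rows(stats_list))
  per_deme <- dplyr::summarise(dplyr::group_by(per, .data$deme),
                               ne = mean(.data$ne), .groups = "drop")
  ne_estimate(point = mean(per$ne), method = "realized",
              aux = list(T = tg, N1 = n1, mean_Vk = mean(per$vk),
                         n_cohorts = length(cohorts),
                         per_cohort = per, per_deme = per_deme))
}

#' Census of related pairs within a sample
#'
#' Classifies every unordered pair of sampled individuals by their closest
#' pedigree relationship, with precedence parent-offspring > full-sibling >
#' half-sibling; remaining pairs are `unrelated` (no shared parent and no
#' parent-offspring link; shared ancestry deeper than grandparents is not
#' chased). Each pair is counted exactly once.
#'
#' @param pedigree A pedigree tibble.
#' @param sample_ids Individual ids of the sample (e.g. from the `samples`
#'   tibble of [run_simulation()]).
#' @return A list of class `kin_pair_census`: counts `parent_offspring`,
#'   `full_sib`, `half_sib`, `unrelated` and `total_pairs`.
#' @export
kin_pair_census <- function(pedigree, sample_ids) {
  sample_ids <- unique(sample_ids)
  idx <- match(sample_ids, pedigree$id)
  if (anyNA(idx)) {
    stop("unknown individual id(s): ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- length(sample_ids)
  total <- n * (n - 1) / 2
  mom <- pedigree$mother_id[idx]
  dad <- pedigree$father_id[idx]
  po <- 0L; fs <- 0L; hs <- 0L
  if (n >= 2) {
    pr <- utils::combn(n, 2)
    i <- pr[1, ]; j <- pr[2, ]
    is_po <- (!is.na(mom[j]) & sample_ids[i] == mom[j]) |
      (!is.na(dad[j]) & sample_ids[i] == dad[j]) |
      (!is.na(mom[i]) & sample_ids[j] == mom[i]) |
      (!is.na(dad[i]) & sample_ids[j] == dad[i])
    share_mom <- !is.na(mom[i]) & !is.na(mom[j]) & mom[i] == mom[j]
    share_dad <- !is.na(dad[i]) & !is.na(dad[j]) & dad[i] == dad[j]
    is_fs <- !is_po & share_mom & share_dad
    is_hs <- !is_po & !is_fs & (share_mom | share_dad)
    po <- sum(is_po); fs <- sum(is_fs); hs <- sum(is_hs)
  }
  structure(
    list(parent_offspring = po, full_sib = fs, half_sib = hs,
         unrelated = total - po - fs - hs, total_pairs = total),
    class = "kin_pair_census"
  )
}

#' @export
print.kin_pair_census <- function(x, ...) {
  cat("<kin_pair_census>", x$total_pairs, "pairs: PO =", x$parent_offspring,
      ", FS =", x$full_sib, ", HS =", x$half_sib,
      ", unrelated =", x$unrelated, "\n")
  invisible(x)
}

#' @export
as_tibble.kin_pair_census <- function(x, ...) {
  tibble::tibble(
    relationship = c("parent_offspring", "full_sib", "half_sib", "unrelated"),
    pairs = c(x$parent_offspring, x$full_sib, x$half_sib, x$unrelated)
  )
}
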