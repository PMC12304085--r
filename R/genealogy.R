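#' @useDynLib nesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- pedigree-phase backward trace -----------------------------------------
#
# Trace sampled haplotypes back through the recorded pedigree, one
# independent inheritance path per locus (free recombination between loci,
# none within: the unlinked-locus model). Lineages that land on the same
# parental haplotype at the same locus coalesce there; a node is created at
# the parent's birth step. Lineages stop on founder haplotypes.
#
# Node ids: leaf (locus l, lineage h) = (l - 1) * H + h; internal nodes are
# numbered from L * H + 1 upwards.
trace_locus_forest <- function(mom, dad, birth, sample_ids, n_loci) {
  n_ind <- length(birth)
  H <- 2L * length(sample_ids)
  glob_hap <- as.integer(rbind(2L * sample_ids - 1L, 2L * sample_ids))
  eloc <- rep(seq_len(n_loci), each = H)
  ehap <- rep(glob_hap, n_loci)
  enode <- seq_len(n_loci * H)
  ebirth <- birth[(ehap + 1L) %/% 2L]
  DEAD <- -.Machine$integer.max %/% 2L
  hap_mult <- 2 * (n_ind + 1)
  next_node <- n_loci * H + 1L
  ec <- list(); ep <- list(); el <- list()
  mn <- list(); mt <- list()
  nchunk <- 0L

  merge_dups <- function(sel, times) {
    # coalesce duplicated (locus, haplotype) entries among `sel`;
    # `times` gives the node time (birth step) per entry (scalar ok)
    key <- as.numeric(eloc[sel]) * hap_mult + ehap[sel]
    dup <- duplicated(key)
    if (!any(dup)) return(sel)
    firsts <- which(!dup)
    grp <- match(key, key[firsts])
    gsz <- tabulate(grp, nbins = length(firsts))
    multi <- which(gsz > 1L)
    newids <- next_node + seq_along(multi) - 1L
    next_node <<- next_node + length(multi)
    gmap <- integer(length(firsts))
    gmap[multi] <- newids
    in_multi <- gsz[grp] > 1L
    nchunk <<- nchunk + 1L
    ec[[nchunk]] <<- enode[sel[in_multi]]
    ep[[nchunk]] <<- gmap[grp[in_multi]]
    el[[nchunk]] <<- eloc[sel[in_multi]]
    mn[[nchunk]] <<- newids
    mt[[nchunk]] <<- if (length(times) == 1L) rep(times, length(multi)) else
      times[firsts][multi]
    keep1 <- sel[firsts]
    enode[keep1[multi]] <<- newids
    ebirth[sel[dup]] <<- DEAD
    keep1
  }

  steps <- sort(unique(ebirth[ebirth > 0L]), decreasing = TRUE)
  for (t in steps) {
    sel <- which(ebirth == t)
    if (!length(sel)) next
    sel <- merge_dups(sel, t)
    h <- ehap[sel]
    owner <- (h + 1L) %/% 2L
    par <- ifelse(h %% 2L == 1L, mom[owner], dad[owner])
    if (anyNA(par)) {
      stop("pedigree integrity error: non-founder born at step ", t,
           " lacks a recorded parent", call. = FALSE)
    }
    ehap[sel] <- 2L * par - (stats::runif(length(sel)) < 0.5)
    ebirth[sel] <- birth[par]
  }
  sel <- which(ebirth != DEAD)
  sel <- merge_dups(sel, birth[(ehap[sel] + 1L) %/% 2L])

  list(
    root_locus = eloc[sel], root_node = enode[sel], root_hap = ehap[sel],
    root_step = birth[(ehap[sel] + 1L) %/% 2L],
    edge_child = unlist(ec), edge_parent = unlist(ep),
    edge_locus = unlist(el),
    node = unlist(mn), node_step = unlist(mt),
    next_node = next_node, H = H, leaf_hap = glob_hap
  )
}

int0 <- function(x) if (is.null(x)) integer(0) else x

# ---- genealogy forest ------------------------------------------------------

new_forest <- function(n_loci, H, parent, node_time, edge_child, edge_parent,
                       edge_locus, root, locus_length, leaves, meta = list()) {
  structure(list(n_loci = n_loci, H = H, parent = parent,
                 node_time = node_time, edge_child = edge_child,
                 edge_parent = edge_parent, edge_locus = edge_locus,
                 root = root, locus_length = locus_length, leaves = leaves,
                 meta = meta),
            class = "genealogy_forest")
}

#' @export
print.genealogy_forest <- function(x, ...) {
  cat("<genealogy_forest>", x$n_loci, "loci x", x$H, "leaf lineages,",
      length(x$edge_child), "edges\n")
  invisible(x)
}

#' Per-locus total branch length of a genealogy forest
#'
#' @param forest A genealogy forest from [recapitate()] or
#'   [simulate_genomes()].
#' @return Numeric vector (generations), one entry per locus.
#' @export
total_branch_length <- function(forest) {
  len <- forest$node_time[forest$edge_parent] -
    forest$node_time[forest$edge_child]
  out <- numeric(forest$n_loci)
  if (length(len)) {
    rs <- rowsum(len, forest$edge_locus)
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

#' Time to the most recent common ancestor, per locus
#'
#' @inheritParams total_branch_length
#' @return Numeric vector of root times (generations before present).
#' @export
root_time <- function(forest) {
  forest$node_time[forest$root]
}

#' Coalescent recapitation of founder lineages
#'
#' Completes the genealogy of a set of lineages under the standard neutral
#' (Kingman) coalescent in a single panmictic ancestral population of
#' diploid size `ancestral_ne`: one independent gene tree per locus
#' (chromosome of `spec`). Pairs of lineages coalesce at rate
#' `1 / (2 ancestral_ne)` per generation, so the expected pairwise
#' coalescence time is `2 ancestral_ne` generations. Used on its own this
#' simulates a constant-size population sample; in the full pipeline it is
#' applied to the founder lineages left over from the pedigree-phase trace,
#' merging all demes into one ancestral population.
#'
#' @param founder_ids Identifiers of the lineages entering the ancestral
#'   population (one lineage each).
#' @param spec A [genome_spec()]; one tree per chromosome is generated.
#' @param ancestral_ne Diploid size of the ancestral population.
#' @param start_time Generations before present at which the lineages enter
#'   the ancestral population (default 0).
#' @param seed Optional integer seed.
#' @return A `genealogy_forest` whose leaves are the founder lineages.
#' @export
#' @examples
#' f <- recapitate(1:10, unlinked_genome(5), ancestral_ne = 100, seed = 1)
#' root_time(f)
recapitate <- function(founder_ids, spec, ancestral_ne, start_time = 0,
                       seed = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (length(founder_ids) < 1) stop("no founder lineages", call. = FALSE)
  if (ancestral_ne <= 0) stop("`ancestral_ne` must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  H <- length(founder_ids)
  L <- length(spec$chromosomes)
  roots <- seq_len(L * H)
  offs <- c(0L, seq_len(L) * H)
  kg <- kingman_coalesce(offs, roots, rep(as.numeric(start_time), L),
                         ancestral_ne, L * H + 1L)
  n_nodes <- kg$next_node - 1L
  node_time <- numeric(n_nodes)
  node_time[seq_len(L * H)] <- start_time
  node_time[kg$node] <- kg$time
  parent <- integer(n_nodes)
  parent[kg$edge_child] <- kg$edge_parent
  new_forest(
    n_loci = L, H = H, parent = parent, node_time = node_time,
    edge_child = kg$edge_child, edge_parent = kg$edge_parent,
    edge_locus = kg$edge_locus, root = kg$root,
    locus_length = spec$chromosomes,
    leaves = tibble::tibble(lineage = seq_len(H), founder_id = founder_ids),
    meta = list(ancestral_ne = ancestral_ne, mode = "recap-only")
  )
}

# ---- pedigree + recapitation pipeline (unlinked loci) ----------------------

ped_arrays <- function(pedigree) {
  list(mom = pedigree$mother_id, dad = pedigree$father_id,
       birth = pedigree$birth_step)
}

# Build the full per-locus genealogy of the sampled individuals: exact
# pedigree phase (with per-locus Mendelian transmission), then Kingman
# recapitation of the remaining founder lineages in one merged ancestral
# population. Times in generations before the end of the simulation;
# forward steps are converted with the generation length T.
build_sample_forest <- function(sim, spec, ancestral_ne, sample_ids = NULL) {
  stopifnot(inherits(sim, "sim_result"), inherits(spec, "genome_spec"))
  if (spec$linkage != "unlinked") {
    stop("build_sample_forest handles unlinked loci; use drop_genomes() for ",
         "linked chromosomes", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sim$samples$id
  if (length(sample_ids) == 0) stop("no sampled individuals", call. = FALSE)
  pa <- ped_arrays(sim$pedigree)
  t_gen <- generation_length(sim$config$rates)
  n_steps <- sim$config$n_steps
  L <- length(spec$chromosomes)
  tr <- trace_locus_forest(pa$mom, pa$dad, pa$birth, sample_ids, L)
  # ancestral phase over founder lineages, all demes merged
  o <- order(tr$root_locus)
  rl <- tr$root_locus[o]; rn <- tr$root_node[o]
  offs <- c(0L, cumsum(tabulate(rl, nbins = L)))
  start_gen <- (n_steps - min(tr$root_step)) / t_gen
  kg <- kingman_coalesce(offs, rn, rep(start_gen, L), ancestral_ne,
                         tr$next_node)
  n_nodes <- kg$next_node - 1L
  node_time <- numeric(n_nodes)
  H <- tr$H
  leaf_birth <- pa$birth[(tr$leaf_hap + 1L) %/% 2L]
  node_time[seq_len(L * H)] <- (n_steps - rep(leaf_birth, L)) / t_gen
  if (length(tr$node)) node_time[tr$node] <- (n_steps - tr$node_step) / t_gen
  node_time[kg$node] <- kg$time
  edge_child <- c(int0(tr$edge_child), kg$edge_child)
  edge_parent <- c(int0(tr$edge_parent), kg$edge_parent)
  edge_locus <- c(int0(tr$edge_locus), kg$edge_locus)
  parent <- integer(n_nodes)
  parent[edge_child] <- edge_parent
  leaves <- tibble::tibble(
    lineage = seq_len(H),
    individual = rep(sample_ids, each = 2L),
    haplotype = rep(c(1L, 2L), length(sample_ids))
  )
  new_forest(
    n_loci = L, H = H, parent = parent, node_time = node_time,
    edge_child = edge_child, edge_parent = edge_parent,
    edge_locus = edge_locus, root = kg$root,
    locus_length = spec$chromosomes, leaves = leaves,
    meta = list(ancestral_ne = ancestral_ne, t_gen = t_gen,
                n_steps = n_steps, mode = "pedigree+recap")
  )
}

# ---- mutation overlay ------------------------------------------------------

#' Overlay neutral mutations on a genealogy forest
#'
#' Places infinite-sites biallelic mutations on the branches of every locus
#' tree: the number of mutations per locus is Poisson with mean
#' `mutation_rate * locus_length * total branch length`, positions are
#' uniform along the locus and each mutation falls on a branch with
#' probability proportional to its length. The ancestral state is known by
#' construction, so the unfolded site-frequency spectrum is available
#' downstream.
#'
#' @param forest A `genealogy_forest`.
#' @param spec The [genome_spec()] supplying the mutation rate (defaults to
#'   the rate used when the forest was built, if recorded).
#' @param seed Optional integer seed.
#' @return An object of class `haplotype_set`: a list with `hap` (leaf
#'   lineages x sites 0/1 matrix) and `sites` (tibble with `chrom`, `pos`,
#'   `locus`).
#' @export
overlay_mutations <- function(forest, spec, seed = NULL) {
  stopifnot(inherits(forest, "genealogy_forest"))
  mu <- if (inherits(spec, "genome_spec")) spec$mutation_rate else
    as.numeric(spec)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  L <- forest$n_loci; H <- forest$H
  len <- forest$node_time[forest$edge_parent] -
    forest$node_time[forest$edge_child]
  len[len < 0] <- 0
  ltot <- numeric(L)
  if (length(len)) {
    rs <- rowsum(len, forest$edge_locus)
    ltot[as.integer(rownames(rs))] <- rs[, 1]
  }
  n_mut <- stats::rpois(L, mu * forest$locus_length * ltot)
  total <- sum(n_mut)
  if (total == 0) {
    return(structure(list(
      hap = matrix(0L, H, 0),
      sites = tibble::tibble(chrom = integer(0), pos = integer(0),
                             locus = integer(0)),
      leaves = forest$leaves), class = "haplotype_set"))
  }
  o <- order(forest$edge_locus)
  len_o <- len[o]; child_o <- forest$edge_child[o]
  cs <- cumsum(len_o)
  cnt <- tabulate(forest$edge_locus, nbins = L)
  off <- c(0, cs[cumsum(cnt)])[seq_len(L)]  # cumulative length before locus l
  off[cnt == 0] <- NA  # loci with no edges get no mutations anyway
  mut_locus <- rep(seq_len(L), n_mut)
  target <- off[mut_locus] + stats::runif(total) * ltot[mut_locus]
  eidx <- findInterval(target, cs, left.open = TRUE) + 1L
  eidx[eidx > length(cs)] <- length(cs)
  site_child <- child_o[eidx]
  pos <- floor(stats::runif(total) * forest$locus_length[mut_locus]) + 1L
  keep <- !duplicated(mut_locus * (max(forest$locus_length) + 1) + pos)
  mut_locus <- mut_locus[keep]; pos <- pos[keep]; site_child <- site_child[keep]
  so <- order(mut_locus, pos)
  mut_locus <- mut_locus[so]; pos <- pos[so]; site_child <- site_child[so]
  n_site <- length(pos)
  # carriers: walk every leaf of a mutated locus up to its root, collecting
  # sites attached to the nodes passed through
  nodes_with <- unique(site_child)
  n_nodes <- length(forest$parent)
  has <- logical(n_nodes); has[nodes_with] <- TRUE
  node_idx <- integer(n_nodes); node_idx[nodes_with] <- seq_along(nodes_with)
  sites_by_node <- split(seq_len(n_site), node_idx[site_child])
  n_per_node <- integer(length(nodes_with))
  n_per_node[as.integer(names(sites_by_node))] <- lengths(sites_by_node)
  lset <- unique(mut_locus)
  cur <- as.integer(outer(seq_len(H), (lset - 1L) * H, `+`))
  wh <- rep(seq_len(H), length(lset))
  res_w <- list(); res_n <- list(); ri <- 0L
  act <- seq_along(cur)
  while (length(act)) {
    cn <- cur[act]
    hit <- has[cn]
    if (any(hit)) {
      ri <- ri + 1L
      res_w[[ri]] <- act[hit]
      res_n[[ri]] <- cn[hit]
    }
    nxt <- forest$parent[cn]
    cur[act] <- nxt
    act <- act[nxt != 0L]
  }
  hap <- matrix(0L, H, n_site)
  if (ri > 0) {
    w_all <- unlist(res_w); n_all <- unlist(res_n)
    sidx <- node_idx[n_all]
    reps <- n_per_node[sidx]
    rows <- rep(wh[w_all], reps)
    cols <- unlist(sites_by_node[as.character(sidx)], use.names = FALSE)
    hap[cbind(rows, cols)] <- 1L
  }
  structure(list(
    hap = hap,
    sites = tibble::tibble(chrom = mut_locus, pos = pos, locus = mut_locus),
    leaves = forest$leaves), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set>", nrow(x$hap), "haplotypes x", ncol(x$hap), "sites\n")
  invisible(x)
}
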