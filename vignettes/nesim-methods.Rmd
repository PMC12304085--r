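---
title: "Models and methods behind nesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nesim` simulates large, age-structured, migration-connected populations
with full pedigree recording and benchmarks estimators of effective
population size (*Ne*) against the demographic truth of the simulation.
This vignette explains the underlying models, the package's numerical and
design choices, and what its validation does and does not demonstrate.

## The demographic model

Each deme is governed by a `vital_rates()` schedule: survival
probabilities $s_x$ (age $x \to x+1$, years), relative fertility weights
$b_x$, maturity age $\alpha$ and longevity $A$; both sexes share the same
schedule and the birth sex ratio is balanced. Each time step (one year)
applies, in this order: Bernoulli survival by age, aging, migration (each
survivor switches demes with probability $m$), and reproduction — exactly
`cohort_size` newborns per deme, each drawing its mother among the deme's
mature females and its father among its mature males, independently, with
replacement, with probability proportional to $b_{\text{age}}$ ("lottery"
polygamy; selfing impossible). The event order is a modelling choice the
underlying biology does not dictate; migration-before-reproduction lets a
migrant breed in its destination deme, the standard reading of a per-step
migration probability. A Poisson-recruitment variant
(`recruitment = "poisson"`) is available but off by default: with fixed
recruitment the census is exactly stationary, which keeps the demographic
theory below clean.

At equilibrium the expected class sizes are $N_x = N_0 \prod_{i<x} s_i$.
Counts are kept in real arithmetic; rounding (half-up) is applied only
for display and census checks, so no truncation error propagates.

### Theoretical and realized Ne

The per-generation effective size follows the hybrid Felsenstein–Hill
form

$$N_e = \frac{4 N_1 T}{V_k + 2},$$

with $N_1$ the recruits surviving to age 1, $T = \sum_x x N_x b_x /
\sum_x N_x b_x$ the mean age of parents, and $V_k$ the lifetime variance
in offspring number of a newborn cohort. `lifetime_rs_moments()` computes
$V_k$ in closed form: conditional on being alive at age $x$ an individual
gains a Binomial(cohort, $p_x$) number of offspring per parental role with
mean $\mu_x = 2 b_x / \sum_y l_y b_y$, and

$$V_k = \sum_x l_x \mu_x (1 - p_x) + \sum_{x,y} \mu_x \mu_y
\left(l_{\max(x,y)} - l_x l_y\right),$$

the second term being the contribution of random age at death. A
Monte-Carlo cohort simulation is bundled as an independent check; the two
routes agree within 1% for the reference schedule. `realized_ne()`
applies the same formula per birth cohort with $V_k$ tallied from the
recorded pedigree; the headline value averages cohorts born in
$[2A, \text{steps} - A]$, after the age structure has equilibrated and
with complete lifetimes.

### The reference schedule is reconstructed

The packaged default schedule emulates a yellowfin-tuna-like
parameterization through its published summary constraints: class sizes
5000 at ages 0–1 falling to 2 at age 15, census $K = 17{,}710$ per deme,
and theoretical $N_e = 3314$ per generation. The original per-age
mortality table is not redistributed; instead a cubic-in-age
log-survivorship curve is fitted (deterministic Newton iteration, three
parameters, three constraints, residuals $\sim 10^{-12}$) with fertility
rising linearly from maturity. Everything derived from it is labelled
`"reconstructed"`.

One consequence deserves emphasis. In this package the simulator *is*
the process the analytic $V_k$ describes, so the realized pedigree Ne
tracks the theoretical value closely (the test suite measures a
realized/theoretical ratio of about 1.003 at full scale). The original
parameterization was reported with a realized value about 16% *below*
the theoretical one, a gap attributed to unexplained stochastic
behaviour of the simulator that produced it; nothing in the published
constraints reproduces that gap, so `nesim` reports both quantities and
leaves any discrepancy to be observed, not built in.

## Genome generation

Sampled individuals' genomes are generated backwards. In the default
**unlinked** mode each locus is a short sequence (5 kb by default) that
segregates independently: every sampled haplotype follows an independent
Mendelian path through the recorded pedigree at each locus, lineages that
meet on the same parental haplotype coalesce there (at the parent's birth
step), and the founder lineages left at step 0 are completed by a Kingman
coalescent in a single panmictic ancestral population — the two demes
merged, with diploid size defaulting to the *sum* of the demes' realized
effective sizes. Mutations then fall on branches as a Poisson process
(infinite sites, rate $\mu \times$ locus length $\times$ branch length in
generations), so the ancestral allele is known and the unfolded SFS is
exact. Forward branch lengths are converted to generations with $T$.

Numerical conventions worth knowing:

* Founder lineages enter the ancestral coalescent at a common epoch (the
  oldest founder birth) rather than at their individual birth years; the
  approximation is bounded by the founder age span (≤ 15 y ≈ 2
  generations) against an ancestral timescale of $2 N_{anc} \sim 10^4$
  generations.
* Mutation positions are uniform integers within a locus; the rare
  coordinate collision is dropped (infinite-sites behaviour).
* The per-locus Kingman merge loop is compiled (Rcpp) because the
  benchmark builds $10^4$–$10^5$ trees per run; it uses R's RNG, so runs
  are reproducible from a single seed.

**Linked** transmission is available through `drop_genomes()`: exact
recombination-aware segment dropping with Poisson crossovers, where all
lineages traversing the same meiosis share one crossover realization, so
identity-by-descent among relatives is exact. What is *not* implemented
is sequential-coalescent recapitation of those segments: ancestral trees
correlated along a chromosome would require an SMC-class process over
pedigree-derived founder segments, and the benchmark instead runs in
unlinked mode. Physically linked locus panels for studying the
linkage bias of LD estimators come from the `wf-ideal` fixture, a
forward Wright–Fisher simulator with a Haldane map — for that purpose a
forward simulation is the more direct oracle anyway.

## LD-based Ne estimation

`burrows_r2()` estimates the Burrows composite disequilibrium from
unphased dosages as $\hat\Delta = \widehat{\mathrm{cov}}(X, Y)/2$ with
maximum-likelihood ($1/n$) moments, normalized by
$D_A = p(1-p) + (P_{AA} - p^2)$ per locus. ML moments keep
$\hat r^2 \le 1$ with equality at perfect association. Pairs use
complete cases and the summary reports the harmonic-mean pair sample
size. The baseline estimator inverts
$E[\hat r^2] = 1/(3N_e) + 1/S$ (or $1/(2N_e)$ under lifetime monogamy);
when the observed mean does not exceed the sampling expectation the
estimate is flagged infinite and the raw (possibly negative) inversion
is kept in the auxiliary slot — never silently clamped, because the
bimodal infinite/negative behaviour is itself a finding when samples are
small relative to Ne. The opt-in refined mode applies the published
second-order sampling expectations and quadratic inversion; those
constants are stated for the bias-corrected ($n/(n-1)$) composite, so the
mean $r^2$ is rescaled by $(S/(S-1))^2$ before they are applied. On an
ideal Wright–Fisher fixture (Ne = 200, S = 100, 2000 unlinked loci) the
refined estimator recovers the truth with a median within a few percent,
while the first-order inversion shows its known downward bias of roughly
$-15\%$.

Jackknife confidence intervals delete one individual (or one locus) at a
time, form the pseudo-variance on the drift-signal scale
$\bar r^2 - 1/S$ (where the estimator is a smooth monotone transform),
and map the normal-theory interval back to Ne; a lower bound at or below
zero maps to an infinite upper Ne bound. Degenerate inputs (no variation
among pseudo-values) return a flagged NA interval.

The physical-linkage correction divides a raw estimate by a predicted
ratio $a + b\,\ln(\text{chromosomes})$ with defaults $a = 0.098$,
$b = 0.219$, capped at 1. The coefficients are configuration — they
transcribe an empirical regression from the literature on simulated
chromosome numbers of 2–64, and the package tests assert only the
qualitative contract (upward adjustment, monotone in chromosome number,
vanishing for large genomes).

## SFS tools

`compute_sfs()` tallies exact derived-allele counts (unfolded; folding
pools $\xi_i$ with $\xi_{n-i}$), including the two-deme joint SFS.
`watterson_ne()` converts $\theta_W = S / \sum_{i<n} 1/i$ to
$N_e = \theta_W / (4\mu\ell)$. Model fitting beyond constant size is
deliberately exported, not re-implemented: `write_dadi_sfs()` emits the
standard dadi/moments three-line text format (dimension header, counts,
corner mask) so external optimizers can consume the spectra.

## The benchmark and its reduced-scale behaviour

`run_benchmark()` executes the factorial design (migration
{0.01, 0.05, 0.10} × 3 replicate simulations × locus counts × per-deme
sample sizes, final-step samples only, 108 subsets at the reference
settings), per deme and per estimator, with per-subset seeds, flag-and-
continue error isolation and optional on-disk caching for resumability.
All subset sizes draw from the same final-step sample pool, seeded.

The test suite runs the design at `scale = 0.1` (cohort 500, local
realized Ne ≈ 345; locus counts scaled likewise). Two scale-down
artefacts are worth understanding:

* The full-scale sample sizes cannot be scaled proportionally: 5% of
  the reduced Ne would be ~17 individuals, leaving no detectable drift
  signal. The absolute sizes are kept instead and capped at the ~127
  final-step samples available per deme, i.e. the reduced benchmark
  *oversamples* relative to the full-scale design.
* The migration effect on local LD-based estimates saturates: inflation
  of the local estimate towards the metapopulation value is governed by
  $m N_e$, and at $N_e \approx 345$ both $m = 0.01$ and $m = 0.05$ give
  $m N_e \gg 1$. The mean-estimate ordering across migration rates
  therefore separates cleanly only for $m = 0.10$ at this scale; the
  0.01-vs-0.05 contrast is at the edge of resolution with three
  replicates. At full scale the contrast is stronger by an order of
  magnitude in $1/(3N_e)$ terms.

Problem sizes used by the default test run were chosen to keep each
check's Monte-Carlo error several times smaller than its tolerance:
e.g. 2500 loci for pairwise-TMRCA means, 200 replicates for the LD
recovery fixture, 40–50 replicates for Watterson recovery.

## What the synthetic data do and do not emulate

The generator reproduces: overlapping generations with realistic
lifetime reproductive-success variance, serial sampling with
never-recapture, symmetric two-deme migration, neutral genealogies with
correct drift and a 1/i-shaped unfolded SFS, and exact pedigree-derived
relatedness (usable for kin-pair censuses). It does not emulate:
genotyping error, missing data patterns (missingness is supported by the
estimators but not generated), null alleles, selection, linked-selection
backgrounds, non-equilibrium ancestral demography (the ancestral
population is constant-size by design), sex-specific or time-varying
vital rates, or spatially continuous structure. Passing the test suite
therefore demonstrates estimator behaviour under the model's
assumptions, not robustness to the technical artefacts of real data.

## Known limitations

* Linked-mode recapitation (ancestral trees correlated along
  chromosomes) is not implemented; see above.
* Watterson's estimator is applied to unfiltered polymorphic sites; on
  MAF-screened subsets it would be biased and the benchmark therefore
  computes it on the full candidate set.
* The jackknife interval is known to undercover when $S \ll N_e$; the
  package reproduces (and tests) that behaviour rather than correcting
  it.
* Realized Ne requires complete lifetimes; cohorts within one longevity
  of the simulation end are refused unless explicitly overridden.
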