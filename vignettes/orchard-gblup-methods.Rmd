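---
title: "Methods: pedigree and genomic evaluation of open-pollinated seed-orchard trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree and genomic evaluation of open-pollinated seed-orchard trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modelling assumptions, numerical choices and
design decisions behind `orchardgblup`, in the spirit of the methods
vignettes that accompany mixed-model and genomic-prediction packages. It
states no empirical result that the test suite does not itself compute.

## 1. The evaluation model

One trait at a time, the package fits

$$ y = X\beta + Z_1 u + Z_2 r + Z_3 r(s) + e $$

with fixed intercept and seed-source effects, additive genetic effects
$u \sim N(0, \sigma^2_a K)$, random replicates $r \sim N(0, \sigma^2_r I)$,
sets nested within replicates $r(s) \sim N(0, \sigma^2_{r(s)} I)$ and
residuals $e \sim N(0, \sigma^2_e I)$. The pedigree-based evaluation (BLUP)
and the marker-based evaluation (GBLUP) share one code path and differ only
in the kernel $K$; the test suite verifies bit-identical results when the
same matrix is passed under either label. Fixed effects are deliberately
minimal (intercept + seed source); in single-orchard subsets a confounded
seed-source contrast is dropped by a rank check with a logged message.

**Assumptions.** Additive gene action only (no dominance/epistasis kernels);
one record per trait per individual (repeated records are supported by the
solver and tested against the half-residual-variance equivalence); traits
are analysed independently; environments are not modelled beyond the
replicate/set design.

### Heritability and accuracy conventions

Narrow-sense heritability is reported as
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_e)$, i.e. the replicate and
set variances are excluded from the denominator. This matches the reporting
convention of the field-trial literature this package follows; an optional
"full phenotypic variance" ratio is available (`heritability(vc, full =
TRUE)`) but is not the default. Standard errors come from the inverse
average-information matrix by the first-order delta method.

Theoretical accuracy of a breeding value is
$r = \sqrt{1 - \mathrm{PEV}/(K_{ii}\sigma^2_a)}$ with the kernel diagonal in
the denominator (so inbred individuals are handled consistently in both
evaluations). PEV values in $[-10^{-10}, 0)$ are clamped to zero (numerical
overshoot); larger violations indicate a model/PEV inconsistency and are
flagged `NA` rather than clamped.

## 2. REML: algorithm and numerical choices

Variance components are estimated by average-information (AI) REML with
expectation-maximisation (EM) fallback. The restricted log-likelihood is
$-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]$.

Implementation: with $H = Z_1 K Z_1'$ eigendecomposed once per fit,
$V = \sigma^2_a H + \sigma^2_e I + [Z_2, Z_3]\,S\,[Z_2, Z_3]'$ becomes
diagonal-plus-low-rank in the rotated basis, and every iteration costs
$O(n^2 m)$ with $m$ = number of replicates + sets (the Woodbury identity in
a square-root form that remains valid when a design variance is exactly
zero). An independent *dense direct-inversion* implementation lives in the
test helpers and is compared against the package on every oracle instance —
the two routes share no code.

Iteration policy, in order:

1. AI step over the free (non-pinned) components; a proposal that would go
   negative is decayed geometrically ($\theta/100$) instead of rejected.
2. If the AI step fails or decreases the likelihood: an EM step with
   geometric overrelaxation (step lengths $1,2,4,\dots,32$ along the EM
   direction, keeping the best non-decreasing point), then step-halving as
   a last resort. Plain EM steps crawl near zero-variance boundaries; the
   overrelaxed variant retains EM's ascent guarantee because every accepted
   point is verified against the current likelihood.
3. Boundary handling: a component with negative score is additionally
   offered an order-of-magnitude shrink (accepted only if the likelihood
   does not decrease); components falling below $10^{-8}\times$ phenotypic
   variance with outward-pointing gradient are pinned at exactly zero and
   released if their gradient later turns positive. Pinned components are
   reported as 0 with a boundary flag. The residual variance is floored at
   $10^{-8}\times$ phenotypic variance — below that the mixed-model
   equations become numerically meaningless — and is never reported as zero.
4. Convergence requires both $|\Delta \log RL| < 10^{-6}$ and a maximum
   relative parameter change below $10^{-6}$ (100-iteration cap).
   Non-convergence returns the last iterate flagged `converged = FALSE`,
   and downstream reports display the `NA` convention for such fits.

Solutions and PEV come from the mixed-model equations at the plugged-in
components, with one step of iterative refinement on the solution and one
Newton step on the inverse used for PEV: the MME parametrisation is
ill-conditioned when $\sigma^2_e/\sigma^2_a$ is extreme, and refinement keeps
the package within $10^{-6}$ of the dense oracle there. A kernel with
eigenvalues below $10^{-8}$ is bent by adding $10^{-6}$ to the diagonal
(logged); trace-scaled G matrices are near-singular by construction whenever
markers are fewer than individuals.

At $\sigma^2_a = 0$ the solver short-circuits: breeding values are zero,
accuracy zero, and fixed effects are generalised least squares under the
remaining design random effects.

## 3. Genomic relationship matrix and marker QC

$G = ZZ'/(\mathrm{tr}(ZZ')/n)$ with $Z = M - P$ and $P$ twice the observed
reference-allele frequency. The source description of this estimator says
"$n$ is the number of markers", but the trace scaling it cites requires
dividing the trace by the number of **individuals** for the mean diagonal to
equal 1; this package scales by individuals, which makes the invariant
`mean(diag(G)) == 1` exact and testable to $10^{-12}$. $P$ is a per-marker
constant broadcast over individuals. Monomorphic markers contribute nothing
(tested as an invariance), and dosages are assumed pre-harmonised to a
single reference allele per marker — no strand flipping is attempted.

Marker QC applies, in order of attribution: platform quality score `qa`
> 0.5, score `qb` > 0.15, MAF > 0.01, call rate > 0.6 (all computed from
non-missing entries), then LD pruning on the survivors at composite
$r^2 \ge 0.9$. The first four rules are order-independent (each marker is
labelled by its first failing rule only for reporting); LD pruning is
order-dependent, so the algorithm is fixed: greedy sliding window of 50
markers, step 5, scanning in genome order and removing the later-positioned
marker of an offending pair. The composite LD estimator is the squared
Pearson correlation of 0/1/2 dosages over pairwise-complete individuals —
computable without phasing, symmetric, and invariant to allele-coding swaps.

**EM imputation.** Missing dosages start at column means; the algorithm then
alternates re-estimating the realized individual-by-individual covariance
from the completed matrix with replacing each missing entry by its
conditional expectation given the observed entries at that marker (computed
through the precision matrix, so each column costs a small solve in the
number of its missing entries). Tolerance $10^{-4}$ on the largest dosage
change, cap 100 sweeps, imputed values clamped to $[0,2]$, observed entries
never moved. Convergence within the cap is comfortable at the tested scale
(hundreds of individuals × ~1000 markers); matrices with many more
individuals than markers make the realized covariance noisy and converge
slowly — `max_iter` is exposed for that case, and on non-convergence the
column-mean imputation is returned with a warning and a flag rather than a
half-converged state.

**LD decay.** Mean composite $r^2$ of intra-chromosome pairs in half-open
distance bins (default width 500 bp, maximum 50 kb). The threshold-crossing
distance (conventionally at $r^2 = 0.2$) interpolates linearly between bin
midpoints; a curve that never reaches the threshold returns `NA` flagged
`not_reached`. Positions are 1-based physical bp; distances are absolute
differences.

## 4. Cross-validation and genetic gain

Predictive accuracy follows the convention
$r_p = \mathrm{cor}(\mathrm{EBV}, \mathrm{GEBV})$: the reference vector is
the **pedigree-model EBV fit once on the full data**, and GEBV are
marker-only predictions of individuals whose phenotypes were withheld.
10 folds × 30 replications at the individual level, folds balanced to within
one individual, replication $r$ seeded `seed + r` so any single replication
reruns in isolation.

Design decisions where the convention leaves room:

* *Per-fold refits.* Variance components are estimated once per scenario on
  the training population and plugged into the per-fold mixed-model solves;
  "one fit" = one MME solve, giving exactly 300 solves per scenario. At
  desk scale this is the standard plug-in shortcut of the CV literature and
  keeps the estimator noise out of the fold-to-fold comparison.
* *Between-orchard scenarios* (training ≠ validation): the full source
  orchard trains every fold; folds partition the target orchard so that a
  10 × 30 prediction structure still exists. Because the training set is
  constant, between-orchard replications differ only through fold
  composition and their spread is near zero — reported as such, not hidden.
* *Unphenotyped validation individuals* are predicted through the joint
  kernel in the MME (masked records), not by a two-step marker-effect
  back-solution; the two are equivalent under GBLUP and the MME route is
  verified against the dense oracle. For GBLUP the kernel must be built
  jointly over training ∪ validation individuals.
* A pedigree kernel with no relationship between validation and training
  (the between-orchard case with unknown sires) is flagged
  `zero_information`; correlations that are undefined because predictions
  are constant return `NA`, never a silent 0.

Genetic gain is the mean breeding value of the top `ceiling(0.2 n)`
individuals, ranked in the trait's favourable direction with ties broken by
id order (determinism). Directions are configurable; the comparison report
shows BLUP and GBLUP side by side per trait and applies the `NA` convention
to non-converged fits. Gains are computed on the genotyped/phenotyped
subset, so pedigree-only ancestors never enter selection.

## 5. The synthetic generator: what it emulates, and what not

The generator produces the *stated world* of the study system at desk
scale: two orchard founder pools ("W", large, mild selection; "T", smaller,
harsh selection) plus an optional small external control group; OP families
with a known mother and pollen parents drawn from the orchard's retained
founder pool (selfing probability 0.04, the estimate quoted for this
population); documented pedigrees that record every sire as unknown while
the realized parents are kept separately for diagnostics; family sizes from
a truncated shifted Poisson on 1–24 with mean 9.6; a replicated design with
sets nested in replicates. Defaults (46 + 25 + 2 families, ~9.6 offspring)
give populations of ~690 genotyped individuals whose documented-pedigree
status numbers bracket the reported field values — these emerge from the
family structure, they are not fitted.

Markers: shared map (11 chromosomes), ancestral allele frequencies
U(0.1, 0.9), per-orchard frequencies diverged by a Balding–Nichols draw
(drift parameter 0.10). Haplotypes come from a latent Gaussian AR(1) copula
whose squared correlation halves at the orchard's `ld_decay_bp` (3 kb for
W-like, 5 kb for T-like, mirroring the reported contrast), checked against
an independent Wright–Fisher forward simulation in the tests. Each orchard
draws its own random ±1 phase sign per marker interval: $r^2$ decay is
unchanged but the *sign* of marker–marker (hence marker–QTL) association is
population-specific, so prediction between orchards can only work through
relatedness — the mechanism behind the near-zero between-orchard predictive
accuracies. Meiosis uses a Haldane-type crossover process at 1 Morgan per
chromosome. Genotype entries are masked completely at random (default 5%)
and two platform quality scores are drawn uniform(0, 1) so every filtering
rule genuinely removes markers.

Phenotypes: `y = 10 + seed-source shift + replicate + set + TBV + e`, with
QTL effects rescaled so the realized TBV variance equals
$\sigma^2_a = h^2_{target}$ exactly, $\sigma^2_e = 1 - h^2$, and replicate /
set variances each 10% of phenotypic variance (the design includes these
terms but no magnitudes are reported; 10% is a typical field-trial share).
The trait direction defaults to higher-is-better and is configurable.

`qtl_in_panel` controls whether causal loci are genotyped. Default `TRUE`
(markers tag the QTL — the favourable case for marker-based selection);
`FALSE` withholds the QTL columns so prediction works purely through LD,
which is the honest setting for divergence experiments: with causal markers
on the panel, effects transfer between populations regardless of LD phase
and the between-orchard collapse cannot be observed.

All randomness derives from one master seed through named substreams
(`substream_seed`), so identical configurations are bit-identical and new
stochastic features never perturb existing draws.

**What a green test does not establish.** The generator has no pedigree
errors, no genotyping error model beyond MCAR missingness, exact
half-sib/selfing paternity (no mixture of correlated pollen donors), a
single generation, no genotype-by-environment structure, and compressed
chromosomes (200 kb) so that marker pairs fall within LD range at desk
scale. Quantities that depend on those features — absolute predictive
accuracies, the surviving marker count of the real chip, the exact reported
status numbers — are emulated qualitatively, not reproduced.

## 6. Status number and pedigree conventions

Group coancestry is computed on the numerator-relationship scale divided by
two, $\theta = \sum_{ij} K_{ij} / (2N^2)$ over the subset, so $N$ unrelated
non-inbred individuals give $N_S = 1/(2\theta) = N$ exactly — the identity
that anchors the definition. Unknown parents are unrelated, non-inbred
founders (the tabular convention); pedigree depth is unlimited and a
topological sort is performed internally, so input files need not be
ordered. Cyclic pedigrees and duplicate ids are structural errors naming
the offenders. `selection_intensity` is the *retained fraction* of
founders: a smaller fraction (harsher selection) concentrates parentage and
lowers the offspring status number, and is also what slows measured LD
decay in the smaller orchard.

## 7. Known limitations

* Single-trait analyses only; no multivariate or GxE models.
* No Bayesian whole-genome regression alternatives to GBLUP.
* No pedigree/parentage reconstruction; the documented pedigree is taken
  as given.
* No sequence-level output (dosages only) and no VCF ingestion; the
  supported dialects are the dense TSV, PLINK-RAW-style text and CSV tables
  documented in the readers.
* The EM imputer targets the individual-covariance structure (families,
  relatedness); it does not exploit marker-order LD directly and is slow
  when individuals greatly outnumber markers.
* Between-orchard cross-validation inherits the design decision that the
  full source orchard trains every fold; its replication spread is
  therefore nearly zero by construction.
* The "across-orchard accuracies are intermediate when orchards share
  founders" property is not tested: the generator draws disjoint founder
  pools, so the property's precondition never holds in the simulated world.
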