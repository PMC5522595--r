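---
title: "Designing SNP panels for conservation monitoring with panelkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SNP panels for conservation monitoring with panelkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkit)
```

`panelkit` implements the full marker-panel design workflow for a species
managed as two small, strongly diverged genetic pools plus their admixed
descendants: quality control, Mendelian and X-linkage screening, per-pool
population-genetic filtering, per-locus informativeness statistics with
nested panel extraction, likelihood-ratio power for relationship inference,
and Bayesian classification of admixed ancestry. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the methodology left room.

## The synthetic study fixture

Every stage is testable offline because `simulate_dataset()` generates data
with the statistical structure of the target study design:

* **Markers.** 1500 biallelic loci by default, 21 of them X-linked, with an
  ancestral allele frequency drawn uniformly on [0.4, 0.6] — an
  ascertainment floor mirroring discovery panels selected for high minor
  allele frequency. Positions are spaced 0.7 Mb apart so loci are plausibly
  unlinked, and genotypes at different loci are simulated independently.
* **Two pools.** Pool allele frequencies follow a Balding–Nichols model:
  given ancestral frequency $p$ and pool divergence $F$, the pool frequency
  is $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, with
  mean $p$ and variance $p(1-p)F$. The two pools get separate divergences,
  default $F = (0.524, 0.193)$. These were fixed once, before any testing,
  by moment matching: $E[H_E] = E[2p(1-p)](1-F)$ with
  $E[2p(1-p)] = 0.4933$ under the ascertainment floor, so the defaults give
  expected pool heterozygosities of 0.235 and 0.398 — the contrast the
  fixture is meant to emulate. Under this model the realized weighted
  Weir–Cockerham $\theta$ between the pools is about 0.35–0.38: a symmetric
  ancestral distribution floored at MAF 0.4 cannot simultaneously reproduce
  both heterozygosity anchors and a between-pool $\theta$ of 0.28, and we
  prioritized the diversity contrast. Tests therefore validate $\theta$
  against a Monte-Carlo calibration band of the generator itself rather
  than against a nominal equality.
* **Pedigree.** Unrelated founders (40) plus 108 single-recorded-parent
  offspring (dyads, alternating known dam and known sire) and 77 two-parent
  offspring (triads), gamete-dropped from pool-1 founders. At X loci sons
  receive only a dam allele (stored homozygous-coded — the hemizygote
  convention) and daughters receive the sire's single X allele plus a dam
  allele. Unrecorded parents contribute population gametes.
* **Degradation.** Each call is replaced with probability $e$ (default
  $10^{-5}$) by a fresh Hardy–Weinberg draw at that marker — so a corrupted
  call can coincide with the truth — and set missing with probability $m$
  (default 0.02). Twenty samples are duplicated as internal replicate
  controls; original and copy receive independent degradation.

What the generator does **not** emulate: linkage and real LD structure
(loci are independent, so LD pruning exercises only sampling noise and
small-sample artefacts of rare alleles), inbreeding within pools, sequencing
batch effects, allele dropout typical of non-invasive samples, null alleles,
and continuous admixture beyond the eight discrete ancestry classes.
Passing tests therefore demonstrate correctness of the statistics and the
machinery on a faithful null structure, not robustness to every artefact of
real field data.

## Quality control

Markers with more than 20% missing genotypes are removed first, then samples
with more than 20% missingness over the retained markers; the strict
inequality and marker-first order make the filter idempotent. Monomorphic
markers are flagged globally or within a pool; all-missing markers are
reported separately as vacuously monomorphic.

Replicated samples are first identity-checked (pairwise concordance at least
0.95 by default — pairs below this are reported as probable sample mix-ups
and excluded), then discordances are tallied over valid (both-called)
comparisons, triplicates contributing all three pairs. With zero
discordances among $V$ comparisons the error rate is reported as the upper
bound $1/V$ to three significant figures. Under the generator's error model
the expected discordance per comparison is $(2e - e^2)(1 - \sum_g P(g)^2)$ —
two independently degraded copies can collide on the same wrong genotype —
and the test suite inverts exactly this expression (the collision
correction) when checking that the injected $e$ is recovered with correct
coverage. The correction lives in the tests, not the product: on real data
the raw discordance rate is the deliverable.

## Mendelian screening, X linkage, sex association

Dyads are inconsistent when parent and offspring share no allele; triads
when no assignment of one allele from each parent reproduces the offspring.
Missing calls never create an inconsistency (a triad with an untyped parent
call degrades to a dyad check). An inconsistency counts as *sire–son* when
the offspring is male and the sire–offspring pair alone already fails —
the signature of an X locus: sons inherit their single X from the dam, so a
hemizygous son stored as a homozygote is incompatible with his sire whenever
their alleles differ, while dam–offspring and sire–daughter comparisons stay
clean.

`flag_x_linked()` requires at least `min_mismatches = 5` inconsistencies of
which at least `sire_son_fraction = 0.9` are sire–son. Both thresholds are
deliberately permissive and configurable: detection power scales with the
number of sire–son pairs and the locus's heterozygosity in the dams, so an
X locus that barely segregates in the pedigree pool is undetectable in
principle (and, being near-monomorphic, also irrelevant downstream). On the
default fixture, where pool 1 is strongly drifted, roughly half the planted
X loci segregate well enough to clear the floor; in the informative regime
(modest divergence, study-scale pedigree) all planted X markers are flagged
with zero autosomal false positives, and that is the property the
acceptance suite pins.

Sex association uses two-sided Fisher exact tests on the allele-count × sex
and genotype-count × sex tables per marker within a pool, BH-adjusted per
table family; pool-monomorphic markers get $p = 1$ by convention.

## Population-genetic filtering

Per-pool statistics count hemizygous males once in X allele frequencies and
exclude them from heterozygosity. $F_{IS}$ uses the ratio-of-sums form
$1 - \sum H_O / \sum H_E$ over polymorphic loci. Between-pool
differentiation is the Weir–Cockerham (1984) estimator: per-locus variance
components $(a, b, c)$ and the weighted multi-locus ratio of sums
$\sum a / \sum(a+b+c)$ — the conventional "weighted" estimator; loci
monomorphic in both pools are skipped, and X loci are evaluated on females
only since the diploid component algebra does not apply to hemizygotes.

Autosomal HWE uses the fixation-index z-test,
$\hat F = 1 - H_O/H_E$, $z = \sqrt{n}\,\hat F$, two-sided
$p = 2\Phi(-|z|)$; $z^2$ is the classical one-degree-of-freedom HWE
chi-square, an identity the tests check numerically. X-linked loci get a
joint exact test conditioning on the total allele count across female
genotypes and male hemizygous alleles; with no males it reduces exactly to
the autosomal (Levene) exact test. The two-sided exact p-value sums the
probabilities of all outcomes no more probable than the observed one.
p-values are BH-adjusted within each marker family.

LD is the squared Pearson correlation of allele dosages over
pairwise-complete samples, computed on user-supplied subsets of unrelated
individuals (founders, in synthetic runs; the default fixture uses subsets
of 35 and 45 to match the study design). Pruning is exact all-pairs greedy:
while any retained pair exceeds the threshold (default $r^2 > 0.5$), the
worst pair loses its lower-MAF member, ties broken by removing the
lexicographically later marker id — deterministic and invariant to input
order. A windowed heuristic was deliberately not used: the markers are
sparse by construction and the all-pairs matrix is what the filter
conceptually operates on. Panels retained per pool are intersected in map
order.

## Informativeness and nested panels

With power sums $a_n = \sum_i p_i^n$ over allele frequencies:

* $\mathrm{PID} = 2a_2^2 - a_4$, and
  $\mathrm{PIDs} = \tfrac14 + \tfrac12 a_2 + \tfrac12 a_2^2 - \tfrac14 a_4$
  for pairs of full siblings (the conservative choice when relatives are
  present).
* Exclusion probabilities (one parent known / no parent known / parent
  pair) follow the Jamieson–Taylor closed forms. Because the literature's
  labels for these formulas are frequently permuted, the test suite pins
  the label-to-formula mapping against an exhaustive enumeration oracle
  (all mother × true-father × child × candidate configurations under HWE),
  to $10^{-10}$, for 2–4 alleles.
* All statistics accept multiallelic frequency vectors, so microsatellite
  panels can be scored with the same code.

The dyad likelihood under IBD coefficients $(k_0, k_1, k_2)$ is
$P(g_1,g_2) = k_0 P(g_1)P(g_2) + k_1 P(g_1) T(g_2|g_1) + k_2 P(g_1)
\mathbf 1[g_1 = g_2]$ with $T$ the share-one-allele transition; genotyping
error mixes in an independent Hardy–Weinberg draw per observed genotype,
giving $(1-e)^2 P + (2e - e^2) P(g_1)P(g_2)$.

**Informativeness for relatedness.** The Fisher information about
relatedness $r$ along the non-inbred path
$k(r) = ((1-r)^2,\, 2r(1-r),\, r^2)$ evaluated exactly at $r = 0$ equals 1
for every polymorphic biallelic locus — a degenerate ranking criterion for
SNPs. `ir_locus()` therefore reports the information averaged over a flat
prior on $r \in (0,1)$ (a uniform prior over the path, in the spirit of the
$\{1,1,1\}$ prior used by relationship-informativeness software), which is
strictly increasing in MAF and ranks loci concordantly with $H_E$; the
$r = 0$ point evaluation remains available via the `at` argument and its
unit value is kept as a test anchor.

**Power for relationship inference.** For two candidate relationships the
per-locus distribution of $\log L(R_1)/L(R_2)$ over genotype pairs is
computed exactly under each hypothesis and convolved across loci on a
discrete grid; the "precision" of the computation is the grid bin width,
default 0.01 log units. The critical value is the smallest grid point with
null exceedance at most $\alpha$ (conservative, non-randomized) and PWR is
the alternative exceedance there. Defaults: $\alpha = 0.05$, genotyping
error $10^{-5}$ for SNPs (0.015 is the conventional choice for
microsatellites). A Monte-Carlo simulation of dyads under each hypothesis
must agree with the convolution within three standard errors; both routes
are kept in the tests.

Ranking sorts best-first per criterion (ties by marker id) and cuts nested
prefix panels, default sizes 343/192/96/48/24/12, with global products
$\prod \mathrm{PID}$ and $\prod(1-\mathrm{PE})$. On biallelic loci all six
criteria are monotone transforms of MAF, so their Kendall $\tau_b$
concordance is exactly 1 up to ties — the provable form of the empirical
rank-agreement the workflow relies on.

## Admixture simulation and classification

Eight ancestry classes are defined by $\varphi = (\varphi_{11},
\varphi_{12}, \varphi_{22})$, the distribution of a locus's two gene-copy
origins: P1 $(1,0,0)$, P2 $(0,0,1)$, F1 $(0,1,0)$, F2
$(\tfrac14,\tfrac12,\tfrac14)$, first backcrosses Bc1 $(\tfrac12,\tfrac12,0)$
and Bc2 $(0,\tfrac12,\tfrac12)$, second backcrosses 2Bc1
$(\tfrac34,\tfrac14,0)$ and 2Bc2 $(0,\tfrac14,\tfrac34)$. Simulation draws
the origin pair from $\varphi$ per locus and each allele from its origin
pool — frequency-based and linkage-free, matching the standard hybrid
simulator's behaviour; a genealogical mode was considered and rejected as
default for that reason.

The classifier is a Gibbs sampler (C++ core) over each individual's latent
class (uniform prior), per-locus latent origin pairs given the class
$\varphi$, per-call allocation of allele copies to pools, and per-pool
allele frequencies under Jeffreys $\mathrm{Beta}(\tfrac12,\tfrac12)$
priors. Frequencies are estimated jointly from the sample by default (a
known-frequency mode exists for calibration tests). The joint model is
symmetric under swapping pools and mirroring classes, so an unsupervised
run's labels are arbitrary; `evaluate_panel_admixture()` anchors them by
comparing the posterior-mean frequencies to the true pool table — standard
mixture-model relabelling, applied after sampling. Default run length is
11,000 iterations with 1000 burn-in; the two post-burn-in half-chains are
compared and a posterior difference above 0.1 for any individual raises a
non-mixing warning. Assignment takes the highest-posterior class only when
it strictly exceeds 0.60, otherwise the individual is reported ambiguous;
confusion matrices carry an explicit ambiguous column.

## Numerical and scale choices

* Genotypes are unordered; every statistic is invariant to allele order
  within a call. Partial calls are rejected as malformed.
* The PWR convolution refuses infinite log-likelihood ratios (set a
  positive error rate to score parent-offspring contrasts).
* Exact-test p-values use log-gamma arithmetic; outcome probabilities are
  compared with a $1 + 10^{-9}$ relative guard against ties lost to
  floating point.
* The pipeline derives per-stage seeds from one master seed so stages are
  independently reproducible; identical configuration and seed give
  byte-identical outputs.
* Test and acceptance problem sizes (e.g. 150–1500 markers, 12–50
  simulated individuals per ancestry class, 2000–5000 Gibbs iterations,
  200 Monte-Carlo replicates for calibration bands) were chosen as the
  smallest sizes at which the checked contrasts are decisively resolved;
  they are stated in the scripts and can be scaled up freely.

## Known limitations

* X-linkage flagging is power-limited by pedigree size and X-locus
  diversity, as discussed above; it reports what segregation data can
  support, not a census of X loci.
* The Weir–Cockerham estimator is implemented for exactly two populations;
  no hierarchical F-statistics.
* The Gibbs classifier handles biallelic loci only; multiallelic ancestry
  classification is limited to simulation plus the informativeness
  statistics.
* Relatedness is treated through likelihood ratios between fixed candidate
  relationships; point estimation of relatedness and sibship
  reconstruction are out of scope.
* LD pruning addresses statistical association only; with no genetic map,
  physical linkage is represented solely through the generator's marker
  spacing.
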