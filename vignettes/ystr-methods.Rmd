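---
title: "Models and methods behind ystrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ystrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpop)
```

`ystrpop` analyses Y-chromosomal STR haplotype surveys: cohorts of
unrelated males genotyped on a fixed marker panel such as PowerPlex Y23
(21 single-copy loci plus the duplicated DYS385a/b, 23 markers in all).
This vignette is the package's own account of the statistics it
implements, the parameters that matter, and the design choices made where
the design was genuinely open.

## Data model and quality control

Alleles are repeat counts; a microvariant such as `13.2` is stored as the
integer pair (13 full repeats, 2 partial bases), never as floating point,
because haplotype identity — the basis of every forensic statistic and of
network collapsing — must be exact. DYS385a/b is one locus holding an
unordered allele pair, canonically sorted ascending so that `"14,11"` and
`"11,14"` are the same genotype.

Two filters mirror standard practice:

* `qc_filter_biallelic()` removes any sample showing more than one allele
  at a *single-copy* locus (a multi-peak genotyping artifact or a private
  duplication). DYS385a/b never triggers removal.
* `reduce_for_rst()` prepares distance-based analyses: DYS385a/b is
  dropped (an unordered pair has no single repeat-difference), then any
  sample still carrying a microvariant at a retained locus is removed,
  because a partial repeat has no integer step distance to a full repeat.
  The order matters: a microvariant only at DYS385a/b costs nothing.

Missing data are deliberately not modeled — a blank cell is a parse error
— because reference-database submissions require complete profiles.

## Diversity and forensic parameters

All four summary statistics are functions of a frequency spectrum
(category counts $c_i$, $n = \sum_i c_i$, $p_i = c_i/n$):

* genetic diversity of a locus, $GD = \frac{n}{n-1}(1 - \sum_i p_i^2)$;
* haplotype diversity $HD$, the same estimator on whole-haplotype
  frequencies;
* discrimination capacity $DC = (\text{distinct haplotypes})/n$;
* combined match probability $CMP = \sum_i h_i^2$.

Implementation note: GD is evaluated as $(n^2 - S)/(n^2 - n)$ with
$S = \sum_i c_i^2$ computed in integer arithmetic, so the monomorphic
endpoint is exactly 0 and the all-distinct endpoint exactly 1, and the
identity $HD = \frac{n}{n-1}(1 - CMP)$ holds to machine precision
whenever both are computed on the same spectrum — which this package
always does. Published surveys occasionally report HD and CMP on
different denominators (e.g. squared frequencies over distinct
haplotypes rather than samples), which breaks that identity; here one
spectrum feeds all three statistics, and rounding happens only at
presentation. Forensic statistics always use the *full* panel (DYS385a/b
pair and microvariants included): discarding markers would discard
discrimination. Only distance-based analyses use the reduced panel.

## AMOVA on repeat-count distances

The molecular distance between reduced haplotypes is the Slatkin-style
sum over loci of squared repeat differences,
$d^2(x, y) = \sum_l (x_l - y_l)^2$ — the convention used when comparing
Y-STR datasets by R_ST. Sums of squares are partitioned from pairwise
distances ($SSD = \frac{1}{N}\sum_{i<j} d^2_{ij}$ within each stratum),
and variance components follow the standard nested ANOVA coefficients;
with a grouping of populations the design has three levels and yields
$\Phi_{CT}$ (among groups), $\Phi_{SC}$ (among populations within
groups) and $\Phi_{ST}$.

Numerical choices:

* **Negative variance components are kept raw** internally (they arise
  legitimately from the unbiased estimator when structure is absent, and
  zeroing them would break equality with any independent oracle); they
  are clamped at zero only in printed percent-of-variance summaries, and
  `pairwise_rst(clamp = TRUE)` offers the same for display. A
  consequence worth knowing: two populations with *identical* haplotype
  multisets give a strictly negative $\Phi_{ST}$ estimate, not 0 — the
  among-population sum of squares is then at its minimum, below its
  null expectation.
* **Permutation schemes**: sample population labels are permuted for
  $\Phi_{ST}$; whole populations are permuted across groups for
  $\Phi_{CT}$. p-values use the add-one convention
  $(1 + \#\{\Phi^* \ge \Phi\})/(B + 1)$ and every permuted analysis is
  seeded, so results are reproducible.
* **Pairwise R_ST** is literally `amova()` on each two-population
  restriction, so the pairwise matrix and the global analysis can never
  disagree about a pair.

`nei_distance()` gives Nei's (1972) standard distance $D = -\ln I$ with
the normalized identity $I = J_{XY}/\sqrt{J_X J_Y}$ and the $J$ terms
averaged arithmetically over loci before the ratio. Under this standard
form a single locus with disjoint allele sets cannot produce an infinite
distance; only total disjointness ($I = 0$) can, and that case is capped
at $\ln 10^3 \approx 6.9$ with a warning rather than returned as
infinity, so toy matrices stay usable by ordination.

`samova_search()` maximizes $\Phi_{CT}$ over partitions of populations
into $k$ groups. The number of such partitions is a Stirling number of
the second kind; when it is at most $10^4$ the search enumerates them
all and is exact. Otherwise simulated annealing is used: single-population
reassignment moves, geometric cooling at rate 0.95 with 100 moves per
temperature from $T_0 = 0.1$ (the scale of typical $\Phi_{CT}$ spreads),
and independent restarts — deterministic given the seed. Group count is
an argument, not a constant, because "regions" are an analysis choice.

## Ordination and geography

`pcoa()` is classical metric scaling (double-centered Gram matrix,
eigendecomposition). Explained percentages are shares of the *positive*
eigenvalues; negative eigenvalues (non-Euclidean input, routine for Nei
matrices) are excluded from the denominator, with a warning when the
most negative exceeds 5% of the largest — beyond that the planar picture
should not be over-read.

`sammon_mds()` minimizes Sammon stress
$E = \frac{1}{\sum \delta_{ij}} \sum_{i<j} (\delta_{ij} - d_{ij})^2 /
\delta_{ij}$ by gradient descent with step-halving line search (initial
step 0.3, Sammon's classic magic factor) from the PCoA configuration.
The PCoA start makes the run deterministic with no RNG at all, and the
line search guarantees a monotone non-increasing stress trace — asserted
on every run, and the property the test suite leans on. Zero
off-diagonal input distances are an error by construction of the stress
weight; callers collapse duplicate objects first.

`haversine_km()` is the great-circle distance on a 6371 km sphere.
`mantel_test()` correlates the upper triangles of two labeled distance
matrices; significance comes from permuting the labels of one matrix
(one-sided, positive association), because distance-matrix entries are
not independent and parametric regression p-values would be wrong. When
the full permutation group fits the budget ($n! \le B + 1$) the
enumeration is exhaustive and the p-value exact. The squared correlation
is reported alongside, as the share of variation in one distance
explainable by the other — the regression framing and the correlation
framing share the same statistic.

## Haplogroup prediction

Y haplogroups are defined by SNPs, but STR allele frequencies differ
enough between haplogroups to predict them. `predict_haplogroup()` is a
naive Bayes classifier: per haplogroup $g$, likelihood
$\prod_l f_{g,l}(a_l)$ with pseudocount smoothing (default $10^{-3}$) so
an allele unseen in one haplogroup cannot veto it; posteriors from
configurable priors (uniform by default, the predictor-tool convention);
and a fitness score

$$\mathrm{score} = 100 \left( \prod_l \frac{f_{g,l}(a_l)}
{\max_a f_{g,l}(a)} \right)^{1/L},$$

the per-locus-normalized geometric mean — 100 means modal at every
locus. A call is `UNASSIGNED` unless score ≥ 40 *and* posterior ≥ 95%
(both thresholds are arguments). The DYS385a/b pair contributes the
product of its two single-allele frequencies. The score scale is this
package's own definition: external predictor tools publish thresholds
but not their internal tables, so the shipped semantics are fixed by the
formula above and the model is always a *synthetic* fixture fitted from
labeled training data (`fit_haplogroup_model()`), typically simulator
output with truth labels. Assignment tallies are properties of whatever
cohort subset the caller passes in — subsetting is explicit, never
implicit.

## Haplotype networks

`collapse_and_msn()` collapses identical full-panel haplotypes into
multiplicity-weighted nodes and connects them by the minimum spanning
*network*: the union of all minimum spanning trees, so tied alternative
links survive (an edge of weight $w$ is included iff its endpoints are
disconnected using only strictly lighter edges). DYS385a/b contributes
the minimum over pair alignments of summed absolute differences (for
sorted pairs, the aligned pairing), and microvariant steps count 0.1 per
partial base — enough to separate `13.2` from `13` without letting one
partial repeat outweigh a full one.

`mj_network()` adds inferred intermediates on the reduced panel, where
state space is integer. Distances are weight-multiplied absolute repeat
differences; weights come from `locus_weights_from_variance()`, binning
each locus's repeat variance as $[0,0.2) \to 10$, $[0.2,0.4) \to 8$,
$[0.4,0.6) \to 6$, $[0.6,0.8) \to 4$, $\ge 0.8 \to 2$. The published
convention states overlapping range endpoints, so a deterministic rule
is required: bins here are half-open on the left (variance exactly 0.2
gets weight 8). Variance is computed over the whole cohort by default
with a `subset` argument for per-haplogroup weighting, since either
scope is defensible.

Median generation is greedy Steiner-point insertion: candidate medians
are the per-locus medians of triplets linked in the ε-relaxed MSN (the
per-locus median minimizes the summed L1 distance to the triplet); the
candidate that most shortens the minimum-spanning length is added, with
lexicographic tie-breaking for determinism, until no candidate shortens
it (or a cap, default 500, is hit); a pruning pass then removes any
median whose removal leaves the spanning length unchanged. By
construction observed haplotypes are never removed and the spanning
length never increases — both are asserted in tests, the star case
against a brute-force Steiner enumeration. A guard (default 200 distinct
haplotypes) keeps the combinatorics honest; per-haplogroup subsets are
the intended unit of analysis, as is conventional for these plots.

## The synthetic-cohort generator

`simulate_cohort()` draws, per sample: a haplogroup from the configured
mixture, a genealogy depth from an exponential distribution, and then
for each locus a Poisson(depth × rate) number of symmetric ±1 repeat
steps applied to that haplogroup's founder haplotype (both DYS385
copies mutate independently). Population labels are assigned by weight
independently of haplotype, so the default cohort has *no* population
structure — matching the empirical situation the package targets, where
nearly all variance is within populations. Microvariants are injected
with per-sample probability 0.02, and an exact, configurable number of
biallelic artifacts (a second allele one repeat longer at a random
single-copy locus) supports QC testing with known truth.

Defaults and why:

* **n = 407 samples, 12 populations in 4 regions** with equal weights —
  the survey design scale the package targets.
* **Haplogroup mix** R1a 51.5%, H 16.2%, L 15.8%, remainder J2 8.5%,
  Q 5%, G 3% — the major-lineage composition typical of pan-Indian
  cohorts; the three majors are exact and the tail is a plausible split.
* **Mutation rates** 2×10⁻³ per locus per generation, with the two
  rapidly mutating loci of the PPY23 system (DYS570, DYS576) at 10⁻² —
  the order of magnitude of published Y-STR rate estimates.
* **Mean genealogy depth 150 generations** (~4–5 kyr at 28–30 yr per
  generation), a late-Holocene expansion scale; with 23 markers this
  yields HD ≈ 0.99 and mostly unique haplotypes, the regime real PPY23
  surveys report.
* Rates must lie in [0, 0.05) and mixtures sum to 1; invalid fields are
  rejected by name.

`simulate_two_pop_divergence()` evolves two population stem haplotypes
independently from one founder for a configurable number of generations
before within-population radiation, producing an expected $\Phi_{ST}$
that grows with divergence time — the knob used for structure-recovery
tests.

What the generator does **not** emulate — and therefore what passing
tests do and do not show: genealogies are star-like (independent
lineages from the founder), not coalescent, so haplotype sharing decays
faster than in real pedigreed populations and the multiplicity spectrum
is geometric-ish rather than clumped; there is no migration, admixture
or drift-induced allele-frequency structure among the default
populations; mutation is strictly single-step (no two-step jumps, no
locus-specific directionality); and no missing data. Tests passing on
these cohorts validate the *estimators* (their algebra, invariances and
oracle agreement) and parameter recovery under a known model — they do
not certify empirical claims about any real population, which require
the real databases.

## Problem sizes and determinism

The test suite runs every stochastic check at desk scale, chosen to keep
the full suite under two minutes while leaving comfortable statistical
margins: 100 simulated cohorts for the HD/CMP identity, 50 random small
cohorts (≤ 12 samples) against the brute-force AMOVA oracle, 20
replicates per divergence setting at 50 samples per population for
monotone $\Phi_{ST}$ recovery, 2000-sample cohorts for classifier and
mixture recovery, and 200 replicates of 99 permutations for p-value
uniformity. Every random quantity in the package — simulation,
permutation tests, annealing — flows from an explicit integer seed, and
`run_ystr_pipeline()` with a fixed config reproduces all artifacts byte
for byte.

## Known limitations

Match-probability corrections (θ-type adjustments) and confidence
intervals on HD are out of scope, as are SNP-based haplogrouping,
reduced-median networks, network time-depth estimation, and demographic
inference from the simulator. The median-joining construction is a
greedy variant optimized for determinism and testability; it satisfies
the containment and length contracts of the classical algorithm but is
not guaranteed to reproduce another implementation's network edge for
edge.
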