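# ystrpop

Population-genetic and forensic analysis of Y-chromosomal STR haplotype
panels (PowerPlex Y23 and compatible), for forensic geneticists building
regional Y-STR reference data and for population geneticists studying
patrilineal structure.

A Y-STR survey genotypes a panel of `L` loci in `n` unrelated males; each
haplotype is the joint vector of repeat counts (with microvariant alleles
such as `13.2`, and the duplicated DYS385a/b locus reported as an unordered
allele pair). `ystrpop` implements the full analysis such a survey runs:

- **I/O and QC** — CSV haplotype tables; removal of samples biallelic at a
  single-copy locus; panel reduction (drop DYS385a/b, drop microvariant
  carriers) for repeat-difference distance analyses.
- **Diversity and forensic parameters** — per-locus genetic diversity
  GD = n/(n−1)·(1 − Σᵢ pᵢ²), haplotype diversity HD (same estimator on
  whole-haplotype frequencies hᵢ), discrimination capacity
  DC = (distinct haplotypes)/n, and combined match probability
  CMP = Σᵢ hᵢ².
- **Structure** — one- and two-level AMOVA on R_ST-style squared
  repeat-count distances with permutation tests (Φ_ST, Φ_CT, Φ_SC),
  pairwise population R_ST, Nei's (1972) standard distance D = −ln I, and
  a SAMOVA-style search for the population grouping maximizing Φ_CT
  (exhaustive when feasible, simulated annealing otherwise).
- **Ordination and geography** — principal coordinates analysis with
  explained-variance shares, Sammon multidimensional scaling with a
  provably monotone stress trace, great-circle distances, and Mantel
  tests of geography against genetic distance (exhaustive enumeration on
  small label sets).
- **Haplogroup prediction** — a naive-Bayes classifier over per-locus
  allele frequencies with the standard assignment contract (fitness score
  ≥ 40 and posterior ≥ 95% or the call is `UNASSIGNED`).
- **Haplotype networks** — minimum spanning networks (union of all MSTs,
  tied links retained) and median-joining networks with variance-binned
  integer locus weights (variance [0,0.2) → weight 10 … ≥ 0.8 → 2).
- **Synthetic cohorts** — a forward stepwise-mutation-model simulator
  (star genealogies from per-haplogroup founder haplotypes, Poisson
  mutation counts of symmetric ±1 steps) that generates cohorts with
  known truth, so every stage above is testable without restricted data.

## Worked example

Simulate a 407-male, 12-population cohort with four engineered biallelic
artifacts, run QC, and compute the forensic parameters and structure:

```r
library(ystrpop)

cfg <- sim_config(seed = 42, n_samples = 407, biallelic_artifact_count = 4)
sim <- simulate_cohort(cfg)

qc <- qc_filter_biallelic(sim$cohort)
qc$cohort
#> Y-STR cohort: 403 samples, 22 loci (23 markers), 12 populations in 4 regions

forensic_summary(qc$cohort)
#> Forensic summary (n = 403, distinct haplotypes = 352)
#>   haplotype diversity (HD):       0.9929014975
#>   discrimination capacity (DC):   0.8734491315
#>   combined match prob. (CMP):     0.009562277953

red <- reduce_for_rst(qc$cohort)      # drop DYS385a/b + microvariant carriers
amova(red, permutations = 199, seed = 1)
#> AMOVA on squared repeat-count differences (n = 392, 12 populations)
#>                    df       SS
#> among_populations  11  298.564
#> within            380 8145.824
#> Variance components (raw):  among_populations = 0.1748, within = 21.44
#> Percent of variance (clamped at 0):  among_populations = 0.8%, within = 99.2%
#> Phi:  phi_st = 0.00809
#> Permutation p (199 perms): phi_st = 0.065
```

The four artifact samples are exactly the ones QC removes; HD near 1 and
CMP near 1/n say almost every male carries a unique 23-marker haplotype
(the panel discriminates well); Φ_ST ≈ 0.008 with p = 0.065 says the
simulated populations are essentially unstructured, as designed — over 99%
of the molecular variance lies within populations.

Haplogroup calls against a model fitted from the simulation's truth
labels recover the configured lineage mixture:

```r
model <- fit_haplogroup_model(qc$cohort,
                              setNames(sim$truth$haplogroup,
                                       sim$truth$sample_id))
batch_predict(qc$cohort, model)
#> Haplogroup predictions: 323 of 403 samples assigned
#> Overall proportions among assigned (%):
#>  R1a    H    L   J2    Q    G
#> 49.2 16.1 15.8  8.4  7.1  3.4
```

`run_ystr_pipeline()` chains all stages (diversity → AMOVA/R_ST/SAMOVA →
Nei + PCoA + Sammon MDS → Mantel → haplogroups → networks) from one
config and writes per-stage CSV/JSON/GraphML artifacts; reruns with the
same config reproduce every output byte for byte.

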