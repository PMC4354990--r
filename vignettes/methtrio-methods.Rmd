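---
title: "Models and methods behind methtrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methtrio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methtrio analyses matched trios of normal kidney (NK), nephrogenic rest
(NR) and Wilms tumour (WT) methylomes measured as beta-values
(β ∈ [0,1], the methylated signal fraction per CpG). This vignette
explains the statistical models, the defaults and why they were chosen,
what the synthetic-cohort generator does and does not emulate, and the
numerical conventions that make results reproducible.

## Differential methylation

All differential models operate on β directly, so effect sizes are
interpretable as methylation differences (Δβ); an M-value transform
(`beta_to_m()`, `m = log2(β/(1-β))`, clipped at 1e-6) is provided for
users who prefer the variance-stabilized scale.

**Paired contrasts.** For two tissues of the same patients, the model is a
one-sample test on within-patient differences, which for complete pairs is
exactly the patient-blocked two-group linear model but simpler and
testable in closed form. Per-probe variances are moderated by the standard
empirical-Bayes hierarchy: sample variances are scaled chi-square around
σ²_g, and 1/σ²_g is chi-square with prior degrees of freedom d₀ and prior
variance s₀². The hyper-parameters are fitted by method-of-moments on the
log variances (digamma/trigamma identities; the trigamma inverse uses
bounded Newton steps). The posterior variance is the df-weighted average
of prior and observation, the moderated t gets d₀ + df degrees of freedom,
and p-values are BH-adjusted. With constant planted differences the
moderation keeps the statistic finite (s₀² > 0); with d₀ = 0 the ordinary
paired t is recovered, and with identical variances d₀ → ∞ and all probes
share the pooled value. The unit tests verify hyper-parameter recovery on
simulated variance mixtures and agreement with an independent
empirical-Bayes implementation.

**Three-way ANOVA.** The NK/NR/WT contrast uses a linear model with a
3-level tissue factor and patient blocks (blocking is the default because
trios are matched; an unblocked variant is available via `blocked =
FALSE`). The 2-df tissue term is tested with a moderated F. Genome-wide
significance uses the raw p < 5e-8 convention, deliberately not an FDR,
because this set seeds the unsupervised subtype analysis and a fixed
threshold keeps it comparable across cohorts. Numerical zeros from the
projection arithmetic are clamped (relative epsilon 1e-10) so that
degenerate probes yield F = 0, p = 1 rather than noise-driven values, and
a positive tissue sum of squares over a zero residual yields F = ∞, p = 0.

## Probe-lasso DMR detection

Array probes are distributed very unevenly, dense at transcription start
sites and CpG islands, sparse in open sea. A fixed window would therefore
either fragment island signals or bridge unrelated open-sea probes. The
probe lasso adapts: for every gene-feature × CpG-island-relation category,
the radius is the median (configurable quantile) of the nearest-neighbour
distances within that category, floored at half the global minimum lasso
size (10 bp). Categories with fewer than two probes inherit the global
median.

"Connected" is formalized as mutual containment — two significant probes
are linked when each lies within the other's lasso — because mutual
containment is symmetric and makes the result independent of probe
ordering; connected components with at least 3 significant probes become
regions. All probes inside the union of the member lassos join the region
(non-significant interior probes temper the combined significance), and
regions on one chromosome whose bounds are closer than 1 kb are merged.
The gap is measured between region bounds (end-to-start, half-open), not
between probe positions: bounds are what the output reports, so the rule
is checkable from the output alone. The combined region p-value is
Stouffer's Z over the member probes' one-sided p-values aligned to the
region direction (the sign of the mean Δβ over significant members);
one-sided p-values are clamped to [1e-300, 1 − 1e-16] before the normal
quantile. The implementation is validated against a brute-force
connectivity oracle on hundreds of random fixtures.

## Reference-free cell-mixture adjustment

Bulk tissue methylation mixes cell types, and composition differences
between tissues masquerade as differential methylation. Without reference
methylomes the mixture must be estimated from the data itself:

1. per-probe OLS of the design (patient blocks + tissue, or intercept +
   group for unpaired contrasts) gives coefficients and residuals;
2. the top-d left singular vectors of the residual matrix estimate the
   latent *loadings* (the probe-space signature of composition axes);
3. per-sample *scores* are re-estimated by regressing the centred data —
   not the residuals — on those loadings. This step matters: residual-based
   scores are exactly orthogonal to the design, so re-fitting with them
   cannot change any design coefficient; centred-data scores retain the
   design-correlated component of composition, which is precisely what the
   adjustment must remove;
4. a per-probe re-fit on [design | scores] separates the direct
   (phenotype) effect from the mixture-mediated one.

With d = 0 the procedure reduces exactly to the unadjusted OLS fit.

P-values are bootstrap-derived. The default is a studentized bootstrap:
patients (or samples within groups) are resampled with replacement, the
whole procedure is repeated, each replicate's coefficient deviation is
studentized by its own model SE, and p is the add-one exceedance fraction.
On synthetic confounded cohorts of 20 patients this is well calibrated at
the 1% level, whereas the plain normal approximation from the bootstrap SE
is anticonservative by a factor of 2–6 (the bootstrap SE both
underestimates at n = 20 and ignores the heavy tails of β-scale
differences); both the normal approximation and a centred raw-fraction
mode remain available and are recorded in the output metadata. At the
default 100 replicates the p-value floor is 1/101 ≈ 0.0099.

The latent dimension can be fixed (default d = 3, matching the three
kidney cell compartments the generator simulates) or estimated by
permutation parallel analysis: observed singular values are compared,
component by component, with the 95th percentile of singular values from
column-permuted residual matrices. On full synthetic cohorts the estimator
returns more than 3 components because the logistic link spreads a 3-type
mixture across additional small axes; the fixed default keeps the
adjustment at the effective mixture rank (a d-type simplex has d − 1 free
axes).

**A caveat on subgroup-structured cohorts.** When a tumour subgroup carries
a broad, coherent methylation signature that is not encoded in the design,
that signature forms a dominant residual axis and is statistically
indistinguishable from a composition axis — the latent scores absorb it and
the "adjusted" effects vanish. The pipeline therefore runs the WT-vs-NR
adjustment within the discovered group-1 pairs, where the signature is
aligned with the design; this is a deliberate design choice, and users
adjusting heterogeneous contrasts should be aware of the identifiability
limit.

## Subtype discovery

Consensus clustering follows the usual subsampling recipe: 1,000
resamples of 80% of samples, average-linkage hierarchical clustering on
1 − Pearson correlation distance, consensus = co-clustering frequency
among co-sampled pairs, final assignment by clustering 1 − consensus.
These internals are conventional choices; none is data-derived. The
number of clusters may be selected by the largest relative change in the
area under the consensus CDF, but the trio pipeline fixes k = 3 — the
structure it interrogates is "NK / NR-like / tumour-distinct". WT samples
in clusters containing at least 20% NRs are assigned to group-2 (they
co-cluster with their precursor lesions); the threshold tolerates a stray
NR inside a tumour cluster. Identical samples make the correlation
distance degenerate; the result is flagged rather than clustered.

Classical (Torgerson) multidimensional scaling wraps the standard
double-centering eigendecomposition with a fixed sign convention (first
nonzero coordinate of each axis positive) so embeddings are bitwise
reproducible. Probe-wise Bartlett tests are vectorized across probes and
verified against the textbook formula to 1e-10; probes with zero variance
in every group return p = 1 (flagged), zero variance in some group yields
K² = ∞, p = 0 (flagged). Cluster–clinical association uses Pearson's
chi-square without continuity correction by default (Yates optional).

## Multisampling enrichment and the hypermethylation rule

Enrichment of a probe set in a genomic feature set is measured against
equal-size draws without replacement from the post-filter probe universe —
size-matched but not GC- or probe-type-matched. The empirical p uses the
add-one convention on the side indicated by the enrichment sign, so 100
draws give the familiar 0.0099 floor. Because the side is chosen by the
sign, that reported p cannot be uniform under the null (it concentrates
below 0.5); the result also carries fixed-side `p_greater`/`p_less`, and
calibration properties are stated for the fixed-side value. Probe-level
overlap (a region is "in" a feature through its member probes) is the
default; positions are 1-based, features 0-based half-open, and a probe at
position pos overlaps [start, end) iff start < pos ≤ end.

The hypermethylation call is purely arithmetic: a tumour is called at a
DMR when its mean β over member probes strictly exceeds the reference
cohort's mean + 1 SD, where mean and SD (n − 1) are taken over per-sample
DMR means — not over all CpG × sample values, which would conflate
within-region with between-sample variation. NA-robust means make the
call invariant to all-NA probes.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with ground truth for every planted signal:

- **Baseline methylomes** are bimodal on the logit scale (hypo- and
  hyper-methylated modes plus an intermediate class), the familiar
  450k-type β distribution.
- **Cell mixtures**: d = 3 latent cell types with Dirichlet per-sample
  weights; concentrations are tissue-specific (NK and EK differ from NR).
  By default NR and *both* WT groups share the same concentrations, so the
  paired WT-vs-NR contrast is exactly null when nothing is planted;
  tumour-composition confounding is an explicit switch
  (`confounded_config()`). Mixture-sensitive probes (15% by default) carry
  per-cell-type logit offsets and sit at intermediate baselines
  (β ~ U(0.35, 0.65)), where proportion-weighted mixing of β is close to
  linear — cell-composition markers are intermediate-methylation CpGs, and
  this is also the regime in which a linear reference-free adjustment is
  well specified.
- **Planted signals**: contiguous DMRs (4–8 probes) hosted in dense CpG
  islands for the NR-vs-NK ("KR", 55% hypermethylated, Δβ = 0.30) and
  group-1-WT-vs-NR ("WT", 73.6% hypomethylated, Δβ = 0.35) contrasts, plus
  scattered non-adjacent single-probe MVPs for both contrasts (5% of
  probes each — tumour and precursor methylomes carry far more isolated
  MVPs than DMR-clustered ones, and without them the genome-wide
  significant set would be dominated by a single contrast and the
  three-cluster topology would not be recoverable). Shifts are computed on
  the logit scale so that the β-scale difference at the baseline equals
  the configured Δβ; Monte-Carlo checks confirm realized mean differences
  within 20%.
- **Island geometry**: islands come in a dense (15–45 bp spacing) and a
  loose (60–200 bp) regime, with shores and shelves flanking them and
  sparse open-sea probes between. Planted DMRs live in dense islands; the
  category-wide median nearest-neighbour distance then sits between the
  regimes, so the lasso connects genuinely clustered signals without
  bridging sparse ones. (With homogeneous spacing, a median-based radius
  would structurally disconnect about half of adjacent pairs, since the
  nearest-neighbour distance is the minimum of two gaps.)
- **Patients and subgroups**: patient random effects shared within a trio;
  13 of 20 tumours form group-1, which alone receives the planted WT
  effects and a 1.5× probe-noise multiplier (hypervariability); 9 of the
  13 group-1 patients are bilateral, group-2 is entirely unilateral.
  Group-2 WTs are drawn from the same distribution as their NRs.
- **Embryonic kidney**: 4 unmatched EK samples with their own composition;
  planted NR/WT-vs-EK probes (1.5% of the array, Δβ = 0.3), 35% of the
  hypermethylated ones placed inside the `prc2_targets` feature set — the
  planting rate was chosen so that the in-feature fraction among *detected*
  hyper pheno-MVPs lands near 20% after detection dilution. 15% of
  hyper-KR-DMRs fall inside `bivalent_domains`, against a ~4% island
  background.

What the generator does **not** emulate: array chemistry (type I/II probe
behaviour, detection chemistry beyond a configurable failure-rate flag
matrix), batch and slide effects, FFPE degradation, SNP-driven outliers,
correlated noise along the genome, or realistic chromosome counts (four
autosomes plus a small chrX stand in for the genome). Passing recovery
tests on these cohorts therefore demonstrates the correctness and
calibration of the statistical machinery under its own assumptions, not
performance on raw array data — in particular, normalization is assumed
done before the pipeline starts.

## Numerical conventions and test scales

Probe positions are 1-based (array-manifest convention); every exported
interval (DMRs, features) is 0-based half-open BED, with boundary
behaviour unit-tested in both directions. Beta TSVs are written with 10
decimals so round-trips are stable to 1e-9; missing values are "NA", and
model-fitting operations drop probes with any NA among the used samples.
Ties in the top-variable ranking break lexicographically by probe id.
Every stochastic operation takes an explicit seed and restores the
caller's RNG state; pipeline outputs are a pure function of inputs,
configuration and seed (rerun-identical, verified byte-for-byte in the
tests).

The test suite exercises cohorts of 6,000–20,000 probes and 20 trios:
full-scale (20,000-probe) cohorts for FDR control (10 replicates),
planted-DMR recovery and the ten-seed subtype-topology check, 8,000-probe
cohorts for deconvolution calibration, and 200 small random fixtures
(≤ 200 probes) for exact brute-force equivalence of the probe lasso. These
sizes give stable Monte-Carlo estimates for every property asserted while
keeping a full run in the low minutes on one core.

## Known limitations

- The probe-lasso category radii depend on the annotation's category
  vocabulary; unseen categories fall back to the global quantile rather
  than erroring.
- The reference-free adjustment assumes the mixture acts approximately
  linearly on β and at an effective rank ≤ d; strongly bimodal
  composition markers or subgroup-wide signatures violate this (see the
  caveat above).
- Bootstrap p-values are bounded below by 1/(n_bootstrap + 1); joint
  thresholds such as p < 0.01 require n_bootstrap ≥ 100.
- The consensus k = 3 default encodes the three-tissue expectation of the
  trio design; other designs should set `consensus_k` or use auto
  selection.
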