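---
title: "Methods: models, parameters and design choices in permamicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in permamicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permamicro)
```

permamicro implements the computational chain of a paired soil-warming
study: isotope-based microbial physiology, biomarker necromass accounting,
random-matrix-theory (RMT) co-occurrence networks, gene-family enrichment
scoring, and permutation community statistics, all driven by a synthetic
generator with recorded ground truth. This vignette explains the models,
their assumptions, the tunable parameters, and the design decisions taken
where the methods literature leaves room.

## The paired design

The experimental unit is a block holding one control and one warming plot;
`validatePairedDesign()` enforces exactly one sample per (block, treatment,
year). All treatment contrasts are paired two-sided t-tests on the
block-wise differences `d = warming − control`; `t = mean(d)/(sd(d)/√n)`
on `n − 1` df. A zero-variance difference vector is reported as a flagged
degenerate result (t undefined, p = 1 when the mean difference is 0) rather
than an error, since noiseless simulated data legitimately produce it.

## ¹⁸O physiology

Growth is inferred from ¹⁸O-water incorporated into DNA over a 24 h, 15 °C
closed-vial incubation of 0.3 g soil in a 50 ml vial at 20 at% ¹⁸O in final
soil water (all defaults, all overridable per record):

- `DNA_produced (µg) = O_total · (O_excess/100) · (100/O_label) · (100/31.21)`,
  where `O_total` is the µg O in the dried DNA extract, `O_excess` the at%
  ¹⁸O of the labelled extract minus the **mean** natural-abundance at%
  across the run's unlabelled replicates, and 31.21 the mass percentage of
  oxygen in an average DNA molecule.
- `G (µg C g⁻¹ h⁻¹) = (C_mic/DNA_mic) · DNA_produced / (w·t)`, scaling new
  DNA to biomass C by the sample's own MBC : DNA ratio. MBC is the
  fumigation-extraction flush divided by 0.45.
- `R` converts the headspace CO₂ excess over empty-control vials to carbon
  via the ideal gas law at incubation temperature. The headspace volume is
  taken as the vial volume: the 0.3 g soil aliquot occupies ≈0.2 ml of
  50 ml, a ≤0.5 % bias smaller than the gas chromatograph's precision, and
  no pressure correction is applied (vials are crimped at ambient
  pressure).
- `CUE = G/(G+R)`, `T_m = 24·G/C_mic` (day⁻¹), `G_m = 1000·G/C_mic` and
  likewise `R_m` (mg C g⁻¹ C_mic h⁻¹). `R_m` uses the MBC measured at the
  start of the incubation; over 24 h at these turnover rates
  (≈0.01 day⁻¹) the distinction from final MBC is negligible.

Degenerate inputs are handled by flooring, not failure: a negative ¹⁸O
excess (natural-abundance scatter around zero signal) or sample CO₂ below
the blank yields 0 with a flag column in `physiologyTable()` output,
because small-signal noise is expected in real runs.

## Amino-sugar necromass

Bacterial necromass C is `45·m` (muramic acid, found only in bacterial
peptidoglycan); fungal necromass C is
`(n/179.17 − 2·m/251.23) · 179.17 · 9`, i.e. total glucosamine minus two
moles of GluN per mole of MurA (the bacterial share), converted with factor
9. 179.17 and 251.23 are the molecular weights of GluN and MurA. If the
bacterial correction exceeds total GluN the negative value is floored at 0
and flagged — the conversion factors are population averages and can
overshoot in strongly bacterial soils. Totals are bacterial + fungal by
definition. The proportion of SOC converts SOC from g C kg⁻¹ to µg g⁻¹
with a single factor of 1000 held in one internal constant table.
Internal-standard quantification (`aminoSugarContent()`) uses a response
factor of 1 per analyte unless a calibration is supplied; per-run GC
response factors are rarely published, and the default keeps peak-area
inputs interpretable.

## Co-occurrence networks

Within one treatment's samples the pipeline keeps features with a non-zero
count in **every** sample (so a pseudocount is unnecessary), converts to
relative abundance on the rarefied table, log₁₀-transforms, and computes
Pearson correlations across samples. The prevalence filter is the standard
reliability guard for correlation networks at n = 10; it also means the
log transform is always defined.

**RMT thresholding.** Candidate cutoffs are scanned (default 0.30–0.99 by
0.01). At each cutoff, sub-threshold entries are zeroed and the eigenvalue
spectrum examined: degenerate eigenvalues are collapsed, the empirical
cumulative spectral distribution is smoothed with a cubic smoothing spline
(df capped at 15), and the nearest-neighbour spacings (normalised to unit
mean) are histogrammed over [0, 3] in 0.1-wide bins plus an overflow bin.
Chi-square goodness-of-fit compares the counts against the Poisson law
`e^{-s}` and the Wigner surmise `(π/2)·s·e^{-πs²/4}`, pooling tail bins
until each expected count reaches 3. The chosen threshold is the smallest
cutoff whose spacings conform to Poisson (p > 0.05) for three consecutive
scan steps — random (GOE-like) noise correlations have been pruned, real
block structure remains. A spectrum that collapses to fewer than 20
distinct eigenvalues is the independent (diagonal) limit and conforms by
construction. When a scan finds no conforming cutoff below 0.99 the
function stops and asks for a manual threshold. For cross-treatment
comparisons `runPipeline()` defaults to a uniform threshold, the larger of
the two per-treatment RMT thresholds.

**Topology and modules.** Edges carry the correlation and its sign;
isolated nodes are dropped. Average degree is `2L/n`; average clustering is
the mean local transitivity with degree-<2 nodes counted as 0. Modules come
from greedy modularity maximisation (deterministic agglomeration), and
relative modularity is `(M − mean(M_null))/mean(M_null)` over
degree-preserving Maslov–Sneppen rewirings (10·L swaps each, default 100
nulls; fewer than 10 warns). Node roles use within-module degree z-scores
`Zi` (0 where a module's degree sd is 0; sample sd) and participation
`Pi = 1 − Σ_m (k_im/k_i)²`, with the conventional thresholds `Zi > 2.5`
(module hubs) and `Pi > 0.62` (connectors); keystones are all
non-peripheral nodes. Module eigengenes are the first principal component
of the standardised member profiles, sign-oriented to the mean member
profile, and correlated with each environmental covariate (Pearson,
two-sided); modules smaller than 3 are skipped with a flag.

## Gene-family enrichment

Per sample, `RA_i = (r_i/L_i)/Σ_j(r_j/L_j)` length-normalises read counts
over the whole gene catalog; unannotated genes stay in the denominator but
contribute to no label, so family totals are subadditive. LEfSe-style
scoring works per family: a Kruskal–Wallis test (with two groups this is
the rank-sum test, kept as KW for fidelity to the published tool), then,
for families passing p < 0.05, the effect size is log₁₀ of the
bootstrap-averaged absolute difference of group means along the
one-dimensional discriminant axis, with abundances pre-scaled to parts per
million so the conventional |LDA| > 2 cutoff applies. Three deliberate
divergences from the hosted LEfSe tool, all documented here because its
internal normalisation is version-dependent: (i) the subclass Wilcoxon
stage is skipped — a two-arm paired design has no subclasses; (ii) in
balanced designs both groups share one subsampling pattern per bootstrap
round, which makes the score exactly antisymmetric under label swap;
(iii) p-values are unadjusted by default (the conventional reporting rule
for this analysis), with Benjamini–Hochberg available via `adjust = TRUE`.
Scores are comparable to the original tool in rank and threshold
behaviour, not bit-identical.

## Community statistics and carbon pools

Bray–Curtis, richness and Shannon diversity are delegated to vegan on
rarefied tables (rarefaction is a seeded multivariate hypergeometric draw
per sample, i.e. subsampling without replacement to the minimum depth).
PERMANOVA, ANOSIM and MRPP are implemented in-package so that permutation
handling is fully controlled: one-factor pseudo-F from the Gower-centred
decomposition of squared distances; ANOSIM's rank statistic normalised by
`N(N−1)/4`; MRPP's group-size-weighted mean within-group distance with
chance-corrected `A = 1 − δ/E[δ]` using the permutation mean as
expectation. P-values are `(1 + #extreme)/(1 + n_perm)` with a fixed seed,
hence never below `1/(n_perm+1)`; for two small groups an exact mode
enumerates all label assignments. Permutations are unrestricted by default
— the blocked design mainly couples abundance *levels*, which relative
abundances largely cancel — but a `strata` argument restricts permutations
within blocks for users who prefer the conservative variant. vegan's
implementations serve as independent cross-checks in the test suite, never
as the computation.

Variation partitioning between plant and edaphic covariate sets uses RDA
with Ezekiel-adjusted R² and inclusion–exclusion (vegan::varpart);
components can be slightly negative and are reported as computed. Carbon
pools: per-sample fraction C stocks are mass × concentration / initial
mass; proportions divide by **recovered** C by default (robust to <100 %
recovery; bulk SOC denominator available), recoveries above 105 % are
flagged, and the R_h warming effect is `(mean_W − mean_C)/mean_C · 100` on
per-sample seasonal means.

## The synthetic generator

`generateExperiment()` works by inverse measurement models: truths first,
observables back-calculated so the forward pipeline recovers the truths
*exactly* at `cvNoise = 0` (the central identity test), then mean-one
log-normal noise. Its defaults are the study conditions the package
emulates: 10 blocks; CUE 0.41 (control) vs 0.34 (warming) with growth
unchanged and respiration carrying the contrast; necromass 28 % vs 31 % of
SOC (bacterial share 0.30 — fungal residues dominate such meadow soils);
MAOC 65 % vs 71 % of recovered C with POC held at 20 %; R_h +41 %; topsoil
warming 1.5 °C (within the observed 0.8–2.2 °C); 30 warming- vs 13
control-enriched gene families at 3-fold change; mass recovery drawn in
[0.945, 0.985] and C recovery in [0.975, 0.99].

Choices a scientist should know:

- **Block effects** are one shared log-normal multiplier (sd 0.15 on the
  log scale) applied to both arms of a block — the structure that makes
  paired tests strictly more powerful than unpaired, which is the design's
  purpose.
- **Noise** is a single `cvNoise` (default 0.1) scaled per instrument:
  headspace GC, isotope-ratio MS excess and field flux chambers carry the
  full cv; TOC-analyser flushes, PicoGreen DNA yields, GC-FID amino sugars
  and elemental-analyser fraction C carry half of it, reflecting the usual
  precision ranking of those instruments.
- **ASV tables** are multinomial draws at a per-sample depth
  (`seqDepth` minus a simulated loss of up to 5 %) from log-normal latent
  abundances. Planted-module members share a latent factor (pairwise
  latent correlation 0.99, chosen so that, at n = 10 samples per arm, the
  sample correlations survive the RMT threshold and ≥90 % of planted
  within-module edges are retained); under warming the factor variance is
  multiplied by `warmingModuleBoost`, so warming networks are denser. One
  prokaryotic module's factor follows standardised soil temperature,
  giving the eigengene analysis a known covariate-driven module. Planted
  members are guaranteed present in every sample (a one-count transfer
  from the most abundant feature repairs the rare multinomial zero).
- **Gene tables** use integer per-bp coverages with counts =
  coverage × length, so length normalisation is consequential and, at zero
  noise, enriched families have exactly `foldChange`-times the
  length-normalised coverage. A 600-gene unannotated background dominates
  the denominator, putting family abundances in the realistic
  ~100–500 ppm range that makes the |LDA| > 2 rule meaningful.
- **What it does not emulate:** compositional correlation artefacts (no
  SparCC-style effects are induced or corrected), taxon-specific dynamics,
  chimeras or sequencing error, within-season R_h autocorrelation, or any
  particular between-plot covariance beyond the shared block multiplier —
  the generator is calibrated to reproduce reported means ± SE, not full
  covariance structure. Passing recovery tests therefore demonstrates the
  pipeline's correctness and calibration under this model, not robustness
  to every pathology of real sequence data.

Determinism: every stage derives its seed from the single config seed via
a fixed affine map mod 2³¹−1, so stages are independently reproducible and
two runs of `runPipeline()` with the same config produce byte-identical
data files (verified by manifest digests).

## Problem sizes used by the test suite

The suite exercises the generator at its default size (300 + 150 ASVs,
1 200 genes, 20 samples) for end-to-end checks, 50-block variants to
estimate latent correlations, 200 simulations for the type-I calibration
of the permutation tests and the Kruskal–Wallis false-positive rate,
50 + 50 spectral draws for the NNSD classifier, and 20 generator seeds for
enrichment sensitivity — sizes at which Monte-Carlo error is well inside
the asserted tolerances while a full run stays in the minutes range on one
CPU.

## Known limitations

- The RMT scan convention (0.01 step, Poisson conformity at chi-square
  p > 0.05 sustained for three steps, [0, 3] × 0.1 spacing histogram) is a
  de facto standard rather than a published constant; other pipelines may
  select slightly different thresholds on the same matrix.
- LEfSe scores match the published decision rule, not the hosted
  implementation bit for bit.
- Greedy modularity is deterministic but can split giant modules
  differently from Louvain-family algorithms; relative modularity is
  robust to this because the nulls are scored with the same algorithm.
- The multivariate tests are one-factor; repeated-measures and
  multi-factor designs are out of scope.
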