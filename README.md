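# permamicro

Analysis toolkit for paired (blocked) soil-warming experiments in permafrost
and other cold-region soils, for microbial ecologists and biogeochemists who
measure how warming reshapes the microbial mediation of soil carbon. It
covers the full desk-side computational chain of such a study:

- **¹⁸O-water microbial physiology.** Growth is measured
  substrate-independently from ¹⁸O incorporated into newly synthesised DNA:
  `DNA_produced = O_total · (O_excess/100) · (100/O_label) · (100/31.21)`
  (31.21 = mass % of O in DNA), converted to biomass carbon via
  `G = (C_mic/DNA_mic) · DNA_produced / (w·t)` with MBC from
  chloroform fumigation-extraction (flush / 0.45). Respiration `R` comes
  from closed-vial headspace CO₂ against empty controls (ideal-gas
  conversion), and carbon use efficiency is `CUE = G/(G+R)`, with turnover
  `T_m = 24·G/C_mic` and mass-specific rates `G_m`, `R_m`.
- **Amino-sugar necromass.** Bacterial necromass C `= 45·m` (muramic acid),
  fungal necromass C `= (n/179.17 − 2m/251.23)·179.17·9` (glucosamine
  corrected for its bacterial share), summed and expressed as a proportion
  of SOC.
- **Co-occurrence networks.** Per-treatment Pearson correlation of
  log₁₀ relative abundances (features present in all samples), thresholded
  where the eigenvalue nearest-neighbour spacing distribution turns from
  GOE (Wigner) to Poisson statistics (random-matrix-theory thresholding);
  topology, greedy-modularity modules, relative modularity against
  Maslov–Sneppen degree-preserving nulls, Zi–Pi keystone roles and module
  eigengene–environment correlations.
- **Gene-family enrichment.** Length-normalised gene relative abundance
  `RA_i = (r_i/L_i)/Σ_j(r_j/L_j)` aggregated to CAZy families/classes/KOs,
  scored LEfSe-style (Kruskal–Wallis + bootstrap linear-discriminant effect
  size; enriched at `|LDA| > 2` and unadjusted `P < 0.05`).
- **Community and carbon-pool statistics.** Richness/Shannon, Bray–Curtis,
  from-scratch PERMANOVA/ANOSIM/MRPP with seeded (or exhaustive)
  permutations, RDA variation partitioning of plant vs edaphic drivers, and
  POC / heavy-POC / MAOC bookkeeping with mass- and C-recovery diagnostics.
- **A synthetic-data generator** (`generateExperiment()`) that emulates a
  10-block paired warming design with known ground truth (per-sample G, R,
  CUE, necromass and MAOC proportions, planted network modules, enriched
  families, R_h effect), so the entire pipeline is testable end to end
  without any sequencing download.

## Worked example

```r
library(permamicro)
sim <- generateExperiment(GeneratorConfig(seed = 7L))
ph  <- physiologyTable(sim$experiment)
subset(ph$contrasts, variable %in% c("Gm", "Rm", "CUE"),
       select = c(variable, mean_control, mean_warming, t, df, p))
#>   variable mean_control mean_warming     t df        p
#> 1       Gm        0.327        0.345  1.46  9 0.179013
#> 2       Rm        0.497        0.672  5.11  9 0.000634
#> 3      CUE        0.398        0.340 -3.46  9 0.007130

nt <- necromassTable(sim$experiment)
subset(nt$contrasts, variable == "prop_of_soc",
       select = c(variable, mean_control, mean_warming, t, p))
#>      variable mean_control mean_warming   t        p
#> 5 prop_of_soc        0.278        0.311 9.8 4.24e-06

carbonPools(sim$experiment)$rhWarmingEffectPct
#> [1] 39.97715
```

Reading: warming leaves mass-specific growth unchanged but accelerates
mass-specific respiration, so CUE drops (here 0.40 → 0.34, paired t-test
across the 10 blocks); microbial necromass rises from 27.8 % to 31.1 % of
SOC; heterotrophic respiration increases by ~40 %. These recovered values
sit on the generator's configured truths (CUE 0.41/0.34, necromass
0.28/0.31, R_h +41 %) within measurement noise, which is exactly what
`checkRecovery()` verifies.

`runPipeline(GeneratorConfig(seed = 7L), outDir = "run1")` executes the
whole chain (simulation, rarefaction, physiology, necromass, per-treatment
RMT networks, enrichment, multivariate statistics, carbon pools) and writes
every stage table, a markdown report and a JSON manifest with per-stage
seeds and file digests, so a run is reproducible byte for byte.

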