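# rootscreen

Screening tools for root-system-architecture trials of crop genotypes under
drought and low-phosphorus stress.

Breeding for water- and phosphorus-limited environments leans on root
traits: deep, long root systems improve water capture under drought, and
long, fine roots improve uptake of immobile phosphorus. Semi-hydroponic
phenotyping platforms make it feasible to measure root systems of on the
order of a hundred genotypes under factorial stress treatments — control
(C), low phosphorus (LP), PEG-induced osmotic drought (D) and their
combination (DLP) — in replicated blocks. `rootscreen` implements the
complete downstream analysis for such a trial, from per-plant raw
measurements to ranked, grouped genotypes, for quantitative geneticists and
root physiologists working in R.

## What it computes

Starting from a per-plant table (maximum root depth, root number, root
length and mean diameter per 20 cm depth layer, root/shoot dry weights,
shoot height, leaf and tiller counts, root/shoot P concentrations):

- **Trait derivation** (`derive_traits`): 35 global and depth-local traits —
  totals (RL, RA, RV), ratios (SRL = RL/RDW, RTD = RDW/RV, RSR = RDW/SDW,
  RLI = RL/MRD, RLD = RL/1430 cm²), growth rates (RGR = MRD/DAT,
  SGR = SH/DAT), phosphorus contents (RP, SP, TP), and the top-layer (s1,
  0–20 cm) versus sub-layer (below 20 cm) decomposition of length, diameter,
  area, volume and length density.
- **Stress response** (`relative_change`, `pae`, `stress_indices`): relative
  trait changes Δ = (x_S − x_C)/x_C; phosphorus acquisition efficiency
  PAE = 100·P_S/P_C; and the seven tolerance/productivity indices per
  genotype from control and stressed total dry weight,

      SSI = (1 − DW_S/DW_C) / (1 − D̄W_S/D̄W_C)      TI  = DW_C − DW_S
      SI  = DW_S/DW_C                                MPI = (DW_C + DW_S)/2
      HMI = 2·DW_C·DW_S/(DW_C + DW_S)                GMPI = √(DW_C·DW_S)
      STI = DW_C·DW_S / D̄W_C²

  summed into the stress-tolerance score STS per stress and STS_SUM over the
  three stresses.
- **Variance analysis** (`factorial_anova`, `tukey_hsd`,
  `variance_components`, `heritability`): the genotype × phosphorus × water
  factorial ANOVA with block, Tukey HSD compact letter displays, and
  broad-sense heritability from expected mean squares —
  H = V_G/(V_G + V_ε/r) within a treatment and
  H_com = V_G/(V_G + V_GE/e + V_ε/(r·e)) across treatments.
- **Effect sizes** (`effect_table`, `pool_effects`): log response ratios
  LnR = ln(V_S/V_C) with sampling variance
  v = S_S²/(n_S·V_S²) + S_C²/(n_C·V_C²), percent change
  100·(e^LnR − 1), normal 95 % CIs, and fixed-effect inverse-variance
  pooling per stress and overall.
- **Multivariate grouping** (`filter_by_cv`, `pearson_with_p`,
  `pca_standardized`, `ahc_cluster`, `sts_grouping`): CV ≥ 0.3 trait
  selection, Pearson correlation matrices with significance stars,
  correlation-matrix PCA with eigenvalue > 1 retention, average-linkage
  Euclidean clustering of genotypes cut into k groups with unit-sum group
  profiles, and tolerance grouping of genotypes on STS_SUM (group I = most
  tolerant).
- **Simulation** (`sim_config`, `wheat_preset`, `simulate_plants`): a
  log-normal genotype × treatment × block generator with geometric
  consistency of the root primitives, used to validate every stage.

`run_screen()` chains all stages and returns a `root_screen` object with
`print`/`summary` methods; with `out_dir` set it writes the full CSV bundle
deterministically.

## Worked example

```r
library(rootscreen)
screen <- run_screen(wheat_preset(seed = 42))
summary(screen)
```

```
Root-trait genotype screen
  1600 plants (100 genotypes x C/LP/D/DLP x 4 blocks), 35 derived traits
  22 traits selected at CV >= 0.3: MRD, RN, RL, RD, RA, RV, SRL, RLI, RTD, ...
  PCA: 9 components with eigenvalue > 1 (88.7% variance)
  STS grouping: 1 genotypes in group I (most tolerant)

Pooled effect sizes (log response ratio):
 stress   k     lnr  ci_low ci_high    pct
      D  35 -0.0616 -0.0858 -0.0374  -5.97
    DLP  35 -0.3788 -0.4030 -0.3547 -31.53
     LP  35 -0.2297 -0.2532 -0.2061 -20.52
    all 105 -0.2237 -0.2375 -0.2098 -20.04

Combined heritability: median 0.88 over 35 traits; 34 traits with H > 0.5
```

Reading: across all 35 traits the three stresses depress plant performance
by 20 % on average; the combined stress is most damaging (−32 %), low
phosphorus intermediate (−21 %), and drought mild overall (−6 %) because
its biomass losses are offset by root-system expansion. Most traits are
highly heritable under the preset's variance components, so genotype
ranking is meaningful. Tukey letters on total root length reproduce the
drought signature — D alone is lettered "a":

```r
gm <- lapply(c("C","LP","D","DLP"),
             function(t) genotype_means(screen$traits, t, select = "RL")[, 1])
tukey_hsd(unlist(gm), rep(c("C","LP","D","DLP"), each = 100))
#>   D  LP   C DLP
#> "a" "b" "b" "b"
```

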