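---
title: "Methods: root-trait screening under drought and low-phosphorus stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-trait screening under drought and low-phosphorus stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootscreen)
```

# The screening problem

A genotype screen for drought and phosphorus-stress tolerance grows a panel
of genotypes under four treatments — control (C), low phosphorus (LP),
osmotic drought (D, PEG-induced in hydroponics), and combined stress
(DLP) — in replicated blocks, measures the root system per plant (depth,
number, per-layer length and diameter, biomass, phosphorus status), and
asks three questions: how much genotypic variation is there and how
heritable is it; how do the stresses reshape the root system; and which
genotypes tolerate stress best. `rootscreen` implements that analysis
chain. This vignette records the models, the parameter choices, and the
design decisions taken where more than one defensible convention exists.

# Trait derivation

Roots are measured in 20 cm depth layers on a flat growth panel. Layer
surface area and volume follow cylinder geometry from layer length $L_k$
(cm) and mean diameter $d_k$ (mm):
$A_k = \pi (d_k/10) L_k$, $V_k = \tfrac{\pi}{4} (d_k/10)^2 L_k$. Totals
sum over layers, and the whole-plant diameter is the length-weighted mean
of the layer diameters (the averaging must be length-weighted for the
total-area identity to be consistent; an unweighted mean would not be).
When a table carries scanner-measured per-layer areas/volumes
(`ra_s*_cm2`, `rv_s*_cm3`), those override the geometric formulas.

Ratio traits: SRL = RL/RDW (cm g⁻¹), RTD = RDW/RV (g cm⁻³),
RSR = RDW/SDW, RLI = RL/MRD (cm cm⁻¹), RLD = RL/1430 cm², RGR = MRD/DAT and
SGR = SH/DAT (cm d⁻¹). Two unit choices deserve a note: SRL is reported in
cm g⁻¹ and RTD in g cm⁻³ because only those units are consistent with the
magnitudes such trials report (SRL ≈ 10⁴ for RL ≈ 1300 cm and
RDW ≈ 0.1 g); "per mg" labels occasionally seen for these traits do not
survive a dimensional check.

The depth decomposition splits the root system at 20 cm: the top segment
s1 and everything below to the root tip ("sub"). Layer reference areas for
length density derive from the 1430 cm² panel over 0–110 cm depth
(width 13 cm): 260 cm² for s1 and 1170 cm² for sub.

Degenerate inputs are *flagged, never zeroed*: a ratio with zero
denominator (e.g. RLR_s1/sub when no root grows below 20 cm) is `NA`.
Negative measurements are validation errors.

# The trial simulator

No raw per-plant dataset is distributed with the package, so a simulator
(`simulate_plants`) provides data with exactly the statistical structure
the analysis assumes. Each of the eleven measured primitives is log-normal:

$$y_{tijk} = \mu_t \, m_{tj} \exp\!\left(g_{ti} + (gt)_{tij} + b_{tk} +
\varepsilon\right),$$

with baseline mean $\mu_t$, treatment multiplier $m_{tj}$ (control
multiplier fixed at 1), and independent zero-mean Gaussian genotype,
genotype × treatment, block and residual effects on the log scale. The
log-normal form guarantees positivity of lengths and weights and makes the
log response ratio the natural effect scale. Counts (RN, LN, TN) are
generated on the log scale and rounded to non-negative integers; block
effects are shared by all genotypes within a block, as when sowing batches
define the blocks.

Total root length is split over the occupied depth layers (those the root
system reaches, i.e. $20(k-1) < \mathrm{MRD}$) by a Dirichlet draw whose
expected weights decay with depth — steeply (rate 0.9 per layer) under C
and LP, gently (rate 0.25) under D and DLP, so drought shifts length
downward. Layer diameters receive a mild surface-ward thickening trend and
record-level noise, then are rescaled so their length-weighted mean equals
the simulated whole-plant diameter exactly; the trait engine therefore
recovers the simulated RL and RD without refitting. When every variance
component is zero the allocation uses the expected weights directly, so a
noise-free configuration is fully deterministic — the degenerate case used
to verify that generated cell means equal $\mu_t m_{tj}$ exactly.

`wheat_preset()` fixes the study conditions: 100 genotypes × 4 treatments ×
4 blocks, 6 layers (0–120 cm), harvest at 65 days after transplanting.
Baseline means and the multipliers for MRD, RL, RD, RDW, SDW and RN come
from treatment/control mean ratios typical of published winter-wheat
screens (e.g. $m_{\mathrm{RL,D}} = 1.43$: drought lengthens roots;
$m_{\mathrm{SDW,LP}} = 0.23$ and $m_{\mathrm{SDW,DLP}} = 0.21$: stress
collapses shoot biomass, worst under combined stress). Traits without
published means (SH, LN, TN, RPC, SPC) carry qualitative multipliers in
the depressing direction. Variance components default to
$\sigma^2_G = 0.15$, $\sigma^2_{GT} = 0.02$, $\sigma^2_{block} = 0.005$,
$\sigma^2_\varepsilon = 0.08$ on the log scale, chosen so genotype-mean
CVs land near 0.3–0.5, the range in which real screens report most root
traits. These are scientific defaults, not fitted values; the preset is
qualitative and every parameter is user-facing.

What the simulator does *not* emulate: osmotic physiology of PEG,
nutrient-solution chemistry, imaging/scanning noise, genotype-specific
layer preferences, or correlated residuals between traits of the same
plant (each primitive's noise is drawn independently; derived ratios do
correlate through their shared primitives). Passing tests therefore
demonstrate correctness of the *analysis* under the assumed generative
structure, not biological realism of any particular dataset.

# Stress indices and scores

All seven indices use total dry mass (root + shoot) as the productivity
measure, and genotype values are block-averaged before index computation.
Population means $\bar{DW}_C$, $\bar{DW}_S$ are taken over genotypes with
complete control and stress data. Two identities pin the implementation:
$\mathrm{HMI} \le \mathrm{GMPI} \le \mathrm{MPI}$ (the classical
harmonic–geometric–arithmetic chain, equality iff $DW_C = DW_S$) and
$\mathrm{STI}\cdot\bar{DW}_C^2 = \mathrm{GMPI}^2$; both are enforced in
the test suite to 1e-9.

STS is the literal unweighted sum of the seven indices even though they
mix units (grams and dimensionless) and directions (SSI rises with
sensitivity, the productivity means with performance). That convention is
kept as the reference definition because it is how the score is used in
the screening literature; a z-standardized variant is available via
`stress_indices(..., standardize = TRUE)` but is not the default.
STS_SUM adds the per-stress scores over LP, D and DLP, and is `NA` when
any stress is missing. A degenerate population with
$\bar{DW}_S = \bar{DW}_C$ makes SSI undefined (division by zero) and is a
hard error rather than a silent `NA`.

# ANOVA, variance components and heritability

The treatment codes decompose into a 2 × 2 factorial — phosphorus supply
P ∈ {sufficient, low} and water status W ∈ {watered, stress} — and the
per-trait model is `value ~ block + G * P * W` with sequential (Type I)
sums of squares. On the balanced design all SS types coincide; missing
trait values (flagged ratios) can unbalance the data, in which case a
warning notes the order dependence. Block enters as an additive fixed
term; with nothing known about the block process beyond "sowing time",
fixed-versus-random makes no difference to the F tests against the
residual and the fixed choice keeps the machinery classical. Empty design
cells are an error naming the cells; zero residual degrees of freedom is
an error; all-constant data yields 0/0 mean squares, reported as flagged
(`NaN`) statistics rather than fabricated zeros.

Heritability uses the expected-mean-squares construction for genotype
(random) × treatment (fixed) with $r$ replicates and $e$ treatments:
within one treatment $V_G = (MS_G - MS_E)/r$ and
$H = V_G/(V_G + V_\varepsilon/r)$; across treatments
$V_{GE} = (MS_{GE} - MS_E)/r$, $V_G = (MS_G - MS_{GE})/(re)$ and
$H_{com} = V_G/(V_G + V_{GE}/e + V_\varepsilon/(re))$. Negative component
estimates are truncated at zero (the classical convention, flagged in the
result), which keeps $H \in [0,1]$. REML mixed models would be the modern
alternative; the EMS route is kept because it matches the formulas the
heritability definitions are stated in, and on balanced data the two
coincide.

One relationship is worth spelling out because intuition misleads:
$H_{com} \le H$ is *not* an algebraic consequence of the formulas — pooling
$e$ treatments divides the error term by $e$, which raises $H_{com}$
whenever $V_{GE}$ is small. The real mechanism is confounding: a
single-treatment analysis cannot separate $V_G$ from $V_{GE}$ (its
genotypic component estimates $V_G + V_{GE}$), so once genotype × treatment
variance is appreciable the combined estimate falls below the
single-treatment one. The test suite asserts the corrected conditional
property and verifies the empirical comparison on simulations with
$\sigma^2_{GT} = \sigma^2_G/2$.

Because the generative model is additive on the log scale, heritability
recovery simulations analyse `log(value)`; with $\sigma^2_G =
\sigma^2_\varepsilon = 2$ and $r = 4$ the analytic value is
$H = 2/(2 + 2/4) = 0.8$, and the acceptance checks require the mean
estimate over 200 simulated traits to lie within ±0.03 of it.

Tukey HSD letters come from `multcomp` on the one-way fit; letter symbols
are re-mapped by first appearance while scanning groups in descending mean
order, so the largest mean always carries "a" (the convention used in
treatment-mean tables).

# Effect sizes

Per trait and stress, group summaries are computed over genotype means
(blocks averaged first): $LnR = \ln(V_S/V_C)$, delta-method variance
$v = S_S^2/(n_S V_S^2) + S_C^2/(n_C V_C^2)$, percent change
$100(e^{LnR}-1)$, and a normal 95 % CI $LnR \pm 1.96\sqrt{v}$. Pooling —
per stress, and grand over all trait × stress records — uses fixed-effect
inverse-variance weights, the meta-analytic standard for log response
ratios when only means and CIs are displayed; no heterogeneity model
($\tau^2$, Q) is fitted. Records with $v = 0$ are excluded from weighting
with a warning.

The variance formula assumes independent stress and control groups. In a
real screen the same genotypes appear in both groups, so genotype main
effects are shared and the intervals are conservative (true coverage
above 95 %). The null-calibration check therefore switches the genotype
and block channels off ($\sigma^2_G = \sigma^2_{block} = 0$), leaving
independent genotype × treatment and residual noise, under which the
nominal rate applies: over 1000 simulated null traits the fraction of 95 %
CIs excluding zero must land in [3 %, 7 %]. This conservatism under
shared genotype effects is a known property of unpaired lnRR intervals
applied to paired designs, and a limitation to keep in mind when reading
forest tables from real trials.

# Multivariate screening

Trait selection keeps traits with CV ≥ 0.3 (inclusive) across genotype
means within a treatment, minus a drop list defaulting to RGR and RLD,
which are deterministic rescalings of MRD and RL and would double-count
their variance. Pearson correlations use pairwise-complete observations
with p-values from the t transform on $n-2$ degrees of freedom; pairs with
fewer than 3 complete observations or a constant member are `NA`. No
multiple-testing correction is applied to the correlation stars — a
deliberate match to common practice in trait-matrix displays, and a
documented limitation.

PCA standardizes each trait and eigendecomposes the correlation matrix;
components with eigenvalue > 1 are retained (with eigenvalues near 1 the
retention count is unstable — the boundary behaviour is exercised in the
tests). Eigenvector signs are fixed by making the largest-magnitude
loading positive, so results are deterministic. Missing values are
mean-imputed for PCA and clustering *only*, never for univariate
statistics; constant traits are dropped with a warning.

Genotype clustering z-standardizes traits before Euclidean distances
(without this, SRL at ~10⁴ would dominate RTD at ~10⁻¹), then applies
average-linkage agglomeration cut at k = 5 groups by default. Group
profiles divide each group's trait mean by the sum over groups, so
profiles sum to 1 per trait. Tolerance grouping clusters the
one-dimensional STS_SUM values the same way and relabels groups by
descending mean score, so group I always holds the most tolerant
genotypes — a deterministic convention chosen because verbal descriptions
of such groupings mix ranking with clustering and do not pin down a unique
rule.

# Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: 10 000 random dry-weight
pairs for the index algebra, 1000 random group summaries for the
effect-size oracle, 1000 simulated traits (100 genotypes, 4 blocks) for
the null calibration, 200 traits for heritability recovery, a planted
3-cluster structure of 60 genotypes × 12 traits for multivariate recovery,
and the full 100 × 4 × 4 preset (1600 plants, 35 derived traits) run twice
for end-to-end determinism. All randomness flows from a single seed;
`run_screen` writes plain CSVs, so identically-seeded runs are
bit-identical.

# Known limitations

- The preset is qualitative: it reproduces directions and rough magnitudes
  of treatment responses, not any specific dataset.
- Primitives are simulated independently per trait, so cross-trait
  residual correlations (beyond those induced by shared primitives in
  derived ratios) are absent.
- lnRR intervals are conservative for paired (same-genotype) designs, as
  discussed above.
- EMS variance components assume the balanced random-genotype,
  fixed-treatment layout; severely unbalanced real data would warrant a
  REML mixed model instead.
- Correlation stars are unadjusted for multiplicity.
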