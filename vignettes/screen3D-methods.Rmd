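---
title: "Methods: normalization and cross-model analysis of 2D/3D drug screens"
author: "screen3D authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization and cross-model analysis of 2D/3D drug screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screen3D)
```

# The problem

High-throughput viability screens read one luminescence value per well of a
384-well plate (CellTiter-Glo signal, proportional to viable cell mass).
When the same compound libraries are screened across several culture
models — a 7-day monolayer (`2D7d`), Matrigel spheroid cultures drugged at
plating (`MG7d`) or after four days of pre-growth (`MG4+7d`), and the
corresponding polyHEMA anchorage-independent cultures (`PH7d`,
`PH4+7d`) — three obstacles stand between the raw plates and a statement
like "this culture model is more drug-sensitive than the monolayer":

1. **Spatial plate artifacts.** Evaporation, dispenser geometry and
   incubator gradients impose smooth row/column trends and edge effects on
   the raw signal.
2. **Scale differences between models.** The models differ hugely in
   signal per well (cells on Matrigel grow about 1.86× faster than in 2D;
   polyHEMA cultures about 7.2× slower, and are plated at different
   densities), so raw values are not comparable across arms.
3. **Drug-by-drug heterogeneity.** Individual drugs can favour any model;
   only a matched analysis over the whole library supports a general
   sensitization claim.

The pipeline addresses these in order: loess-log plate normalization,
percent-of-control dose-response summaries, and two independent
library-wide comparisons (rank-product hit calling and a blocked multiple
linear regression).

# Loess-log normalization

Per plate, `correctSpatialBias()` fits a locally weighted degree-1
regression of well value on `(row, column)` with tricube distance weights,
followed by robustness passes that re-weight wells by the Tukey bisquare
function of their residual scaled by six times the median absolute
residual (`stats::loess`, `family = "symmetric"`). Outlying wells — a
clogged tip, a contaminated well — therefore barely influence the surface.
The correction is multiplicative and preserves the plate median:

$$\mathrm{corrected}_{rc} = \mathrm{raw}_{rc}\cdot
\frac{\mathrm{median}(\hat f)}{\hat f(r,c)}.$$

Corrected values are divided by the median of the plate's negative
controls and log2-transformed (the *loess-log* value), so 0 means
"like the untreated controls" and −1 means "half the viability".
Non-positive values are floored at a small fraction of the control centre
(default 1/1000) and flagged.

Tunables and defaults:

| parameter | default | meaning |
|---|---|---|
| `span` | 0.7 | fraction of wells in each local neighbourhood; large enough that the surface tracks plate-scale trends, not drug effects |
| `iterations` | 2 | bisquare re-weighting passes (Cleveland's robust loess) |
| `center` | median | negative-control centre statistic (mean available) |
| `epsFraction` | 1e-3 | floor for non-positive corrected values |

Two choices deserve explanation:

* **Which wells drive the surface.** Sample and negative-control wells do;
  positive-control (killed) wells do not, because their near-zero signal
  is pharmacology, not spatial artifact, and a 95%-kill boundary in the
  outer columns drags a degree-1 surface non-positive under
  extrapolation. They are still *corrected*, using the surface clamped to
  its range over the fitted wells (long-range linear extrapolation is not
  trusted). `fitPositiveControls = TRUE` and `fitSamplesOnly = TRUE`
  restore the alternatives.
* **Multiplicative correction.** Luminescence errors grow with signal;
  dividing by the surface (rather than subtracting it) keeps the noise
  model homogeneous on the log scale.

Replicates are aggregated per culture model and library by least squares
(`aggregateReplicates()`): `loess_log ~ 0 + (drug × concentration) +
replicate`, with a sum-to-zero biological-replicate offset, so a plate
that ran globally hot or cold is absorbed instead of averaged into the
estimates. On a balanced design this reduces to the replicate mean.
Finally, `centerToPlateMedian()` subtracts each plate's median sample
loess-log — the centred quantity that hit calling consumes. The
median is taken over *sample* wells (configurable to all wells) so that
the drug-effect distribution is centred rather than pinned to the
controls' zero.

# Dose-response summaries and the activity filter

`percentOfLowest()` puts aggregated responses back on the linear scale and
reports, per drug × model, each concentration as a percentage of the
drug's lowest-concentration response — the baseline is the lowest
concentration for the 80-compound library and the mean of the two lowest
for the 22-compound library, whose dose series starts much lower. The
percent-of-control value (`100·2^{loess-log}`) is carried alongside.

`selectActiveDrugs()` keeps drugs that reduced viability by strictly more
than 30% relative to the negative controls in at least one model at some
concentration (minimum percent-of-control < 70; a drug at exactly 70.0%
is not active). The filter operates on the percent-of-control scale — a
drug potent already at its lowest tested dose shows a flat
percent-of-lowest profile yet is plainly active. The threshold basis is
configurable (`basis = "lowest"`).

`averageByConcentrationBin()` assigns each drug's three highest tested
concentrations to high/medium/low bins by rank, averages across drugs per
model per bin (and across bins), and compares each 3D model to `2D7d`
with a two-sided Welch t-test over the per-drug values — Welch because the
spread differs visibly between culture models; a pooled-variance option
exists. Stars encode p < 0.05/0.01/0.001. **No multiple-testing
correction is applied across bins or models**; the stars are descriptive
annotations, matching screening practice, and should not be read as
family-wise error control.

# Rank-product hit calling

For one 3D model versus `2D7d`, `rankProduct()` computes the per-drug
difference of plate-median-centred loess-log values at each concentration
and treats every concentration as an independent *origin*. Within each
origin the drugs are ranked (direction `"down"`: the most sensitizing
difference gets rank 1; ties share mid-ranks), and the evidence is
combined as the geometric mean of ranks,
$RP_d = (\prod_{j=1}^{k} r_{dj})^{1/k}$. A drug consistently near the top
across independent concentrations gets a small RP regardless of the
response's absolute scale — the statistic is non-parametric and robust to
origin-specific scale differences.

Significance comes from the permutation null: ranks are permuted
independently within each origin, RPs recomputed, and

* `p` = fraction of null RPs at or below the observed RP,
* `pfp` (proportion of false positives, an expected false-discovery
  count per list position) = (mean per-permutation count of null RPs ≤
  observed) / (position in the RP-sorted list), made monotone
  non-decreasing down the list.

When the number of distinct rank assignments $(n!)^k$ does not exceed the
requested permutation count, the null is *enumerated exactly* rather than
sampled — at small `n` and `k` the permutation p-values are therefore
exact, with zero Monte-Carlo error, and reproducibility does not depend
on the seed. Default 10,000 permutations otherwise; at least a few
hundred are needed before `pfp` at the 0.05 level is meaningful.

# Multiple linear regression classification

`fitMLR()` fits, per library,

$$\mathrm{loessLog} \sim \mathrm{model} + \mathrm{strata}(\mathrm{drug}
\times \mathrm{concentration}),$$

with `2D7d` as the reference level. Because every drug × concentration
cell appears in all arms, each model coefficient is the pairwise-matched
mean shift versus 2D in log2 units: −0.1 means "on average 7% less
viability than matched 2D wells". Fitting one blocked model per library
(rather than one fit per concentration) maximizes power and yields one
estimate per culture model; `mode = "per-concentration"` provides the
per-dose fits alongside. The fit runs on loess-log normalized values — a
raw-scale fit would be dominated by the models' growth-scale differences;
any column of the screen table can be supplied via `value=`.

`classifySensitized()` applies the decision rule: estimate < 0 with
p < 0.05 → *sensitized*; estimate > 0 with p < 0.05 → *resistant*;
otherwise *indistinguishable*. Two-sided p-values throughout.

A known limitation, measured during calibration: with one culture model
per plate, plate-level noise in the negative-control median propagates
into every well of that plate's arm and is statistically inseparable from
the model effect. The well-level standard errors of the blocked fit do
not see this component, so confidence intervals for *absolute* model
shifts are honest only with respect to well-level noise; replication
across biological replicates (three in the study design) is what
constrains the plate-level component. The parameter-recovery study below
therefore injects its shift at the normalized-response level, where the
fit's error model matches the data-generating process.

# The synthetic screen generator

`makeTruth()` / `simulateScreen()` emulate the screen design so every
stage is testable without external data:

* **Design**: five culture models; an 80-compound library at 0.02, 0.2,
  2, 20 µM in single wells and a 22-compound library at seven ten-fold
  dilutions from 20 µM in two technical replicates; three biological
  replicates; columns 1–2 negative controls, 23–24 positive controls
  (95% kill), 320 sample wells per plate.
* **Truth**: per drug a four-parameter Hill curve — `e0 = 1`,
  `emax ~ U(0, 0.9)`, `h ~ U(0.5, 3)`, EC50 log-uniform over the tested
  dose range; per model the EC50 is shifted by a configurable
  log2 offset plus `N(0, modelSd)` jitter (default 0.25), so culture-model
  sensitization is injectable and recoverable.
* **Scale**: endpoint signal = plate scale × cells plated × growth scale ×
  viability; growth scales 1 / 1.86 / (1/7.2) for 2D / Matrigel /
  polyHEMA (so the Matrigel-to-polyHEMA rate ratio is 13.392), cells
  plated 850 / 500 / 5000.
* **Artifacts**: a multiplicative field `1 + a_r·u + a_c·v + radial bowl`
  renormalized to plate mean 1, an edge-effect multiplier on the
  outermost wells (default 0.95), and multiplicative lognormal noise with
  configured CV (default 5%), mean exactly 1.
* **Reproducibility**: a single master seed derives one substream per
  plate; identical inputs give identical plates.

The Hill form is a modelling choice for the truth generator — the real
screen's dose-response shapes are unknown — and the generator does not
emulate sphere-formation kinetics, drug diffusion into spheroids,
apoptosis readouts, or cross-well contamination. Passing tests on
synthetic screens therefore validate the *statistical machinery* (bias
removal, calibration, recovery), not the biology of any particular
culture system.

# Validation studies and problem sizes

The test suite and the acceptance script re-run these studies end to end
(sizes chosen to keep a full run within a few minutes):

* **Bias removal**: 100 single-plate screens, gradient amplitude
  U(0.1, 0.3), noise CV 5% — the pooled SD of negative-control loess-log
  values after correction must be at most half the uncorrected SD.
* **Outlier robustness**: one 10× well on an otherwise smooth plate moves
  every other corrected value by < 1%.
* **Rank-product calibration**: exact-enumeration agreement at n ≤ 4
  drugs, k ≤ 3 origins; and on 500 null screens (80 drugs, 4 origins, no
  model effect) the fraction of drugs with pfp < 0.05 stays ≤ 0.07.
* **MLR recovery**: 200 simulations of 102 drugs × 4 concentrations ×
  3 replicates with a −0.15 loess-log shift injected on one arm —
  mean bias below 0.01 and ≥ 90% coverage of the 95% CI.
* **Filter fidelity**: on noise-free screens the active set equals
  exactly the drugs whose truth curves cross 70% viability within the
  tested doses.

# Expression comparisons

The downstream utilities operate on already-normalized log2 gene × sample
matrices (replicate columns averaged on load): `foldChangeCounts()`
counts ≥ fold up/down genes between two samples (inclusive threshold on
|log2 difference|), `vennPartition()` splits gene sets into exact disjoint
membership regions, and `correlationAndCluster()` builds the
average-linkage tree on 1 − Pearson distance with ordinary bootstrap
probabilities per split (gene resampling). Multiscale bootstrap
("approximately unbiased") p-values are deliberately out of scope; bp
values are reported on 0–100 in the Newick output. `xenograftArea()` is
the palpation ellipse `(length/2)·(width/2)·π`.

Because microarray preprocessing and empirical-Bayes differential
expression are outside this package, fold-change counts on public
accessions are comparable only in ordering, not exact values.

# Worked example

```{r example, eval = FALSE}
tr  <- makeTruth(102, sensitivityShift = c(MG7d = -0.5, "MG4+7d" = -0.3),
                 seed = 11)
lay <- screenLayouts(tr)                       # 30 plates
scr <- assembleScreen(simulateScreen(tr, lay, seed = 2), lay)
nrm <- normalizeScreen(scr)
agg <- aggregateReplicates(nrm)
prof <- percentOfLowest(agg)
act <- selectActiveDrugs(prof)
averageByConcentrationBin(prof, act)
cen <- aggregateReplicates(nrm, value = "centered")
rankProduct(cen[cen$library == "lib80", ], "MG7d", seed = 3)
classifySensitized(fitMLR(nrm, library = "lib80"))
```
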