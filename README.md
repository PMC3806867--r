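# screen3D

Analysis of high-throughput 384-well drug screens run in parallel across
2D monolayer and 3D (Matrigel spheroid, polyHEMA anchorage-independent)
cell culture models.

Raw CellTiter-Glo luminescence plates carry smooth spatial artifacts, and
the culture models differ enormously in signal scale (Matrigel cultures
grow ~1.86× faster than monolayers, polyHEMA cultures ~7.2× slower), so
cross-model drug-sensitivity claims need a matched, normalized,
library-wide analysis. screen3D implements that pipeline:

* **Loess-log normalization** — per plate, a robust (outlier
  down-weighted, Tukey bisquare) degree-1 loess surface over
  (row, column) is divided out with the plate median preserved,
  `corrected = raw · median(f̂)/f̂(r,c)`; values are then divided by the
  negative-control median and log2-transformed, and replicates are
  aggregated by least squares with plate offsets.
* **Dose-response summaries** — responses as percent of each drug's
  lowest tested concentration (mean of the two lowest for the
  low-starting 22-compound library), a >30%-response activity filter
  against the controls, and concentration-binned cross-model averages
  with Welch t-tests versus 2D.
* **Rank-product hit calling** — each concentration an independent
  origin, `RP_d = (∏_j r_dj)^{1/k}`, with permutation p-values and pfp
  (expected false positives per list position); the null is enumerated
  exactly whenever `(n!)^k` fits in the permutation budget.
* **MLR classification** — `loess_log ~ model + strata(drug × conc)` per
  library, 2D as reference; a culture model with a significant negative
  estimate (p < 0.05) is classified as drug-**sensitized**.
* **Expression comparison utilities** — ≥ k-fold up/down counting, exact
  Venn partitioning, and average-linkage correlation clustering with
  ordinary bootstrap support, for comparing culture models against
  xenograft profiles.
* **A synthetic screen generator** — per drug × model four-parameter Hill
  truth, model growth scales, smooth plate gradients, edge effects and
  multiplicative lognormal noise, fully seeded — so every stage of the
  pipeline is validated against known ground truth.

## Worked example

A fully synthetic screen at the study design — 102 drugs, five culture
models, three biological replicates, 30 plates — with Matrigel arms made
more drug-sensitive (EC50 shifts −0.5 and −0.3 log2):

```r
library(screen3D)
tr  <- makeTruth(102, sensitivityShift = c(MG7d = -0.5, "MG4+7d" = -0.3),
                 seed = 11)
lay <- screenLayouts(tr)
scr <- assembleScreen(simulateScreen(tr, lay, seed = 2), lay)
nrm <- normalizeScreen(scr)

agg  <- aggregateReplicates(nrm)
prof <- percentOfLowest(agg)
act  <- selectActiveDrugs(prof)      # 73 of 102 drugs pass the 30% filter

subset(averageByConcentrationBin(prof, act), bin == "across")
#>     model    bin  mean  n      p stars
#> 4    2D7d across 56.09 73     NA
#> 8  MG4+7d across 54.96 73 0.7598
#> 12   MG7d across 53.84 73 0.5431
#> 16 PH4+7d across 56.94 73 0.8207
#> 20   PH7d across 57.18 73 0.7746
```

Per-drug bin means barely separate the arms — drug responses are too
heterogeneous — which is exactly why the two matched library-wide
analyses exist. Rank-product hit calling names the drugs driving the
Matrigel sensitization, and the blocked MLR detects the arm-level shift:

```r
cen <- aggregateReplicates(nrm, value = "centered")
rankProduct(cen[cen$library == "lib80", ], "MG7d", seed = 3)
#> RankProductResult: MG7d vs 2D7d (direction down)
#>   80 drugs, 4 origins, sampled null (10000 permutations), seed 3
#>      drug        RP expectedRP          p     pfp
#> 1 drug004  4.590349    8.02020 0.00064875 0.05190
#> 2 drug048  6.054800   10.12855 0.00238625 0.09545
#> ...

classifySensitized(fitMLR(nrm, library = "lib80"))
#>     term estimate        p      label
#> 1 MG4+7d  -0.0225 4.13e-06 sensitized
#> 2   MG7d  -0.0498 3.14e-24 sensitized
#> 3 PH4+7d  -0.0132 6.63e-03 sensitized
#> 4   PH7d  -0.0133 6.58e-03 sensitized
```

The MG7d estimate (−0.0498 log2 ≈ 3.4% lower viability than matched 2D
wells, p ≈ 1e-24) is about twice the MG4+7d estimate, matching the
injected 2:1 ratio of EC50 shifts; the small PH estimates reflect the
generator's random per-model EC50 jitter in this single simulated screen,
not an injected effect.

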