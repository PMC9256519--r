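# plimst

Band-limited functional-connectivity and network-topology analysis for
source-space MEG (or EEG) recordings, with two-group permutation inference.
`plimst` is aimed at researchers who have region-level source time series
(e.g. 90 non-cerebellar AAL regions) for two groups of subjects and want to
ask: *in which frequency bands, and at which regions, does the backbone of
the functional network differ between the groups?*

## What it computes

For every subject, frequency band (delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30, gamma 30–48 Hz) and 8-s epoch:

1. **Phase Lag Index (PLI)** between every region pair,

   PLI = | ⟨ sign sin ΔΦ(t_k) ⟩ |,

   where ΔΦ is the Hilbert phase difference. PLI ∈ [0, 1]; it ignores
   zero-lag coupling, making it insensitive to volume conduction.
2. **Minimum spanning tree (MST)** of the PLI matrix with edge weights
   1/PLI (Kruskal), i.e. the N−1 strongest-synchronization backbone — a
   topology comparison unbiased by edge density.
3. **Tree metrics**: nodal degree and betweenness centrality; global leaf
   fraction, degree divergence κ = ⟨k²⟩/⟨k⟩, and tree hierarchy
   Th = L/(2·M·BC_max).

Metrics are averaged across epochs per subject (epoch counts are equalized
across subjects by seeded random selection), and groups are compared per
metric/node/band by a 10000-draw label-permutation test on the difference of
group means, with Benjamini–Hochberg FDR at q = 0.05, plus an
epoch-resampling robustness procedure (100 iterations of 24 random epochs).

Because no recordings ship with the package, a lag-coupled phase-oscillator
simulator (`simulate_cohort()`) generates cohorts with a *planted*
topological group difference — three strong lagged couplings converging on a
hub region in the beta band — used throughout the tests to verify that the
pipeline recovers exactly what was planted and nothing elsewhere. See the
methods vignette (`vignettes/pli-mst-methods.Rmd`) for the model and all
design decisions.

## Worked example

```r
library(plimst)

cfg <- pipeline_config(
  simulation = list(n_regions = 24, recording_duration_s = 104),
  n_epochs = 12, n_perm = 2000, n_iter_robustness = 20,
  n_epochs_robustness = 8,
  seeds = list(simulation = 1L, epochs = 2L, permutation = 3L, robustness = 4L))
res <- run_pipeline(cfg)
significant_nodes(res)[, c("band", "metric", "node", "observed_diff", "p_fdr")]
```

This simulates a 26 vs 29 cohort of 24-region subjects (the planted hub is
region `R012`), runs the full pipeline and prints the FDR-significant tests.
Output from this exact configuration (`analysis/02_full_pipeline.R`, desk
scale):

```
 band metric node observed_diff        p_raw       p_fdr
 beta degree R012    1.22701149 0.0004997501 0.005997001
 beta degree R020   -0.73629531 0.0004997501 0.005997001
 beta     bc R005    0.07462833 0.0019990005 0.015992004
 beta     bc R012    0.13941412 0.0004997501 0.005997001
 beta     bc R020   -0.13688392 0.0004997501 0.005997001
```

The planted hub gains about 1.2 MST links and +0.14 betweenness in the
effect group, significant after FDR in the beta band only; untouched bands
stay silent. The accompanying negative differences at other beta-band nodes
are real consequences of the planted effect — a spanning tree has a fixed
edge budget, so links gained by the hub are lost elsewhere. The
epoch-resampling robustness keeps the hub significant in 20 of 20
iterations. The numbered scripts under
`analysis/` run the same study end to end and write their tables under
`results/`:

* `01_simulate_cohort.R` — generator sanity: spectral placement per band,
  visibility of the planted couplings (beta hub-edge PLI ≈ 0.96 in group A
  vs ≈ 0.30 in group B).
* `02_full_pipeline.R [desk|full]` — the complete analysis (simulate →
  filter → phase → epoch → PLI → MST → metrics → permutation + FDR →
  robustness). `full` is the 90-region, 26-vs-29-subject, 24-epoch,
  10000-permutation design (~30 min, one CPU); its significant set is
  exactly the planted beta-band cluster — the hub `Postcentral_L`
  (degree +2.35, p_FDR = 0.0045; BC +0.25, p_FDR = 0.0045) and its three
  coupled partners — with all other bands silent and the hub significant in
  100 of 100 epoch-resampling iterations.
* `03_null_calibration.R` — type-I error of the permutation test at 26 vs 29
  (0.032 at α = 0.05 over 500 null cohorts) and exhaustive 3-vs-3 agreement
  (max gap 0.007).
* `04_planted_effect_replicates.R` — recovery rate over independently seeded
  cohorts.

## Package layout

```
R/            simulator, spectral processing, PLI, MST + metrics, statistics,
              pipeline orchestration
src/          compiled kernels: oscillator integration, PLI matrix, zero-phase IIR
analysis/     numbered narrative drivers writing tables under results/
tests/        testthat suite incl. brute-force oracles and end-to-end checks
vignettes/    methods vignette (model, parameters, design decisions, limits)
scripts/      acceptance.R (reference-quantity recomputation)
```
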