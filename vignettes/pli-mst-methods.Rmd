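---
title: "Methods: PLI connectivity, minimum spanning trees and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity, minimum spanning trees and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plimst)
```

## The analysis in one paragraph

`plimst` compares the band-limited functional network topology of two groups
of subjects, starting from source-reconstructed MEG region time series (90
non-cerebellar AAL regions by default, resampled to 512 Hz). Per subject and
frequency band (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–48 Hz) the recording is band-pass filtered, the Hilbert phase extracted,
and the record cut into 8-s epochs with the same epoch count for every
subject. Each epoch yields a Phase Lag Index (PLI) adjacency matrix, reduced
to its minimum spanning tree (MST) over 1/PLI weights; nodal (degree,
betweenness centrality) and global (leaf fraction, degree divergence, tree
hierarchy) tree metrics are computed per epoch and averaged per subject.
Group differences are assessed per metric/node/band by label permutation on
the difference of group means, with Benjamini–Hochberg FDR correction, plus
an epoch-resampling robustness procedure.

## Connectivity: the Phase Lag Index

For two phase series the PLI is

$$\mathrm{PLI} = \left| \left\langle \mathrm{sign}\,
\sin\!\big(\Delta\Phi(t_k)\big) \right\rangle \right|,$$

the absolute mean over samples of the sign of the sine of the instantaneous
phase difference. It is 1 when the phase difference has a consistent nonzero
sign and 0 either when there is no consistent phase relation or when the lag
is exactly zero: a zero-lag interaction — the signature of volume conduction
/ field spread — is invisible by construction. We define `sign(0) = 0`, so
samples with exactly zero phase difference contribute nothing; this makes
`PLI(x, x) = 0` exact. PLI is computed per epoch for all region pairs
(`pli_matrix()`, a compiled kernel checked in the tests against a plain
double-loop reference, `pli_matrix_reference()`).

Phases come from the analytic signal (one-sided FFT spectrum), wrapped to
$(-\pi, \pi]$. The analytic-signal construction is implemented in the package
and validated against quadrature-pair and phase-slope oracles in the test
suite. Filtering and Hilbert transform are applied to the continuous
recording *before* epoching, which avoids per-epoch edge artifacts in the
analytic signal; epochs are then slices of the phase matrix.

Band-pass filtering uses a Butterworth IIR design (`signal::butter`, design
order 4 by default) applied forward–backward, so the net phase response is
zero — essential, since phase is the quantity the PLI consumes. The
forward–backward pass doubles the effective attenuation order. The record is
reflection-padded by about three cycles of the band's low edge before
filtering so that low-band edge transients stay out of the analysed samples.

## Epoching and cross-subject equalization

Connectivity estimates improve with epoch count, so unequal epoch counts
bias group comparisons. `select_epochs()` therefore draws, uniformly at
random without replacement and deterministically given a seed, the same
number of epochs for every subject — either a stated count (24 by default,
the meditation-condition count; 12 is the typical resting-state count) or
the cohort-wide minimum (`n_epochs = "min"`). The same selected epochs are
used in every band. Where a human operator would select artifact-free epochs
by hand, the random selection is the reproducible stand-in; inputs are
assumed clean (artifact removal is out of scope).

## Trees and their metrics

Thresholding weighted networks biases topology comparisons through edge
density; the MST avoids this by always keeping exactly $N-1$ links. Edge
weights are $1/\mathrm{PLI}$, so Kruskal's algorithm — rank links ascending,
add links that do not close a loop — retains the strongest synchronizations.
Implementation notes:

* Zero-PLI pairs are treated as absent edges; if they disconnect the graph,
  the error names the components rather than returning a spanning forest.
* Ties in weight (measure-zero for float PLI, but certain in degenerate
  inputs) are broken by the lexicographic (i, j) edge index under a stable
  ordering, so equal-weight graphs always yield the same tree.

Metrics on the tree:

* **degree** — the raw number of incident links (not normalized by $M$).
* **betweenness centrality (BC)** — paths are unique in a tree, so BC of
  node $v$ is the number of node pairs whose path passes strictly through
  $v$, normalized by $(N-1)(N-2)/2$ to lie in $[0,1]$. Computed from subtree
  sizes in one depth-first pass; verified against brute-force path
  enumeration and igraph.
* **leaf fraction** — fraction of degree-1 nodes; higher = more star-like,
  integrated.
* **degree divergence** $\kappa = \langle k^2\rangle / \langle k \rangle$ —
  broadness of the degree distribution.
* **tree hierarchy** $T_h$ — balance between integration and hub overload.
  The phrase "number of leaves over the maximum betweenness centrality"
  admits two readings; we default to the conventional MST-literature form
  $T_h = L / (2 M\, \mathrm{BC}_{\max})$ with $M = N-1$ and
  $\mathrm{BC}_{\max}$ the maximum *normalized* BC, which lies in $(0, 1)$.
  The literal form $L/\mathrm{BC}_{\max}$ is available via
  `tree_hierarchy(..., formula = "literal")`; at fixed $N$ the two differ by
  the positive constant $2M$, so group inference is unaffected by the
  choice.

Metrics are computed **per epoch** and averaged across epochs per subject
afterwards; adjacency matrices are never averaged.

## Group inference

The test statistic is the difference of group means (group A minus group B),
not a t-statistic. Subject labels are permuted (10000 times by default)
preserving group sizes; the two-sided p-value uses the finite-sample
correction $p = (1 + \#\{|d^\ast| \ge |d|\})/(n_{\mathrm{perm}} + 1)$, which
keeps $p > 0$ and makes the test valid (slightly conservative). Two-sided
was chosen because no direction is pre-registered even when increases are
expected. Numerical note: permuted statistics within a relative tolerance
($10^{-10}$ of the metric scale) of the observed one count as ties, so
constant data give exactly $p = 1$ instead of a float-dependent value.

Multiple comparisons are handled by Benjamini–Hochberg FDR at $q = 0.05$.
The family definition is not uniquely determined by the study description;
the default (`fdr_family = "per_band"`) adjusts each nodal metric within its
(metric, band) family across the 90 nodes, and each global metric across the
five bands. The alternative `"all_bands_pooled"` pools nodes and bands. Both
are exposed because the choice materially affects which hypotheses share the
error budget.

The robustness procedure re-draws a random epoch subset per subject (24 by
default), re-averages, and re-runs the whole test battery, 100 times; the
permutation seed is held fixed across iterations so that only the epoch
choice varies. Its summary reports, per test, the fraction of iterations
significant after FDR and median p-values.

## The synthetic cohort generator

No recordings are distributed with the analysis, so validation runs on
synthetic cohorts built from lag-coupled phase oscillators. Per band $b$
each region follows

$$\dot\theta_i = \omega_i + \sum_j K_{ij} \sin(\theta_j - \theta_i + \tau_{ij})
+ \sigma_\omega \xi_i(t),$$

integrated by Euler–Maruyama at $dt = 1/f_s$, observed as
$x_i = \sum_b \sin\theta_i^{(b)} + \varepsilon_i$ with white measurement
noise. This model is used because it provides direct, controllable
phase-lag structure — exactly what the PLI measures. Parameter choices, with
rationale:

* **Natural frequencies**: uniform within ±0.5 Hz of the band centre
  (midpoint of the band edges), so uncoupled regions drift apart and their
  PLI decays.
* **Frequency noise** $\sigma_\omega = 1\ \mathrm{rad}/\sqrt{\mathrm{s}}$:
  decorrelates uncoupled pairs within an 8-s epoch (phase-difference SD
  ≈ 4 rad over 8 s) while locked pairs fluctuate only ≈ 0.2 rad around
  their lag.
* **Coupling scale**: strength 1 maps to $4\pi$ rad/s, so a strength-0.8
  planted edge locks firmly against worst-case detuning, while backbone
  strengths 0.05–0.25 sit in the partially-locking regime. The weak
  backbone matters: a strong backbone globally synchronizes the band,
  producing uniformly high PLI — an unrealistic regime in which topology
  carries no information. With the default backbone the off-diagonal PLI
  has median ≈ 0.2 and 90th percentile ≈ 0.6, resembling empirical PLI
  matrices.
* **Planted effect**: group A receives 3 extra couplings of strength 0.8
  converging on one hub (the left postcentral region for the 90-region
  atlas), all with lag $\pi/4$ and the *same orientation* (the hub leads
  every partner). Orientation matters: partners then sit at mutual lag ≈ 0,
  which the PLI cannot see, so the strong links converge on the hub in PLI
  space as well as in the coupling graph. Group B is the identical backbone
  without the extra edges, making every non-effect band exchangeable
  between groups.
* **Cohort**: 26 vs 29 subjects, 240-s recordings at 512 Hz (30 complete
  8-s epochs, leaving headroom for the 24-epoch resampling robustness),
  per-subject seeds derived from one cohort seed.

What the generator does *not* emulate: 1/f broadband background, amplitude
dynamics and cross-frequency coupling, spatially correlated sensor noise,
source-leakage mixing (the zero-lag contamination PLI is designed to
reject), artifacts, and any anatomical geometry. Passing tests therefore
show that the pipeline recovers lag-coupling topology planted in its own
model class, and that its statistics are calibrated — not that any specific
empirical finding would replicate.

## Problem sizes used in the checks

The full design (90 regions, 26 + 29 subjects, 24 epochs, 10000
permutations) runs in about half an hour on one CPU
(`analysis/02_full_pipeline.R full`). The automated test suite exercises the
identical code paths at reduced sizes chosen to keep the suite fast: the
planted-effect recovery check uses 24 regions, 6 epochs of 8 s, 2000
permutations and 10 seeded replicates (group sizes and effect parameters
unchanged); metric oracles enumerate all labelled trees up to 6 nodes
(1441 trees, via Prüfer sequences) plus 200 random trees up to 15 nodes;
calibration uses 500 null cohorts at 26 vs 29 with 1000 permutations each.

## Degenerate inputs and numerical conventions

* Phases are principal values in $(-\pi, \pi]$; wrapped differences use
  $\mathrm{Arg}\, e^{i(\phi_a - \phi_b)}$.
* Zero-variance channels have undefined phase: they are flagged at phase
  extraction and any PLI computation touching them raises a typed
  degenerate-input error rather than propagating NaNs.
* `sign(0) = 0` in the PLI (samples at exactly zero lag are uninformative).
* A zero-lag coupling in the generator is allowed but warned about: it is
  the PLI's designed blind spot and cannot be recovered.
* Errors carry condition classes (`plimst_invalid_argument`,
  `plimst_degenerate_input`, `plimst_disconnected_graph`,
  `plimst_undefined_metric`) so callers can distinguish contract violations
  from degenerate data.

## Design choices that were genuinely open

* **Filter direction and per-band isolation**: the study description states
  a 4th-order Butterworth broadband filter but not the per-band mechanism;
  time-domain zero-phase Butterworth per band was chosen to protect phase.
* **Tree-hierarchy normalization**: see above; both variants exposed.
* **FDR family**: see above; both variants exposed.
* **Epoch selection**: random without replacement with a stored seed, the
  reproducible analogue of manual clean-epoch choice, and consistent with
  the epoch-resampling robustness procedure.
* **Statistic**: plain mean difference (not standardized), matching the
  stated procedure; the permutation null makes it a valid test either way.
* **Interface shape**: the package is organised as an analysis workflow —
  functions plus numbered driver scripts under `analysis/` — rather than a
  shell tool; `run_pipeline()` over a `pipeline_config()` (YAML-serializable)
  is the single orchestration point.

## Known limitations

* The generator's recovery guarantees are within-model; real MEG violates
  the model in the ways listed above.
* PLI discards genuine zero-lag physiology by design.
* The MST view is deliberately sparse: metrics describe the backbone of the
  strongest synchronizations, not the full weighted graph.
* With very few permutations the smallest attainable p,
  $1/(n_{\mathrm{perm}}+1)$, can exceed the BH threshold $q/m$ of a large
  family; use $n_{\mathrm{perm}} \gtrsim 2 m / q$ (the defaults satisfy
  this).
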