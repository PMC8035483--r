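---
title: "Small-world connectome analysis of ROI time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world connectome analysis of ROI time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connsweep)
```

## What the package computes

`connsweep` implements a complete graph-theoretical analysis of
resting-state functional brain networks for a three-group clinical design
(cognitively impaired patients, CI; non-impaired patients, NCI; healthy
controls, HC), starting from region-of-interest (ROI) time series rather
than image volumes. The stages are:

1. **Signal cleaning** — discard initial volumes, remove linear trends,
   regress out nuisance signals (Friston-24 motion expansion, optionally
   cerebrospinal-fluid / white-matter signals), band-pass filter to
   0.01–0.08 Hz, and scrub high-motion volumes by framewise displacement.
2. **Connectivity** — a 90 × 90 partial-correlation matrix per subject:
   each edge is the correlation between two regions conditional on the
   remaining 88, computed as `-O[i,j]/sqrt(O[i,i] O[j,j])` from the
   precision matrix `O` of the (shrinkage-regularised) sample covariance.
3. **Binarization over a sparsity sweep** — at sparsity `S` the
   `round_half_up(S * N(N-1)/2)` strongest edges by `|partial correlation|`
   are kept.
4. **Graph metrics** — clustering coefficient `Cp`, characteristic path
   length `Lp`, global and local efficiency, nodal degree, nodal efficiency
   and betweenness; `gamma`, `lambda` and `sigma = gamma/lambda` normalise
   `Cp` and `Lp` by their means over degree-preserving rewired null
   networks.
5. **Range selection and AUC** — the analysed sparsity range is the
   largest contiguous sub-grid on which `sigma` is estimable and above 1
   for *every* subject; each metric curve is then reduced to its
   trapezoidal area under the curve (AUC) over that range.
6. **Statistics** — demographic tests (chi-square, summary t, summary
   ANOVA), ANCOVA on the AUC values with age, sex and glomerular filtration
   rate as nuisance covariates plus Bonferroni post hoc contrasts, and
   FDR-corrected partial correlations between nodal AUCs and cognitive
   scores within the impaired group.

A synthetic-cohort generator produces ROI series, motion traces and
phenotypes with known ground truth, so the whole pipeline is testable
end to end.

## The generative model

Each group's ground truth is a precision matrix over 90 regions organised
into 6 contiguous modules of 15. Within a module, nodes are joined in a
ring lattice of strong conditional dependencies plus a weak dense
background; sparse, weaker between-module shortcuts give the implied
network a small-world topology. Seven atlas regions — bilateral medial
superior frontal gyrus, left posterior cingulate gyrus, left angular gyrus,
right precuneus, right amygdala, right hippocampus — form the
**default-mode seed set**: they are additionally tied into a densely
connected hub community (a within-set clique plus extra strong edges into
their home modules), mirroring the hub role of the default-mode network in
real connectomes.

Group structure enters through two factors:

* **Focal DMN attenuation** `a`: all precision entries incident to the
  seven seed regions are multiplied by `1 - a`
  (HC `0`, NCI `0.2`, CI `0.9` by default, per-subject jitter sd `0.05`).
  Because the diagonal is re-loaded after attenuation, every implied
  partial correlation at a seeded node is *strictly* smaller in magnitude
  than in the unattenuated model — the group ordering HC > NCI > CI holds
  edge by edge, not just on average.
* **Diffuse global attenuation** `g` (HC `0`, NCI `0.25`, CI `0.55`):
  all off-diagonal entries are scaled by `1 - g`, emulating the
  whole-brain connectivity weakening of the patient groups. This is what
  produces the group differences in the *global* metrics (`sigma`,
  `Cp`, local efficiency): with 7 of 90 nodes, the focal effect alone has
  too small a footprint to move whole-network summaries at these sample
  sizes.

The diagonal is set to `(1 + 0.1) * sum(|row|) + 0.5`, which guarantees
positive definiteness by strict diagonal dominance; a Cholesky
factorisation is still run and failure is an error, never silently
repaired. Subject time series are Gaussian innovations with covariance
equal to the inverse precision, passed through an AR(1) with coefficient
0.3 to give BOLD-like smoothness (this rescales the stationary covariance
uniformly and leaves partial correlations untouched).

Phenotypes use the published group summaries (36/30/48 subjects, ages
about 31.5 ± 7.5 truncated to 18–45, group-matched sex and education,
MoCA/TMT/SDMT group means and SDs). The cognitively-impaired label and the
MoCA score are kept mutually consistent with the score < 26 rule by
construction. Cognitive scores are linear in each subject's true
default-mode nodal strength (the row sums of |implied partial correlation|
at the seed regions) with within-group target correlations of about
0.45 for SDMT, −0.45 for TMT-A, −0.35 for TMT-B and 0.3 for MoCA —
magnitudes in the band reported for such couplings in the clinical
literature this design emulates. eGFR is generated low (≈ 8 mL/min/1.73 m²)
in the patient groups and normal (≈ 100) in controls; no published values
constrain these ranges, so they are generator choices.

Motion traces are smooth AR(1) excursions clipped to ±0.25 mm / degrees —
comfortably inside the 1.0 mm / 1.0° exclusion rule — and a configurable
30 % of subjects receive single-volume 0.7 mm translation spikes. A spike
displaces one volume and returns, so framewise displacement flags exactly
two volumes per spike; the flagged indices are recorded in the ground
truth and recovered exactly by the scrubbing stage in the tests.

### What the generator does not emulate

No hemodynamic response, physiological noise, scanner drift beyond a
linear trend, spatial autocorrelation between neighbouring regions, or
non-Gaussian artefacts. Passing tests therefore demonstrate that the
pipeline recovers the seeded statistical structure under Gaussian,
band-limited, motion-contaminated conditions — not that it would behave
identically on real scanner data.

## Numerical and design choices

* **Shrinkage.** With ~230 band-limited volumes and 90 regions the
  unregularised precision estimate is noise dominated. The band-pass to
  0.01–0.08 Hz leaves roughly half the nominal degrees of freedom, and we
  observed that lightly-shrunk estimates produce *spurious* clustering:
  binarized networks look small-world even though few selected edges are
  real, and at intermediate intensities the normalised clustering can even
  dip below 1. The pipeline therefore fixes a heavy intensity (0.9) toward
  the diagonal of the sample covariance, where edge ranking is most
  faithful to the generative structure; `partial_correlation_matrix()`
  also offers the analytic (Ledoit–Wolf / Schäfer–Strimmer) intensity via
  `shrinkage = "auto"` and any fixed value. The intensity used is recorded
  as an attribute of every connectivity matrix.
* **Edge ranking** uses absolute partial correlation (negative edges are
  eligible), with ties broken by ascending (row, column) pairs so that
  edge sets are nested across thresholds and runs are bit-reproducible.
  Edge counts round half-up, so `S = 0.10` on 90 nodes keeps
  401 of 4005 edges.
* **Disconnected graphs.** `Lp` is the mean over connected ordered pairs;
  unreachable pairs are excluded from `Lp` but contribute 0 to the
  efficiencies; the number of components is always reported.
  Small-worldness is treated as estimable only when `gamma` and `lambda`
  are finite and `lambda > 0`.
* **Null model.** Degree-preserving double-edge swaps (Maslov–Sneppen),
  aiming at 10 successful swaps per edge with a 10× attempt cap; if no
  legal swap exists (complete graphs) the input is returned with a
  warning. The null generator uses its own xorshift RNG so results are
  identical across platforms and independent of R's RNG state. Null counts
  default to 100 per grid point; the packaged study-scale runs use 20 to
  keep a full 114-subject sweep a few minutes long.
* **Processing order** is discard → detrend → nuisance regression →
  band-pass → scrub. Regressing before filtering avoids re-introducing
  out-of-band nuisance energy; scrubbed volumes are dropped (not
  interpolated) just before covariance estimation, so surviving rows stay
  bit-identical. The band-pass is a zero-phase (forward–backward)
  order-2-per-pass Butterworth.
* **Framewise displacement** uses the displacement formula with a 50 mm
  head radius (rotations converted from degrees to arc length), threshold
  0.5 mm, flagged volumes only (no neighbour augmentation); all
  configurable, since the underlying exclusion conventions vary between
  laboratories.
* **Seeds.** Every stochastic element traces back to one master seed via a
  fixed polynomial hash of (seed, key) — per subject, per grid point, per
  null batch — so curves are reproducible regardless of subject order or
  parallel scheduling, and all derived seeds stay below 2^31.

## Statistical stage

ANCOVA is the linear model `y ~ covariates + group` tested by the extra
sum of squares of the group dummies; with zero covariates it reduces
exactly to one-way ANOVA. Post hoc comparisons are t tests on the
model-based adjusted means with Bonferroni correction (×3, capped at 1).
Summary-statistic tests (chi-square without continuity correction, pooled
and Welch t, one-way ANOVA from n/mean/sd) reproduce raw-data tests to
numerical precision when fed matching summaries. Partial correlations
residualise both variables on age, sex and education (configurable) and
use the t transform with n − k − 2 degrees of freedom; multiplicity is
handled by Benjamini–Hochberg across all score × metric × region pairs.

## Problem sizes used by the packaged runs

The tests and the acceptance script run the full default cohort
(114 subjects, 90 regions, 240 volumes) with 20 null networks per grid
point; the pipeline's default candidate grid is 0.10–0.34 (step 0.01),
the window conventionally analysed for binarized connectomes of this
size, while the acceptance script searches a wider 0.05–0.50 candidate
grid. Unit tests use smaller
cohorts (9–12 subjects, 20–40 regions) and exhaustive oracles on graphs of
up to 8 nodes. These sizes are the package's own choices for routine runs;
`n_null = 100` remains the default for standalone metric computations.

## Known limitations

* With 230 band-limited volumes, partial-correlation edge estimates are
  noisy (per-edge sampling error comparable to true edge strengths); the
  pipeline's power to localise nodal effects depends on the seeded regions
  being hubs, and region-level recovery varies somewhat between cohort
  realisations.
* The sparsity range selected on heavily-shrunk connectomes typically
  extends lower (0.05–0.50) than ranges reported for lightly-regularised
  analyses; the estimability rule, not a fixed window, is authoritative
  here.
* Correlations between *estimated* nodal AUCs and cognitive scores are
  attenuated relative to the generative coupling; the packaged ground
  truth stores the true nodal strengths so recovery can be assessed
  against them.
* The ANCOVA covariate set follows the emulated design (age, sex, eGFR).
  Because end-stage renal disease makes eGFR bimodal (≈ 8 in patients,
  ≈ 100 in controls), the covariate is nearly collinear with
  patient-versus-control status and absorbs most of that contrast: the
  group F test is then driven largely by the CI-versus-NCI difference.
  This mirrors an awkwardness inherent in the emulated design rather than
  resolving it, and it is why the generator's default group contrasts
  place most of the focal default-mode separation between the two patient
  groups (NCI 0.2 vs CI 0.9) while the diffuse global attenuation
  separates patients from controls.
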