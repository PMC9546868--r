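---
title: "Detecting resting-state replay of movement-evoked patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting resting-state replay of movement-evoked patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restreplay)
```

# The question and the measurement model

Motor cortex encodes different hand movements as distinguishable multi-vertex
BOLD patterns. `restreplay` asks whether those task-defined patterns re-occur
spontaneously during rest, and whether ecological movements (Grip, Extend,
Pinch) are represented at rest more than a non-ecological control (Shake).
Because the original scanner data for this design are not redistributable, the
package pairs the analysis with a generative model of the acquisition, so that
the whole chain is exercised against a known ground truth.

## The hemodynamic model

Neural events drive BOLD through a gamma impulse response

$$h(t) = \left(\frac{t-\Delta}{\tau}\right)^2 e^{-(t-\Delta)/\tau}, \quad t \ge \Delta,$$

with onset delay $\Delta = 2.25$ s and dispersion $\tau = 1.25$ s
(`make_hrf()`). The kernel is sampled at the TR over a support of
$\Delta + 10\tau \approx 14.75$ s and scaled to unit peak, so that amplitude
parameters read as peak response sizes. Its analytic maximum is at
$\Delta + 2\tau = 4.75$ s. Responses of overlapping blocks and events sum
linearly — the standard linear-systems BOLD assumption.

## The synthetic world

`sim_config()` fixes the stated experimental world; its defaults are the
acquisition the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_vertices` | 5000 | hemisphere-mask vertices |
| `n_active_vertices` | 2187 | truly responsive region |
| `tr_seconds` | 1 (2 s variant supported) | sampling interval |
| `n_task_runs` | 5 | task runs |
| `blocks_per_movement_per_run` | 3 | 12 blocks/run |
| `block_duration_s` | 10 | movement block length |
| `rest_gap_range_s` | [20, 24] | uniform integer inter-block gaps |
| `n_rest_runs_pre`, `n_rest_runs_post` | 3, 3 | 5-minute rest runs |
| `hrf_delta`, `hrf_tau` | 2.25, 1.25 s | gamma HRF |
| `pattern_amplitude` | 0.5 | peak pattern response, units of `noise_sd` |
| `common_activation` | 2 | movement-independent evoked response |
| `noise_sd` | 1 | i.i.d. measurement noise |
| `global_noise_sd` | 0.5 | frame-wise fluctuation shared by all vertices |
| `baseline_level` | 100 | constant baseline intensity |
| `ecological_similarity` | 0.5 | target r among Grip/Extend/Pinch patterns |
| `control_similarity` | 0.1 | target r of each with Shake |
| `rest_event_rate_per_min` | Grip 4, Extend 3, Pinch 3, Shake 0.5 | pre-task replay rates |
| `rest_event_rate_post_per_min` | all 0 | post-task replay rates |

Three parameters deserve comment because they are this package's own modeling
choices rather than quantities any experiment reports:

* **`common_activation`.** The active region responds to *every* movement with
  a shared positive component, on top of which the movement-specific zero-mean
  pattern rides. Without it no vertex would show a positive task-vs-baseline
  contrast on average and percent signal change would hover at zero; with it,
  the region behaves like motor cortex: a robust common BOLD response whose
  fine structure differs between movements. The value 2 (twice the pattern SD)
  makes ~98% of active vertices positively activated, so the 2187-target ROI
  is attainable.
* **`global_noise_sd`.** Real resting fMRI contains global fluctuations
  (respiration, vigilance) — the very nuisance global-signal regression (GSR)
  exists to remove. With purely i.i.d. noise the simulated global mean would
  be almost noise-free, and GSR would then remove *any* shared signal,
  including embedded replay transients, far more aggressively than it can in
  real data. A shared fluctuation at half the thermal noise SD restores the
  intended behaviour: GSR removes the global component and only mildly
  attenuates structured signals.
* **Post-task rates default to zero.** The stated world builds in
  pattern-specific adaptation: replay events are embedded in pre-task rest
  only, so the pre/post dissociation is a recoverable ground truth rather than
  an accident of sampling.

Rest "replay" transients use the same HRF as task responses and, by default,
the same amplitude (`rest_event_amplitude = pattern_amplitude`) — one fewer
free parameter; both are overridable. Event onsets are drawn per movement from
a Poisson process on the frame grid and logged, so parameter-recovery tests
can condition on the truth.

**Pattern geometry.** `make_ground_truth()` draws four Gaussian vertex
vectors, centers and orthonormalizes them, and mixes them with a symmetric
square root of the target correlation matrix. The realized pairwise Pearson
correlations therefore equal the targets *exactly* (well inside the ±0.1
contract) at any region size — important because sampling error of r at small
test scales (1/√n ≈ 0.13 at 60 vertices) would otherwise make scaled-down
tests flaky. An infeasible (non-PSD) target matrix is rejected.

**What the generator does not emulate:** spatial autocorrelation and smoothing
of noise, physiological confounds beyond the single global component, head
motion, scanner drift beyond a linear term, and the anatomical geometry of the
cortical surface (no vertex adjacency). A green test therefore establishes
that the *pipeline* recovers what it should from data obeying its stated
assumptions — not that those assumptions hold in any particular scanner.

# Preprocessing

Per run, in a fixed order that is part of the analysis contract:

1. `drop_initial_frames()` — the first four TRs are discarded
   (pre-steady-state magnetization); `realign_events()` re-expresses onsets
   relative to the new first frame.
2. `regress_global_signal()` — each vertex's time course is replaced by its
   least-squares residual on [intercept, mask-mean time course]. A constant
   global signal degrades to intercept-only removal, with a warning.
3. `zscore_frames()` — each frame becomes a relative spatial pattern: centered
   and scaled to sample SD 1 (ddof = 1) over the ROI vertices. Frames with
   zero spatial variance cannot be standardized; they are excluded and logged
   rather than imputed (a constant frame has no defined correlation with
   anything).

Two conventions are deliberate choices the upstream description leaves open:
z-scores use the *sample* SD, and the z-scoring population is the *ROI*
vertex set (the analysis object is a relative pattern within the motor
region); the hemisphere enters only through GSR. Both are configurable.

**GSR at simulation scale.** In real data the analysis ROI is a tiny fraction
of the hemisphere, so task responses barely leak into the global mean. In the
synthetic world the active region is a large fraction of the mask
(2187/5000 by default, more in scaled-down tests), so the global signal
contains an appreciable copy of the shared evoked response, and GSR partially
projects the across-movement mean pattern out of each movement's estimated
pattern. The consequence is a roughly constant negative offset in the RSA
matrix: pattern *differences*, classifier geometry, and every ordering the
package asserts (ecological pairs more similar than Shake pairs; embedded
replay ranks) are untouched, but absolute pattern-vs-ground-truth correlations
are reduced. Tests and acceptance criteria therefore assert orderings and
recovery under the documented toggles (the noiseless forward-recovery
criterion runs with GSR off, where it is degenerate anyway: in a noiseless
world every vertex is an affine function of the global signal).

# ROI selection

The GLM (`fit_glm()`) is ordinary least squares per vertex on raw
(frame-dropped, non-GSR, non-z-scored) data. The design
(`build_design_matrix()`) contains an intercept, one combined task regressor —
all four movements pooled, to avoid biasing the ROI toward any one movement —
a linear drift, and optional nuisance columns; multiple runs concatenate with
per-run intercept and drift blocks. The contrast t statistic uses
df = frames − rank(design).

`select_roi()` reproduces the adjust-the-p-level procedure: count the
candidate vertices with contrast p below a threshold *and positive task beta*
(the region of interest is activated cortex, not deactivations — a one-sided
choice this package makes explicit), then bisect on log₁₀(p) over
[10⁻¹², 0.05]. ROI size is non-decreasing in the threshold, so bisection is
exact up to count granularity; it runs to convergence and keeps the threshold
whose count is closest to the 2187 target, succeeding if within ±7%. An
unattainable target returns the closest achievable set with `achieved =
FALSE` and a warning rather than an error, so cohort pipelines can proceed
and report. No spatial-contiguity constraint is applied: the anatomical
central-sulcus clustering of real surfaces has no analogue in the synthetic
vertex set.

# Patterns, similarity, decoding

Block patterns (`extract_block_patterns()`) average the z-scored frames in the
window 10–18 s after block onset — the most activated period, one full HRF
lag after movement start; with TR = 1 s that is 8 frames, with TR = 2 s,
`floor(8/TR) = 4`. Mean spatial patterns average a movement's block means
across runs; the spatio-temporal variant averages each window frame across
blocks and concatenates them vertex-major into one vector of length
|ROI| × window frames (2187 × 8 = 17496 at full scale).

`rsa_matrix()` is the plain Pearson correlation matrix of the four mean
patterns.

**Decoding** (`lda_fit()`, `crossval_timecourse()`) uses linear discriminant
analysis with the pooled within-class covariance shrunk toward its diagonal,
$\Sigma = (1-\lambda)S + \lambda\,\mathrm{diag}(S)$. Plain LDA is singular
here — ~2187 features against ~48 training samples — and the original
Matlab implementation's handling of that singularity is not documented, so
shrinkage LDA is this package's stated substitute. The intensity λ is chosen
analytically (Ledoit–Wolf/Schäfer–Strimmer style: summed sampling variances of
the off-diagonal covariance entries over their summed squares), computed with
O(n²p) identities so the p × p covariance is never formed; prediction uses the
Woodbury identity when p > n. Ties break toward the lowest class index.

Training uses block-mean window patterns (the stable choice given p ≫ n);
testing classifies every single z-scored frame of the held-out run's blocks at
each within-block frame index (0 ≤ t − onset < 28 s), under
leave-one-run-out cross-validation. Folds whose training runs lack a movement
are skipped with a warning; fold bookkeeping (held-out run, training runs, λ)
is returned so hygiene is testable. A mean-pattern variant classifies held-out
block means and accumulates the 4 × 4 confusion matrix (rows: performed;
entries: P(predicted | performed)). Group inference on the accuracy curve is a
per-index one-sample t against chance 0.25 across subjects with BH-FDR over
indices (`accuracy_group_inference()`).

`mean_bold_timecourse()` reports percent signal change relative to the
ROI-mean over baseline frames (frames outside every block-plus-HRF-tail
window), on raw data: the simulator's positive `baseline_level` exists so this
quantity is well defined.

# The replay statistic

For each movement and rest phase, the mean task pattern is Pearson-correlated
with every retained rest frame, pooled across the phase's runs
(`frame_pattern_correlations()`); the order of runs cannot matter and a test
asserts it. The similarity measure is the 90th-percentile value of the
empirical CDF of the transformed correlations (`cdf_cutoff()`), in variants:

* `r2` — squared correlations (the headline measure; sensitive to both tails),
* `r` — signed correlations (positive matches only),
* `neg_r` — inverted correlations (the lower tail, read as an upper tail),
* `spatiotemporal_r2` — r² of correlations between the 8-s concatenated task
  pattern and every sliding 8-s rest window (stride 1 frame by default,
  configurable; windows never span runs).

The empirical quantile rule is stated bit-exactly: linear interpolation
between order statistics at position h = (n − 1)·0.9 (the common "type 7"
definition), and an acceptance test pins the implementation to an independent
sort-and-interpolate oracle on 1000 random vectors. Fewer than 10 values is an
error — a 90th percentile of fewer points is not a statistic worth reporting.
`replay_summary()` tabulates subject × movement × phase × variant cutoffs.

# Group statistics

`rm_anova_1way()` is the classical within-subject decomposition
(F = MS_condition / MS_condition×subject, df = (k−1, (k−1)(n−1)); for the
15-subject, 4-movement design: F(3,42)). No sphericity correction is applied —
a documented limitation chosen to match the plain degrees of freedom this
analysis tradition reports. `paired_t()` is the two-tailed paired t;
`holm_bonferroni()` and `fdr_bh()` implement the step-down and step-up
corrections exactly as defined. All reported p-values are raw; correction
decisions are flagged separately.

`analyze_experiment()` mirrors the planned comparison families rather than all
pairwise tests: per phase and variant, the movement ANOVA, then (i) each
ecological movement vs Shake (Holm within family), (ii) pre vs post per
movement, and (iii) Grip vs Pinch for the spatio-temporal variant, where that
contrast is part of the plan.

# Numerical and testing choices

* **Determinism.** Every random quantity derives from a master seed through a
  fixed arithmetic stream (`derive_seed()`, kept below 2³¹); identical config
  and seed give byte-identical on-disk outputs, which a pipeline test asserts
  via checksums.
* **Degenerate inputs.** Zero-variance frames are excluded, not imputed;
  zero-variance patterns and constant rank inputs are errors; a constant
  global signal degrades GSR to intercept removal with a warning; an
  infeasible ROI target returns flagged rather than failing.
* **Scaled-down property tests.** Heavy stochastic properties (replay-rate
  recovery, null exchangeability of cutoffs, the pre/post cohort
  dissociation) run at reduced vertex counts and rest durations. The asserted
  properties are scale-free orderings and error rates, not absolute effect
  sizes; the decoding-at-chance and ROI-sizing acceptance criteria run at the
  full 2187-/5000-vertex scale. The null-exchangeability cohort uses an
  equal-correlation pattern geometry, because exchangeability of the four
  cutoff statistics requires a symmetric dependence structure that the
  deliberately asymmetric default geometry (ecological 0.5 vs control 0.1)
  does not provide.
* **Binomial bands.** Where a criterion states an approximate rate ("type I
  ≈ 5% over 200 replicates"), the test asserts the exact central 99.5%
  binomial interval around the nominal rate, so the assertion has a stated
  false-alarm probability instead of an ad-hoc margin.

# Known limitations

* The simulator's noise is white in space (beyond the one global component)
  and time; real BOLD noise is smooth in both. Absolute cutoff magnitudes are
  therefore not comparable to values from scanner data.
* GSR's mean-pattern leakage at simulation scale (above) makes absolute RSA
  values offset-shifted; only orderings are meaningful at small mask sizes.
* The event amplitude and duration of spontaneous replay are free simulation
  parameters, not estimates — nothing in the upstream description constrains
  them.
* Decoding trains on block means by default; per-frame training is possible in
  principle but is not implemented as a toggle.
* No HDF5/GIFTI readers: the on-disk interchange format is plain TSV matrices
  with JSON sidecars, which every tool in this environment can produce.
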