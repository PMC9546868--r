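# restreplay

Detecting spontaneous "replay" of movement-evoked fMRI activity patterns in
resting-state data.

## The scientific problem

Multivoxel (multi-vertex) activity patterns in primary motor cortex
discriminate between different hand movements. A natural question is whether
those task-defined spatial patterns also re-occur *spontaneously* while a
person simply rests — and whether patterns for ecological, everyday movements
(closing the hand in a **Grip**, opening it in an **Extend**, a precision
**Pinch**) are represented at rest more strongly than an unusual control
movement (a wrist **Shake**).

`restreplay` implements the complete analysis needed to ask that question,
together with a synthetic surface-sampled BOLD generator that makes every
stage testable without any scanner data:

1. **Simulation** (`sim_config()`, `simulate_subject()`): a block-design motor
   task (five runs of twelve 10-s movement blocks, three per movement,
   separated by 20–24 s rest gaps), plus pre- and post-task 5-minute rest runs
   into which movement-pattern transients are embedded as a Poisson "replay"
   process with a known per-movement rate — the recoverable ground truth.
2. **Preprocessing** (`drop_initial_frames()`, `regress_global_signal()`,
   `zscore_frames()`): discard the first four TRs, regress the hemisphere-mean
   (global) signal out of every vertex, and convert each frame to a spatial
   z-pattern over the ROI.
3. **ROI selection** (`fit_glm()`, `select_roi()`): a mass-univariate GLM with
   a gamma HRF (Δ = 2.25 s, τ = 1.25 s) contrasts all movements combined
   against baseline; the p-threshold is adjusted by bisection until the ROI
   holds 2187 ± 7 % vertices.
4. **Decoding and RSA** (`crossval_timecourse()`, `rsa_matrix()`): shrinkage
   LDA classifies each single frame under leave-one-run-out cross-validation,
   tracing decoding accuracy across the trial (chance = 0.25), and Pearson
   correlations between the mean patterns quantify their similarity geometry.
5. **Replay statistic** (`frame_pattern_correlations()`, `cdf_cutoff()`,
   `replay_summary()`): each movement's mean pattern is correlated with every
   rest frame; the headline similarity measure is the **90th percentile of the
   empirical CDF of the r² values**,

   cutoff(m, phase) = Q₀.₉₀{ r²(pattern_m, frame_t) : t ∈ rest frames },

   computed in four variants (r², signed r, inverted −r, and a spatio-temporal
   variant correlating 8-s concatenated vertex × TR windows).
6. **Group statistics** (`rm_anova_1way()`, `paired_t()`,
   `holm_bonferroni()`, `fdr_bh()`, `analyze_experiment()`): one-way
   repeated-measures ANOVA over the four movements per phase and variant, the
   planned post-hoc paired t-tests with Holm–Bonferroni correction, and
   BH-FDR for the per-frame decoding curve.

## Worked example

```r
library(restreplay)

cfg    <- sim_config(n_vertices = 300, n_active_vertices = 200, seed = 1)
bundle <- simulate_subject(cfg)
res    <- analyze_subject(bundle, roi_target = 200)

res$roi
#> <roi_definition> 200 vertices (target 200 +/- 7%) at p < 1e-12

res$classification$mean_pattern_accuracy
#> [1] 1

subset(res$cutoffs, phase == "pre" & variant == "r2")
#>  subject movement phase variant     cutoff n_frames
#>   sub-01     Grip   pre      r2 0.07952663      888
#>   sub-01   Extend   pre      r2 0.05391570      888
#>   sub-01    Pinch   pre      r2 0.04518896      888
#>   sub-01    Shake   pre      r2 0.04364395      888
```

The adaptive threshold recovers exactly the 200-vertex responsive region, the
leave-run-out classifier separates the four movements perfectly at this
signal-to-noise ratio, and the pre-task rest cutoffs mirror the embedded
replay rates (Grip 4/min > Extend = Pinch 3/min > Shake 0.5/min).

At the group level (8 simulated subjects, ~10 s):

```r
out <- file.path(tempdir(), "demo")
res <- run_pipeline(pipeline_config(out_dir = out, n_subjects = 8,
                                    sim = list(n_vertices = 300, n_active_vertices = 200),
                                    roi_target = 200, variants = "r2", seed = 1))
subset(res$stats, test == "rm_anova")[, c("phase", "statistic", "df1", "df2", "p_raw")]
#>  phase statistic df1 df2    p_raw
#>    pre      28.6   3  21 1.32e-07
#>   post       0.3   3  21 8.25e-01
```

Replay is embedded in pre-task rest only, and the repeated-measures ANOVA
reproduces the expected dissociation: a strong movement-type effect before the
task and none after it. Post-hoc, Grip vs Shake survives Holm correction in
the pre phase (t(7) = 11.7, p = 7.7e-06) and not in the post phase.

## Command line

```sh
Rscript inst/cli/restreplay.R run-all --out results_dir --subjects 15 --seed 1
Rscript inst/cli/restreplay.R validate --input results_dir/subjects
```

## Vignette

`vignettes/replay-analysis.Rmd` documents the model, every tunable parameter,
what the synthetic generator does and does not emulate, and the numerical and
design choices (quantile rule, LDA shrinkage, GSR behaviour at simulation
scale, scaled-down property tests).
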