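---
title: "ROI-network connectivity: model, inference, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ROI-network connectivity: model, inference, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

## The analysis

`fcnet` implements a seed-sphere resting-state functional connectivity
analysis over three brain networks — the cingulo-opercular network (CON),
the default mode network (DMN), and the orbitofrontal–striatal–thalamic
circuit (OST) — followed by a three-group comparison with covariate
adjustment. The pipeline is:

1. **ROI extraction.** Each region of interest is a sphere of radius 5 mm
   (configurable per ROI) around an MNI-space coordinate. A voxel belongs
   to the sphere iff its *center's* world coordinate lies within the
   radius; this voxel-center criterion is the simplest reproducible
   convention (an any-overlap rule would depend on voxel geometry).
   Overlapping spheres are permitted; overlap voxels contribute to both
   ROIs' means. The BOLD signal is averaged over the mask at every frame.
2. **Connectivity.** The T×R table of ROI means is reduced to an R×R
   Pearson correlation matrix, and Fisher's variance-stabilizing transform
   `z = atanh(r)` is applied to every cell. Self-correlations (`z = Inf`)
   are excluded from everything downstream. A correlation of exactly ±1
   raises an error by default; an opt-in clamp maps it to
   `±atanh(1 − 1e−7)` with a warning, because silent clamping can mask
   degenerate input data.
3. **Block means.** Six metrics per subject: the mean z over all unordered
   ROI pairs within each network (within-CON, within-DMN, within-OST), and
   the mean z over all cross pairs for each network pair (OST–CON,
   OST–DMN, CON–DMN). Averaging each ROI's intra-network z values first
   and then across ROIs gives the identical number — every unordered pair
   appears in exactly two of the ROI-wise averages — so the two phrasings
   of the within-network metric coincide; a property test asserts this on
   random matrices.
4. **Inference.** One ANCOVA per metric, `metric ~ group + age + mean_fd`,
   fitted by least squares with no interactions. The omnibus group F comes
   from the nested-model residual-sum-of-squares comparison (full model
   vs. covariates only), with `df1 = G − 1` and `df2 = N − G − C`. Effect
   size is partial eta squared, `SS_group / (SS_group + SS_error)`, which
   equals `F·df1 / (F·df1 + df2)`. The six omnibus p-values — exactly this
   family, nothing else — are adjusted with the Benjamini–Hochberg
   step-up procedure. Adjusted group means are model predictions at the
   *whole-sample* covariate means (the standard ANCOVA presentation), with
   standard errors from the coefficient covariance. Pairwise contrasts use
   Fisher's least-significant-difference method: t statistics from the
   pooled model error, df equal to the model error df, two-sided p with no
   further adjustment. Whether LSD should be gated on omnibus
   significance is genuinely ambiguous in practice, so the gate is
   *reported* as a flag and all three pairs are always emitted.

Group dummy coding uses the first factor level as reference; the omnibus F
is coding-invariant (tested). Two-sided tests and α = 0.05 throughout.

### Motion covariate

Framewise displacement follows the Power convention: backward differences
of the six rigid-body realignment parameters, rotations converted to arc
length on a 50-mm sphere (configurable), absolute values summed. Mean FD
includes the leading zero of frame 1, which keeps the summary invariant to
frame ordering conventions. No frame censoring is applied; high-motion
*subjects* can be excluded upstream as a cohort-table filter. All
preprocessing (realignment, normalization, nuisance regression, filtering)
is assumed done upstream; the pipeline accepts preprocessed 4D NIfTI
volumes or plain per-subject time-series tables and is agnostic to the
preprocessing chain.

### Secondary analyses

`severity_correlations()` computes Pearson correlations between a severity
scale and each metric with pairwise deletion of missing values (per-row n
reported); the OCD-severity scale is scoped to the OCD group, the anxiety
scale to all subjects with data. `sensitivity_analysis()` refits either
with a binary co-morbid-depression covariate (error df drops by one) or
after excluding subjects older than 18 (df recomputed from the reduced N).

## The synthetic-cohort generator

No subject-level data are deposited for studies of this design, so the
package carries a first-class simulator that emulates the study
conditions: three all-female groups of 23/26/44 (OCD, anxiety control,
healthy control), ages uniform on 8–21 years, T = 200 frames at TR = 2 s
(a conventional resting-state acquisition length; the defaults are
package conventions, not claims about any particular study).

Per group, the generator takes six Fisher-z block targets. The defaults
use the group values the analysis is designed to detect — within-CON
0.54/0.43/0.46 and OST–CON 0.40/0.30/0.33 for OCD/AC/HC — and
group-constant values for the four null metrics (within-DMN 0.45,
within-OST 0.50, OST–DMN 0.15, CON–DMN 0.10). The within-block defaults
must exceed the between-block values: a block matrix whose cross-network
correlations exceed its within-network correlations is not positive
semidefinite, i.e. no such correlation structure exists. The shipped
atlas (`inst/extdata/atlas_synthetic.tsv`) is likewise a synthetic
reconstruction — standard literature MNI coordinates for the named nodes
of the three networks — not a transcription of any published table.

Subject heterogeneity is modelled as additive jitter on the six z-targets,
decomposed into a shared global-coupling offset (SD 0.08) plus
block-specific variation (SD 0.05). The shared component reflects the
well-known global coupling factor in resting-state data and, numerically,
keeps the jittered block matrix positive semidefinite with overwhelming
probability; independent per-block jitter of the same total variance
frequently produces unrepairable matrices. If a jittered target set is
still unrepairable within tolerance (probability ~5 × 10⁻⁵ per subject),
the jitter is deterministically shrunk toward the group target by factors
of 0.7 until the repair fits.

The block matrix itself sets within-network off-diagonals to
`tanh(z_within)` and cross entries to `tanh(z_between)`. If the result is
not positive semidefinite it is repaired by clipping eigenvalues at a
floor of 1e−6 and renormalizing to unit diagonal; the maximum elementwise
deviation from the targets is attached to the result and must not exceed
`psd_tolerance` (default 0.05) — deviations are reported, never silently
accepted. Subject time series are T draws from a zero-mean multivariate
normal via the symmetric eigen square root; an optional AR(1) coefficient
is available (default 0) because BOLD autocorrelation inflates the
variance of sample z values, but the stationary white default keeps the
sampling theory exact.

Covariates are generated independent of group and connectivity (ages
uniform; mean FD log-normal with median 0.12 mm, a typical pediatric
value), so covariate adjustment is testable under the null. Severity
scores are generated uncorrelated with the metrics (OCD-severity mean
23.03, SD 6.41, first group only; anxiety scores for all groups with
~12% missingness), matching null secondary analyses. Motion-parameter
tables are synthesized by rescaling random increment directions so the
subject's mean FD is realized *exactly*, then integrating. All randomness
flows from the single master seed through per-subject seeds drawn once;
the global RNG stream is saved and restored, so nothing leaks.

### What the simulator does and does not emulate

It reproduces the block-correlation structure, group sizes, covariate
ranges and missingness patterns of a three-group pediatric resting-state
design. It does not model hemodynamics, scanner drift, spikes,
physiological noise, spatial autocorrelation of the noise background, or
any real registration/preprocessing imperfection. Passing
parameter-recovery tests therefore demonstrates that the *pipeline
arithmetic and inference* are correct under the assumed generative model —
not that the pipeline is robust to artifacts real fMRI data contain.

## Numerical choices

- Correlation matrices are symmetrized as `(r + t(r))/2` and asserted
  symmetric to 1e−10 relative tolerance.
- `fisher_z` agrees with `atanh` to 1e−12 over r ∈ (−0.999, 0.999)
  (tested); the closed form is kept for documentation value.
- Eigen decomposition (symmetric) is used both for the PSD check/repair
  and the simulator's square-root factor; eigenvalues are clipped at 0
  when building the factor.
- The nested-model F equals the Type-III group F of the dummy-coded fit
  for this single-factor no-interaction design; the suite asserts
  equality to 1e−8 against an independent implementation.
- Degenerate inputs fail loudly: empty sphere masks name the ROI,
  zero-variance columns name the ROI and (in the pipeline) the subject,
  rank-deficient designs (e.g. a constant covariate) are rejected rather
  than silently dropped.

## Problem sizes used in the shipped studies

The packaged recovery study runs 100 replicates of the full design
(93 subjects, T = 200, 24 ROIs) and the type-I calibration 200 replicates
with group-constant targets; both complete in a few minutes on a single
core and give binomial standard errors of ~0.015 on the calibrated
rejection rate, adequate for a 0.05 ± 0.03 band.

## A worked example

```{r example, eval = FALSE}
cohort <- cohort_table(simulate_cohort(sim_config(seed = 42)))
res <- group_analysis(cohort)
print(res)
summary(res$models$within_CON)
lsd_posthoc(res$models$within_CON)
```

## Known limitations

- Only the six block means are analysed; no edgewise (pair-level)
  inference, no partial correlations, no covariance shrinkage.
- The ANCOVA assumes homogeneous covariate slopes across groups (no
  interaction terms), the standard form of this design.
- Between-network metrics are symmetric by construction, so only the
  three unordered network pairs exist.
- NIfTI support assumes the header affine is trustworthy; no reorientation
  logic is applied beyond it.
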