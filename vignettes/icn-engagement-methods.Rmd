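---
title: "Quantifying ICN engagement: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ICN engagement: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icnengage)
```

This vignette is the package's own account of its methods: the models and
formulas it implements, the parameters that matter, the choices made where
the design was genuinely open, and what the synthetic validation does and
does not establish about real data.

## The atlasing model

An ICN base atlas is built from K co-registered prototype Z-score volumes,
one per network (typically Gaussianised group-ICA component maps in MNI
space). Construction has three parts, all driven by one threshold T:

1. **Masked base maps** — each prototype keeps its Z value where Z > T and
   is undefined elsewhere. The inequality is strict: a voxel exactly at T
   is excluded, consistently here and in input-map thresholding.
2. **Winner-take-all labels** — each voxel with at least one
   supra-threshold component is labelled with the component of highest Z,
   so the labelled base maps are mutually exclusive; sub-threshold voxels
   are `NA`, which is deliberately distinct from a zero label.
3. **Binary masks** — per-component indicators of Z > T. These may
   overlap across components and are the sets the engagement metrics are
   written in terms of.

`threshold` defaults to 3 (a Z-score), the conventional operating point
for published ICN template sets; it is a free parameter and the package
makes no attempt to optimise it. Raising T can only shrink the labelled
set (a property the tests assert across T ∈ {2, 3, 4}).

**Tie-breaking.** Two components with identical supra-threshold Z at a
voxel are resolved to the lower component index. On real-valued Z maps
ties have measure zero; the rule exists so synthetic runs and regression
tests are exactly reproducible. It is a package convention, documented
rather than inherited.

**Artefact components.** Template sets often ship noise/artefact
components (2 of 20 and 5 of 70 in the two widely used BrainMap
decompositions). These are built into the atlas like any other component
and carry a flag; exclusion is a reporting decision, not a construction
decision, because removing them from construction would silently hand
their voxels to neighbouring networks.

## Input maps

Input volumes (NIfTI, optionally gzipped, or Analyze) are reconciled onto
the atlas grid in world space. Trilinear interpolation is the default for
continuous statistic volumes, nearest-neighbour for masks and labels; the
package always resamples the input onto the atlas grid, never the atlas
onto the input. Missingness is conservative: a trilinear stencil touching
any `NA` source voxel yields `NA`, and voxels outside the source field of
view are `NA` — interpolation never manufactures values from partial
stencils. Nearest-neighbour ties (a coordinate exactly half-way between
voxel centres) go to the lower index, for the same reproducibility reason
as above.

Significance thresholding is strict (`v > threshold`) and optionally
followed by a cluster-extent filter: 26-connected components smaller than
`cluster_k` voxels are removed, the cluster-extent convention of common
SPM practice (a clinical use case in this family of analyses applies a
5-voxel extent to F maps). Deactivation maps are analysed explicitly via
`tail = "negative"`, which flips the sign before thresholding; negative
tails are never silently mixed into a positive-tail analysis.

## The engagement metrics

Writing A for the set of active voxels of the (possibly thresholded)
input map, the eleven ICN-specific metrics divide into

* **spatial**: involvement `I_i = |A∩ICN_i|/|ICN_i|`, relative involvement
  `IR_i`, overlap `OL_i = |A∩ICN_i|/|A|`, Sørensen–Dice `SQ_i`, Jaccard
  `J_i`;
* **activation-weighted**: raw mean `MA_i`, normalised mean `MA_N,i`,
  relative normalised `RA_N,i`, relative-of-means `IR_i^M`, density
  `I_i^M`;
* **correlation**: Pearson `r_i` between the unthresholded input values
  and the *unmasked* prototype Z, over the union of all binary masks.

and four globals (`I_T`, `MA`, `MA_N`, `I_T^M`) that pool the
corresponding sums over all components, so `I_T` is the base-map-size
weighted mean of the `I_i`.

Choices worth making explicit:

* **Normalisation.** `MA_N,i` averages per-voxel normalised values
  `(v − min)/(max − min)`. The bounds default to the input map's own
  min/max; an explicit `bounds` argument reproduces the session-matched
  variant in which the bounds are shared across all maps of one scanning
  session so that between-map intensity differences remain meaningful.
  A constant map cannot be normalised and is a hard error; bounds that
  fail to bracket the data warn and clip into [0, 1].
* **Intersection semantics.** The metric formulas are written against the
  binary masks `ICN_i^B`, which may overlap; the winner-take-all labelled
  volume is produced for reporting. Both counts are computed, and
  `counts = "labels"` switches the metrics to mutually exclusive
  accounting for users who want voxels counted once. With disjoint masks
  the two agree exactly.
* **Correlation domain.** `r_i` is computed over voxels belonging to any
  component rather than the whole grid, because a whole-grid correlation
  is dominated by the empty background; and over unthresholded values,
  because thresholding would truncate exactly the variance the metric is
  meant to capture.
* **Undefined is not zero.** `MA_i`/`MA_N,i` with no active voxel in the
  network, `OL_i` for an empty map, `IR_i` when no network voxel is
  active: all are `NA` with a `defined` flag in the tidy output. Folding
  these to 0 would silently bias group summaries.
* **Activity.** A voxel is active when it carries a non-missing, non-zero
  value; for thresholded maps this is exactly the surviving set. Zero is
  treated as "no activation", matching the convention that |X| counts
  non-zero voxels.

## Test–retest repeatability

Reliability of engagement scores across repeated scans is estimated with
the two-way consistency ICC,

ICC = (MS_R − MS_E) / (MS_R + (k − 1) MS_E),

whose defining property is insensitivity to systematic between-session
offsets (the session main effect is removed before the residual is
formed). This is the appropriate choice when scanner- or session-level
shifts are not of interest; the absolute-agreement variant, which does
penalise offsets, is available behind `type = "agreement"` for
sensitivity analysis. Estimates can be negative when subject variance is
small relative to noise — typically items with minimal overlap between
the map and the base map — and are reported as such, with pairwise
dropping of undefined cells and the dropped count surfaced.

Three pooling levels mirror how multi-network score sets are analysed:
per item (one ICC per IC × base map × metric; rows are subjects), per
base map (collapsed across ICs; rows are subject × IC pairs) and global
(collapsed across ICs and base maps). Pooling is pure aggregation and
never alters the per-item estimates.

The session design follows the structure of longitudinal test–retest
resting-state studies: a baseline scan followed months later by two scans
45 minutes apart. "Within-session" compares the two same-day scans;
"between-session" stacks the (baseline, later) pairings as rows of one
two-column matrix. The stacking rule is a documented package choice — the
alternative (averaging two separate ICCs) is not identical but close —
and is configurable through `session_design()`.

Voxel-wise repeatability is summarised by the mode of the ICC
distribution: values ≤ 0 are discarded and the remaining values binned
into 80 equal left-closed bins on [0, 1]; the mode is reported as the
centre of the fullest bin (ties to the lower bin). The bin centre is our
choice of representative point; the bin count and domain are fixed by the
convention this summary follows.

## Metric-set reduction

Eleven metrics per network is more than most applications want to report.
The reduction procedure runs, twice, a PCA plus an exploratory factor
analysis with principal-axis extraction and varimax rotation: stage 1 on
all metrics retains five — the strongest loaders on the two
highest-variance factors, the highest-uniqueness metric, and the
remaining best loaders — and stage 2 repeats the analysis on the
survivors to select three: the top loader on each factor plus the
highest-uniqueness survivor. Defaults (2 factors, keep 5, select 3)
follow the two-stage design this procedure operationalises; the counts
are exposed as parameters because the retention criterion genuinely mixes
two rankings ("high uniqueness" and "high loadings") without a canonical
cut-off.

Numerical details: factor extraction iterates communalities from squared
multiple correlations; rotation uses `stats::varimax`; the sign of each
factor is fixed by forcing its largest-magnitude loading positive;
explained-variance shares are sorted non-increasing. A singular
correlation matrix (duplicated or collinear metrics) is an error that
names the offending pair rather than a silently regularised fit.

## What the synthetic generator emulates — and what it does not

The fixture generator exists so that every pipeline stage can be tested
against *constructed* truth, with no reference imaging data:

* **Atlases** are constant-amplitude spherical blobs (one grid octant per
  component in the disjoint default, so masks cannot collide) with
  distinct amplitudes separated by more than twice the sub-threshold
  noise half-width — the winner at every overlap voxel is known by
  construction, not by running the builder. Optional Gaussian smoothing
  (separable kernel, FWHM in voxels) produces softer maps at the price of
  constructive truth.
* **Activation maps** sample exactly `floor(I · |ICN_i|)` voxels from each
  binary mask, so the involvement recovered by the full pipeline is known
  exactly, including its floor quantisation.
* **Session scores** follow y_st = u_s + d_{s,day(t)} + b_t + e_st with
  independent normal components. The session offsets b_t are included
  precisely because the consistency ICC's defining property is to ignore
  them — the simulator must be able to falsify that property. The
  subject-by-day term d gives same-day sessions an extra shared variance
  component, making true within-session ICC exceed between-session ICC,
  the qualitative pattern expected of real test–retest data. Defaults
  (25 subjects, 3 sessions, sessions 2 and 3 sharing a day) mirror the
  standard longitudinal test–retest design; for the directional
  validation we set σ_u = σ_day = σ_e = 1 and σ_session = 0.5, chosen
  once as a moderate-reliability regime (true ICC_W = 2/3, ICC_B = 1/3).
* **Metric matrices** plant two orthogonal factors with graded loadings
  (0.9 down in steps of 0.06) over 5 + 5 columns plus one independent
  column, so the reduction's expected selection is unambiguous.

What passing these tests shows: the arithmetic of every metric, the
labelling rule, the estimator calibration and the selection logic are
correct, to 1e-12 where exactness is claimed. What it does not show:
behaviour on real fMRI data — spatially autocorrelated noise, partial
voluming, inter-individual network variability, registration error and
non-spherical network shapes are all outside the generator. Validation
problem sizes (grids 6³–12³, K ≤ 6, 25–200 subjects, 2000 factor-analysis
rows, 100–200 seeds per property) were chosen as the smallest instances
that exercise every code path with comfortable Monte-Carlo margins.

## Known limitations

* Base atlases are hard (winner-take-all) parcellations of group-level
  templates; probabilistic/weighted atlases that respect inter-individual
  variability are not implemented.
* Statistical inference across groups of engagement tables is out of
  scope; the package is a quantifier, not a test battery.
* Random-field-theory corrected thresholds are not computed; users supply
  their own significance thresholds.
* The correlation metric uses a fixed domain (union of binary masks); its
  value therefore depends on the atlas threshold.
* 4-D inputs require an explicit volume index; no automatic splitting.
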