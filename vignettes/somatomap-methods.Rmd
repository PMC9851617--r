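---
title: "somatomap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somatomap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the scientific model behind each stage of the
package, the parameters that matter (with units and defaults), what the
synthetic cohort does and does not emulate, and the design choices made
where the methodology was genuinely open.  It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The synthetic world

### Geometry

The folded S1 strip is replaced by a flat rectangular triangulated patch
(`build_flat_patch_mesh()`), with the x coordinate modelling the
medial-to-lateral axis of the sensorimotor homunculus.  On a flat patch the
exact geodesic is the planar Euclidean distance, which turns the geodesic
distance code into something that can be checked against an analytic
oracle.  The grid is triangulated with one diagonal per cell, so the
graph-geodesic over-estimates the planar distance by at most a factor
sqrt(2); the test suite asserts this bound.  The price of flatness is that
no gyral folding, curvature or cortical thickness effects are represented.

The hand region of interest is the medial band (default 20 mm), the face
region the adjoining lateral band (default 40 mm), mirroring a hand
territory defined above the face representation.  The anchor used for all
distances is the midpoint vertex of the hand band's lateral border — the
synthetic analog of an anatomical landmark drawn about 1 cm lateral to the
hand knob.  For representational analyses both ROIs are trimmed back from
their facing edges by half the configured gap (default total gap 10 mm,
i.e. the 1 cm separation used on real surfaces) so that vertices near the
hand/face boundary cannot leak pattern information between ROIs.

### Ground truth and remapping effects

Each condition's true activation is an isotropic planar Gaussian blob.
The default layout is an upright face map: forehead nearest the hand
border, then nose, lips, tongue at equal steps laterally (centres
`hand_extent + (0.15, 0.35, 0.55, 0.75) * face_extent`, i.e. 26, 34, 42,
50 mm with default bands; width 4 mm SD; unit amplitude).  An optional
thumb blob sits inside the hand band; it is generated but excluded from
all face-map analyses by default, mirroring designs that omit the thumb
from face-part competition.

Remapping is injected per group as a condition-wise displacement of the
blob centre in the deprived hemisphere, positive toward the hand border.
The default encodes the pattern reported for congenital one-handers —
forehead 5 mm away from, lips and tongue 5 mm toward the deprived hand
area — and no shifts for amputee-like subjects or controls.  Subject
individuality is modelled as Gaussian jitter of the blob centres (SD 1 mm
by default, drawn independently per hemisphere and condition).  With
jitter disabled the deprived-minus-intact truth CoG difference equals the
configured shift exactly, which the tests exploit.

### Protocol and noise

The block protocol follows the emulated study: 8 s blocks, each condition
repeated 4 times per run plus 5 baseline blocks, 3 runs, TR 1.45 s, with
block order randomised uniformly without replacement per run (the original
ordering scheme is not documented, so the least-structured choice was
made).  Run length is computed from the protocol plus 12 trailing rest
volumes; with the study's six movement conditions this yields the study's
172 volumes per run, while the default four-condition synthetic protocol
yields 128.

Noise is AR(1) in time (marginal SD `noise_sd`, coefficient `noise_ar1`,
defaults 1 and 0.3), optionally smoothed on the mesh by iterated
neighbour averaging calibrated so the accumulated kernel variance matches
a Gaussian of the requested FWHM (default 3 mm, the smoothing used on the
real data).  Iterated averaging is a surrogate for exact mesh-Gaussian
smoothing; it reproduces the spatial correlation structure that matters to
the noise-covariance stage but reduces the marginal SD below `noise_sd`
(the SD is defined pre-smoothing).  The real data's effect sizes and noise
levels are not reported, so the defaults were chosen for test power, not
realism: a green test establishes that the estimators behave correctly in
a world obeying their assumptions, not that the pipeline is robust to
scanner artefacts, motion, or physiological noise, none of which are
simulated.

Everything is a pure function of `(spec, seed)`; sub-seeds for subjects,
hemispheres and runs are derived with a deterministic integer hash kept
below 2^31.

## 2. GLM

Per run, ordinary least squares per vertex on a design with one
double-gamma-HRF-convolved boxcar per condition plus a constant and a
linear drift.  Rest is the implicit baseline, so condition betas are
directly condition-versus-rest contrasts.  Prewhitening, high-pass
filtering and motion regressors are deliberately not implemented: the
synthetic noise is generated at the GLM's assumptions, and the
representational stage performs its own noise normalisation.  Temporal
derivative columns are available (`derivatives = TRUE`) but default off;
at synthetic SNR they change winner maps negligibly.

Fixed-effects averaging combines runs as the mean beta, with a t-like
statistic `beta_mean / SE` whose SE pools run-level residual variances
with the design-derived beta variance.  The t-like statistic approximates
the z-statistics used on real data and is the default winner statistic;
plain mean betas are selectable.

## 3. Topography

`winner_takes_all()` labels each ROI vertex with the argmax condition if
the maximum reaches the threshold (default 0, i.e. minimally thresholded
t-like maps), ties broken by the fixed condition order.  Vertex areas are
one third of incident triangle areas, so areas sum exactly to the surface
area.  The CoG is the area-weighted mean over all of a condition's winner
vertices, pooled across clusters: "weighted by cluster size" is read as
larger clusters dominating through mass, not per-cluster averaging
(statistic-value weighting is available as an option).  Because a 3D CoG
need not lie on the mesh, it is snapped to the nearest winner vertex
(lowest index on ties) before the geodesic computation; the geodesic is
Dijkstra on the edge graph rather than an exact polyhedral geodesic, and
the flat-patch oracle quantifies that approximation.  Distances are signed
negative lateral to the hand border.  A per-subject multiplicative hook
(`distance_scale`) exists for brain-size normalisation on real data but
has no synthetic analog and is untested against real volumes.

One consequence worth understanding: the winner region of a condition is
bounded by where its activation overtakes its neighbours'.  When a single
blob is shifted while its neighbours stay put, the region's boundary
midpoints move by only half the blob shift, so the winner-map CoG
under-recovers an isolated truth shift at default blob widths.  The
parameter-recovery acceptance test therefore uses narrow blobs and a low
absolute threshold, a configuration in which the winner region tracks the
blob itself and the full 5 mm shift is recovered within one grid spacing.

The laterality index per condition is
`(deprived% − intact%) / (deprived% + intact%)` of hand-ROI coverage from
a WTA re-run restricted to the hand ROI; 0/0 is defined as 0 and flagged
degenerate.

## 4. Jaccard similarity

Per-condition Jaccard similarity between winner vertex sets, averaged over
every member of a reference group, excluding the target from its own group
(leave-self-out).  Empty-versus-empty is defined as 0 with a degeneracy
flag (the ratio is otherwise 0/0).  The per-condition table is the
primitive — group modelling of a "complete face map" is represented as the
long-format per-condition table consumed by the statistics stage, matching
a model with a facial-movement factor, rather than a single pooled
coefficient.

## 5. Crossnobis RSA

The noise covariance is estimated from run-wise GLM residual covariances,
averaged and shrunk toward their diagonal with an analytic optimal weight
(Schafer–Strimmer rule on the off-diagonal entries; the original
toolbox's regularisation settings are not documented, so only the
estimator's defining properties are asserted).  The weight is exposed as
`rsa_lambda` for users who want a fixed value; shrinkage keeps the matrix
positive definite even when vertices outnumber time points.

The crossnobis distance for conditions A, B is the mean over ordered run
pairs (m ≠ n) of `(b_A^m − b_B^m)' Σ̂⁻¹ (b_A^n − b_B^n) / P`, with P the
ROI vertex count.  Cross-validation across independent runs makes the
estimator unbiased — expectation zero for identical true patterns, with
negative estimates possible under noise — which the acceptance suite
verifies over 500 simulations.  Dividing by P makes distances invariant to
vertex duplication, so hand- and face-ROI RDMs of different sizes are
comparable (a choice the original method leaves open).  The thumb
condition, when generated, joins RDMs only for groups that have it; the
facial-information summary always averages the 6 unique face-face pairs.
Classical MDS (double-centred squared distances, eigendecomposition,
negative eigenvalues clipped to zero) is provided for visualisation.

## 6. Questionnaire scoring

Frequency is recoded as `6 − table_code` for table codes in (0, 5],
inferred from the two opposite coding legends (table: 5 = all the time;
formula: 1 = all the time) and verified against every consistent row of
the packaged table; fractional codes (e.g. 2.5) pass through the same
map.  The chronic score is intensity divided by the recoded frequency,
rounded half-away-from-zero to 1 decimal (matching printed precision;
demographics round to 2 decimals).  A frequency code of 0 or intensity 0
gives a score of 0, fixed by a row with positive intensity but frequency 0
printing a chronic score of 0.  One PLS cell of the packaged table prints
14.6 where the rule yields 50 / 3.5 = 14.3; the discrepancy is flagged by
`score_phantom_table()` and the rule is not bent to match.  Whether the
fractional code in that row was averaged before or after recoding is not
stated; the package applies the recode to the stored code as printed.
PLP status is chronic score > 0.

## 7. Statistics and reporting

The original inference used mixed ANOVAs and linear mixed models; on
synthetic data these are replaced by a permutation surrogate:
the group-by-hemisphere interaction statistic is the between-group
difference of mean within-subject (deprived − intact) differences, with
group labels permuted and the two-sided p-value
`(1 + #{|null| ≥ |obs|}) / (1 + n_perm)` (exact enumeration available for
tiny groups).  Type-I calibration (rejection rate 5% ± 2% under a null
world) and power at a 5 mm / d ≈ 1.5 effect are asserted in the
acceptance suite on subject-level summary values — running 500 full
imaging pipelines would add nothing to what those stages' own tests
establish and would not fit a desk-scale budget.  Outliers are flagged at
strictly more than 3 sample SDs from the mean and are reported, never
removed.

`run_pipeline()` chains all stages, writes TSV tables, GIFTI files
(ASCII-encoded; a minimal writer/reader pair, since no R GIFTI package is
available in the target environment), a run log, and a JSON config
snapshot; identical `(config, seed)` produce byte-identical TSVs.  The
CLI (`somatomap_main()`) exposes each stage as a subcommand.

## Known limitations

- The flat patch cannot express folding-dependent phenomena (geodesic
  versus Euclidean divergence, area distortion on inflated surfaces).
- Volumetric effects — registration error, distortion, motion — are out
  of scope; the generator's realism claims end at AR(1)-plus-smoothing
  noise on a mesh.
- Group-level inference is permutation-based only; no mixed models, Bayes
  factors or covariate adjustment are provided (an age/brain-size hook
  exists but has no synthetic test bed).
- GIFTI support covers exactly the three file kinds the pipeline emits.
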