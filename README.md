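# somatomap

Surface-based analysis of somatotopic organisation and deprivation-triggered
remapping in primary somatosensory cortex (S1), for researchers studying how
face representations reorganise after hand loss (amputation or congenital
absence of a hand).

After limb loss, do neighbouring body parts "invade" the deprived hand
territory?  Answering this on fMRI data requires a chain of surface-based
measurements, each of which this package implements as a tested, reusable
component:

- **Winner-takes-all (WTA) mapping** — within an S1 region of interest,
  each surface vertex is labelled with the facial movement (forehead, nose,
  lips, tongue) showing maximal activity there.
- **Cluster-weighted centre of gravity (CoG) and signed geodesic
  distance** — each face-winner map's CoG (area-weighted, pooled over
  clusters so larger clusters dominate by mass) is snapped to the surface
  and its geodesic distance to an anchor at the midpoint of the hand ROI's
  lateral border is computed; distances are signed negative when the CoG
  lies lateral to ("below") the hand border.
- **Laterality index** of surface-area coverage in the hand ROI:

      LI_m = (deprived_m − intact_m) / (deprived_m + intact_m)

  where `deprived_m`, `intact_m` are the percentages of hand-ROI surface
  area won by movement `m` in each hemisphere; +1 means coverage only in
  the deprived hemisphere.
- **Jaccard map similarity** `J(A,B) = |A ∩ B| / |A ∪ B|` between
  winner maps across individuals and groups, with leave-self-out averaging
  for intra-group comparisons.
- **Crossnobis RSA** — cross-validated Mahalanobis distances between
  condition activity patterns in trimmed hand/face ROIs, with multivariate
  noise normalisation (shrunk residual covariance) so noisier vertices are
  down-weighted.  Cross-validation makes the estimator unbiased: its
  expectation is zero when two patterns do not differ, and estimates can be
  negative.  RDMs can be embedded by classical MDS for visualisation.
- **Block-design GLM** — per-run OLS with double-gamma HRF-convolved
  boxcar regressors, fixed-effects averaging across runs, t-like winner
  statistics.
- **Questionnaire scoring** — chronic phantom-limb pain/sensation scores
  (worst-week intensity divided by a recoded frequency), PLP
  classification, and demographic summaries, with a packaged worked-example
  table.
- **Synthetic cohort generator** — a flat triangulated cortical patch
  standing in for the S1 strip, three groups × two hemispheres with
  ground-truth somatotopic blob maps, configurable remapping shifts,
  a block protocol (8 s blocks, 4 repeats per condition, 5 baseline blocks,
  3 runs, TR 1.45 s), and AR(1) + spatially smoothed noise.  Every analysis
  stage is testable end-to-end without any imaging data.

## Worked example

```r
library(somatomap)

# a small cohort: controls vs one-hander-like subjects with injected
# lips/tongue remapping toward the deprived hand border
spec <- cohort_spec(groups = c(controls = 3, one_handers = 3),
                    n_medial = 7, n_lateral = 16, spacing = 2,
                    hand_extent = 10, face_extent = 20, rsa_gap = 4,
                    noise_sd = 0.4, jitter_sd = 0.5, runs = 2, seed = 7)
res <- run_pipeline(pipeline_config(spec, n_perm = 500),
                    out_dir = "demo_out")

subset(res$distances, condition == "lips" & group == "one_handers")
#>    subject       group hemisphere condition distance_mm
#> 27     O01 one_handers   deprived      lips          -2
#> 31     O01 one_handers     intact      lips         -10
#> 35     O02 one_handers   deprived      lips           2
#> 39     O02 one_handers     intact      lips         -10
#> 43     O03 one_handers   deprived      lips           0
#> 47     O03 one_handers     intact      lips         -10
```

In the intact hemisphere the lips CoG sits 10 mm lateral to (below) the
hand-border anchor; in the deprived hemisphere it has moved up to the
border (distances around zero).  The injected truth shift is +5 mm toward
the hand, and the winner-map CoG moves even further because the
neighbouring forehead blob is simultaneously shifted away (the default
one-hander-like remapping pattern), vacating territory that the lips
winner region then occupies.  `res$laterality`, `res$jaccard`,
`res$rdm` and `res$permutation` hold the coverage indices, map-overlap
table, crossnobis RDMs and permutation interaction tests;
`demo_out/` additionally contains the GIFTI surface and winner label maps,
all TSV tables, the run log, and a JSON config snapshot that reproduces the
run byte-for-byte.

Scoring the packaged questionnaire table:

```r
tab <- score_phantom_table(read_table1())
table(tab$plp_class[tab$group == "amputees"])
#>    with_plp without_plp
#>          11           6
cohort_demographics(tab)[, c("group", "n", "mean_age", "se_age")]
#>         group  n mean_age se_age
#> 1    amputees 17    53.71   2.69
#> 2 one_handers 21    42.67   3.04
```

## Command line

```sh
Rscript -e 'somatomap::somatomap_main()' report --seed 1 --out out_dir
Rscript -e 'somatomap::somatomap_main()' scores --table my_table.tsv --out out_dir
```

Subcommands `simulate`, `glm`, `topography`, `jaccard`, `rsa`, `scores`,
`report` run the pipeline up to the named stage; see the methods vignette
(`vignettes/somatomap-methods.Rmd`) for the model, parameter and design
documentation.
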