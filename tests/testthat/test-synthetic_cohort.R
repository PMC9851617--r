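test_that("flat patch mesh has the expected counts, area and invariants", {
  m22 <- build_flat_patch_mesh(2, 2, 1)
  expect_equal(nrow(m22$vertices), 4)
  expect_equal(nrow(m22$triangles), 2)
  expect_equal(sum(somatomap:::triangle_areas(m22)), 1.0)

  m33 <- build_flat_patch_mesh(3, 3, 1)
  expect_equal(nrow(m33$vertices), 9)
  expect_equal(nrow(m33$triangles), 8)  # 2 (n_med-1)(n_lat-1) by enumeration

  # valid indices, connected edge graph, no zero-area triangles
  for (m in list(m22, m33, build_flat_patch_mesh(4, 7, 0.5))) {
    expect_true(all(m$triangles >= 1 & m$triangles <= nrow(m$vertices)))
    expect_true(all(somatomap:::triangle_areas(m) > 0))
    g <- somatomap:::mesh_graph(m)
    expect_true(igraph::is_connected(g))
  }
  expect_error(build_flat_patch_mesh(1, 3, 1), "must both be")
  expect_error(build_flat_patch_mesh(3, 3, 0), "positive")
})

test_that("ROI definition partitions the patch and anchors the hand border", {
  mesh <- build_flat_patch_mesh(5, 11, 2)   # x in 0..20
  rois <- define_rois(mesh, hand_extent = 8, face_extent = 12, rsa_gap = 0)
  # no trimming when the gap is zero
  expect_identical(rois$hand_trimmed, rois$hand)
  expect_identical(rois$face_trimmed, rois$face)
  # hand spans columns x = 0,2,4,6,8 -> 5 columns x 5 rows
  expect_length(rois$hand, 25)
  expect_length(intersect(rois$hand, rois$face), 0)
  expect_setequal(rois$s1_combined, union(rois$hand, rois$face))
  # anchor path is the border column, midpoint belongs to it
  expect_true(all(abs(mesh$axis[rois$anchor_path] - 8) < 1e-9))
  expect_true(rois$anchor_midpoint %in% rois$anchor_path)
  expect_true(all(rois$anchor_path %in% rois$hand))

  # trimming removes half the gap from each facing edge
  r2 <- define_rois(mesh, 8, 12, rsa_gap = 4)
  expect_true(all(mesh$axis[r2$hand_trimmed] <= 8 - 2 + 1e-9))
  expect_true(all(mesh$axis[r2$face_trimmed] >= 10 + 2 - 1e-9))
  expect_true(all(r2$hand_trimmed %in% r2$hand))
  expect_true(all(r2$face_trimmed %in% r2$face))
  gap <- min(mesh$axis[r2$face_trimmed]) - max(mesh$axis[r2$hand_trimmed])
  expect_gte(gap, 4)

  expect_error(define_rois(mesh, 15, 12, 0), "extent")
})

test_that("subject truths encode an upright somatotopy and exact shifts", {
  spec <- tiny_spec(jitter_sd = 0)
  geom <- somatomap:::cohort_geometry(spec)
  x <- geom$mesh$vertices[, 1]

  planar_cog <- function(pat) sum(x * pat) / sum(pat)

  tr <- generate_subject_truth(spec, "controls", 1, geometry = geom)
  cogs <- apply(tr$deprived, 1, planar_cog)
  # forehead < nose < lips < tongue along the medial->lateral axis
  expect_true(all(diff(cogs[c("forehead", "nose", "lips", "tongue")]) > 0))
  # controls have no shift: hemispheres identical with jitter off
  expect_equal(tr$deprived, tr$intact)

  # exact effect injection: deprived - intact CoG difference equals -delta
  # (narrow blobs so edge truncation of the Gaussian tails is negligible)
  spec2 <- tiny_spec(jitter_sd = 0,
                     truth_params = data.frame(
                       condition = c("forehead", "nose", "lips", "tongue"),
                       centre = c(13, 17, 21, 25), width = 2, amplitude = 1),
                     shift_params = list(one_handers = c(lips = 5)))
  tr2 <- generate_subject_truth(spec2, "one_handers", 1, geometry = geom)
  expect_equal(planar_cog(tr2$deprived["lips", ]) -
                 planar_cog(tr2$intact["lips", ]), -5, tolerance = 1e-3)
  expect_equal(planar_cog(tr2$deprived["nose", ]) -
                 planar_cog(tr2$intact["nose", ]), 0, tolerance = 1e-9)

  # determinism and non-negativity
  tra <- generate_subject_truth(spec, "amputees", 99, geometry = geom)
  trb <- generate_subject_truth(spec, "amputees", 99, geometry = geom)
  expect_identical(tra, trb)
  expect_true(all(tra$deprived >= 0))
  expect_error(generate_subject_truth(spec, "martians", 1, geometry = geom),
               "unknown group")
})

test_that("run generation: protocol, noiseless limit, determinism", {
  spec <- tiny_spec(noise_sd = 0, jitter_sd = 0)
  geom <- somatomap:::cohort_geometry(spec)
  tr <- generate_subject_truth(spec, "controls", 1, geometry = geom)
  run <- generate_run_timeseries(tr$deprived, spec, 1, seed = 5,
                                 geometry = geom)

  # 4 blocks per condition; baseline blocks fill the rest of the schedule
  cnt <- table(run$events$condition)
  expect_true(all(cnt == spec$repeats))
  n_blocks <- length(spec$conditions) * spec$repeats + spec$baseline_blocks
  expect_equal(nrow(run$events), n_blocks - spec$baseline_blocks)
  expect_equal(ncol(run$data), somatomap:::n_run_volumes(spec))

  # events tile without overlap
  ons <- sort(run$events$onset)
  expect_true(all(diff(ons) >= spec$block_s - 1e-9))

  # noiseless run equals the convolved signal exactly
  X <- somatomap:::convolved_regressors(run$events, spec$conditions,
                                        spec$tr, ncol(run$data))
  expect_equal(run$data,
               t(tr$deprived[spec$conditions, , drop = FALSE]) %*% t(X))

  # determinism: same seed -> identical run
  run2 <- generate_run_timeseries(tr$deprived, spec, 1, seed = 5,
                                  geometry = geom)
  expect_identical(run, run2)
  expect_error(generate_run_timeseries(tr$deprived, spec, 99, seed = 1,
                                       geometry = geom), "run_index")
})

test_that("with AR(1) = 0 pure-noise vertices are temporally white", {
  spec <- tiny_spec(noise_sd = 1, noise_ar1 = 0, noise_fwhm = 0,
                    jitter_sd = 0)
  geom <- somatomap:::cohort_geometry(spec)
  zero_truth <- matrix(0, length(spec$conditions), nrow(geom$mesh$vertices),
                       dimnames = list(spec$conditions, NULL))
  run <- generate_run_timeseries(zero_truth, spec, 1, seed = 11,
                                 geometry = geom)
  ac1 <- apply(run$data, 1, function(ts)
    stats::cor(ts[-1], ts[-length(ts)]))
  # mean lag-1 autocorrelation ~ 0 within sampling error (SE ~ 1/sqrt(T*V))
  expect_lt(abs(mean(ac1)), 3 / sqrt(length(ac1) * ncol(run$data)))

  # and with AR(1) = 0.5 it is clearly positive
  spec2 <- tiny_spec(noise_sd = 1, noise_ar1 = 0.5, noise_fwhm = 0,
                     jitter_sd = 0)
  run2 <- generate_run_timeseries(zero_truth, spec2, 1, seed = 11,
                                  geometry = geom)
  ac2 <- apply(run2$data, 1, function(ts) stats::cor(ts[-1], ts[-length(ts)]))
  expect_gt(mean(ac2), 0.35)
})

test_that("the optional thumb condition is generated but excluded from WTA", {
  spec <- tiny_spec(include_thumb = TRUE, jitter_sd = 0)
  expect_identical(spec$conditions,
                   c("forehead", "nose", "lips", "tongue", "thumb"))
  geom <- somatomap:::cohort_geometry(spec)
  tr <- generate_subject_truth(spec, "controls", 1, geometry = geom)
  # thumb blob sits inside the hand band
  x <- geom$mesh$vertices[, 1]
  thumb_cog <- sum(x * tr$deprived["thumb", ]) / sum(tr$deprived["thumb", ])
  expect_lt(thumb_cog, spec$hand_extent)
  # winner-takes-all competes the four face parts only by default
  w <- winner_takes_all(maps_from_matrix(tr$deprived), geom$rois$s1_combined)
  expect_identical(w$conditions, c("forehead", "nose", "lips", "tongue"))
})

test_that("cohort generation is complete and deterministic", {
  spec <- tiny_spec()
  co <- generate_cohort(spec)
  expect_equal(sum(co$subjects$group == "controls"), 2)
  expect_equal(sum(co$subjects$group == "amputees"), 1)
  expect_equal(sum(co$subjects$group == "one_handers"), 2)
  # 2 hemispheres x runs per subject
  expect_length(co$runs[[co$subjects$subject_id[1]]], 2)
  expect_length(co$runs[[co$subjects$subject_id[1]]]$deprived, spec$runs)
  # questionnaire covers the amputee-like group
  expect_equal(nrow(co$phantom), 1)
  expect_true(all(co$phantom$pls_intensity >= 0 &
                    co$phantom$pls_intensity <= 100))
  expect_true(all(co$phantom$plp_freq_code %in% 0:5))

  # byte-identical participant TSV across invocations
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_participant_tsv(co, f1)
  write_participant_tsv(generate_cohort(spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
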