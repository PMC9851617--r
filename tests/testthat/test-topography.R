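test_that("winner-takes-all labelling, threshold and tie rule", {
  mesh <- build_flat_patch_mesh(4, 6, 1)
  roi <- seq_len(nrow(mesh$vertices))
  n <- length(roi)
  conds <- c("forehead", "nose", "lips", "tongue")
  base <- matrix(0, 4, n, dimnames = list(conds, NULL))

  # one condition uniformly dominant
  m <- base; m["lips", ] <- 1
  w <- winner_takes_all(maps_from_matrix(m), roi, threshold = 0)
  expect_true(all(w$labels == match("lips", w$conditions)))

  # everything below threshold -> unassigned; partition is exact
  w2 <- winner_takes_all(maps_from_matrix(m), roi, threshold = 2)
  expect_true(all(w2$labels == 0L))
  expect_length(w2$labels, length(roi))

  # two equal maps: earlier condition in fixed order wins
  m3 <- base; m3["nose", ] <- 1; m3["tongue", ] <- 1
  w3 <- winner_takes_all(maps_from_matrix(m3), roi, threshold = 0)
  expect_true(all(w3$labels == match("nose", w3$conditions)))

  # missing condition map is an inconsistency error
  expect_error(winner_takes_all(maps_from_matrix(m)[1:3], roi), "missing")
})

test_that("connected clusters match a flood-fill oracle", {
  mesh <- build_flat_patch_mesh(5, 10, 1)
  n <- nrow(mesh$vertices)
  conds <- c("forehead", "nose", "lips", "tongue")

  # single contiguous band -> 1 cluster; split band -> 2 clusters
  m <- matrix(0, 4, n, dimnames = list(conds, NULL))
  x <- mesh$axis
  m["lips", x >= 2 & x <= 4] <- 1
  m["nose", x > 4 & x < 6] <- 2
  m["lips", x >= 6 & x <= 7] <- 1
  w <- winner_takes_all(maps_from_matrix(m), seq_len(n), threshold = 0.5)
  expect_length(connected_clusters(w, mesh, "nose"), 1)
  expect_length(connected_clusters(w, mesh, "lips"), 2)
  expect_length(connected_clusters(w, mesh, "tongue"), 0)

  # random 50-vertex maps vs exhaustive flood fill
  set.seed(7)
  for (rep in 1:10) {
    mm <- matrix(runif(4 * n), 4, n, dimnames = list(conds, NULL))
    ww <- winner_takes_all(maps_from_matrix(mm), seq_len(n), threshold = 0.5)
    for (cn in conds) {
      got <- connected_clusters(ww, mesh, cn)
      want <- oracle_flood_fill(mesh, somatomap:::winner_vertices(ww, cn))
      expect_equal(length(got), length(want))
      expect_setequal(lapply(got, sort), want)
    }
  }
})

test_that("vertex areas conserve total area and scale quadratically", {
  m22 <- build_flat_patch_mesh(2, 2, 1)
  expect_equal(sum(vertex_areas(m22)), 1.0)

  m33 <- build_flat_patch_mesh(3, 3, 1)
  va <- vertex_areas(m33)
  expect_equal(sum(va), 4.0)
  expect_equal(va[5], 1.0)   # interior vertex of a unit grid gets spacing^2

  big <- m33; big$vertices <- m33$vertices * 2
  expect_equal(vertex_areas(big), 4 * va)
})

test_that("area-weighted CoG pools clusters by mass and snaps to a winner", {
  mesh <- build_flat_patch_mesh(7, 9, 1)    # x in 0..8, interior rows 2..6
  n <- nrow(mesh$vertices)
  conds <- c("forehead", "nose", "lips", "tongue")
  idx <- function(r, c) (c - 1) * 7 + r     # row r, column c (1-based)

  # single-vertex cluster: CoG is the vertex itself
  m <- matrix(0, 4, n, dimnames = list(conds, NULL))
  m["forehead", ] <- 0.5
  m["lips", idx(4, 3)] <- 1
  w <- winner_takes_all(maps_from_matrix(m), seq_len(n), threshold = 0)
  cog <- weighted_cog(w, mesh, "lips")
  expect_equal(cog$snapped_vertex, idx(4, 3))
  expect_equal(unname(cog$position[1:2]), c(2, 3))

  # two symmetric single-vertex clusters: midpoint, snapped breaks ties low
  m2 <- matrix(0, 4, n, dimnames = list(conds, NULL))
  m2["forehead", ] <- 0.5
  m2["lips", c(idx(4, 3), idx(4, 7))] <- 1
  w2 <- winner_takes_all(maps_from_matrix(m2), seq_len(n), threshold = 0)
  cog2 <- weighted_cog(w2, mesh, "lips")
  expect_equal(unname(cog2$position[1]), 4)
  expect_equal(cog2$n_clusters, 2)
  expect_equal(cog2$snapped_vertex, idx(4, 3))  # lowest index on distance tie

  # clusters of area 3a and a, 4 mm apart -> CoG 1 mm from the big one
  m3 <- matrix(0, 4, n, dimnames = list(conds, NULL))
  m3["forehead", ] <- 0.5
  big <- c(idx(3, 3), idx(4, 3), idx(5, 3))   # 3 interior vertices at x = 2
  small <- idx(4, 7)                          # 1 interior vertex at x = 6
  m3["lips", c(big, small)] <- 1
  w3 <- winner_takes_all(maps_from_matrix(m3), seq_len(n), threshold = 0)
  cog3 <- weighted_cog(w3, mesh, "lips")
  expect_equal(unname(cog3$position[1]), 3)   # (3*2 + 1*6)/4
  expect_equal(cog3$total_weight, 4)

  # no winners -> explicit error
  expect_error(weighted_cog(w3, mesh, "tongue"), "no winner")
})

test_that("graph geodesics match brute-force Dijkstra and the planar bound", {
  mesh <- build_flat_patch_mesh(6, 6, 1)
  expect_equal(geodesic_distance(mesh, 8, 8), 0)
  expect_equal(geodesic_distance(mesh, 1, 2), 1)       # adjacent: edge length

  set.seed(3)
  pairs <- cbind(sample(36, 12, TRUE), sample(36, 12, TRUE))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    d <- geodesic_distance(mesh, a, b)
    expect_equal(d, oracle_shortest_path(mesh, a, b), tolerance = 1e-12)
    eu <- sqrt(sum((mesh$vertices[a, ] - mesh$vertices[b, ])^2))
    expect_gte(d, eu - 1e-12)
    expect_lte(d, eu * sqrt(2) + 1e-12)
  }
})

test_that("signed distance to the anchor follows the medial/lateral rule", {
  mesh <- build_flat_patch_mesh(5, 9, 1)    # x in 0..8
  rois <- define_rois(mesh, hand_extent = 4, face_extent = 4)
  anchor <- rois$anchor_midpoint
  fake_cog <- function(v) structure(
    list(condition = "lips", position = mesh$vertices[v, ],
         snapped_vertex = v, total_weight = 1, n_clusters = 1),
    class = "cog_result")

  expect_equal(signed_distance_to_anchor(fake_cog(anchor), rois, mesh)$value, 0)
  medial <- anchor - 5   # one column toward the midline
  lateral <- anchor + 5  # one column away
  expect_equal(signed_distance_to_anchor(fake_cog(medial), rois, mesh)$value, 1)
  expect_equal(signed_distance_to_anchor(fake_cog(lateral), rois, mesh)$value, -1)
})

test_that("laterality index: worked cases, bounds and antisymmetry", {
  mesh <- build_flat_patch_mesh(5, 9, 1)
  rois <- define_rois(mesh, hand_extent = 4, face_extent = 4)
  n <- nrow(mesh$vertices)
  conds <- c("forehead", "nose", "lips", "tongue")
  va <- vertex_areas(mesh)
  hand_area <- sum(va[rois$hand])

  # build hand-ROI winner maps with controlled coverage fractions
  cover <- function(frac_by_cond) {
    m <- matrix(-1, 4, n, dimnames = list(conds, NULL))
    hand <- rois$hand
    start <- 1
    for (cn in names(frac_by_cond)) {
      k <- round(frac_by_cond[[cn]] * length(hand))
      if (k > 0) m[cn, hand[start:(start + k - 1)]] <- 1
      start <- start + k
    }
    winner_takes_all(maps_from_matrix(m), hand, threshold = 0.5)
  }

  # 30% vs 10% -> 0.5 ; equal -> 0 ; 20% vs 0% -> +1
  # (vertex areas differ at ROI edges, so compare using realised pcts)
  wd <- cover(c(lips = 0.3)); wi <- cover(c(lips = 0.1))
  li <- coverage_and_laterality(wd, wi, rois, mesh = mesh)
  lips <- li[li$condition == "lips", ]
  expect_equal(lips$value,
               (lips$deprived_pct - lips$intact_pct) /
                 (lips$deprived_pct + lips$intact_pct))
  expect_gt(lips$value, 0)

  we <- cover(c(lips = 0.2))
  li0 <- coverage_and_laterality(we, we, rois, mesh = mesh)
  expect_equal(li0[li0$condition == "lips", "value"], 0)

  w20 <- cover(c(lips = 0.2)); w0 <- cover(c(nose = 0.2))
  li1 <- coverage_and_laterality(w20, w0, rois, mesh = mesh)
  expect_equal(li1[li1$condition == "lips", "value"], 1)
  # degenerate: no coverage on either side -> 0 with flag
  expect_equal(li1[li1$condition == "tongue", "value"], 0)
  expect_true(li1[li1$condition == "tongue", "degenerate"])

  # property: bounded and antisymmetric under hemisphere swap
  set.seed(9)
  for (rep in 1:10) {
    fa <- runif(1, 0, .4); fb <- runif(1, 0, .4)
    wa <- cover(c(lips = fa)); wb <- cover(c(lips = fb))
    ab <- coverage_and_laterality(wa, wb, rois, mesh = mesh)
    ba <- coverage_and_laterality(wb, wa, rois, mesh = mesh)
    expect_true(all(ab$value >= -1 & ab$value <= 1))
    expect_equal(ab$value, -ba$value)
  }
})
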