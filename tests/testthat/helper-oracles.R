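# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.  These deliberately share no code
# with the package internals.

# shortest path by naive Dijkstra over an explicit edge list
oracle_shortest_path <- function(mesh, a, b) {
  tri <- mesh$triangles
  ee <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  ee <- unique(cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2])))
  n <- nrow(mesh$vertices)
  wfun <- function(i, j) sqrt(sum((mesh$vertices[i, ] - mesh$vertices[j, ])^2))
  dist <- rep(Inf, n); dist[a] <- 0
  visited <- rep(FALSE, n)
  repeat {
    u <- which(!visited & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    if (u == b) break
    visited[u] <- TRUE
    nb <- c(ee[ee[, 1] == u, 2], ee[ee[, 2] == u, 1])
    for (v in nb) {
      alt <- dist[u] + wfun(u, v)
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  dist[b]
}

# connected components of a vertex set by explicit flood fill
oracle_flood_fill <- function(mesh, verts) {
  tri <- mesh$triangles
  ee <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  ee <- unique(cbind(pmin(ee[, 1], ee[, 2]), pmax(ee[, 1], ee[, 2])))
  keep <- ee[, 1] %in% verts & ee[, 2] %in% verts
  ee <- ee[keep, , drop = FALSE]
  unseen <- verts
  comps <- list()
  while (length(unseen)) {
    frontier <- unseen[1]
    comp <- frontier
    unseen <- unseen[-1]
    while (length(frontier)) {
      nb <- unique(c(ee[ee[, 1] %in% frontier, 2],
                     ee[ee[, 2] %in% frontier, 1]))
      nb <- intersect(nb, unseen)
      comp <- c(comp, nb)
      unseen <- setdiff(unseen, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# OLS by the normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# crossnobis by a literal double loop over ordered run pairs
oracle_crossnobis <- function(betas_list, Sigma_inv) {
  conds <- rownames(betas_list[[1]])
  K <- length(conds); M <- length(betas_list)
  P <- ncol(betas_list[[1]])
  d <- matrix(0, K, K, dimnames = list(conds, conds))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (a == b) next
    acc <- 0; np <- 0
    for (m in seq_len(M)) for (n in seq_len(M)) {
      if (m == n) next
      dm <- betas_list[[m]][a, ] - betas_list[[m]][b, ]
      dn <- betas_list[[n]][a, ] - betas_list[[n]][b, ]
      acc <- acc + as.numeric(t(dm) %*% Sigma_inv %*% dn)
      np <- np + 1
    }
    d[a, b] <- acc / (np * P)
  }
  d
}

# jaccard by literal set operations
oracle_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  sum(u %in% a & u %in% b) / length(u)
}

# activation maps straight from per-condition value vectors (bypasses GLM)
maps_from_matrix <- function(mat) {
  maps <- lapply(rownames(mat), function(cn)
    structure(list(values = mat[cn, ], condition = cn, kind = "beta_mean"),
              class = "activation_map"))
  names(maps) <- rownames(mat)
  maps
}

# winner_map whose winner sets are exactly `sets` (bypasses the WTA)
wmap_from_sets <- function(roi, sets, conds = c("forehead", "nose",
                                                "lips", "tongue")) {
  labels <- setNames(integer(length(roi)), roi)
  for (cn in names(sets)) labels[as.character(sets[[cn]])] <-
      match(cn, conds)
  structure(list(labels = labels, roi = roi, conditions = conds,
                 threshold_used = 0), class = "winner_map")
}

# small cohort spec used across tests (any default overridable via ...)
tiny_spec <- function(...) {
  args <- list(groups = c(controls = 2, amputees = 1, one_handers = 2),
               n_medial = 7, n_lateral = 16, spacing = 2,
               hand_extent = 10, face_extent = 20, rsa_gap = 4,
               noise_sd = 0.5, noise_ar1 = 0.2, noise_fwhm = 0,
               jitter_sd = 0.5, runs = 2, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

# fit all runs of one subject-hemisphere and return glm_results
fit_subject <- function(cohort, sid, hemi) {
  spec <- cohort$spec
  lapply(cohort$runs[[sid]][[hemi]], function(rn)
    fit_glm(rn, build_design_matrix(rn$events, rn$tr, ncol(rn$data),
                                    conditions = spec$conditions)))
}
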