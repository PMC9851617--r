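#' Winner-takes-all map over an ROI
#'
#' Labels every ROI vertex with the condition whose statistic is maximal
#' there, provided that maximum reaches the threshold; otherwise the vertex
#' is left unassigned.  Ties are broken by the fixed condition order
#' (forehead before nose before lips before tongue).  The default threshold
#' of 0 on t-like maps corresponds to a minimally thresholded winner map.
#'
#' @param maps named list of `activation_map`s, one per competing condition,
#'   all on the same mesh.
#' @param roi integer vertex-index set the map should cover.
#' @param threshold statistic cutoff; a vertex is labelled only if its
#'   maximal statistic is `>= threshold`.
#' @param conditions ordered labels of the competing conditions; defaults to
#'   the four face parts.
#' @return object of class `winner_map`: list with `labels` (named integer
#'   vector over `roi`: index into `conditions`, 0 = unassigned), `roi`,
#'   `conditions`, `threshold_used`.
#' @export
winner_takes_all <- function(maps, roi, threshold = 0,
                             conditions = FACE_CONDITIONS) {
  missing <- setdiff(conditions, names(maps))
  if (length(missing))
    stop("missing condition map(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  stat <- vapply(conditions, function(cn) maps[[cn]]$values[roi],
                 numeric(length(roi)))
  if (length(roi) == 1L) stat <- matrix(stat, nrow = 1)
  if (any(!is.finite(stat)))
    stop("non-finite statistic inside the ROI", call. = FALSE)
  win <- apply(stat, 1, which.max)          # first max = fixed-order ties
  mx <- stat[cbind(seq_along(roi), win)]
  labels <- ifelse(mx >= threshold, win, 0L)
  structure(
    list(labels = setNames(as.integer(labels), roi), roi = roi,
         conditions = conditions, threshold_used = threshold),
    class = "winner_map"
  )
}

# Winner vertex set of one condition.
winner_vertices <- function(wmap, condition) {
  ci <- match(condition, wmap$conditions)
  if (is.na(ci)) stop("condition not in winner map", call. = FALSE)
  wmap$roi[wmap$labels == ci]
}

#' Connected clusters of a condition's winner vertices
#'
#' Connected components under triangle-edge adjacency (vertices sharing a
#' triangle edge; vertex-only contact does not connect), sorted by
#' descending total vertex area.
#'
#' @param wmap a `winner_map`.
#' @param mesh the `surface_mesh` the map lives on.
#' @param condition condition label.
#' @return list of integer vertex-index vectors (possibly empty list).
#' @export
connected_clusters <- function(wmap, mesh, condition) {
  verts <- sort(winner_vertices(wmap, condition))
  if (length(verts) == 0L) return(list())
  g <- igraph::induced_subgraph(mesh_graph(mesh), verts)
  comp <- igraph::components(g)
  # induced_subgraph keeps vertices in the order of `verts`
  clusters <- split(verts, comp$membership)
  va <- vertex_areas(mesh)
  areas <- vapply(clusters, function(cl) sum(va[cl]), numeric(1))
  clusters <- clusters[order(-areas)]
  names(clusters) <- NULL
  lapply(clusters, as.integer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area-weighted centre of gravity of a condition's winner map
#'
#' The CoG is weighted by cluster size through pooling: the positions of all
#' winner vertices are averaged with their vertex areas as weights, so a
#' larger cluster dominates the result by mass.  Optionally the statistic
#' values can multiply the weights.  Because the 3D CoG need not lie on the
#' mesh, it is snapped to the nearest winner vertex (Euclidean; lowest index
#' on ties) before any geodesic computation.
#'
#' @param wmap a `winner_map`.
#' @param mesh the `surface_mesh`.
#' @param condition condition label.
#' @param stat_values optional per-vertex statistic (full mesh length) to
#'   include in the weights.
#' @return object of class `cog_result`: list with `condition`, `position`
#'   (3D point, mm), `snapped_vertex`, `total_weight` (mm^2), `n_clusters`.
#' @export
weighted_cog <- function(wmap, mesh, condition, stat_values = NULL) {
  verts <- winner_vertices(wmap, condition)
  if (length(verts) == 0L)
    stop("condition '", condition, "' has no winner vertices", call. = FALSE)
  va <- vertex_areas(mesh)
  w <- va[verts]
  if (!is.null(stat_values)) w <- w * pmax(stat_values[verts], 0)
  if (sum(w) <= 0)
    stop("total CoG weight is zero", call. = FALSE)
  pos <- colSums(mesh$vertices[verts, , drop = FALSE] * w) / sum(w)
  d2 <- rowSums((mesh$vertices[verts, , drop = FALSE] -
                 matrix(pos, length(verts), 3, byrow = TRUE))^2)
  snapped <- verts[which.min(d2)]          # which.min = lowest index on ties
  structure(
    list(condition = condition, position = pos, snapped_vertex = snapped,
         total_weight = sum(va[verts]),
         n_clusters = length(connected_clusters(wmap, mesh, condition))),
    class = "cog_result"
  )
}

#' Signed geodesic distance from a CoG to the hand-border anchor
#'
#' Geodesic distance between the CoG's snapped vertex and the anchor
#' midpoint, negated when the CoG lies lateral to the hand border (below it
#' on the homunculus axis).  Positive distances therefore mean the CoG sits
#' medial to the anchor, inside/above the hand territory.
#'
#' @param cog a `cog_result`.
#' @param rois a `roi_set` (provides `anchor_midpoint` and the border
#'   coordinate).
#' @param mesh the `surface_mesh`.
#' @return object of class `signed_distance`: list with `condition`, `value`
#'   (mm, signed), `anchor_vertex`.
#' @export
signed_distance_to_anchor <- function(cog, rois, mesh) {
  anchor <- rois$anchor_midpoint
  d <- geodesic_distance(mesh, cog$snapped_vertex, anchor)
  lateral <- mesh$axis[cog$snapped_vertex] > mesh$axis[anchor] + 1e-9
  structure(
    list(condition = cog$condition, value = if (lateral) -d else d,
         anchor_vertex = anchor),
    class = "signed_distance"
  )
}

#' Surface coverage and laterality index per condition
#'
#' For each condition, the percentage of hand-ROI surface area won by that
#' condition is computed in both hemispheres (the winner-takes-all map must
#' have been re-run restricted to the hand ROI), and the laterality index
#'
#'   LI = (deprived% - intact%) / (deprived% + intact%)
#'
#' is formed.  +1 means coverage exclusively in the deprived hemisphere, 0
#' an equal balance; when both coverages are zero the index is defined as 0
#' and flagged degenerate.
#'
#' @param wmap_deprived,wmap_intact `winner_map`s restricted to each
#'   hemisphere's hand ROI.
#' @param rois_deprived,rois_intact `roi_set`s per hemisphere (the intact
#'   set defaults to the deprived one, as synthetic hemispheres share a
#'   mesh).
#' @param mesh the `surface_mesh` (shared).
#' @return data frame with columns `condition`, `deprived_pct`,
#'   `intact_pct`, `value`, `degenerate`.
#' @export
coverage_and_laterality <- function(wmap_deprived, wmap_intact,
                                    rois_deprived, rois_intact = rois_deprived,
                                    mesh) {
  va <- vertex_areas(mesh)
  pct <- function(wmap, rois, cond) {
    hand <- rois$hand
    if (length(hand) == 0L) stop("empty hand ROI", call. = FALSE)
    wv <- intersect(winner_vertices(wmap, cond), hand)
    100 * sum(va[wv]) / sum(va[hand])
  }
  conds <- wmap_deprived$conditions
  if (!identical(conds, wmap_intact$conditions))
    stop("winner maps have different condition sets", call. = FALSE)
  out <- lapply(conds, function(cn) {
    dp <- pct(wmap_deprived, rois_deprived, cn)
    ip <- pct(wmap_intact, rois_intact, cn)
    degen <- (dp + ip) == 0
    data.frame(condition = cn, deprived_pct = dp, intact_pct = ip,
               value = if (degen) 0 else (dp - ip) / (dp + ip),
               degenerate = degen, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
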