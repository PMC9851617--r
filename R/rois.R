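#' Define hand/face regions of interest on a flat patch
#'
#' Splits the patch into a medial hand band and a lateral face band along the
#' medial-to-lateral axis, mirroring an S1 strip in which the hand territory
#' sits medially above the face representation.  The anchor path is the hand
#' band's lateral border column (the synthetic analog of a manually drawn
#' landmark ~1 cm lateral to the hand knob), and its midpoint vertex is the
#' reference point for all signed geodesic distances.  For representational
#' similarity analyses both ROIs are trimmed back from their facing edges by
#' `rsa_gap / 2` each, leaving a gap of at least `rsa_gap` between them.
#'
#' @param mesh a `surface_mesh` from [build_flat_patch_mesh()].
#' @param hand_extent lateral extent of the hand band, mm (vertices with
#'   axis coordinate `<= hand_extent` are hand).
#' @param face_extent lateral extent of the face band, mm (axis coordinate in
#'   `(hand_extent, hand_extent + face_extent]`).
#' @param rsa_gap total gap width between the trimmed ROIs, mm (>= 0).
#' @return An object of class `roi_set`: list with integer vertex-index sets
#'   `hand`, `face`, `s1_combined`, `hand_trimmed`, `face_trimmed`, the
#'   ordered `anchor_path` along the hand band's lateral border, and
#'   `anchor_midpoint` (single vertex index).
#' @export
define_rois <- function(mesh, hand_extent, face_extent, rsa_gap = 0) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (rsa_gap < 0) stop("rsa_gap must be >= 0", call. = FALSE)
  x <- mesh$axis
  tol <- 1e-9
  if (hand_extent <= 0 || face_extent <= 0 ||
      hand_extent + face_extent > max(x) + tol)
    stop("hand/face extents exceed the mesh's lateral extent", call. = FALSE)

  hand <- which(x <= hand_extent + tol)
  face <- which(x > hand_extent + tol & x <= hand_extent + face_extent + tol)
  if (length(hand) == 0L || length(face) == 0L)
    stop("empty ROI: extents do not cover any vertex column", call. = FALSE)

  hand_border_x <- max(x[hand])
  face_inner_x <- min(x[face])
  anchor_path <- hand[abs(x[hand] - hand_border_x) < tol]
  anchor_path <- anchor_path[order(mesh$vertices[anchor_path, 2],
                                   anchor_path)]
  anchor_midpoint <- anchor_path[ceiling(length(anchor_path) / 2)]

  hand_trimmed <- hand[x[hand] <= hand_border_x - rsa_gap / 2 + tol]
  face_trimmed <- face[x[face] >= face_inner_x + rsa_gap / 2 - tol]

  structure(
    list(hand = hand, face = face, s1_combined = sort(c(hand, face)),
         hand_trimmed = hand_trimmed, face_trimmed = face_trimmed,
         anchor_path = anchor_path, anchor_midpoint = anchor_midpoint,
         hand_border_x = hand_border_x),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf(
    "roi_set: hand %d, face %d vertices (trimmed %d / %d); anchor path %d vertices, midpoint %d\n",
    length(x$hand), length(x$face), length(x$hand_trimmed),
    length(x$face_trimmed), length(x$anchor_path), x$anchor_midpoint))
  invisible(x)
}
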