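#' Build a flat rectangular cortical patch mesh
#'
#' Constructs a regularly triangulated planar grid standing in for a strip of
#' primary somatosensory cortex.  The x coordinate of each vertex is its
#' medial-to-lateral position in mm (medial wall at x = 0); the y coordinate
#' spans the orthogonal (roughly anterior-posterior) direction.  Each interior
#' quad is split into two triangles along the (+x, +y) diagonal, so the edge
#' graph is the grid plus one diagonal per cell.
#'
#' On a flat patch the exact geodesic between two points is the planar
#' Euclidean segment, which gives an analytic oracle for graph-based geodesic
#' distances: for this triangulation the graph distance is bounded between the
#' Euclidean distance and sqrt(2) times it.
#'
#' @param n_medial number of vertex rows (>= 2), i.e. vertices per
#'   medial-lateral column.
#' @param n_lateral number of vertex columns (>= 2) along the medial-lateral
#'   axis.
#' @param spacing grid spacing in mm (> 0).
#' @return An object of class `surface_mesh`: a list with `vertices`
#'   (n x 3 numeric matrix, mm), `triangles` (m x 3 integer matrix, 1-based
#'   vertex indices), `axis` (numeric vector, per-vertex medial-lateral
#'   coordinate in mm) and `spacing`.
#' @examples
#' m <- build_flat_patch_mesh(3, 3, 1)
#' nrow(m$vertices)   # 9
#' nrow(m$triangles)  # 8
#' @export
build_flat_patch_mesh <- function(n_medial, n_lateral, spacing) {
  if (!is.numeric(n_medial) || !is.numeric(n_lateral) ||
      n_medial < 2 || n_lateral < 2)
    stop("n_medial and n_lateral must both be >= 2", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar", call. = FALSE)
  n_medial <- as.integer(n_medial)
  n_lateral <- as.integer(n_lateral)

  # vertex (row r, column c) -> index (c - 1) * n_medial + r
  cols <- rep(seq_len(n_lateral), each = n_medial)
  rows <- rep(seq_len(n_medial), times = n_lateral)
  vertices <- cbind(
    x = (cols - 1) * spacing,
    y = (rows - 1) * spacing,
    z = 0
  )

  idx <- function(r, c) (c - 1L) * n_medial + r
  tris <- vector("list", (n_medial - 1L) * (n_lateral - 1L))
  k <- 0L
  for (c in seq_len(n_lateral - 1L)) {
    for (r in seq_len(n_medial - 1L)) {
      v00 <- idx(r, c); v10 <- idx(r + 1L, c)
      v01 <- idx(r, c + 1L); v11 <- idx(r + 1L, c + 1L)
      k <- k + 1L
      # split along the v00-v11 diagonal
      tris[[k]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
    }
  }
  triangles <- do.call(rbind, tris)
  storage.mode(triangles) <- "integer"

  structure(
    list(vertices = vertices, triangles = triangles,
         axis = vertices[, "x"], spacing = spacing,
         n_medial = n_medial, n_lateral = n_lateral),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, extent %.1f x %.1f mm\n",
              nrow(x$vertices), nrow(x$triangles),
              diff(range(x$vertices[, 1])), diff(range(x$vertices[, 2]))))
  invisible(x)
}

# Unique undirected edges of a mesh, as a 2-column matrix of vertex indices.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# igraph of the mesh edge graph with Euclidean edge lengths as weights.
mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_graph(t(e), n = nrow(mesh$vertices), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Areas of all triangles (cross-product formula; works for any 3D embedding).
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  tri <- mesh$triangles
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex surface areas
#'
#' Assigns each vertex one third of the summed areas of its incident
#' triangles, so that the vertex areas sum exactly to the total mesh surface
#' area.  Used as the area weight for centre-of-gravity and surface-coverage
#' computations.
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ta <- triangle_areas(mesh)
  if (any(ta <= 0)) stop("mesh contains zero-area triangles", call. = FALSE)
  va <- numeric(nrow(mesh$vertices))
  tri <- mesh$triangles
  for (j in 1:3) {
    inc <- tapply(rep(ta / 3, 1), tri[, j], sum)
    ii <- as.integer(names(inc))
    va[ii] <- va[ii] + as.numeric(inc)
  }
  va
}

#' Geodesic distance between two mesh vertices
#'
#' Graph-geodesic approximation: length of the shortest path over the mesh
#' edge graph with Euclidean edge weights (Dijkstra).  On the flat synthetic
#' patch this over-estimates the exact planar geodesic by at most a factor
#' sqrt(2) for the grid triangulation used by [build_flat_patch_mesh()].
#'
#' @param mesh a `surface_mesh`.
#' @param a,b vertex indices (1-based).
#' @return distance in mm; 0 iff `a == b`.
#' @export
geodesic_distance <- function(mesh, a, b) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("vertex index out of range", call. = FALSE)
  if (a == b) return(0)
  d <- igraph::distances(mesh_graph(mesh), v = a, to = b)[1, 1]
  if (!is.finite(d))
    stop("vertices are not connected on the mesh", call. = FALSE)
  d
}

# Geodesic distances from one source vertex to many targets (single Dijkstra).
geodesic_distances_from <- function(mesh, from, to = NULL, graph = NULL) {
  if (is.null(graph)) graph <- mesh_graph(mesh)
  if (is.null(to)) to <- seq_len(nrow(mesh$vertices))
  d <- igraph::distances(graph, v = from, to = to)[1, ]
  if (any(!is.finite(d)))
    stop("some vertices are not connected on the mesh", call. = FALSE)
  unname(d)
}

# Adjacency list (neighbour indices per vertex) under triangle-edge adjacency.
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  adj
}

#' Smooth a per-vertex map on the mesh
#'
#' Iterated neighbour averaging (each pass replaces a vertex value with the
#' mean of itself and its edge neighbours), with the number of passes
#' calibrated so that the accumulated kernel variance approximates a Gaussian
#' of the requested full width at half maximum.  This is a cheap surrogate
#' for exact Gaussian smoothing on meshes; `fwhm = 0` returns the input
#' unchanged.
#'
#' @param values numeric vector, one value per vertex.
#' @param mesh a `surface_mesh`.
#' @param fwhm target full width at half maximum, mm.
#' @return smoothed numeric vector.
#' @export
smooth_on_mesh <- function(values, mesh, fwhm) {
  stopifnot(length(values) == nrow(mesh$vertices), fwhm >= 0)
  if (fwhm == 0) return(values)
  # one averaging pass over {self + 6 grid neighbours} adds ~ 4 h^2 / 7 of
  # kernel variance along each planar axis; iterate to the target variance
  drop(smooth_matrix_on_mesh(matrix(values, ncol = 1), mesh, fwhm))
}
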