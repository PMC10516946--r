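#' Triangle surface mesh
#'
#' The basic container used throughout the package: a vertex matrix, a face
#' matrix and an optional set of named per-vertex scalar arrays (used to carry
#' surface heatmaps). Faces are stored 1-based internally; format boundaries
#' (OBJ is 1-based, VTK/VTP/PLY are 0-based) convert on read/write.
#'
#' @param vertices numeric matrix, one row per vertex, 3 columns (x, y, z).
#' @param faces integer matrix, one row per triangle, 3 columns of 1-based
#'   vertex indices.
#' @param vertex_scalars named list of numeric vectors, each of length
#'   `nrow(vertices)`.
#' @return An object of class `triangle_mesh`.
#' @export
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1L, 2L, 3L), 1))
#' n_vertices(m)
triangle_mesh <- function(vertices, faces, vertex_scalars = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (length(vertices) == 0L) stop("empty mesh: no vertices")
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  if (length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  }
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)")
  mesh <- structure(list(vertices = vertices, faces = faces,
                         vertex_scalars = as.list(vertex_scalars)),
                    class = "triangle_mesh")
  validate_mesh(mesh)
  mesh
}

#' Validate the invariants of a triangle mesh
#'
#' Checks that every face index is a valid vertex index and that every named
#' scalar array has one value per vertex. Called by all constructors; exported
#' so callers can re-check meshes built by hand.
#'
#' @param mesh a `triangle_mesh`.
#' @return `mesh`, invisibly; errors if an invariant is violated.
#' @export
validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv < 1L) stop("empty mesh: no vertices")
  if (nrow(mesh$faces) > 0L) {
    rng <- range(mesh$faces)
    if (rng[1] < 1L || rng[2] > nv)
      stop(sprintf("face index out of range [1, %d]: found %d", nv,
                   if (rng[1] < 1L) rng[1] else rng[2]))
  }
  sc <- mesh$vertex_scalars
  if (length(sc)) {
    if (is.null(names(sc)) || any(!nzchar(names(sc))))
      stop("vertex_scalars must be a named list")
    bad <- names(sc)[vapply(sc, length, 1L) != nv]
    if (length(bad))
      stop("scalar array length != n_vertices: ", paste(bad, collapse = ", "))
  }
  invisible(mesh)
}

#' @rdname triangle_mesh
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname triangle_mesh
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              n_vertices(x), n_faces(x)))
  if (length(x$vertex_scalars))
    cat("  scalar arrays:", paste(names(x$vertex_scalars), collapse = ", "),
        "\n")
  invisible(x)
}

#' Normalize mesh pose for rendering
#'
#' Centers the vertex centroid at the origin and scales the mesh so the
#' farthest vertex sits at distance 1. No rotation is applied: the multi-view
#' camera sampling makes the classifier tolerant to orientation, so only a
#' common position/scale frame is needed to guarantee that fixed-radius
#' cameras see every specimen.
#'
#' The map is idempotent and commutes with rigid translations of the input.
#'
#' @param mesh a `triangle_mesh` with at least one vertex.
#' @return The normalized `triangle_mesh`; faces and scalar arrays untouched.
#' @export
normalize_pose <- function(mesh) {
  validate_mesh(mesh)
  ctr <- colMeans(mesh$vertices)
  v <- sweep(mesh$vertices, 2L, ctr)
  r <- sqrt(max(rowSums(v * v)))
  if (r <= .Machine$double.eps)
    stop("degenerate mesh: all vertices coincide (zero scale)")
  mesh$vertices <- v / r
  mesh
}

# Bounding radius after centering; used by preconditions in render/views.
mesh_radius <- function(mesh) {
  v <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  sqrt(max(rowSums(v * v)))
}
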