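#' Render a mesh from one camera into a multi-channel snapshot
#'
#' Z-buffer rasterization of the mesh as seen from `camera`, producing the
#' image the per-view CNN consumes plus the exact inverse mapping that the
#' surface Grad-CAM needs:
#'
#' * `channels`: a `resolution x resolution x 4` array — camera-space face
#'   normal x, y, z mapped to \[0, 1\] and depth normalized to \[0, 1\] over
#'   the camera frustum (background pixels have depth 1 and normals 0.5).
#' * `face_id`: integer matrix of 1-based face indices, 0 for background.
#'
#' Shading is two-sided (normals are flipped toward the camera): cleft
#' meshes are open surfaces and must not be back-face culled. Rasterization
#' is deterministic; pixel centers sit at half-integer coordinates with the
#' image origin at the top-left.
#'
#' @param mesh a pose-normalized [triangle_mesh] (see [normalize_pose()]).
#' @param camera a camera from [icosphere_cameras()].
#' @param resolution image side in pixels (>= 16). Default 128.
#' @param near,far frustum depth range used to normalize the depth channel;
#'   defaults bracket the unit mesh at the camera's distance. Geometry is
#'   clipped only at a small fixed distance in front of the camera, not at
#'   `near`: depth values closer than `near` clamp to 0.
#' @return an object of class `rendered_view`: list(`channels`, `face_id`,
#'   `camera`, `resolution`).
#' @export
render_view <- function(mesh, camera, resolution = 128L,
                        near = NULL, far = NULL) {
  validate_mesh(mesh)
  if (n_faces(mesh) == 0L) stop("empty mesh: no faces to render")
  resolution <- as.integer(resolution)
  if (resolution < 16L) stop("resolution must be >= 16")
  dist <- sqrt(sum(camera$position^2))
  if (is.null(near)) near <- max(0.05, dist - 1.2)
  if (is.null(far)) far <- dist + 1.2
  M <- camera_view_matrix(camera)
  vcam <- t(M %*% rbind(t(mesh$vertices), 1))
  tanh2 <- tan(camera$fov * pi / 360)
  raw <- .rasterize_cpp(vcam, mesh$faces, resolution, tanh2, near, far,
                        0.05)
  channels <- array(0, c(resolution, resolution, 4L))
  channels[, , 1L] <- raw$nx
  channels[, , 2L] <- raw$ny
  channels[, , 3L] <- raw$nz
  channels[, , 4L] <- raw$depth
  if (all(raw$face_id == 0L))
    warning("mesh projects to no pixel (outside frustum?): all-background view")
  structure(list(channels = channels, face_id = raw$face_id,
                 camera = camera, resolution = resolution),
            class = "rendered_view")
}

#' Render a mesh from every camera of a view set
#'
#' @param mesh a pose-normalized [triangle_mesh].
#' @param viewset a `view_set` from [icosphere_cameras()].
#' @param resolution image side in pixels.
#' @return list of `rendered_view`, in camera order.
#' @export
render_all <- function(mesh, viewset, resolution = 128L) {
  lapply(viewset$cameras, function(cam)
    render_view(mesh, cam, resolution = resolution))
}

#' @export
print.rendered_view <- function(x, ...) {
  fg <- sum(x$face_id > 0L)
  cat(sprintf("rendered_view: %dx%d, camera %d, %d foreground pixels\n",
              x$resolution, x$resolution, x$camera$id, fg))
  invisible(x)
}

# Stack the channel arrays of a list of rendered views into one
# (res, res, C, V) array — the per-mesh input tensor of the model.
views_to_tensor <- function(views) {
  res <- views[[1L]]$resolution
  out <- array(0, c(res, res, 4L, length(views)))
  for (v in seq_along(views)) out[, , , v] <- views[[v]]$channels
  out
}

#' Render every mesh of a dataset manifest
#'
#' Renders each mesh once (pose-normalized) from every camera of `viewset`
#' and returns the stacked image tensors. Training iterates over epochs, so
#' rendering up front avoids re-rasterizing every epoch. Set
#' `keep_face_ids = TRUE` when the views will also feed [pool_to_surface()].
#'
#' @param manifest a dataset manifest (see [generate_dataset()] /
#'   [read_manifest()]), or a data.frame with columns `mesh_path`, `label`.
#' @param viewset a `view_set`.
#' @param resolution image side in pixels.
#' @param base_dir directory that relative `mesh_path` entries are resolved
#'   against (defaults to the manifest's own directory attribute, if any).
#' @param keep_face_ids keep the per-view face-id buffers (memory heavy).
#' @return list with `x` (list of `(res, res, 4, V)` arrays), `labels`
#'   (integer vector, grades 0-3), `paths`, and optionally `views` (the full
#'   `rendered_view` lists).
#' @export
render_dataset <- function(manifest, viewset, resolution = 64L,
                           base_dir = NULL, keep_face_ids = FALSE) {
  recs <- if (is.data.frame(manifest)) manifest else manifest$records
  if (is.null(base_dir))
    base_dir <- attr(manifest, "base_dir") %||% "."
  x <- vector("list", nrow(recs))
  views_out <- if (keep_face_ids) vector("list", nrow(recs)) else NULL
  for (i in seq_len(nrow(recs))) {
    p <- recs$mesh_path[i]
    if (!file.exists(p)) p <- file.path(base_dir, recs$mesh_path[i])
    mesh <- normalize_pose(read_mesh(p))
    vs <- render_all(mesh, viewset, resolution)
    x[[i]] <- views_to_tensor(vs)
    if (keep_face_ids) views_out[[i]] <- vs
  }
  out <- list(x = x, labels = as.integer(recs$label), paths = recs$mesh_path)
  if (keep_face_ids) out$views <- views_out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
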