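#' Icosphere unit mesh
#'
#' Builds the unit icosahedron and optionally subdivides it (each triangle
#' split in four, new vertices pushed to the unit sphere). Used both as the
#' camera-placement lattice for the fly-by views and as a convenient convex
#' test shape.
#'
#' @param level non-negative integer subdivision level; the result has
#'   `10 * 4^level + 2` vertices and `20 * 4^level` faces.
#' @return a [triangle_mesh] on the unit sphere.
#' @export
icosphere_mesh <- function(level = 0L) {
  if (level < 0L) stop("level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      if (!is.null(mids[[key]])) return(mids[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mids[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    for (t in seq_len(nf)) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4L * t - 3L, ] <- c(a, ab, ca)
      newf[4L * t - 2L, ] <- c(b, bc, ab)
      newf[4L * t - 1L, ] <- c(cc, ca, bc)
      newf[4L * t, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  triangle_mesh(v, f)
}

#' Sample fly-by cameras on an icosphere around the origin
#'
#' Places one camera at every vertex of a subdivided icosahedron scaled to
#' `radius`, each looking at the origin. The up vector is global +z projected
#' perpendicular to the view direction; at the two near-polar positions
#' (view direction within ~1e-6 of the z axis) the fallback up vector +x is
#' used. Camera ordering follows the deterministic icosphere vertex
#' construction order.
#'
#' @param subdivision_level icosphere subdivision level; level 0 gives 12
#'   cameras, level 1 gives 42 (`10 * 4^level + 2` in general).
#' @param radius camera distance from the origin, in model units; must exceed
#'   1 so cameras sit outside a pose-normalized mesh.
#' @param fov vertical field of view in degrees (perspective projection).
#'   The default 43 makes the unit sphere fill roughly 90% of the frame at
#'   radius 3.
#' @return an object of class `view_set`: list with `cameras` (each a list
#'   `position`, `look_at`, `up`, `fov`, `id`), `radius`, `subdivision_level`,
#'   `fov`.
#' @export
#' @examples
#' vs <- icosphere_cameras(0, radius = 3)
#' length(vs$cameras)  # 12
icosphere_cameras <- function(subdivision_level = 0L, radius = 3,
                              fov = 43) {
  if (radius <= 1) stop("radius must be > 1 (camera inside the unit bound)")
  ico <- icosphere_mesh(subdivision_level)
  pos <- ico$vertices * radius
  cameras <- lapply(seq_len(nrow(pos)), function(i) {
    p <- pos[i, ]
    dir <- -p / sqrt(sum(p^2))                 # toward origin
    z <- c(0, 0, 1)
    upp <- z - sum(z * dir) * dir
    if (sqrt(sum(upp^2)) < 1e-6) {             # polar fallback
      x <- c(1, 0, 0)
      upp <- x - sum(x * dir) * dir
    }
    list(position = p, look_at = c(0, 0, 0),
         up = upp / sqrt(sum(upp^2)), fov = fov, id = i)
  })
  structure(list(cameras = cameras, radius = radius,
                 subdivision_level = as.integer(subdivision_level),
                 fov = fov),
            class = "view_set")
}

#' @export
print.view_set <- function(x, ...) {
  cat(sprintf("view_set: %d cameras, radius %.3g, fov %.3g deg (level %d)\n",
              length(x$cameras), x$radius, x$fov, x$subdivision_level))
  invisible(x)
}

#' Serialize / restore a view set as JSON
#'
#' @param viewset a `view_set`.
#' @param path output (input) file path.
#' @return `path` invisibly (`viewset_from_json` returns the `view_set`).
#' @export
viewset_to_json <- function(viewset, path) {
  jsonlite::write_json(unclass(viewset), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname viewset_to_json
#' @export
viewset_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cams <- if (is.data.frame(x$cameras)) {
    lapply(seq_len(nrow(x$cameras)), function(i) {
      list(position = unlist(x$cameras$position[[i]]),
           look_at = unlist(x$cameras$look_at[[i]]),
           up = unlist(x$cameras$up[[i]]),
           fov = x$cameras$fov[[i]], id = x$cameras$id[[i]])
    })
  } else {
    lapply(x$cameras, function(cm) {
      list(position = unlist(cm$position), look_at = unlist(cm$look_at),
           up = unlist(cm$up), fov = cm$fov, id = cm$id)
    })
  }
  structure(list(cameras = cams, radius = x$radius,
                 subdivision_level = as.integer(x$subdivision_level),
                 fov = x$fov),
            class = "view_set")
}

# 4x4 world->camera (view) matrix for a camera list: camera at origin
# looking down -z, x right, y up.
camera_view_matrix <- function(camera) {
  eye <- camera$position
  fwd <- camera$look_at - eye
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- c(fwd[2] * camera$up[3] - fwd[3] * camera$up[2],
             fwd[3] * camera$up[1] - fwd[1] * camera$up[3],
             fwd[1] * camera$up[2] - fwd[2] * camera$up[1])
  right <- right / sqrt(sum(right^2))
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  R <- rbind(right, up, -fwd)
  cbind(R, -R %*% eye)
}
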