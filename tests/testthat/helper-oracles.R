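# Independent oracles and small fixture builders used across the suite.

# Number of connected components of a mesh's vertex graph (igraph route,
# independent of the generator's own bookkeeping).
mesh_components <- function(mesh) {
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::components(g)$no
}

# Brute-force ray-cast face-id oracle (Moller-Trumbore per pixel center),
# replicating the renderer's camera model. Returns a list with `face_id`
# (0 = background) and `near_edge` (pixels whose ray passes within `tol`
# of a triangle edge, where z-buffer and ray-cast may legitimately differ).
raycast_face_id <- function(mesh, camera, resolution, tol = 0.03) {
  M <- surfgradcam:::camera_view_matrix(camera)
  vcam <- t(M %*% rbind(t(mesh$vertices), 1))
  th <- tan(camera$fov * pi / 360)
  fid <- matrix(0L, resolution, resolution)
  near_edge <- matrix(FALSE, resolution, resolution)
  f <- mesh$faces
  v0 <- vcam[f[, 1], , drop = FALSE]
  e1 <- vcam[f[, 2], , drop = FALSE] - v0
  e2 <- vcam[f[, 3], , drop = FALSE] - v0
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      d <- c((2 * (j - 0.5) / resolution - 1) * th,
             (1 - 2 * (i - 0.5) / resolution) * th, -1)
      best_t <- Inf
      best_f <- 0L
      for (k in seq_len(nrow(f))) {
        p <- c(d[2] * e2[k, 3] - d[3] * e2[k, 2],
               d[3] * e2[k, 1] - d[1] * e2[k, 3],
               d[1] * e2[k, 2] - d[2] * e2[k, 1])
        det <- sum(p * e1[k, ])
        if (abs(det) < 1e-12) next
        tv <- -v0[k, ]
        u <- sum(p * tv) / det
        q <- c(tv[2] * e1[k, 3] - tv[3] * e1[k, 2],
               tv[3] * e1[k, 1] - tv[1] * e1[k, 3],
               tv[1] * e1[k, 2] - tv[2] * e1[k, 1])
        v <- sum(q * d) / det
        w <- 1 - u - v
        hit_t <- sum(q * e2[k, ]) / det
        if (hit_t <= 1e-9) next
        inside_loose <- u > -tol & v > -tol & w > -tol
        if (inside_loose && min(u, v, w) < tol)
          near_edge[i, j] <- TRUE
        if (u >= 0 && v >= 0 && w >= 0 && hit_t < best_t) {
          best_t <- hit_t
          best_f <- k
        }
      }
      fid[i, j] <- best_f
    }
  }
  list(face_id = fid, near_edge = near_edge)
}

# Pairwise concordance AUC oracle: concordant pairs + half ties over all
# positive/negative pairs.
auc_pair_count <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# A random blobby (convex-ish star-shaped) test mesh around the origin.
random_star_mesh <- function(level = 0L, seed = 1L, bump = 0.15) {
  m <- icosphere_mesh(level)
  set.seed(seed)
  r <- 1 + runif(n_vertices(m), -bump, bump)
  m$vertices <- m$vertices * r
  m
}

default_views <- function() icosphere_cameras(0L, radius = 3)

# Small deterministic mvcnn for algorithm tests (fast, untrained).
toy_model <- function(resolution = 32L, seed = 5L) {
  mvcnn_init(mvcnn_config(resolution = resolution,
                          conv_channels = c(4L, 8L),
                          final_channels = 8L, attn_hidden = 6L,
                          seed = seed))
}
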