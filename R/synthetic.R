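#' Default per-severity parameter ranges of the synthetic arch generator
#'
#' Uniform sampling ranges for each severity grade, mirroring the clinical
#' severity-index semantics: grade 0 is a buccal bone depression with the
#' palate intact, grade 1 a unilateral full-thickness cleft, grade 2 a
#' projected premaxilla with some palatal continuity, grade 3 a projected
#' premaxilla with small or no palatal continuity. Adjacent grades share
#' slightly overlapping ranges so the classification task is not trivially
#' separable; widening the overlaps raises difficulty.
#'
#' Units: `notch_width` is in radians of arch angle (the horseshoe spans
#' roughly pi); `notch_depth_fraction` is the fraction of the cross-section
#' carved out (1 = full thickness); `premaxilla_projection` is an anterior
#' displacement in model units (arch radius approximately 1);
#' `palatal_bridge_thickness` in \[0, 1\] scales the palatal connecting
#' strip, 0 meaning no palatal continuity at all.
#'
#' @return nested list: one entry per severity `"0"`..`"3"`, each holding
#'   `notch_width`, `notch_depth_fraction`, `premaxilla_projection`,
#'   `palatal_bridge_thickness` ranges (length-2 numeric) and `bilateral`.
#' @export
defect_param_ranges <- function() {
  list(
    "0" = list(notch_width = c(0.30, 0.55),
               notch_depth_fraction = c(0.40, 0.85),
               premaxilla_projection = c(0, 0),
               palatal_bridge_thickness = c(1, 1),
               bilateral = FALSE),
    "1" = list(notch_width = c(0.30, 0.55),
               notch_depth_fraction = c(1, 1),
               premaxilla_projection = c(0, 0),
               palatal_bridge_thickness = c(0, 0.5),
               bilateral = FALSE),
    "2" = list(notch_width = c(0.35, 0.55),
               notch_depth_fraction = c(1, 1),
               premaxilla_projection = c(0.10, 0.26),
               palatal_bridge_thickness = c(0.25, 0.60),
               bilateral = TRUE),
    "3" = list(notch_width = c(0.50, 0.80),
               notch_depth_fraction = c(1, 1),
               premaxilla_projection = c(0.24, 0.45),
               palatal_bridge_thickness = c(0, 0.08),
               bilateral = TRUE))
}

# Run fn with a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Sample defect parameters for one severity grade
#'
#' Draws a `defect_params` object uniformly from the per-grade ranges (see
#' [defect_param_ranges()]). Deterministic in `(severity, seed)`.
#'
#' @param severity integer grade in 0..3.
#' @param seed integer RNG seed for this specimen.
#' @param ranges range table, defaulting to [defect_param_ranges()].
#' @return an object of class `defect_params`.
#' @export
#' @examples
#' sample_params(3, seed = 11)
sample_params <- function(severity, seed, ranges = defect_param_ranges()) {
  if (!severity %in% 0:3) stop("severity must be one of 0, 1, 2, 3")
  r <- ranges[[as.character(severity)]]
  with_seed(as.integer(seed), function() {
    u <- function(rg) if (rg[1] == rg[2]) rg[1] else runif(1, rg[1], rg[2])
    structure(list(severity = as.integer(severity),
                   notch_width = u(r$notch_width),
                   notch_depth_fraction = u(r$notch_depth_fraction),
                   bilateral = r$bilateral,
                   premaxilla_projection = u(r$premaxilla_projection),
                   palatal_bridge_thickness = u(r$palatal_bridge_thickness),
                   seed = as.integer(seed)),
              class = "defect_params")
  })
}

#' @export
print.defect_params <- function(x, ...) {
  cat(sprintf(paste0("defect_params: severity %d, width %.3f rad, depth %.2f,",
                     " %s, projection %.3f, bridge %.2f (seed %d)\n"),
              x$severity, x$notch_width, x$notch_depth_fraction,
              if (x$bilateral) "bilateral" else "unilateral",
              x$premaxilla_projection, x$palatal_bridge_thickness, x$seed))
  invisible(x)
}

#' Build a parametric cleft-arch mesh for one set of defect parameters
#'
#' Sweeps an elliptical cross-section along a parabolic horseshoe midline
#' (a generic alveolar-arch stand-in, not an anatomical maxilla template),
#' then applies the defect: a carved buccal depression
#' (`notch_depth_fraction < 1`), full-thickness gap(s) of angular width
#' `notch_width` at one or both cleft sites (`notch_depth_fraction = 1`),
#' an anterior premaxillary segment translated forward by
#' `premaxilla_projection`, and a palatal connecting strip across each gap
#' whose width scales with `palatal_bridge_thickness` (absent when 0, so the
#' mesh then splits into separate bony segments, as a complete cleft does).
#'
#' The indices of vertices inside the carved/gap region (plus the premaxilla
#' for projected grades) are returned as the ground-truth defect mask used
#' by the heatmap-localization checks.
#'
#' @param params a `defect_params` from [sample_params()].
#' @param resolution number of cross-section rings along the arch
#'   (default 44); the ring vertex count scales with it. Must be >= 24.
#' @return list with `mesh` (a [triangle_mesh]) and `defect_vertices`
#'   (integer vector of 1-based vertex indices; empty when there is no
#'   defect).
#' @export
build_arch <- function(params, resolution = 44L) {
  nu <- as.integer(resolution)
  if (nu < 24L) stop("resolution must be >= 24 rings")
  nv <- max(12L, as.integer(round(nu * 0.36)))
  with_seed(params$seed + 104729L, function() {
    # per-specimen anatomy jitter
    W <- 0.9 * runif(1, 0.92, 1.08)    # half arch width
    D <- 1.1 * runif(1, 0.92, 1.08)    # arch depth (anterior bulge)
    rb <- 0.17 * runif(1, 0.9, 1.1)    # buccolingual half thickness
    rz <- 0.27 * runif(1, 0.9, 1.1)    # vertical half thickness
    site <- runif(1, 0.44, 0.56)       # cleft site in arch coordinate
    side <- sample(c(-1, 1), 1)        # unilateral side

    s <- seq(-1, 1, length.out = nu)
    phi <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    # midline and its outward (buccal) in-plane normal
    cx <- W * s; cy <- D * (1 - s^2)
    tx <- W + 0 * s; ty <- -2 * D * s
    tn <- sqrt(tx^2 + ty^2)
    nxv <- -ty / tn; nyv <- tx / tn

    vid <- function(j, k) (j - 1L) * nv + k
    verts <- matrix(0, nu * nv, 3L)
    for (j in seq_len(nu)) {
      off_b <- rb * cos(phi)           # along outward normal
      off_z <- rz * sin(phi)
      verts[vid(j, seq_len(nv)), ] <- cbind(cx[j] + off_b * nxv[j],
                                            cy[j] + off_b * nyv[j],
                                            off_z)
    }

    hw <- (params$notch_width / 2) / (pi / 2)   # gap half-width in s units
    sites <- if (params$bilateral) c(-site, site) else side * site
    defect <- integer(0)
    ring_verts <- function(rings)
      as.vector(outer(seq_len(nv), (rings - 1L) * nv, `+`))

    site_rings <- list()
    if (params$notch_depth_fraction < 1) {
      # grade 0: carve a buccal depression at the (unilateral) site
      s0 <- sites[1L]
      wgt_s <- exp(-((s - s0) / hw)^2)
      for (j in seq_len(nu)) {
        wgt <- wgt_s[j] * pmax(0, cos(phi))
        push <- params$notch_depth_fraction * rb * wgt
        idx <- vid(j, seq_len(nv))
        verts[idx, 1L] <- verts[idx, 1L] - push * nxv[j]
        verts[idx, 2L] <- verts[idx, 2L] - push * nyv[j]
        if (params$notch_depth_fraction > 0)
          defect <- c(defect, idx[wgt > 0.35])
      }
      gap_rings <- integer(0)
    } else {
      # full-thickness gap(s): drop whole rings inside each notch interval
      gap_rings <- integer(0)
      for (si in seq_along(sites)) {
        s0 <- sites[si]
        inside <- which(abs(s - s0) < hw)
        if (!length(inside)) inside <- which.min(abs(s - s0))
        if (min(inside) <= 1L || max(inside) >= nu)
          stop("notch_width too large: an arch segment vanished")
        site_rings[[si]] <- inside
        gap_rings <- union(gap_rings, inside)
        margin <- which(abs(s - s0) < hw + 0.12)
        defect <- c(defect, ring_verts(setdiff(margin, inside)))
      }
    }

    keep_ring <- setdiff(seq_len(nu), gap_rings)
    if (params$bilateral && length(site_rings) == 2L) {
      anterior <- keep_ring[keep_ring > max(site_rings[[1L]]) &
                            keep_ring < min(site_rings[[2L]])]
      if (!length(anterior))
        stop("notch_width too large: the premaxillary segment vanished")
      if (params$premaxilla_projection > 0) {
        idx <- ring_verts(anterior)
        verts[idx, 2L] <- verts[idx, 2L] + params$premaxilla_projection
        defect <- c(defect, idx)
      }
    }

    # faces between consecutive surviving rings
    faces <- list()
    for (j in seq_len(nu - 1L)) {
      if (j %in% gap_rings || (j + 1L) %in% gap_rings) next
      k <- seq_len(nv); k2 <- c(seq_len(nv)[-1L], 1L)
      a <- vid(j, k); b <- vid(j, k2); cc <- vid(j + 1L, k2); d <- vid(j + 1L, k)
      faces[[length(faces) + 1L]] <- cbind(a, b, cc)
      faces[[length(faces) + 1L]] <- cbind(a, cc, d)
    }

    # palatal bridge strip across each gap (welds the segments when > 0)
    if (length(gap_rings) && params$palatal_bridge_thickness > 0) {
      pal <- order(cos(phi))                      # most palatal first
      npal <- sum(cos(phi) < -0.3)
      kstrip <- max(2L, as.integer(round(params$palatal_bridge_thickness *
                                         npal)))
      strip <- sort(pal[seq_len(min(kstrip, npal))])
      for (si in seq_along(sites)) {
        inside <- site_rings[[si]]
        jL <- max(keep_ring[keep_ring < min(inside)])
        jR <- min(keep_ring[keep_ring > max(inside)])
        for (q in seq_len(length(strip) - 1L)) {
          p1 <- strip[q]; p2 <- strip[q + 1L]
          faces[[length(faces) + 1L]] <-
            rbind(c(vid(jL, p1), vid(jL, p2), vid(jR, p2)),
                  c(vid(jL, p1), vid(jR, p2), vid(jR, p1)))
        }
      }
    }

    # end caps so the posterior tube ends are closed
    caps <- matrix(0, 2L, 3L)
    caps[1L, ] <- c(cx[1L], cy[1L], 0)
    caps[2L, ] <- c(cx[nu], cy[nu], 0)
    cap_id <- nu * nv + 1:2
    verts <- rbind(verts, caps)
    k <- seq_len(nv); k2 <- c(seq_len(nv)[-1L], 1L)
    faces[[length(faces) + 1L]] <- cbind(cap_id[1L], vid(1L, k2), vid(1L, k))
    faces[[length(faces) + 1L]] <- cbind(cap_id[2L], vid(nu, k), vid(nu, k2))
    faces <- do.call(rbind, faces)

    # slight surface noise so specimens are never pixel-identical
    verts <- verts + matrix(rnorm(length(verts), sd = 0.004), nrow(verts))

    # drop vertices that no face references (the removed gap rings)
    used <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
    mesh <- triangle_mesh(verts[used, , drop = FALSE],
                          matrix(remap[faces], nrow(faces), 3L))
    defect <- sort(unique(remap[intersect(defect, used)]))
    list(mesh = mesh, defect_vertices = defect)
  })
}

#' Generate a labeled synthetic cleft-arch dataset
#'
#' Writes one mesh file per specimen plus a manifest CSV with columns
#' `mesh_path,label,seed,defect_vertices` (defect vertex indices joined by
#' `;`). Fully reproducible: the same `seed` yields byte-identical manifests
#' and meshes. The default class counts `c(62, 45, 45, 38)` reproduce the
#' class imbalance of the clinical cohort the package's evaluation
#' conventions are modeled on.
#'
#' @param n_per_class either one integer (balanced classes) or a length-4
#'   vector of per-grade counts.
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param format mesh file format (see [write_mesh()]).
#' @param resolution arch ring count passed to [build_arch()].
#' @return the manifest data.frame (invisibly carries `base_dir` as an
#'   attribute), of class `dataset_manifest`.
#' @export
generate_dataset <- function(n_per_class = c(62L, 45L, 45L, 38L), out_dir,
                             seed = 1L, format = "vtk", resolution = 44L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 4L)
  stopifnot(length(n_per_class) == 4L, all(n_per_class >= 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  labels <- rep(0:3, n_per_class)
  n <- length(labels)
  rec_seed <- as.integer((as.numeric(seed) * 1000003 +
                          seq_len(n) * 7919) %% 2147483629)
  paths <- character(n); defects <- character(n)
  for (i in seq_len(n)) {
    pars <- sample_params(labels[i], rec_seed[i])
    built <- build_arch(pars, resolution = resolution)
    paths[i] <- sprintf("arch_%03d_class%d.%s", i, labels[i], format)
    write_mesh(file.path(out_dir, paths[i]), built$mesh, format = format)
    defects[i] <- paste(built$defect_vertices, collapse = ";")
  }
  manifest <- data.frame(mesh_path = paths, label = labels,
                         seed = rec_seed, defect_vertices = defects,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "base_dir") <- out_dir
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

GENERATOR_VERSION <- "surfgradcam-arch-1"

#' Write / read a dataset manifest CSV
#'
#' @param manifest manifest data.frame (`mesh_path,label,seed,defect_vertices`).
#' @param path CSV path.
#' @return the manifest (read) or `path` invisibly (write).
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# generator: %s", GENERATOR_VERSION), con)
  utils::write.csv(manifest[, c("mesh_path", "label", "seed",
                                "defect_vertices")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  manifest <- utils::read.csv(path, comment.char = "#",
                              stringsAsFactors = FALSE,
                              colClasses = c(mesh_path = "character",
                                             label = "integer",
                                             seed = "integer",
                                             defect_vertices = "character"))
  attr(manifest, "base_dir") <- dirname(path)
  class(manifest) <- c("dataset_manifest", class(manifest))
  manifest
}

#' Defect-region vertex indices recorded in a manifest
#'
#' @param manifest a `dataset_manifest`.
#' @param i record index.
#' @return integer vector of 1-based vertex indices (possibly empty).
#' @export
manifest_defect_vertices <- function(manifest, i) {
  s <- manifest$defect_vertices[i]
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
}
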