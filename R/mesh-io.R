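#' Read a triangle mesh from a standard surface-model file
#'
#' Supports VTK legacy polydata (`.vtk`, ascii), VTK XML polydata (`.vtp`,
#' ascii-encoded data arrays), Wavefront OBJ and PLY (ascii and
#' binary-little-endian). Non-triangle polygons are fan-triangulated on read.
#' Per-vertex point-data arrays (VTK/VTP scalars, extra PLY vertex
#' properties) are preserved by name in `vertex_scalars`.
#'
#' @param path path to the mesh file.
#' @param format one of `"auto"` (default, from the file extension), `"vtk"`,
#'   `"vtp"`, `"obj"`, `"ply"`.
#' @return a [triangle_mesh].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "vtk", "vtp", "obj", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("vtk", "vtp", "obj", "ply"))
      stop("cannot detect mesh format from extension '.", ext, "'")
    format <- ext
  }
  switch(format,
         vtk = read_vtk_legacy(path),
         vtp = read_vtp(path),
         obj = read_obj(path),
         ply = read_ply(path))
}

#' Write a triangle mesh to a standard surface-model file
#'
#' Writes VTK legacy polydata, VTK XML polydata, OBJ or PLY (ascii). Scalar
#' arrays are written as point-data arrays (VTK/VTP), or as extra float
#' vertex properties (PLY). OBJ has no per-vertex scalar standard: scalar
#' arrays are dropped with a warning.
#'
#' @param path output path.
#' @param mesh a [triangle_mesh].
#' @param format one of `"auto"`, `"vtk"`, `"vtp"`, `"obj"`, `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(path, mesh,
                       format = c("auto", "vtk", "vtp", "obj", "ply")) {
  format <- match.arg(format)
  validate_mesh(mesh)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("vtk", "vtp", "obj", "ply"))
      stop("cannot detect mesh format from extension '.", ext, "'")
    format <- ext
  }
  switch(format,
         vtk = write_vtk_legacy(path, mesh),
         vtp = write_vtp(path, mesh),
         obj = write_obj(path, mesh),
         ply = write_ply(path, mesh))
  invisible(path)
}

# Fan-triangulate a list of polygons (integer vectors, 1-based) into an
# m x 3 face matrix.  Polygons with < 3 vertices are dropped.
fan_triangulate <- function(polys) {
  tri <- lapply(polys, function(p) {
    k <- length(p)
    if (k < 3L) return(NULL)
    if (k == 3L) return(matrix(p, 1L, 3L))
    cbind(p[1L], p[2:(k - 1L)], p[3:k])
  })
  tri <- tri[!vapply(tri, is.null, TRUE)]
  if (!length(tri)) return(matrix(integer(0), 0L, 3L))
  out <- do.call(rbind, tri)
  storage.mode(out) <- "integer"
  out
}

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

## ---- VTK legacy polydata (ascii) -------------------------------------------

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) >= 3L && toupper(trimws(lines[3L])) == "BINARY")
    stop("VTK legacy BINARY files are not supported; convert to ASCII")
  toks <- scan(text = paste(lines[-(1:2)], collapse = "\n"),
               what = character(), quiet = TRUE)
  i <- 1L
  peek <- function() if (i <= length(toks)) toupper(toks[i]) else NA_character_
  nxt <- function() { t <- toks[i]; i <<- i + 1L; t }
  expect <- function(word) {
    t <- nxt()
    if (is.na(t) || toupper(t) != word)
      stop("VTK parse error: expected '", word, "', got '", t, "'")
  }
  expect("ASCII")
  expect("DATASET"); ds <- toupper(nxt())
  if (ds != "POLYDATA") stop("VTK parse error: DATASET ", ds,
                             " (only POLYDATA supported)")
  verts <- NULL; polys <- list(); scalars <- list()
  while (!is.na(peek())) {
    key <- toupper(nxt())
    if (key == "POINTS") {
      n <- as.integer(nxt()); nxt()  # dtype ignored
      vals <- as.numeric(toks[i:(i + 3L * n - 1L)]); i <- i + 3L * n
      verts <- matrix(vals, n, 3L, byrow = TRUE)
    } else if (key == "POLYGONS") {
      m <- as.integer(nxt()); total <- as.integer(nxt())
      vals <- as.integer(toks[i:(i + total - 1L)]); i <- i + total
      p <- 1L
      for (f in seq_len(m)) {
        k <- vals[p]
        polys[[length(polys) + 1L]] <- vals[(p + 1L):(p + k)] + 1L
        p <- p + k + 1L
      }
    } else if (key %in% c("VERTICES", "LINES", "TRIANGLE_STRIPS")) {
      m <- as.integer(nxt()); total <- as.integer(nxt()); i <- i + total
    } else if (key == "POINT_DATA") {
      np <- as.integer(nxt())
      while (!is.na(peek())) {
        sub <- peek()
        if (sub == "SCALARS") {
          nxt(); nm <- nxt(); nxt()  # dtype
          ncomp <- 1L
          if (!is.na(peek()) && grepl("^[0-9]+$", toks[i])) ncomp <- as.integer(nxt())
          if (peek() == "LOOKUP_TABLE") { nxt(); nxt() }
          vals <- as.numeric(toks[i:(i + np * ncomp - 1L)]); i <- i + np * ncomp
          if (ncomp == 1L) scalars[[nm]] <- vals
        } else if (sub == "FIELD") {
          nxt(); nxt(); narr <- as.integer(nxt())
          for (a in seq_len(narr)) {
            nm <- nxt(); ncomp <- as.integer(nxt()); ntup <- as.integer(nxt())
            nxt()  # dtype
            vals <- as.numeric(toks[i:(i + ncomp * ntup - 1L)])
            i <- i + ncomp * ntup
            if (ncomp == 1L && ntup == np) scalars[[nm]] <- vals
          }
        } else break
      }
    } else if (key == "CELL_DATA") {
      break  # cell data not carried by the container
    } else {
      stop("VTK parse error: unexpected section '", key, "'")
    }
  }
  if (is.null(verts) || nrow(verts) == 0L)
    stop("empty mesh: VTK file has no POINTS")
  triangle_mesh(verts, fan_triangulate(polys), scalars)
}

write_vtk_legacy <- function(path, mesh) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  writeLines(c("# vtk DataFile Version 3.0", "surface mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nv)), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  if (nf > 0L)
    writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
  sc <- mesh$vertex_scalars
  if (length(sc)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(sc)) {
      writeLines(c(sprintf("SCALARS %s float 1", sanitize_name(nm)),
                   "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(sc[[nm]]), con)
    }
  }
}

## ---- VTK XML polydata (.vtp, ascii data arrays) ----------------------------

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing"))
    stop("VTP parse error: no <Piece> element")
  get_da <- function(node) {
    fmt <- xml2::xml_attr(node, "format")
    if (!is.na(fmt) && tolower(fmt) != "ascii")
      stop("VTP parse error: DataArray format '", fmt,
           "' not supported (ascii only)")
    scan(text = xml2::xml_text(node), what = numeric(), quiet = TRUE)
  }
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  if (inherits(pts_node, "xml_missing"))
    stop("VTP parse error: no Points/DataArray")
  pts <- get_da(pts_node)
  verts <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- off <- numeric(0)
  for (node in xml2::xml_find_all(piece, "./Polys/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    if (identical(nm, "connectivity")) conn <- get_da(node)
    if (identical(nm, "offsets")) off <- get_da(node)
  }
  starts <- c(1L, head(off, -1L) + 1L)
  polys <- mapply(function(s, e) as.integer(conn[s:e]) + 1L,
                  starts, off, SIMPLIFY = FALSE)
  scalars <- list()
  for (node in xml2::xml_find_all(piece, "./PointData/DataArray")) {
    nm <- xml2::xml_attr(node, "Name")
    nc <- xml2::xml_attr(node, "NumberOfComponents")
    if (!is.na(nc) && as.integer(nc) != 1L) next
    scalars[[nm]] <- get_da(node)
  }
  triangle_mesh(verts, fan_triangulate(polys), scalars)
}

write_vtp <- function(path, mesh) {
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">')
  w('  <PolyData>')
  w('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">', nv, nf)
  sc <- mesh$vertex_scalars
  if (length(sc)) {
    w('      <PointData>')
    for (nm in names(sc)) {
      w('        <DataArray type="Float32" Name="%s" format="ascii">',
        sanitize_name(nm))
      writeLines(paste("         ", paste(fmt_num(sc[[nm]]), collapse = " ")),
                 con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <Points>')
  w('        <DataArray type="Float32" NumberOfComponents="3" format="ascii">')
  writeLines(paste("         ",
                   apply(mesh$vertices, 1L, function(r)
                     paste(fmt_num(r), collapse = " "))), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Polys>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  if (nf > 0L)
    writeLines(paste("         ", paste(t(mesh$faces) - 1L, collapse = " ")),
               con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  if (nf > 0L)
    writeLines(paste("         ", paste(seq_len(nf) * 3L, collapse = " ")),
               con)
  w('        </DataArray>')
  w('      </Polys>')
  w('    </Piece>')
  w('  </PolyData>')
  w('</VTKFile>')
}

## ---- Wavefront OBJ ---------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines)) stop("empty mesh: OBJ file has no 'v' records")
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t)
    as.numeric(t[2:4])))
  polys <- lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    idx <- as.integer(vapply(t[-1L], function(s)
      strsplit(s, "/", fixed = TRUE)[[1L]][1L], ""))
    # negative OBJ indices count back from the current vertex count
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]
    idx
  })
  triangle_mesh(verts, fan_triangulate(polys))
}

write_obj <- function(path, mesh) {
  if (length(mesh$vertex_scalars))
    warning("OBJ has no per-vertex scalar standard; dropping arrays: ",
            paste(names(mesh$vertex_scalars), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", apply(mesh$vertices, 1L, function(r)
    paste(fmt_num(r), collapse = " "))), con)
  if (n_faces(mesh) > 0L)
    writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
}

## ---- PLY (ascii + binary little-endian read; ascii write) ------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type, n = 1L) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, numeric(), n = n, size = sz, endian = "little")
  else {
    signed <- !startsWith(type, "u")
    if (sz == 1L && !signed)
      as.numeric(readBin(con, integer(), n = n, size = 1L, signed = FALSE,
                         endian = "little"))
    else
      as.numeric(readBin(con, integer(), n = n, size = sz, signed = TRUE,
                         endian = "little"))
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("PLY parse error: unexpected end of header")
    hdr <- c(hdr, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(hdr[1L]) != "ply") stop("PLY parse error: missing 'ply' magic")
  fmt_line <- grep("^format", hdr, value = TRUE)[1L]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY format '", fmt, "' not supported")
  # parse element/property declarations in order
  elements <- list()
  cur <- NULL
  for (line in hdr) {
    t <- strsplit(trimws(line), "\\s+")[[1L]]
    if (t[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2L], count = as.integer(t[3L]), props = list())
    } else if (t[1L] == "property" && !is.null(cur)) {
      if (t[2L] == "list")
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[5L], list = TRUE, count_type = t[3L], type = t[4L])
      else
        cur$props[[length(cur$props) + 1L]] <-
          list(name = t[3L], list = FALSE, type = t[2L])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop("PLY parse error: no vertex element")

  verts <- NULL; scalars <- list(); polys <- list()
  if (fmt == "ascii") {
    toks <- scan(con, what = character(), quiet = TRUE)
    p <- 1L
    for (el in elements) {
      if (el$name == "vertex") {
        k <- length(el$props)
        vals <- matrix(as.numeric(toks[p:(p + el$count * k - 1L)]),
                       el$count, k, byrow = TRUE)
        p <- p + el$count * k
        nms <- vapply(el$props, `[[`, "", "name")
        verts <- vals[, match(c("x", "y", "z"), nms), drop = FALSE]
        for (j in which(!nms %in% c("x", "y", "z")))
          scalars[[nms[j]]] <- vals[, j]
      } else if (el$name == "face") {
        for (f in seq_len(el$count)) {
          k <- as.integer(toks[p]); p <- p + 1L
          polys[[f]] <- as.integer(toks[p:(p + k - 1L)]) + 1L
          p <- p + k
        }
      } else {
        # skip unknown ascii element (assumes no list properties)
        p <- p + el$count * length(el$props)
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        types <- vapply(el$props, `[[`, "", "type")
        nms <- vapply(el$props, `[[`, "", "name")
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          stop("PLY parse error: list property on vertex element")
        if (length(unique(types)) == 1L) {
          vals <- matrix(ply_read_scalar(con, types[1L],
                                         el$count * length(types)),
                         el$count, length(types), byrow = TRUE)
        } else {
          vals <- matrix(0, el$count, length(types))
          for (r in seq_len(el$count))
            for (j in seq_along(types))
              vals[r, j] <- ply_read_scalar(con, types[j])
        }
        verts <- vals[, match(c("x", "y", "z"), nms), drop = FALSE]
        for (j in which(!nms %in% c("x", "y", "z")))
          scalars[[nms[j]]] <- vals[, j]
      } else if (el$name == "face") {
        pr <- el$props[[1L]]
        if (!pr$list) stop("PLY parse error: face element without list")
        polys <- vector("list", el$count)
        for (f in seq_len(el$count)) {
          k <- as.integer(ply_read_scalar(con, pr$count_type))
          polys[[f]] <- as.integer(ply_read_scalar(con, pr$type, k)) + 1L
        }
      } else {
        for (r in seq_len(el$count))
          for (pr in el$props) {
            if (pr$list) {
              k <- as.integer(ply_read_scalar(con, pr$count_type))
              ply_read_scalar(con, pr$type, k)
            } else ply_read_scalar(con, pr$type)
          }
      }
    }
  }
  if (is.null(verts) || nrow(verts) == 0L)
    stop("empty mesh: PLY file has no vertices")
  triangle_mesh(verts, fan_triangulate(polys), scalars)
}

write_ply <- function(path, mesh) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  sc <- mesh$vertex_scalars
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (length(sc)) sprintf("property float %s",
                                   sanitize_name(names(sc))),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  body <- mesh$vertices
  for (nm in names(sc)) body <- cbind(body, sc[[nm]])
  writeLines(apply(body, 1L, function(r) paste(fmt_num(r), collapse = " ")),
             con)
  if (nf > 0L)
    writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                     mesh$faces[, 3L] - 1L), con)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
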