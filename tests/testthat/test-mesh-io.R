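test_that("OBJ faces are converted from 1-based indexing and fans split", {
  f <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3"), f)
  m <- read_mesh(f)
  expect_equal(m$faces, matrix(c(1L, 2L, 3L), 1L))
  # quad -> 2 triangles by fan split
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), f)
  m <- read_mesh(f)
  expect_equal(n_faces(m), 2L)
  expect_equal(m$faces[1L, ], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(m$faces[2L, ], c(1L, 3L, 4L), ignore_attr = TRUE)
})

test_that("VTK legacy polydata quads are fan-triangulated on read", {
  f <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "quad", "ASCII",
               "DATASET POLYDATA", "POINTS 4 float",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "POLYGONS 1 5", "4 0 1 2 3"), f)
  m <- read_mesh(f)
  expect_equal(n_vertices(m), 4L)
  expect_equal(n_faces(m), 2L)
})

test_that("write/read round-trips preserve geometry and named scalars", {
  set.seed(31)
  m <- random_star_mesh(1L, seed = 31)
  m$vertex_scalars$surfgradcam_class3 <- runif(n_vertices(m))
  m$vertex_scalars$thickness <- rnorm(n_vertices(m))
  for (fmt in c("vtk", "vtp", "ply")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(f, m, format = fmt)
    m2 <- read_mesh(f)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
    expect_identical(m2$faces, m$faces)
    expect_setequal(names(m2$vertex_scalars), names(m$vertex_scalars))
    expect_equal(m2$vertex_scalars$surfgradcam_class3,
                 m$vertex_scalars$surfgradcam_class3, tolerance = 1e-6)
    # second round trip is the identity on the parsed values
    f2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(f2, m2, format = fmt)
    m3 <- read_mesh(f2)
    expect_equal(m3$vertices, m2$vertices, tolerance = 1e-7)
    expect_identical(m3$faces, m2$faces)
  }
})

test_that("binary little-endian PLY files are read", {
  m <- random_star_mesh(0L, seed = 4)
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               sprintf("element vertex %d", n_vertices(m)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", n_faces(m)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeBin(as.vector(t(m$vertices)), con, size = 4L, endian = "little")
  for (i in seq_len(n_faces(m))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4L,
             endian = "little")
  }
  close(con)
  m2 <- read_mesh(f)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(m2$faces, m$faces)
})

test_that("OBJ write drops scalar arrays with a warning", {
  m <- triangle_mesh(diag(3), matrix(1:3, 1L),
                     list(heat = c(0, 0.5, 1)))
  f <- withr::local_tempfile(fileext = ".obj")
  expect_warning(write_mesh(f, m, "obj"), "scalar")
  expect_length(read_mesh(f)$vertex_scalars, 0L)
})

test_that("malformed and degenerate inputs produce clear errors", {
  f <- withr::local_tempfile(fileext = ".vtk")
  writeLines(c("# vtk DataFile Version 3.0", "t", "ASCII",
               "DATASET STRUCTURED_GRID"), f)
  expect_error(read_mesh(f), "POLYDATA")
  writeLines(c("# vtk DataFile Version 3.0", "t", "BINARY"), f)
  expect_error(read_mesh(f), "BINARY")
  f2 <- withr::local_tempfile(fileext = ".obj")
  writeLines("# nothing", f2)
  expect_error(read_mesh(f2), "empty mesh")
  expect_error(read_mesh("no/such/file.ply"), "not found")
  expect_error(triangle_mesh(diag(3), matrix(c(1L, 2L, 4L), 1L)),
               "out of range")
  expect_error(triangle_mesh(diag(3), matrix(1:3, 1L), list(s = 1:2)),
               "length")
})

test_that("normalize_pose centers, scales to unit radius, and is idempotent", {
  m <- triangle_mesh(matrix(c(4, 4, 4, 6, 4, 4, 4, 6, 4, 4, 4, 6),
                            4L, 3L, byrow = TRUE),
                     matrix(c(1L, 2L, 3L, 1L, 3L, 4L), 2L, byrow = TRUE))
  mn <- normalize_pose(m)
  expect_equal(colMeans(mn$vertices), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(max(sqrt(rowSums(mn$vertices^2))), 1, tolerance = 1e-12)
  expect_identical(mn$faces, m$faces)
  # fixed point + commutes with rigid translation
  for (seed in 1:3) {
    mr <- random_star_mesh(0L, seed = seed)
    a <- normalize_pose(mr)
    expect_equal(normalize_pose(a)$vertices, a$vertices, tolerance = 1e-12)
    shifted <- mr
    shifted$vertices <- sweep(mr$vertices, 2L, c(3, -2, 7), "+")
    expect_equal(normalize_pose(shifted)$vertices, a$vertices,
                 tolerance = 1e-12)
  }
  bad <- triangle_mesh(matrix(1, 3L, 3L), matrix(1:3, 1L))
  expect_error(normalize_pose(bad), "degenerate")
})
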