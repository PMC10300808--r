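# PLY/STL round trips, cross-format equivalence, landmark file dialects.

cube_mesh <- function() {
  corners <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  hull <- convex_hull3(corners)
  triangle_mesh(hull$vertices, hull$faces, comment = "unit cube")
}

sorted_vertex_key <- function(V, digits = 5) {
  sort(apply(round(V, digits), 1, paste, collapse = ","))
}

test_that("the unit cube hull has 8 vertices and 12 triangles", {
  mesh <- cube_mesh()
  expect_identical(nrow(mesh$vertices), 8L)
  expect_identical(nrow(mesh$faces), 12L)
  # every face normal points away from the cube centre
  ctr <- colMeans(mesh$vertices)
  for (f in seq_len(nrow(mesh$faces))) {
    p <- mesh$vertices[mesh$faces[f, ], ]
    nrm <- c(
      (p[2, 2] - p[1, 2]) * (p[3, 3] - p[1, 3]) - (p[2, 3] - p[1, 3]) * (p[3, 2] - p[1, 2]),
      (p[2, 3] - p[1, 3]) * (p[3, 1] - p[1, 1]) - (p[2, 1] - p[1, 1]) * (p[3, 3] - p[1, 3]),
      (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) - (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    expect_gt(sum(nrm * (colMeans(p) - ctr)), 0)
  }
})

test_that("ascii PLY round-trips vertices and faces losslessly", {
  mesh <- cube_mesh()
  mesh$vertices <- mesh$vertices + runif(24, -0.001, 0.001)
  path <- tempfile(fileext = ".ply")
  rec <- write_mesh(mesh, path, "ply_ascii")
  expect_identical(rec$vertex_count, 8L)
  expect_identical(rec$face_count, 12L)
  back <- read_mesh(path)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-15)
  expect_identical(back$faces, mesh$faces)
  expect_identical(back$comment, "unit cube")
})

test_that("binary PLY matches ascii PLY to float precision and is bit-stable", {
  set.seed(60)
  mesh <- cube_mesh()
  mesh$vertices <- mesh$vertices * 40 + rnorm(24)
  pa <- tempfile(fileext = ".ply"); pb <- tempfile(fileext = ".ply")
  write_mesh(mesh, pa, "ply_ascii")
  write_mesh(mesh, pb, "ply_binary_le")
  a <- read_mesh(pa); b <- read_mesh(pb)
  expect_equal(a$vertices, b$vertices, tolerance = 1e-5)
  expect_identical(a$faces, b$faces)

  pb2 <- tempfile(fileext = ".ply")
  write_mesh(mesh, pb2, "ply_binary_le")
  expect_identical(readBin(pb, "raw", file.size(pb)),
                   readBin(pb2, "raw", file.size(pb2)))
})

test_that("binary STL round-trips geometry up to vertex welding", {
  mesh <- cube_mesh()
  path <- tempfile(fileext = ".stl")
  write_mesh(mesh, path, "stl_binary")
  back <- read_mesh(path)
  expect_identical(nrow(back$vertices), 8L)   # welded from 36 corner copies
  expect_identical(nrow(back$faces), 12L)
  expect_identical(sorted_vertex_key(back$vertices),
                   sorted_vertex_key(mesh$vertices))
})

test_that("malformed and degenerate mesh files are rejected", {
  bad <- tempfile(fileext = ".ply")
  writeLines(c("not a ply", "format ascii 1.0"), bad)
  expect_error(read_mesh(bad), "malformed PLY header")

  expect_error(read_mesh(tempfile(fileext = ".ply")), "file not found")
  expect_error(write_mesh(triangle_mesh(matrix(rnorm(9), 3, 3),
                                        matrix(integer(0), 0, 3)),
                          tempfile(fileext = ".ply"), "ply_ascii"),
               "no faces")

  ascii_stl <- tempfile(fileext = ".stl")
  writeLines(c("solid demo", "endsolid demo"), ascii_stl)
  expect_error(read_mesh(ascii_stl), "ascii STL is not supported")
})

test_that("quad PLY faces are split fan-wise into triangles", {
  path <- tempfile(fileext = ".ply")
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property double x", "property double y", "property double z",
    "element face 1",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "4 0 1 2 3"), path)
  mesh <- read_mesh(path)
  expect_identical(nrow(mesh$faces), 2L)
  expect_identical(mesh$faces[1, ], c(1L, 2L, 3L))
  expect_identical(mesh$faces[2, ], c(1L, 3L, 4L))
})

test_that("landmark CSV and JSON dialects round-trip and agree", {
  co <- generate_cohort(cohort_spec(list(
    cohort_group("f", 2, cal_table$female_f1, sex = "female",
                 true_cluster = 1)), seed = 61))
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_landmarks(co, csv)
  write_landmarks(co, js)

  from_csv <- read_landmarks(csv)
  from_json <- read_landmarks(js)
  expect_length(from_csv, 2)
  for (i in 1:2) {
    expect_identical(nrow(from_csv[[i]]$points), 18L)
    expect_equal(from_csv[[i]]$points, co$specimens[[i]]$points,
                 tolerance = 1e-12)
    expect_equal(from_json[[i]]$points, from_csv[[i]]$points,
                 tolerance = 1e-12)
    expect_identical(from_csv[[i]]$sex, "female")
    expect_equal(from_csv[[i]]$true_cluster, 1)
  }

  bad <- read.csv(csv)
  bad$name[3] <- "Gonion"
  badfile <- tempfile(fileext = ".csv")
  write.csv(bad, badfile, row.names = FALSE)
  expect_error(read_landmarks(badfile), "valid codes are")
})

test_that("mean shapes serialize with their coordinate-frame tag", {
  ens <- gpa_mean(generate_cohort(cohort_spec(list(
    cohort_group("m", 5, cal_table$male, sex = "male", noise_sd_mm = 1)),
    seed = 62))$specimens)
  path <- tempfile(fileext = ".json")
  write_shape_json(ens$mean_shape, path, frame = "gpa_unit", label = "male")
  back <- read_shape_json(path)
  expect_identical(attr(back, "frame"), "gpa_unit")
  expect_equal(back$points, ens$mean_shape$points, tolerance = 1e-12)
})
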