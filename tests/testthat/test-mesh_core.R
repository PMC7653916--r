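one_triangle <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1L, 2L, 3L)), name = "tri")

test_that("ASCII and binary STL of a single triangle read identically", {
  fa <- withr::local_tempfile(fileext = ".stl")
  fb <- withr::local_tempfile(fileext = ".stl")
  write_stl(one_triangle, fa, "ascii")
  write_stl(one_triangle, fb, "binary")

  ma <- read_stl(fa)
  mb <- read_stl(fb)
  expect_equal(nrow(ma$vertices), 3L)
  expect_equal(nrow(ma$faces), 1L)
  expect_equal(ma$vertices, mb$vertices)
  expect_equal(ma$faces, mb$faces)
  # binary layout: 80-byte header + facet count + one 50-byte record
  expect_equal(file.info(fb)$size, 84 + 50)
  # ASCII file holds exactly one facet
  expect_equal(sum(grepl("^facet", trimws(readLines(fa)))), 1L)
})

test_that("STL round-trip preserves vertices and area on the phantom", {
  mesh <- phantom_default_small()$t1$mesh
  fa <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, fa, "ascii")
  back <- read_stl(fa)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  # same vertex set (order may differ after welding)
  key <- function(v) sort(paste(v[, 1], v[, 2], v[, 3]))
  expect_equal(key(back$vertices), key(mesh$vertices))
  expect_lt(max(abs(sort(back$vertices[, 1]) - sort(mesh$vertices[, 1]))),
            1e-6)
  expect_equal(mesh_area(back), mesh_area(mesh), tolerance = 1e-9)

  fb <- withr::local_tempfile(fileext = ".stl")
  write_stl(mesh, fb, "binary")
  backb <- read_stl(fb)
  # float32 quantisation: area agreement at single precision
  expect_equal(mesh_area(backb), mesh_area(mesh), tolerance = 1e-5)
})

test_that("malformed and empty STL inputs fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet normal 0 0 1", " outer loop",
               "  vertex 0 0 zero", "  vertex 1 0 0", "  vertex 0 1 0",
               " endloop", "endfacet", "endsolid x"), f)
  expect_error(read_stl(f), "non-numeric")
  writeLines(c("solid empty", "endsolid empty"), f)
  expect_error(read_stl(f), "empty solid")
  writeLines("not an stl at all", f)
  expect_error(read_stl(f), "malformed|too short")
  expect_error(read_stl(file.path(tempdir(), "nope.stl")), "no such file")
})

test_that("restrict_mesh returns exactly the masked faces", {
  two <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                 rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  expect_equal(restrict_mesh(two, 1:2)$faces, two$faces)
  sub <- restrict_mesh(two, 2L)
  expect_equal(nrow(sub$faces), 1L)
  expect_equal(nrow(sub$vertices), 3L)
  expect_error(restrict_mesh(two, integer(0)), "empty region")
  expect_error(restrict_mesh(two, 3L), "out of range")

  # masked-area summation and idempotence on the phantom
  b <- phantom_default_small()
  mask <- b$t1$masks$palatal_vault
  sub <- restrict_mesh(b$t1$mesh, mask)
  expect_equal(mesh_area(sub), sum(face_areas(b$t1$mesh)[mask$faces]),
               tolerance = 1e-12)
  expect_lte(mesh_area(sub), mesh_area(b$t1$mesh))
  again <- restrict_mesh(sub, seq_len(nrow(sub$faces)))
  expect_equal(again$vertices, sub$vertices)
  expect_equal(again$faces, sub$faces)
})

test_that("landmark sidecar files round-trip and validate", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("A - 0 10 5", f)
  lms <- read_landmarks(f)
  expect_equal(nrow(lms), 1L)
  expect_true(is.na(lms$tooth))
  expect_equal(unlist(lms[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 10, 5))

  # full crown landmark inventory: 2 suture + 5 per U6 + 4 per U1
  ids <- c("A", "B")
  tt <- c(NA, NA)
  for (tooth in c("RU6", "LU6")) { ids <- c(ids, LETTERS[1:5]); tt <- c(tt, rep(tooth, 5)) }
  for (tooth in c("RU1", "LU1")) { ids <- c(ids, LETTERS[6:9]); tt <- c(tt, rep(tooth, 4)) }
  xyz <- matrix(round(stats::runif(20 * 3, -30, 30), 6), ncol = 3)
  lms <- landmark_table(ids, tt, xyz)
  expect_equal(nrow(lms), 20L)
  write_landmarks(lms, f)
  back <- read_landmarks(f)
  expect_identical(back$x, lms$x)   # bit-faithful for <= 6 fractional digits
  expect_identical(back$y, lms$y)
  expect_identical(back$z, lms$z)
  expect_identical(back$id, lms$id)

  writeLines(c("A - 0 1 2", "A - 3 4 5"), f)
  expect_error(read_landmarks(f), "duplicate")
  writeLines("A - 0 one 2", f)
  expect_error(read_landmarks(f), "non-numeric")
})

test_that("mask sidecars round-trip and disjointness is enforced", {
  b <- phantom_default_small()
  f <- withr::local_tempfile(fileext = ".json")
  write_masks(b$t1$masks, f)
  back <- read_masks(f)
  expect_identical(names(back), names(b$t1$masks))
  expect_identical(back$palatal_vault$faces, b$t1$masks$palatal_vault$faces)
  expect_identical(back$RU6_crown$kind, "crown")
  expect_silent(validate_masks(back, b$t1$mesh))

  bad <- back
  bad$RU6_crown$faces <- c(bad$RU6_crown$faces, back$palatal_vault$faces[1])
  expect_error(validate_masks(bad, b$t1$mesh), "overlaps")
  bad2 <- back
  bad2$palatal_vault$faces <- nrow(b$t1$mesh$faces) + 1L
  expect_error(validate_masks(bad2, b$t1$mesh), "exceeds")
})
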