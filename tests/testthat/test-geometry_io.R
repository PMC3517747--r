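# Label-volume I/O, tri-linear upsampling and isosurface extraction.

test_that("label volume construction validates its contract", {
  v <- label_volume(array(2L, c(1, 1, 1)), spacing = c(1, 1, 1))
  expect_s3_class(v, "label_volume")
  expect_identical(as.vector(v$labels), 2L)
  expect_error(label_volume(array(0.5, c(2, 2, 2))), "non-integer")
  expect_error(label_volume(array(1L, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
})

test_that("NIfTI round trip preserves labels, spacing and origin", {
  vol <- sphere_volume(r = 4, spacing = 0.5)
  vol$origin <- c(10, -3, 7)
  path <- file.path(tempdir(), "roundtrip.nii.gz")
  write_label_volume(vol, path)
  back <- read_label_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_error(read_label_volume(file.path(tempdir(), "nope.nii")), "not found")
  unlink(path)
})

test_that("non-integer voxel values are rejected on read", {
  path <- file.path(tempdir(), "float.nii.gz")
  img <- RNifti::asNifti(array(0.5, c(2, 2, 2)))
  RNifti::writeNifti(img, path)
  expect_error(read_label_volume(path), "non-integer")
  unlink(path)
})

test_that("trilinear upsampling: identity, constant field, and contract", {
  vol <- sphere_volume(r = 4, spacing = 1)
  expect_identical(trilinear_upsample(vol, 1L)$labels, vol$labels)
  const <- label_volume(array(3L, c(4, 4, 4)), spacing = c(2, 2, 2))
  up <- trilinear_upsample(const, 2L)
  expect_true(all(up$labels == 3L))
  expect_equal(dim(up$labels), c(7L, 7L, 7L))
  expect_equal(up$spacing, c(1, 1, 1))
  expect_error(trilinear_upsample(vol, 0L), "factor")
})

test_that("trilinear interpolation reduces surface reconstruction error", {
  rms <- function(m) {
    d <- sqrt(rowSums(m$vertices^2)) - 10
    sqrt(mean(d^2))
  }
  # both voxel-grid phases relative to the sphere centre
  for (pad in c(3, 4)) {
    vol <- sphere_volume(r = 10, spacing = 2, pad = pad)
    coarse <- rms(extract_surface(vol, 2L, smooth = FALSE))
    fine <- rms(extract_surface(vol, 2L, smooth = FALSE, upsample = 2))
    expect_lt(fine, coarse)
  }
})

test_that("extracted sphere surface matches analytic area, distance, topology", {
  vol <- sphere_volume(r = 10, spacing = 1)
  m <- extract_surface(vol, 2L)
  expect_lt(abs(mesh_area(m) / (4 * pi * 100) - 1), 0.05)
  d <- sqrt(rowSums(m$vertices^2)) - 10
  expect_lt(sqrt(mean(d^2)), sqrt(3) / 2)   # half the voxel diagonal
  expect_identical(euler_characteristic(m), 2L)
  expect_error(extract_surface(vol, 9L), "not present")
})

test_that("surface vertices translate exactly with the volume origin", {
  vol <- sphere_volume(r = 5, spacing = 1)
  m0 <- extract_surface(vol, 2L)
  vol2 <- vol
  vol2$origin <- vol$origin + c(10, -3, 7)
  m1 <- extract_surface(vol2, 2L)
  expect_equal(m1$vertices, sweep(m0$vertices, 2, -c(10, -3, 7)),
               tolerance = 1e-9)
})

test_that("PLY and STL mesh files round trip", {
  m <- generate_knee(flexion = 0)$meshes$patella
  ply <- file.path(tempdir(), "m.ply")
  stl <- file.path(tempdir(), "m.stl")
  write_ply(m, ply)
  back <- read_ply(ply)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_identical(back$faces, m$faces)
  write_stl(m, stl)
  back2 <- read_stl(stl)
  # STL welds shared vertices; compare areas and vertex sets
  expect_equal(mesh_area(back2), mesh_area(m), tolerance = 1e-5)
  expect_equal(nrow(back2$vertices), nrow(m$vertices))
  expect_error(read_ply(file.path(tempdir(), "absent.ply")), "not found")
  unlink(c(ply, stl))
})

test_that("degenerate faces are cleaned by the mesh constructor", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 0, 0))
  f <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L))  # second face has zero area
  m <- surface_mesh(v, f)
  expect_identical(nrow(m$faces), 1L)
  expect_error(surface_mesh(v, rbind(c(1L, 2L, 9L))), "out of range")
})
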