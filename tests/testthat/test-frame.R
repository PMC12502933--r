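make_cyl_fit <- function(dir, point = c(0, 0, 0)) {
  structure(list(axis_point = point, axis_dir = dir / sqrt(sum(dir^2)),
                 radius = 80, rms_residual = 0), class = "cylinder_fit")
}

# small symmetric head stand-in for frame construction
frame_test_mesh <- function() {
  sph <- auriclesym:::icosphere(2L)
  trimesh(sph$vertices %*% diag(c(60, 90, 70)), sph$faces)
}

test_that("canonical inputs give the standard basis", {
  mesh <- frame_test_mesh()
  fr <- build_frame(plane3(c(1, 0, 0), c(0, 0, 0)),
                    make_cyl_fit(c(0, 1, 0)), mesh,
                    auricle_centroids = rbind(c(-60, -10, 0), c(60, -10, 0)),
                    settings = measure_settings(anterior_override = c(0, 0, 1)))
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-9)
  expect_lt(abs(sum(fr$x_axis * fr$origin) - fr$midsagittal$offset), 1e-9)
})

test_that("y axis is orthogonalized against the midsagittal normal", {
  mesh <- frame_test_mesh()
  cyl <- make_cyl_fit(c(0.1, 0.995, 0))
  fr <- build_frame(plane3(c(1, 0, 0), c(0, 0, 0)), cyl, mesh,
                    auricle_centroids = rbind(c(-60, -10, 0), c(60, -10, 0)),
                    settings = measure_settings(anterior_override = c(0, 0, 1)))
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-9)
  expect_lt(abs(sum(fr$x_axis * fr$y_axis)), 1e-12)
})

test_that("frames are orthonormal and right-handed with origin on the plane", {
  set.seed(31)
  mesh <- frame_test_mesh()
  for (rep in 1:10) {
    nrm <- rnorm(3); cyl_dir <- rnorm(3)
    if (abs(sum(auriclesym:::.unit(nrm) * auriclesym:::.unit(cyl_dir))) >
        cos(10 * pi / 180)) next
    fr <- build_frame(plane3(nrm, rnorm(3, 0, 5)), make_cyl_fit(cyl_dir),
                      mesh, settings = measure_settings())
    M <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
    expect_equal(det(M), 1, tolerance = 1e-9)
    expect_lt(abs(sum(fr$midsagittal$normal * fr$origin) -
                    fr$midsagittal$offset), 1e-9)
  }
})

test_that("near-parallel plane normal and cylinder axis is rejected", {
  mesh <- frame_test_mesh()
  expect_error(
    build_frame(plane3(c(1, 0, 0), c(0, 0, 0)),
                make_cyl_fit(c(0.999, 0.04, 0)), mesh),
    class = "auriclesym_frame_error")
})

test_that("frame CSV round trip preserves the frame", {
  mesh <- frame_test_mesh()
  fr <- build_frame(plane3(c(1, 0.02, 0), c(1, 2, 3)),
                    make_cyl_fit(c(0.05, 1, 0.02)), mesh,
                    settings = measure_settings(anterior_override = c(0, 0, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame(fr, path)
  back <- read_frame(path)
  expect_equal(back$origin, fr$origin, tolerance = 1e-6)
  expect_equal(back$x_axis, fr$x_axis, tolerance = 1e-6)
  expect_equal(back$y_axis, fr$y_axis, tolerance = 1e-6)
  expect_equal(back$z_axis, fr$z_axis, tolerance = 1e-6)
})

test_that("frame coordinates invert the frame mapping", {
  mesh <- frame_test_mesh()
  fr <- build_frame(plane3(c(1, 0, 0), c(0, 0, 0)), make_cyl_fit(c(0, 1, 0)),
                    mesh, settings = measure_settings(anterior_override = c(0, 0, 1)))
  pts <- matrix(rnorm(30, 0, 40), ncol = 3)
  fc <- to_frame_coords(pts, fr)
  world <- sweep(fc %*% t(cbind(fr$x_axis, fr$y_axis, fr$z_axis)), 2,
                 -fr$origin)
  expect_equal(world, pts, tolerance = 1e-9)
})
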