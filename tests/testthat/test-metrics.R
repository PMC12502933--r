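identity_frame <- function() {
  structure(list(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                 y_axis = c(0, 1, 0), z_axis = c(0, 0, 1),
                 midsagittal = plane3(c(1, 0, 0), c(0, 0, 0))),
            class = "head_frame")
}

test_that("lateral selection keeps ties and obeys the keep fraction", {
  fr <- identity_frame()
  set.seed(6)
  pts <- cbind(runif(200, 60, 90), rnorm(200, 0, 20), rnorm(200, 0, 10))
  expect_equal(select_lateral_surface(pts, fr, "right", 1), pts)
  flat <- cbind(75, rnorm(50), rnorm(50))
  expect_equal(nrow(select_lateral_surface(flat, fr, "right", 0.5)), 50L)
  sel <- select_lateral_surface(pts, fr, "right", 0.3)
  expect_gt(mean(sel[, 1]), mean(pts[, 1]))
  # brute-force quantile oracle
  thr <- quantile(pts[, 1], 0.7, names = FALSE)
  expect_equal(nrow(sel), sum(pts[, 1] >= thr - 1e-9))
})

test_that("length and width come from projected principal extents", {
  fr <- identity_frame()
  # 60 x 30 rectangle in a tilted plane: corners give exact extents
  g <- as.matrix(expand.grid(u = seq(-30, 30, 2), w = seq(-15, 15, 1.5)))
  R <- withr::with_seed(9, random_rotation())
  pts <- cbind(g[, 1], g[, 2], 0) %*% t(R)
  lw <- measure_length_width(pts, fr)
  expect_equal(lw$length, 60, tolerance = 1e-9)
  expect_equal(lw$width, 30, tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 400)[-1]
  ell <- cbind(31 * cos(th), 15.5 * sin(th), 0) %*% t(R)
  lw2 <- measure_length_width(ell, fr)
  expect_equal(lw2$length, 62, tolerance = 0.5)
  expect_equal(lw2$width, 31, tolerance = 0.5)
})

test_that("auriculocephalic angle is the unsigned normal angle", {
  p1 <- plane3(c(0, 0, 1), c(0, 0, 0))
  expect_equal(measure_auriculocephalic_angle(p1, p1), 0)
  p2 <- plane3(c(0, 1, 1) / sqrt(2), c(0, 0, 0))
  expect_equal(measure_auriculocephalic_angle(p1, p2), 45, tolerance = 1e-9)
  # flipping a normal must not change the answer
  p3 <- plane3(-c(0, 1, 1) / sqrt(2), c(0, 0, 0))
  expect_equal(measure_auriculocephalic_angle(p1, p3), 45, tolerance = 1e-9)
})

test_that("protrusion is the outward maximum distance, clamped at zero", {
  pl <- plane3(c(0, 0, 1), c(0, 0, 0))
  on_plane <- cbind(rnorm(10), rnorm(10), 0)
  expect_equal(measure_protrusion(on_plane, pl), 0)
  pts <- rbind(c(0, 0, 5), c(1, 2, 18.5), c(0, 0, -40))
  expect_equal(measure_protrusion(pts, pl), 18.5)
  expect_warning(p0 <- measure_protrusion(cbind(0, 0, -(1:5)), pl))
  expect_equal(p0, 0)
  # oracle equivalence: brute-force max over vertices, 100 random cases
  set.seed(17)
  for (rep in 1:100) {
    pl_r <- plane3(rnorm(3), rnorm(3, 0, 5))
    pts_r <- matrix(rnorm(150, 0, 10), ncol = 3)
    brute <- max(drop(pts_r %*% pl_r$normal) - pl_r$offset)
    if (brute <= 0) next
    expect_equal(measure_protrusion(pts_r, pl_r), brute, tolerance = 1e-12)
  }
})

test_that("inclination is signed, posterior-lean positive", {
  fr <- identity_frame()
  g <- as.matrix(expand.grid(u = seq(-30, 30, 2), w = seq(-10, 10, 2)))
  upright <- cbind(5, g[, 1], g[, 2] * 0.3)   # elongated along +y
  expect_equal(measure_inclination(upright, fr), 0, tolerance = 1e-9)
  th <- 15 * pi / 180
  tilted <- cbind(5, g[, 1] * cos(th), -g[, 1] * sin(th) + g[, 2] * 0.2)
  expect_equal(measure_inclination(tilted, fr), 15, tolerance = 0.5)
  # near-circular flattened shape is rejected
  sq <- as.matrix(expand.grid(u = seq(-10, 10, 1), w = seq(-10, 10, 1)))
  circ <- cbind(5, sq[, 1], sq[, 2])
  expect_error(measure_inclination(circ, fr),
               class = "auriclesym_degenerate_error")
})

test_that("position differences project the centroid separation", {
  fr <- identity_frame()
  d <- measure_position_diff(c(-80, 5, 3), c(80, 5, 3), fr)
  expect_equal(d$superoinferior_diff, 0)
  expect_equal(d$posteroanterior_diff, 0)
  d2 <- measure_position_diff(c(-80, 8, 3), c(80, 5, 3), fr)
  expect_equal(d2$superoinferior_diff, 3)
  expect_equal(d2$posteroanterior_diff, 0)
})

test_that("manual measurement reproduces landmark formulas", {
  lm <- list(superaurale = c(0, 62, 0), subaurale = c(0, 0, 0),
             preaurale = c(0, 30, 10), postaurale = c(0, 30, -25),
             helix_lateral = c(20, 30, 0), mastoid_base = c(0, 30, 0),
             tragus = c(0, 30, 0))
  m <- manual_measurement(lm)
  expect_equal(m$length, 62)
  expect_equal(m$width, 35)
  expect_equal(m$protrusion, 20)
  expect_true(is.na(m$inclination))
  # right angle at the tragus
  lm$mastoid_base <- c(0, 30, -10)
  expect_equal(manual_measurement(lm)$acangle, 90)
  lm$helix_lateral <- NULL
  expect_error(manual_measurement(lm),
               class = "auriclesym_missing_landmark_error")
})

test_that("observer noise propagates into distances as sqrt(2)*sd", {
  a <- c(0, 0, 0); b <- c(0, 62, 0)
  sd_obs <- 1.2
  lens <- withr::with_seed(40, {
    vapply(seq_len(4000), function(k) {
      sqrt(sum(((a + rnorm(3, 0, sd_obs)) - (b + rnorm(3, 0, sd_obs)))^2))
    }, 0)
  })
  expect_equal(sd(lens), sqrt(2) * sd_obs, tolerance = 0.06)
})
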