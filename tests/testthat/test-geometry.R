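test_that("fit_plane interpolates coplanar points exactly", {
  pl <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  expect_lt(min(sum(abs(pl$normal - c(0, 0, 1))),
                sum(abs(pl$normal + c(0, 0, 1)))), 1e-12)
  set.seed(3)
  tri <- matrix(rnorm(9, sd = 10), 3)
  pl3 <- fit_plane(tri)
  expect_lt(max(abs(plane_distance(tri, pl3))), 1e-9)
})

test_that("fit_plane matches the smallest-eigenvector oracle on noisy clouds", {
  set.seed(11)
  n_true <- c(1, 2, 2) / 3
  basis <- qr.Q(qr(cbind(n_true, rnorm(3), rnorm(3))))
  for (rep in 1:20) {
    uv <- matrix(runif(2000, -30, 30), ncol = 2)
    pts <- uv %*% t(basis[, 2:3]) + matrix(rnorm(3000, 0, 0.01), ncol = 3)
    pl <- fit_plane(pts)
    # independent oracle: eigen-decomposition of the covariance
    ev <- eigen(cov(pts), symmetric = TRUE)$vectors[, 3]
    expect_gt(abs(sum(pl$normal * ev)), cos(1e-4))
    expect_gt(abs(sum(pl$normal * n_true)), cos(0.5 * pi / 180))
  }
})

test_that("fit_plane rejects degenerate input", {
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "auriclesym_degenerate_error")
  line <- outer(seq(0, 1, length.out = 10), c(1, 2, 3))
  expect_error(fit_plane(line), class = "auriclesym_degenerate_error")
})

test_that("project_to_plane is idempotent, exact and distance-minimizing", {
  set.seed(4)
  pl <- plane3(rnorm(3), rnorm(3, 0, 5))
  pts <- matrix(rnorm(300, 0, 10), ncol = 3)
  proj <- project_to_plane(pts, pl)
  expect_lt(max(abs(plane_distance(proj, pl))), 1e-9)
  expect_equal(project_to_plane(proj, pl), proj, tolerance = 1e-12)
  # displacement equals |signed distance|, along the normal
  d <- plane_distance(pts, pl)
  expect_equal(sqrt(rowSums((pts - proj)^2)), abs(d), tolerance = 1e-9)
  # no other plane point is closer (spot-check random candidates)
  cand <- project_to_plane(matrix(rnorm(300, 0, 20), ncol = 3), pl)
  for (i in 1:5) {
    dc <- sqrt(rowSums(sweep(cand, 2, pts[i, ])^2))
    expect_gte(min(dc) + 1e-12, abs(d[i]))
  }
})

test_that("principal_axes recovers box and ellipse geometry", {
  g <- as.matrix(expand.grid(x = seq(-30, 30, 1), y = seq(-15, 15, 1)))
  rect <- cbind(g, 0)
  ax <- principal_axes(rect, ref = c(1, 0, 0), ref2 = c(0, 1, 0))
  expect_equal(ax$extents, c(60, 30, 0), tolerance = 1e-9)
  expect_equal(abs(ax$axes[1, 1]), 1, tolerance = 1e-9)

  th <- seq(0, 2 * pi, length.out = 721)[-1]
  ell <- cbind(30 * cos(th), 15 * sin(th), 0)
  ax2 <- principal_axes(ell)
  expect_gt(abs(ax2$axes[1, 1]), cos(1 * pi / 180))

  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  ax3 <- principal_axes(two)
  expect_equal(ax3$extents[1], 10, tolerance = 1e-9)
  expect_equal(ax3$extents[2:3], c(0, 0), tolerance = 1e-9)

  expect_error(principal_axes(rbind(c(1, 1, 1), c(1, 1, 1))),
               class = "auriclesym_degenerate_error")
})

test_that("surface_centroid is area-weighted and resolution invariant", {
  # unit cube surface centered at the origin
  s <- 0.5
  quads <- list(
    rbind(c(-s,-s,-s), c(s,-s,-s), c(s,s,-s), c(-s,s,-s)),
    rbind(c(-s,-s,s), c(s,-s,s), c(s,s,s), c(-s,s,s)),
    rbind(c(-s,-s,-s), c(-s,s,-s), c(-s,s,s), c(-s,-s,s)),
    rbind(c(s,-s,-s), c(s,s,-s), c(s,s,s), c(s,-s,s)),
    rbind(c(-s,-s,-s), c(s,-s,-s), c(s,-s,s), c(-s,-s,s)),
    rbind(c(-s,s,-s), c(s,s,-s), c(s,s,s), c(-s,s,s)))
  verts <- do.call(rbind, quads)
  faces <- do.call(rbind, lapply(0:5, function(k)
    rbind(4 * k + c(1, 2, 3), 4 * k + c(1, 3, 4))))
  cube <- trimesh(verts, faces)
  expect_lt(max(abs(surface_centroid(cube))), 1e-9)

  tri <- trimesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                 rbind(c(1, 2, 3)))
  expect_equal(surface_centroid(tri), c(1, 1, 0), tolerance = 1e-12)

  # brute-force oracle on an irregular mesh
  set.seed(8)
  mesh <- tetrahedron_mesh()
  mesh$vertices <- mesh$vertices * 10 + matrix(rnorm(12), 4)
  acc <- c(0, 0, 0); tot <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    ar <- 0.5 * sqrt(sum(auriclesym:::.cross(tri[2, ] - tri[1, ],
                                             tri[3, ] - tri[1, ])^2))
    acc <- acc + ar * colMeans(tri); tot <- tot + ar
  }
  expect_equal(surface_centroid(mesh), acc / tot, tolerance = 1e-12)

  # refining the mesh must not move the centroid
  sph2 <- auriclesym:::icosphere(2L)
  sph4 <- auriclesym:::icosphere(4L)
  off <- c(12, -5, 30)
  c2 <- surface_centroid(trimesh(sweep(sph2$vertices * 40, 2, -off), sph2$faces))
  c4 <- surface_centroid(trimesh(sweep(sph4$vertices * 40, 2, -off), sph4$faces))
  expect_lt(max(abs(c2 - c4)), 1e-3)
})

test_that("geometric primitives are equivariant under rigid motion", {
  set.seed(21)
  pts <- matrix(rnorm(600, 0, 20), ncol = 3)
  mesh <- tetrahedron_mesh()
  for (rep in 1:5) {
    tf <- random_rigid()
    # plane
    pl <- fit_plane(pts)
    plT <- fit_plane(apply_rigid(pts, tf))
    nT <- drop(tf$rotation %*% pl$normal)
    expect_gt(abs(sum(plT$normal * nT)), 1 - 1e-9)
    # axes and extents
    ax <- principal_axes(pts)
    axT <- principal_axes(apply_rigid(pts, tf))
    expect_equal(axT$extents, ax$extents, tolerance = 1e-6)
    # centroid
    cT <- surface_centroid(apply_rigid(mesh, tf))
    expect_equal(cT, drop(apply_rigid(surface_centroid(mesh), tf)),
                 tolerance = 1e-9)
  }
})

test_that("uniform scaling scales extents and centroids, not normals", {
  set.seed(5)
  pts <- matrix(rnorm(300, 0, 10), ncol = 3)
  ax <- principal_axes(pts)
  ax2 <- principal_axes(pts * 2.5)
  expect_equal(ax2$extents, 2.5 * ax$extents, tolerance = 1e-9)
  pl <- fit_plane(pts)
  pl2 <- fit_plane(pts * 2.5)
  expect_gt(abs(sum(pl$normal * pl2$normal)), 1 - 1e-9)
})

test_that("vertex_areas sums to the total surface area", {
  sph <- auriclesym:::icosphere(2L)
  mesh <- trimesh(sph$vertices * 50, sph$faces)
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  total <- sum(0.5 * sqrt(rowSums(cr^2)))
  expect_equal(sum(vertex_areas(mesh)), total, tolerance = 1e-9)
})
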