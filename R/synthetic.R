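# Parametric synthetic head generator: a triangulated ellipsoid cranium with
# a nose bump (so the anterior direction is detectable), locally flattened
# mastoid patches, and per-side parametric auricles with exactly known
# length, width, protrusion, auriculocephalic angle, inclination and
# attachment position. Stands in for CT-derived head surfaces wherever the
# pipeline needs inputs with ground truth.

# Unit icosphere by recursive midpoint subdivision of the icosahedron. The
# icosahedron's vertex set is symmetric under negation of any coordinate, and
# subdivision preserves that, so generated heads are exactly mirror-symmetric
# vertex sets.
icosphere <- function(subdivisions = 4L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivisions)) {
    edge_cache <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- if (i < j) paste(i, j) else paste(j, i)
      hit <- get0(key, envir = edge_cache)
      if (!is.null(hit)) return(hit)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      assign(key, id, envir = edge_cache)
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4L * k - 3L):(4L * k), ] <-
        rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  trimesh(v, f)
}

# Triangulated unit disc: `nr` concentric rings of `ntheta` vertices plus the
# center. ntheta is a multiple of 4 so the four axis apexes are sampled
# exactly (extents must reach the true outermost points).
.disc_mesh <- function(nr, ntheta) {
  theta <- 2 * pi * (seq_len(ntheta) - 1L) / ntheta
  verts <- rbind(c(0, 0),
                 do.call(rbind, lapply(seq_len(nr), function(k)
                   cbind(cos(theta), sin(theta)) * (k / nr))))
  ring_start <- function(k) 2L + (k - 1L) * ntheta
  faces <- list()
  nxt <- c(seq_len(ntheta - 1L) + 1L, 1L)
  r1 <- ring_start(1L)
  faces[[1]] <- cbind(1L, r1 + seq_len(ntheta) - 1L, r1 + nxt - 1L)
  for (k in seq_len(nr - 1L)) {
    ri <- ring_start(k)
    ro <- ring_start(k + 1L)
    j <- seq_len(ntheta)
    faces[[k + 1L]] <- rbind(
      cbind(ri + j - 1L, ro + j - 1L, ro + nxt - 1L),
      cbind(ri + j - 1L, ro + nxt - 1L, ri + nxt - 1L))
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Per-side auricle specification
#'
#' True geometric parameters of one synthetic auricle. The auricle is a flat
#' elliptical shell (length x width) whose long axis lies in the local
#' mastoid tangent plane at the inclination angle from the cranial vertical,
#' hinged off that plane by the auriculocephalic angle and stood off along
#' the surface normal so its outermost point sits exactly at the protrusion
#' distance.
#'
#' @param length,width Ellipse axes (mm); `length > width`.
#' @param protrusion Distance (mm) of the outermost auricle point from the
#'   mastoid plane; must be at least `width * sin(acangle)`.
#' @param acangle Auriculocephalic hinge angle (degrees).
#' @param inclination Long-axis tilt from the cranial vertical (degrees,
#'   positive = superior tip leans posterior).
#' @param y_offset,z_offset Attachment position on the cranium (mm) relative
#'   to the lateral equator point.
#' @return Named list of the six true parameters.
#' @export
auricle_side_spec <- function(length = 62, width = 32, protrusion = 20,
                              acangle = 30, inclination = 25,
                              y_offset = -10, z_offset = 0) {
  if (length <= width || width <= 0)
    stop_input("auricle spec needs length > width > 0")
  if (protrusion < width * sin(deg2rad(acangle)))
    stop_input("protrusion must be >= width * sin(acangle) for the hinged shell")
  list(length = length, width = width, protrusion = protrusion,
       acangle = acangle, inclination = inclination,
       y_offset = y_offset, z_offset = z_offset)
}

#' Synthetic head specification
#'
#' @param semiaxes Cranium semi-axes (x lateral, y vertical,
#'   z anteroposterior at ear level and below), mm, of the superellipsoid
#'   `(x/a)^2 + (z/c(y))^2 + (y/b)^4 = 1`. The quartic vertical profile
#'   gives the vault near-vertical parietal walls (as real crania have),
#'   which makes the least-squares cylinder axis well identified. The
#'   anteroposterior semi-axis blends from `c` below ear level to `a`
#'   (circular cross-section) in the vault: an elliptical vault section
#'   rewards a tilted cylinder axis (foreshortening rounds the section),
#'   while a fully circular cranium is rotationally symmetric and leaves
#'   the midsagittal plane identifiable only through the ears and nose —
#'   the mixed profile avoids both degeneracies.
#' @param left,right Per-side [auricle_side_spec()] lists.
#' @param subdivisions Icosphere subdivision depth of the cranium (4 gives
#'   2562 vertices, about 5 mm edges at head scale).
#' @param ear_edge Target edge length (mm) of the auricle meshes.
#' @param noise_sd Isotropic Gaussian vertex displacement SD (mm), the
#'   scan-repeat noise model.
#' @param seed Seed governing the noise realization.
#' @param nose Add a frontal nose bump (required by the automatic
#'   anterior-direction rule).
#' @return Object of class `head_spec`.
#' @export
head_spec <- function(semiaxes = c(80, 108, 92),
                      left = auricle_side_spec(),
                      right = auricle_side_spec(),
                      subdivisions = 4L,
                      ear_edge = 1.2,
                      noise_sd = 0.1,
                      seed = 1L,
                      nose = TRUE) {
  if (length(semiaxes) != 3L || any(semiaxes <= 0))
    stop_input("semiaxes must be 3 positive lengths")
  if (ear_edge <= 0 || subdivisions < 2L)
    stop_input("resolution parameters out of range")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(semiaxes = as.numeric(semiaxes), left = left, right = right,
                 subdivisions = as.integer(subdivisions), ear_edge = ear_edge,
                 noise_sd = noise_sd, seed = as.integer(seed), nose = nose),
            class = "head_spec")
}

# Build one auricle at attachment point P0 with outward normal n0.
.build_auricle <- function(side_spec, P0, n0, ear_edge) {
  L <- side_spec$length
  W <- side_spec$width
  alpha <- deg2rad(side_spec$acangle)
  phi <- deg2rad(side_spec$inclination)
  h <- side_spec$protrusion - W * sin(alpha)

  yhat <- c(0, 1, 0)
  zhat <- c(0, 0, 1)
  yp <- .unit(yhat - sum(yhat * n0) * n0)
  zp <- zhat - sum(zhat * n0) * n0
  zp <- .unit(zp - sum(zp * yp) * yp)
  e1 <- cos(phi) * yp - sin(phi) * zp       # long axis, superior end at +u
  e2 <- .cross(n0, e1)
  if (sum(e2 * zhat) > 0) e2 <- -e2         # shell extends posteriorly
  d <- cos(alpha) * e2 + sin(alpha) * n0    # hinged width direction

  per <- pi * (L + W) / 2
  ntheta <- 4L * max(5L, ceiling(per / ear_edge / 4))
  nr <- max(5L, ceiling((W / 2) / ear_edge))
  disc <- .disc_mesh(nr, ntheta)
  u <- disc$vertices[, 1] * (L / 2)
  w <- (disc$vertices[, 2] + 1) * (W / 2)
  verts <- matrix(rep(P0 + h * n0, each = length(u)), ncol = 3L) +
    outer(u, e1) + outer(w, d)

  apex <- P0 + h * n0
  landmarks <- list(
    superaurale = apex + (L / 2) * e1 + (W / 2) * d,
    subaurale = apex - (L / 2) * e1 + (W / 2) * d,
    preaurale = apex,
    postaurale = apex + W * d,
    helix_lateral = apex + W * d,
    mastoid_base = P0 + W * cos(alpha) * e2,
    tragus = apex)
  list(vertices = verts, faces = disc$faces, landmarks = landmarks,
       e1 = e1, e2 = e2, d = d, h = h)
}

#' Generate a synthetic labeled head with known ground truth
#'
#' Constructs the cranium (ellipsoid + nose bump), flattens the two mastoid
#' patches onto their tangent planes, attaches the two parametric auricles,
#' labels auricle and mastoid vertex regions, places true anthropometric
#' landmarks, and (optionally) adds i.i.d. Gaussian vertex noise. Fully
#' deterministic given the spec's seed.
#'
#' @param spec A [head_spec()].
#' @return List with `head` (a [labeled_head()]) and `truth` — per-side true
#'   parameter values, the true noise-free auricle surface centroids, and the
#'   true bilateral position differences (`si_diff`, `pa_diff`, left minus
#'   right).
#' @export
generate_head <- function(spec) {
  if (!inherits(spec, "head_spec")) stop_input("spec must be a head_spec")
  a <- spec$semiaxes[1]; b <- spec$semiaxes[2]; cc <- spec$semiaxes[3]
  sphere <- icosphere(spec$subdivisions)
  uv <- sphere$vertices

  # anteroposterior semi-axis: c at/below ear level (y <= 0), blending to a
  # (circular section) by the bottom of the cylinder-fit vault band
  c_of_y <- function(y) {
    u <- pmin(pmax(y / 18, 0), 1)
    s <- 1 - (3 * u^2 - 2 * u^3)
    a + (cc - a) * s
  }

  # radial scale t per unit direction u so that t*u lies on the cranium
  # surface (x/a)^2 + (z/c(y))^2 + (y/b)^4 = 1; solved by bisection since
  # c depends on height
  cranium_scale <- function(u) {
    g <- function(t) {
      (t * u[, 1] / a)^2 + (t * u[, 3] / c_of_y(t * u[, 2]))^2 +
        (t * u[, 2] / b)^4 - 1
    }
    lo <- rep(0.25 * min(a, b, cc), nrow(u))
    hi <- rep(2 * max(a, b, cc), nrow(u))
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      pos <- g(mid) > 0
      hi[pos] <- mid[pos]
      lo[!pos] <- mid[!pos]
    }
    (lo + hi) / 2
  }

  # Nose bump: a compact cap low on the front face. Kept below the cranial
  # vault band (its fringe stays under y ~ 0.1*b) so the cylinder fit never
  # sees it, while still breaking the front/back area symmetry that the
  # anterior-direction rule relies on.
  bump <- 1
  if (isTRUE(spec$nose)) {
    dn <- .unit(c(0, -0.25, 0.95))
    cosang <- drop(uv %*% dn)
    c0 <- cos(deg2rad(20))
    s <- pmax(0, (cosang - c0) / (1 - c0))
    bump <- 1 + 0.22 * s^2
  }
  head_verts <- uv * (cranium_scale(uv) * bump)
  head_faces <- sphere$faces
  nh <- nrow(head_verts)

  r_flat <- 25   # mastoid patch flattening radius (mm)
  sides <- list(right = +1, left = -1)
  ears <- list()
  for (nm in names(sides)) {
    sgn <- sides[[nm]]
    ss <- spec[[nm]]
    c_att <- c_of_y(ss$y_offset)
    arg <- 1 - (ss$y_offset / b)^4 - (ss$z_offset / c_att)^2
    if (arg <= 0.25)
      stop_input("auricle attachment too far from the lateral equator")
    x0 <- sgn * a * sqrt(arg)
    P0 <- c(x0, ss$y_offset, ss$z_offset)
    n0 <- .unit(c(2 * x0 / a^2, 4 * ss$y_offset^3 / b^4,
                  2 * ss$z_offset / c_att^2))
    near <- which(sqrt(rowSums(sweep(head_verts, 2, P0)^2)) < r_flat)
    if (length(near) < 12L)
      stop_input("cranium resolution too coarse for the mastoid patch")
    dd <- drop(sweep(head_verts[near, , drop = FALSE], 2, P0) %*% n0)
    head_verts[near, ] <- head_verts[near, , drop = FALSE] - outer(dd, n0)
    ear <- .build_auricle(ss, P0, n0, spec$ear_edge)
    ear$P0 <- P0
    ear$n0 <- n0
    ear$patch_idx <- near
    ears[[nm]] <- ear
  }

  verts <- rbind(head_verts, ears$right$vertices, ears$left$vertices)
  nr_ <- nrow(ears$right$vertices)
  nl_ <- nrow(ears$left$vertices)
  faces <- rbind(head_faces,
                 ears$right$faces + nh,
                 ears$left$faces + nh + nr_)
  idx_right <- nh + seq_len(nr_)
  idx_left <- nh + nr_ + seq_len(nl_)
  annulus <- function(ear) {
    dd <- sqrt(rowSums(sweep(head_verts[ear$patch_idx, , drop = FALSE],
                             2, ear$P0)^2))
    ear$patch_idx[dd >= 5 & dd <= 20]
  }
  regions <- list(head = seq_len(nh),
                  auricle_right = idx_right,
                  auricle_left = idx_left,
                  mastoid_right = annulus(ears$right),
                  mastoid_left = annulus(ears$left))

  mesh0 <- trimesh(verts, faces)
  c_right <- surface_centroid(submesh(mesh0, idx_right))
  c_left <- surface_centroid(submesh(mesh0, idx_left))

  truth_side <- function(nm, ctr) {
    ss <- spec[[nm]]
    list(length = ss$length, width = ss$width, protrusion = ss$protrusion,
         acangle = ss$acangle, inclination = ss$inclination,
         centroid = ctr)
  }
  truth <- list(left = truth_side("left", c_left),
                right = truth_side("right", c_right),
                si_diff = c_left[2] - c_right[2],
                pa_diff = c_left[3] - c_right[3])

  if (spec$noise_sd > 0) {
    verts <- verts + with_seed(spec$seed,
                               matrix(rnorm(length(verts), 0, spec$noise_sd),
                                      ncol = 3L))
  }

  head <- labeled_head(trimesh(verts, faces), regions,
                       landmarks = list(left = ears$left$landmarks,
                                        right = ears$right$landmarks))
  list(head = head, truth = truth)
}

#' Cohort specification for synthetic subjects
#'
#' Inter-individual variation is normal around the base parameters; true
#' bilateral asymmetry is half-normal per parameter (magnitude `|N(0, s)|`,
#' random side), with scales chosen so that cohort maxima span several
#' millimetres / degrees; positional asymmetry enters through per-side
#' attachment offsets.
#'
#' @param n Number of subjects.
#' @param base_mean,base_sd Named vectors (length, width, protrusion,
#'   acangle, inclination) of the between-subject distribution.
#' @param asym_scale Named half-normal scales of true asymmetry for those
#'   five parameters plus `si` and `pa` attachment offsets (mm).
#' @param noise_sd Scan noise SD (mm) passed to every head.
#' @param subdivisions,ear_edge Mesh resolution, see [head_spec()].
#' @param seed Global seed; per-subject seeds are derived from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 20L,
                        base_mean = c(length = 62, width = 32,
                                      protrusion = 20, acangle = 30,
                                      inclination = 25),
                        base_sd = c(length = 4, width = 3, protrusion = 2.5,
                                    acangle = 4, inclination = 4),
                        asym_scale = c(length = 2.2, width = 3.0,
                                       protrusion = 3.5, acangle = 4.2,
                                       inclination = 3.0, si = 2.0,
                                       pa = 2.0),
                        noise_sd = 0.1,
                        subdivisions = 4L,
                        ear_edge = 1.2,
                        seed = 1L) {
  if (n < 1L) stop_input("cohort needs n >= 1")
  if (any(base_sd < 0) || any(asym_scale < 0))
    stop_input("SDs and asymmetry scales must be >= 0")
  structure(list(n = as.integer(n), base_mean = base_mean, base_sd = base_sd,
                 asym_scale = asym_scale, noise_sd = noise_sd,
                 subdivisions = as.integer(subdivisions),
                 ear_edge = ear_edge, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with a ground-truth table
#'
#' @param spec A [cohort_spec()].
#' @return List: `heads` (list of `generate_head()` results), `truth`
#'   (data.frame, one row per subject and side with the true parameters) and
#'   `bilateral_truth` (per-subject true signed `si_diff`/`pa_diff` and
#'   absolute parameter differences).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_input("spec must be a cohort_spec")
  pm <- spec$base_mean
  ps <- spec$base_sd
  as_ <- spec$asym_scale
  draws <- with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      base <- rnorm(5, pm, ps)
      names(base) <- names(pm)
      delta <- abs(rnorm(7, 0, as_)) *
        sample(c(-1, 1), 7, replace = TRUE)
      names(delta) <- names(as_)
      list(base = base, delta = delta)
    })
  })
  heads <- vector("list", spec$n)
  truth_rows <- list()
  bil_rows <- list()
  for (i in seq_len(spec$n)) {
    base <- draws[[i]]$base
    delta <- draws[[i]]$delta
    mk_side <- function(sgn) {
      v <- base + sgn * delta[names(pm)] / 2
      v[["width"]] <- max(v[["width"]], 15)
      v[["length"]] <- max(v[["length"]], v[["width"]] + 8)
      v[["acangle"]] <- min(max(v[["acangle"]], 8), 60)
      v[["protrusion"]] <- max(v[["protrusion"]],
                               v[["width"]] * sin(deg2rad(v[["acangle"]])) + 0.5)
      auricle_side_spec(length = v[["length"]], width = v[["width"]],
                        protrusion = v[["protrusion"]],
                        acangle = v[["acangle"]],
                        inclination = v[["inclination"]],
                        y_offset = -10 + sgn * delta[["si"]] / 2,
                        z_offset = sgn * delta[["pa"]] / 2)
    }
    hs <- head_spec(left = mk_side(+1), right = mk_side(-1),
                    subdivisions = spec$subdivisions,
                    ear_edge = spec$ear_edge,
                    noise_sd = spec$noise_sd,
                    seed = (spec$seed %% 1000003L) * 1000L + i)
    gh <- generate_head(hs)
    heads[[i]] <- gh
    for (sd_ in c("left", "right")) {
      tt <- gh$truth[[sd_]]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject = i, side = sd_, length = tt$length, width = tt$width,
        protrusion = tt$protrusion, acangle = tt$acangle,
        inclination = tt$inclination,
        centroid_x = tt$centroid[1], centroid_y = tt$centroid[2],
        centroid_z = tt$centroid[3])
    }
    bil_rows[[i]] <- data.frame(
      subject = i,
      si_diff = gh$truth$si_diff, pa_diff = gh$truth$pa_diff,
      length = abs(gh$truth$left$length - gh$truth$right$length),
      width = abs(gh$truth$left$width - gh$truth$right$width),
      protrusion = abs(gh$truth$left$protrusion - gh$truth$right$protrusion),
      acangle = abs(gh$truth$left$acangle - gh$truth$right$acangle),
      inclination = abs(gh$truth$left$inclination -
                          gh$truth$right$inclination))
  }
  list(heads = heads,
       truth = do.call(rbind, truth_rows),
       bilateral_truth = do.call(rbind, bil_rows))
}

#' Repeated scans of one specimen
#'
#' Same true geometry, independent noise realization per repeat — the
#' synthetic analogue of the repeated cadaver-scan precision experiment.
#'
#' @param spec A [head_spec()].
#' @param n_repeats Number of repeats (>= 2).
#' @param seed Base seed; repeat k uses `seed + k`.
#' @return List of `generate_head()` results sharing one truth.
#' @export
simulate_repeated_scans <- function(spec, n_repeats = 10L, seed = 100L) {
  if (n_repeats < 2L) stop_input("need at least 2 repeats")
  lapply(seq_len(n_repeats), function(k) {
    sp <- spec
    sp$seed <- as.integer(seed + k)
    generate_head(sp)
  })
}

#' Perturb landmarks with observer noise
#'
#' I.i.d. isotropic Gaussian displacement per landmark, modelling the placement
#' variability of a human anthropometrist.
#'
#' @param landmarks Named list of length-3 points.
#' @param observer_sd Per-coordinate SD (mm).
#' @param seed RNG seed.
#' @return Perturbed landmark list.
#' @export
perturb_landmarks <- function(landmarks, observer_sd = 1.5, seed = 1L) {
  if (observer_sd < 0) stop_input("observer_sd must be >= 0")
  if (observer_sd == 0) return(landmarks)
  with_seed(seed, lapply(landmarks, function(p)
    as.numeric(p) + rnorm(3, 0, observer_sd)))
}

#' Manual-method precision table by landmark Monte Carlo
#'
#' Estimates the per-parameter SD of the landmark-based manual measurement by
#' repeatedly perturbing true landmarks with observer noise and re-measuring.
#' The three parameters the manual method cannot measure (inclination and the
#' two positions) receive the supplied nominal SDs so that a complete
#' seven-parameter table is available for threshold scoring.
#'
#' @param landmarks True landmark set of one side.
#' @param observer_sd Landmark placement SD (mm).
#' @param n_rep Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param unmeasured_sd Named SDs for `inclination`, `si_position`,
#'   `pa_position`.
#' @return A `precision_table` (method `"manual"`).
#' @export
manual_precision_from_landmarks <- function(landmarks, observer_sd = 1.5,
                                            n_rep = 200L, seed = 7L,
                                            unmeasured_sd = c(
                                              inclination = 3,
                                              si_position = 2.5,
                                              pa_position = 2.5)) {
  reps <- lapply(seq_len(n_rep), function(k) {
    lm <- perturb_landmarks(landmarks, observer_sd, seed = seed * 100000L + k)
    m <- manual_measurement(lm)
    c(length = m$length, width = m$width, protrusion = m$protrusion,
      acangle = m$acangle)
  })
  tab <- precision_from_repeats(as.data.frame(do.call(rbind, reps)),
                                method = "manual")
  extra <- precision_table(unmeasured_sd, method = "manual")
  out <- rbind(tab, extra)
  class(out) <- c("precision_table", "data.frame")
  out
}

#' Write a self-contained fixture directory for one generated head
#'
#' PLY mesh + label CSV + landmark CSVs + truth CSV: everything needed to
#' re-measure the head without the generator.
#'
#' @param generated A `generate_head()` result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_mesh(generated$head$mesh, file.path(dir, "head.ply"))
  write_labels(generated$head$regions, file.path(dir, "labels.csv"))
  write_landmarks(generated$head$landmarks$left,
                  file.path(dir, "landmarks_left.csv"))
  write_landmarks(generated$head$landmarks$right,
                  file.path(dir, "landmarks_right.csv"))
  tt <- generated$truth
  df <- do.call(rbind, lapply(c("left", "right"), function(sd_) {
    t1 <- tt[[sd_]]
    data.frame(side = sd_, length = t1$length, width = t1$width,
               protrusion = t1$protrusion, acangle = t1$acangle,
               inclination = t1$inclination,
               centroid_x = t1$centroid[1], centroid_y = t1$centroid[2],
               centroid_z = t1$centroid[3])
  }))
  write.csv(df, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
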