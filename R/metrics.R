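# The seven auricle parameters of the surface-based pipeline: length, width,
# protrusion distance, auriculocephalic angle, inclination angle, and the
# superoinferior / posteroanterior bilateral position differences.

.param_names <- c("length", "width", "protrusion", "acangle", "inclination",
                  "si_position", "pa_position")

#' Select the most lateral auricle surface
#'
#' Keeps the auricle vertices whose lateral coordinate (along the outward x
#' direction for the given side) lies in the top `keep_fraction` quantile;
#' ties at the threshold are kept. With `keep_fraction = 1` all vertices are
#' returned.
#'
#' @param auricle Auricle [trimesh()] (or point matrix).
#' @param frame A `head_frame`.
#' @param side `"left"` or `"right"`.
#' @param keep_fraction Proportion in (0, 1].
#' @return Matrix of selected points.
#' @export
select_lateral_surface <- function(auricle, frame, side = c("left", "right"),
                                   keep_fraction = 1.0) {
  side <- match.arg(side)
  pts <- if (inherits(auricle, "trimesh")) auricle$vertices else
    as_point_matrix(auricle)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_input("keep_fraction must be in (0, 1]")
  if (keep_fraction == 1) return(pts)
  ctr <- colMeans(pts)
  outward <- frame$x_axis *
    sign(sum((ctr - frame$origin) * frame$x_axis))
  lat <- drop(sweep(pts, 2, frame$origin) %*% outward)
  thr <- quantile(lat, 1 - keep_fraction, names = FALSE)
  sel <- lat >= thr - 1e-9
  if (!any(sel)) stop_degenerate("lateral selection is empty")
  pts[sel, , drop = FALSE]
}

#' Auricle length and width by projected principal axes
#'
#' Fits a total-least-squares plane to the (lateral) auricle points, projects
#' the points into that plane, and takes the peak-to-peak extents along the
#' first two principal axes: length along the first, width along the second.
#'
#' @param lateral_points Points from [select_lateral_surface()].
#' @param frame A `head_frame` (fixes principal-axis signs).
#' @return List with `length`, `width` (mm), the fitted auricle `plane`, and
#'   the in-plane `axes` ([principal_axes()]).
#' @export
measure_length_width <- function(lateral_points, frame) {
  pts <- as_point_matrix(lateral_points)
  pl <- fit_plane(pts)
  proj <- project_to_plane(pts, pl)
  ax <- principal_axes(proj, ref = frame$y_axis, ref2 = frame$z_axis)
  list(length = ax$extents[1], width = ax$extents[2], plane = pl, axes = ax)
}

#' Mastoid plane behind the auricle
#'
#' Fits a plane to the mastoid region: the labeled mastoid vertices when
#' present, otherwise head vertices inside an annulus around the auricle
#' centroid's projection onto the head surface (auricle vertices excluded).
#'
#' @param labeled A [labeled_head()].
#' @param side `"left"` or `"right"`.
#' @param frame A `head_frame`.
#' @param settings A [measure_settings()] list (annulus radii).
#' @return A [plane3()] with normal canonicalized outward (away from the
#'   frame origin).
#' @export
mastoid_plane <- function(labeled, side = c("left", "right"), frame,
                          settings = measure_settings()) {
  side <- match.arg(side)
  lab <- labeled$regions[[paste0("mastoid_", side)]]
  verts <- labeled$mesh$vertices
  if (!is.null(lab) && length(lab) >= 10L) {
    pts <- verts[lab, , drop = FALSE]
  } else {
    ear_idx <- labeled$regions[[paste0("auricle_", side)]]
    ear_ctr <- surface_centroid(auricle_submesh(labeled, side))
    head_idx <- setdiff(seq_len(nrow(verts)),
                        c(labeled$regions$auricle_left,
                          labeled$regions$auricle_right))
    hv <- verts[head_idx, , drop = FALSE]
    # project the ear centroid to the nearest head vertex, then take the
    # annulus around that point
    nn <- .closest_point_idx(matrix(ear_ctr, 1), hv)
    center <- hv[nn, ]
    d <- sqrt(rowSums(sweep(hv, 2, center)^2))
    sel <- d >= settings$mastoid_annulus[1] & d <= settings$mastoid_annulus[2]
    pts <- hv[sel, , drop = FALSE]
  }
  if (nrow(pts) < 10L)
    stop_degenerate(paste0("too few mastoid points (", nrow(pts),
                           ") on side ", side))
  pl <- fit_plane(pts)
  if (sum(pl$normal * (pl$point - frame$origin)) < 0)
    pl <- plane3(-pl$normal, pl$point)
  pl
}

#' Auriculocephalic angle between two planes
#'
#' The unsigned angle between plane normals, `acos(|n1 . n2|)` in degrees,
#' in \[0, 90\]. The reference plane is the mastoid plane by default, or the
#' midsagittal plane under the `reference_plane = "midsagittal"` setting.
#'
#' @param auricle_plane,reference_plane [plane3()] objects.
#' @return Angle in degrees.
#' @export
measure_auriculocephalic_angle <- function(auricle_plane, reference_plane) {
  ca <- abs(sum(auricle_plane$normal * reference_plane$normal))
  rad2deg(acos(min(1, ca)))
}

#' Protrusion distance from the mastoid plane
#'
#' The largest perpendicular distance from the mastoid plane to any auricle
#' point, on the outward (lateral) side of the plane; distances toward the
#' head interior do not contribute.
#'
#' @param auricle_points Auricle points.
#' @param mastoid A [plane3()] with outward normal (see [mastoid_plane()]).
#' @return Distance in mm (0, with a warning, if every point lies on the
#'   interior side).
#' @export
measure_protrusion <- function(auricle_points, mastoid) {
  pts <- as_point_matrix(auricle_points)
  d <- plane_distance(pts, mastoid)
  m <- max(d)
  if (m < 0) {
    warning("all auricle points lie on the interior side of the mastoid plane")
    return(0)
  }
  m
}

#' Inclination angle of the auricle in the midsagittal projection
#'
#' Projects the auricle points onto the midsagittal plane, takes the first
#' principal axis of the flattened shape, and reports the signed angle
#' between that axis and the +y axis, in (-90, 90\]. Positive values mean the
#' superior tip leans posterior (toward -z).
#'
#' @param auricle_points Auricle points.
#' @param frame A `head_frame`.
#' @return Angle in degrees.
#' @export
measure_inclination <- function(auricle_points, frame) {
  pts <- as_point_matrix(auricle_points)
  flat <- project_to_plane(pts, frame$midsagittal)
  ax <- principal_axes(flat, ref = frame$y_axis, ref2 = frame$z_axis)
  if (ax$extents[2] <= 0 || ax$extents[1] / max(ax$extents[2], 1e-12) < 1.05)
    stop_degenerate("inclination axis ill-defined: flattened shape near-circular")
  a <- ax$axes[, 1]
  ay <- sum(a * frame$y_axis)
  az <- sum(a * frame$z_axis)
  ang <- rad2deg(atan2(-az, ay))
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Bilateral position differences of the auricle centroids
#'
#' Signed left-minus-right components of the vector between the auricle
#' centroids along the +y (superoinferior) and +z (posteroanterior) axes.
#'
#' @param centroid_left,centroid_right Length-3 centroids (world
#'   coordinates, mm).
#' @param frame A `head_frame`.
#' @return List with `superoinferior_diff` and `posteroanterior_diff` (mm).
#' @export
measure_position_diff <- function(centroid_left, centroid_right, frame) {
  d <- as.numeric(centroid_left) - as.numeric(centroid_right)
  list(superoinferior_diff = sum(d * frame$y_axis),
       posteroanterior_diff = sum(d * frame$z_axis))
}

#' Measure all auricle parameters of a labeled head
#'
#' Full surface-based pipeline: symmetry plane, cylinder-fit cranial axis and
#' head frame, then per-side length, width, protrusion, auriculocephalic
#' angle, inclination and centroid, plus the bilateral position differences.
#' Deterministic for fixed `settings`.
#'
#' @param labeled A [labeled_head()].
#' @param settings A [measure_settings()] list.
#' @return List of class `auricle_measurement`: `left` and `right`
#'   (each with `length`, `width`, `protrusion`, `acangle`, `inclination` and
#'   `centroid` in head-frame coordinates), `bilateral`
#'   (signed position differences), `frame`, and `settings`.
#' @export
measure_all <- function(labeled, settings = measure_settings()) {
  if (!inherits(labeled, "labeled_head")) stop_input("need a labeled_head")
  head <- labeled$mesh
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        paste0("stage '", name, "': ", conditionMessage(e)),
        class = unique(c(class(e)[startsWith(class(e), "auriclesym")],
                         "auriclesym_error"))))
    })
  }

  # The symmetry plane is estimated from the head without the auricle
  # regions: the frame is the reference the ears are measured against, and
  # letting bilaterally asymmetric ears pull on the mirror registration
  # would bend that reference toward the asymmetry being quantified.
  ear_region <- c(labeled$regions$auricle_left, labeled$regions$auricle_right)
  head_vidx <- setdiff(seq_len(nrow(head$vertices)), ear_region)
  head_noears <- submesh(head, head_vidx)

  midsag <- stage("symmetry_plane", find_symmetry_plane(head_noears, settings))

  ear_left <- auricle_submesh(labeled, "left")
  ear_right <- auricle_submesh(labeled, "right")
  c_left <- surface_centroid(ear_left)
  c_right <- surface_centroid(ear_right)

  # cranial-vault band for the cylinder fit, measured along the candidate
  # long axis with its superior end away from the ears; auricle vertices are
  # excluded so the dense ear meshes cannot bias the cranial axis
  verts <- head_noears$vertices
  pca1 <- principal_axes(verts)$axes[, 1]
  tv <- drop(verts %*% pca1)
  tc <- mean(rbind(c_left, c_right) %*% pca1)
  s <- if ((max(tv) - tc) >= (tc - min(tv))) 1 else -1
  # The band is re-selected along the fitted axis and the fit repeated: the
  # initial PCA axis can be tilted by asymmetric features (e.g. the nose),
  # making the first band an oblique slab; a band perpendicular to the true
  # cranial axis is a fixed point of this iteration.
  axis <- s * pca1
  cyl <- NULL
  ear_verts <- rbind(ear_left$vertices, ear_right$vertices)
  for (k in 1:3) {
    tvs <- drop(verts %*% axis)
    ear_top <- max(ear_verts %*% axis)
    lo <- ear_top + settings$cylinder_margin
    band <- which(tvs >= lo & tvs <= lo + settings$cylinder_band)
    if (length(band) < 6L)
      stop_degenerate("cranial-vault band contains too few vertices")
    band <- band[subsample_idx(length(band), settings$cylinder_subsample,
                               settings$cylinder_seed)]
    cyl <- stage("cylinder_fit",
                 fit_cylinder(verts[band, , drop = FALSE], init_dir = axis))
    newaxis <- cyl$axis_dir
    if (sum(newaxis * axis) < 0) newaxis <- -newaxis
    axis <- newaxis
  }

  frame <- stage("build_frame",
                 build_frame(midsag, cyl, head,
                             auricle_centroids = rbind(c_left, c_right),
                             anterior_mesh = head_noears,
                             settings = settings))

  measure_side <- function(side, ear, ctr) {
    lat <- select_lateral_surface(ear, frame, side, settings$keep_fraction)
    lw <- measure_length_width(lat, frame)
    mast <- mastoid_plane(labeled, side, frame, settings)
    refpl <- if (settings$reference_plane == "mastoid") mast else
      frame$midsagittal
    list(length = lw$length,
         width = lw$width,
         protrusion = measure_protrusion(ear$vertices, mast),
         acangle = measure_auriculocephalic_angle(lw$plane, refpl),
         inclination = measure_inclination(ear$vertices, frame),
         centroid = drop(to_frame_coords(ctr, frame)),
         centroid_world = ctr,
         auricle_plane = lw$plane,
         mastoid_plane = mast)
  }
  left <- stage("measure_left", measure_side("left", ear_left, c_left))
  right <- stage("measure_right", measure_side("right", ear_right, c_right))
  bilateral <- measure_position_diff(c_left, c_right, frame)

  structure(list(left = left, right = right, bilateral = bilateral,
                 frame = frame, settings = settings),
            class = "auricle_measurement")
}

#' @export
print.auricle_measurement <- function(x, ...) {
  fmt <- function(s) sprintf(
    "  %-5s length %6.2f  width %6.2f  protrusion %6.2f  acangle %6.2f  inclination %6.2f",
    s, x[[tolower(s)]]$length, x[[tolower(s)]]$width,
    x[[tolower(s)]]$protrusion, x[[tolower(s)]]$acangle,
    x[[tolower(s)]]$inclination)
  cat("<auricle_measurement> (mm / degrees)\n")
  cat(fmt("Left"), "\n")
  cat(fmt("Right"), "\n")
  cat(sprintf("  position diff (L-R): SI %+.2f  PA %+.2f\n",
              x$bilateral$superoinferior_diff,
              x$bilateral$posteroanterior_diff))
  invisible(x)
}

#' Flatten a measurement into a two-row data frame
#'
#' One row per side with the seven parameters and head-frame centroid
#' coordinates — the per-head unit that cohort tables are built from.
#'
#' @param m An `auricle_measurement`.
#' @param subject Subject identifier.
#' @return data.frame with columns `subject`, `side`, the five per-side
#'   parameters, and `centroid_x/y/z`.
#' @export
measurement_row <- function(m, subject = NA_character_) {
  row <- function(side) {
    p <- m[[side]]
    data.frame(subject = subject, side = side,
               length = p$length, width = p$width, protrusion = p$protrusion,
               acangle = p$acangle, inclination = p$inclination,
               centroid_x = p$centroid[1], centroid_y = p$centroid[2],
               centroid_z = p$centroid[3])
  }
  rbind(row("left"), row("right"))
}
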