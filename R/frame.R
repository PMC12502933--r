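# Head-centric coordinate frame: x lateral (midsagittal normal), y superior
# (cylinder-fit cranial axis), z anterior, right-handed, origin on the
# midsagittal plane.

#' Algorithm settings for the measurement pipeline
#'
#' One settings bundle shared by frame construction and the auricle
#' measurements; all pipeline randomness (vertex subsampling) is governed by
#' `icp_seed`/`cylinder_seed`, making runs deterministic.
#'
#' @param icp_subsample Vertex subsample size used as the moving cloud in
#'   symmetry-plane ICP.
#' @param icp_max_iter,icp_tol ICP iteration cap and relative RMS improvement
#'   tolerance.
#' @param icp_seed,cylinder_seed Seeds for the deterministic subsampling.
#' @param icp_trim Fraction of worst matches discarded per ICP iteration;
#'   keeps bilaterally asymmetric anatomy (which has no mirror counterpart)
#'   from dragging the symmetry plane.
#' @param cylinder_margin Gap (mm) between the auricle top and the lower edge
#'   of the cranial-vault band used for the cylinder fit.
#' @param cylinder_band Height (mm) of that vault band.
#' @param cylinder_subsample Maximum number of band vertices fed to the
#'   cylinder solver.
#' @param keep_fraction Lateral-surface quantile kept by
#'   [select_lateral_surface()]; 1 uses the whole auricle submesh.
#' @param reference_plane Reference for the auriculocephalic angle:
#'   `"mastoid"` (default) or `"midsagittal"`.
#' @param mastoid_annulus Inner/outer radii (mm) of the automatic mastoid
#'   annulus used when no mastoid labels are present.
#' @param anterior_override Optional length-3 vector forcing the anterior
#'   (+z) direction instead of the surface-area hemisphere rule.
#' @return Named list of settings.
#' @export
measure_settings <- function(icp_subsample = 5000L,
                             icp_max_iter = 100L,
                             icp_tol = 1e-8,
                             icp_seed = 1L,
                             icp_trim = 0,
                             cylinder_seed = 2L,
                             cylinder_margin = 5,
                             cylinder_band = 45,
                             cylinder_subsample = 4000L,
                             keep_fraction = 1.0,
                             reference_plane = c("mastoid", "midsagittal"),
                             mastoid_annulus = c(5, 20),
                             anterior_override = NULL) {
  reference_plane <- match.arg(reference_plane)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop_config("keep_fraction must be in (0, 1]")
  if (length(mastoid_annulus) != 2L || mastoid_annulus[1] < 0 ||
      mastoid_annulus[2] <= mastoid_annulus[1])
    stop_config("mastoid_annulus must be increasing radii (inner, outer)")
  list(icp_subsample = as.integer(icp_subsample),
       icp_max_iter = as.integer(icp_max_iter),
       icp_tol = icp_tol,
       icp_seed = as.integer(icp_seed),
       icp_trim = icp_trim,
       cylinder_seed = as.integer(cylinder_seed),
       cylinder_margin = cylinder_margin,
       cylinder_band = cylinder_band,
       cylinder_subsample = as.integer(cylinder_subsample),
       keep_fraction = keep_fraction,
       reference_plane = reference_plane,
       mastoid_annulus = mastoid_annulus,
       anterior_override = anterior_override)
}

#' Build the head coordinate frame
#'
#' Combines the midsagittal plane (its normal becomes the x-axis) and the
#' cylinder-fit cranial axis (y-axis, orthogonalized against x) into a
#' right-handed orthonormal frame. Orientation conventions, which the frame
#' makes deterministic: +y points superior — toward the head extreme along
#' the cranial axis farther from the mean auricle centroid; +z points
#' anterior — toward the hemisphere of `anterior_mesh` with the larger
#' surface area (the nose side), overridable via
#' `settings$anterior_override`; +x completes the right-handed frame
#' (x = y × z). The origin is the head surface centroid projected onto the
#' midsagittal plane.
#'
#' @param midsagittal A [plane3()] from [find_symmetry_plane()].
#' @param cyl A `cylinder_fit` from [fit_cylinder()] on the cranial vault.
#' @param head The head [trimesh()].
#' @param auricle_centroids Optional 2 x 3 matrix of left/right auricle
#'   centroids, used by the superior-direction rule.
#' @param anterior_mesh Mesh used for the anterior hemisphere-area rule;
#'   defaults to `head`. Pass the head with auricle faces removed when ear
#'   shapes would bias the area comparison.
#' @param settings A [measure_settings()] list.
#' @return Object of class `head_frame`: `origin`, unit `x_axis`, `y_axis`,
#'   `z_axis`, and the canonicalized `midsagittal` plane.
#' @export
build_frame <- function(midsagittal, cyl, head, auricle_centroids = NULL,
                        anterior_mesh = head,
                        settings = measure_settings()) {
  x0 <- midsagittal$normal
  ydir <- cyl$axis_dir
  cosang <- abs(sum(x0 * ydir))
  if (cosang > cos(deg2rad(10)))
    stop_cond("frame", "midsagittal normal and cylinder axis are near-parallel")
  y <- .unit(ydir - sum(ydir * x0) * x0)

  # superior: head extreme along y farther from the auricles
  tvals <- drop(head$vertices %*% y)
  tc <- if (!is.null(auricle_centroids)) {
    mean(as_point_matrix(auricle_centroids) %*% y)
  } else {
    mean(tvals)
  }
  if ((max(tvals) - tc) < (tc - min(tvals))) y <- -y

  z <- .cross(x0, y)
  origin <- drop(project_to_plane(surface_centroid(head), midsagittal))

  # anterior: the face (nose) side protrudes farther from the cranial axis
  # than the occiput, so +z points toward the larger extent
  flip_z <- FALSE
  if (!is.null(settings$anterior_override)) {
    flip_z <- sum(z * settings$anterior_override) < 0
  } else {
    zc <- drop(sweep(anterior_mesh$vertices, 2, origin) %*% z)
    flip_z <- max(zc) < -min(zc)
  }
  if (flip_z) z <- -z
  x <- .cross(y, z)
  structure(list(origin = origin, x_axis = x, y_axis = y, z_axis = z,
                 midsagittal = plane3(x, origin)),
            class = "head_frame")
}

#' @export
print.head_frame <- function(x, ...) {
  cat("<head_frame>\n")
  cat("  origin:", sprintf("%.2f", x$origin), "\n")
  cat("  x:", sprintf("%.4f", x$x_axis), "\n")
  cat("  y:", sprintf("%.4f", x$y_axis), "\n")
  cat("  z:", sprintf("%.4f", x$z_axis), "\n")
  invisible(x)
}

#' Express points in head-frame coordinates
#'
#' @param points Points in world coordinates.
#' @param frame A `head_frame`.
#' @return `n x 3` matrix of coordinates along (x, y, z) relative to the
#'   frame origin.
#' @export
to_frame_coords <- function(points, frame) {
  pts <- as_point_matrix(points)
  sweep(pts, 2, frame$origin) %*%
    cbind(frame$x_axis, frame$y_axis, frame$z_axis)
}

#' Write / read a head frame as CSV
#'
#' Four rows (origin, x, y, z) with columns `entity,x,y,z`, for reproducible
#' export of the coordinate system.
#'
#' @param frame A `head_frame`.
#' @param path CSV path.
#' @export
write_frame <- function(frame, path) {
  df <- data.frame(entity = c("origin", "x_axis", "y_axis", "z_axis"),
                   rbind(frame$origin, frame$x_axis, frame$y_axis,
                         frame$z_axis))
  names(df)[2:4] <- c("x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  get_row <- function(nm) as.numeric(df[df$entity == nm, c("x", "y", "z")])
  origin <- get_row("origin")
  x <- .unit(get_row("x_axis"))
  structure(list(origin = origin, x_axis = x,
                 y_axis = .unit(get_row("y_axis")),
                 z_axis = .unit(get_row("z_axis")),
                 midsagittal = plane3(x, origin)),
            class = "head_frame")
}
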