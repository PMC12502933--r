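#' Least-squares cylinder fit
#'
#' Fits an infinite circular cylinder to a point cloud by nonlinear least
#' squares on the residuals (distance-to-axis minus radius), used to recover
#' the cranial long axis that defines the head frame's +y direction. The axis
#' direction is parameterized as a perturbation of `init_dir`, the axis point
#' as an in-plane offset from the point centroid, and the solver is
#' Levenberg-Marquardt.
#'
#' @param points `n x 3` matrix, at least 6 points with spread transverse to
#'   the axis.
#' @param init_dir Initial axis direction; defaults to the cloud's first
#'   principal axis.
#' @return Object of class `cylinder_fit`: `axis_point` (mm), `axis_dir`
#'   (unit), `radius` (mm), `rms_residual` (mm).
#' @export
fit_cylinder <- function(points, init_dir = NULL) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 6L) stop_input("cylinder fit needs at least 6 points")
  if (is.null(init_dir)) init_dir <- principal_axes(pts)$axes[, 1]
  d0 <- .unit(as.numeric(init_dir))
  basis <- .orthobasis(d0)
  u <- basis[, 1]
  v <- basis[, 2]
  c0 <- colMeans(pts)

  geom <- function(par) {
    dirv <- .unit(d0 + par[1] * u + par[2] * v)
    cpt <- c0 + par[3] * u + par[4] * v
    rel <- sweep(pts, 2, cpt)
    ax <- drop(rel %*% dirv)
    rad <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
    list(dir = dirv, cpt = cpt, rad = rad)
  }
  resid_fn <- function(par) {
    g <- geom(par)
    g$rad - par[5]
  }
  rel0 <- sweep(pts, 2, c0)
  ax0 <- drop(rel0 %*% d0)
  r0 <- mean(sqrt(pmax(rowSums(rel0^2) - ax0^2, 0)))
  if (r0 < 1e-9)
    stop_degenerate("points have no radial spread about the initial axis")
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(0, 0, 0, 0, r0), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            maxfev = 5000)),
    error = function(e) stop_fit(paste0("cylinder solver failed: ",
                                        conditionMessage(e))))
  if (!fit$info %in% 1:4)
    stop_fit(paste0("cylinder solver did not converge (info = ", fit$info,
                    "): ", fit$message))
  g <- geom(fit$par)
  res <- g$rad - fit$par[5]
  structure(list(axis_point = g$cpt, axis_dir = g$dir,
                 radius = abs(fit$par[5]),
                 rms_residual = sqrt(mean(res^2))),
            class = "cylinder_fit")
}

# Orthonormal basis of the plane perpendicular to `d` (columns u, v).
.orthobasis <- function(d) {
  d <- .unit(d)
  seed <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross(d, seed))
  v <- .cross(d, u)
  cbind(u, v)
}
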