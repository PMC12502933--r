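#' Triangulated surface mesh
#'
#' A minimal triangle-mesh container: vertex coordinates in millimetres and
#' 1-based triangle vertex indices. All pipeline geometry flows through this
#' type.
#'
#' @param vertices Numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces Integer `m x 3` matrix of 1-based vertex indices.
#' @return An object of class `trimesh` with elements `vertices` and `faces`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices)
  if (is.null(dim(faces))) faces <- matrix(faces, ncol = 3L, byrow = TRUE)
  faces <- unname(as.matrix(faces))
  if (ncol(faces) != 3L) stop_input("faces must be an m x 3 index matrix")
  storage.mode(faces) <- "integer"
  if (nrow(vertices) < 3L) stop_input("a mesh needs at least 3 vertices")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop_input("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop_input("degenerate face: repeated vertex index")
  }
  structure(list(vertices = vertices, faces = faces), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Oriented plane
#'
#' A plane stored as a unit normal and a point on the plane. The sign of the
#' normal is canonicalized by consuming operations, never globally.
#'
#' @param normal Length-3 vector; normalized internally.
#' @param point Length-3 point on the plane (mm).
#' @return Object of class `plane3` with `normal`, `point` and signed `offset`
#'   (`normal . point`).
#' @export
plane3 <- function(normal, point) {
  normal <- .unit(as.numeric(normal))
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    stop_input("plane point must be a finite length-3 vector")
  structure(list(normal = normal, point = point,
                 offset = sum(normal * point)),
            class = "plane3")
}

#' Signed distances from points to a plane
#'
#' @param points Points (vector of 3 or `n x 3` matrix).
#' @param plane A [plane3()].
#' @return Numeric vector of signed perpendicular distances (mm), positive on
#'   the side the normal points to.
#' @export
plane_distance <- function(points, plane) {
  pts <- as_point_matrix(points)
  drop(pts %*% plane$normal) - plane$offset
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared perpendicular residuals: the
#' plane through the centroid whose normal is the direction of smallest
#' spread (smallest right singular vector of the centered coordinates).
#'
#' @param points At least 3 non-collinear points.
#' @return A [plane3()].
#' @export
fit_plane <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3L) stop_degenerate("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  if (sv$d[2] <= max(sv$d[1] * 1e-12, 1e-12))
    stop_degenerate("plane fit is degenerate: points are (near-)collinear")
  plane3(sv$v[, 3], ctr)
}

#' Orthogonal projection of points onto a plane
#'
#' @inheritParams plane_distance
#' @return Matrix of projected points; idempotent, every output point has
#'   signed plane distance 0.
#' @export
project_to_plane <- function(points, plane) {
  pts <- as_point_matrix(points)
  d <- drop(pts %*% plane$normal) - plane$offset
  pts - outer(d, plane$normal)
}

#' Principal axes and peak-to-peak extents of a point cloud
#'
#' Eigen-decomposition of the point covariance, axes ordered by decreasing
#' eigenvalue. Extents are peak-to-peak projections ("distance between the
#' outermost points"), not eigenvalue-derived spreads. Eigenvector signs are
#' arbitrary, so each axis is flipped if needed to have a non-negative dot
#' product with `ref` (ties, i.e. near-orthogonal axes, are broken toward
#' `ref2`).
#'
#' @param points At least 2 distinct points.
#' @param ref,ref2 Reference directions fixing axis signs; defaults are the
#'   head-frame +y and +z.
#' @return Object of class `principal_axes`: `center` (mean point), `axes`
#'   (3 x 3 matrix, axes in columns), `extents` (non-increasing, mm).
#' @export
principal_axes <- function(points, ref = c(0, 1, 0), ref2 = c(0, 0, 1)) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 2L) stop_degenerate("principal axes need at least 2 points")
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (max(abs(cen)) < 1e-12)
    stop_degenerate("principal axes undefined: all points identical")
  ev <- eigen(crossprod(cen) / (nrow(pts) - 1), symmetric = TRUE)
  axes <- ev$vectors
  for (k in 1:3) {
    d <- sum(axes[, k] * ref)
    if (abs(d) < 1e-9) d <- sum(axes[, k] * ref2)
    if (d < 0) axes[, k] <- -axes[, k]
  }
  proj <- cen %*% axes
  extents <- apply(proj, 2, function(x) max(x) - min(x))
  structure(list(center = ctr, axes = axes, extents = extents),
            class = "principal_axes")
}

#' Area-weighted surface centroid of a mesh
#'
#' The centroid of the triangle surface (triangle centroids weighted by
#' triangle area), which is invariant to remeshing density — unlike the plain
#' vertex mean.
#'
#' @param mesh A [trimesh()] with at least one face.
#' @return Length-3 centroid (mm).
#' @export
surface_centroid <- function(mesh) {
  if (!inherits(mesh, "trimesh")) stop_input("mesh must be a trimesh")
  if (nrow(mesh$faces) < 1L) stop_degenerate("surface centroid needs faces")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  ccc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- ccc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  tot <- sum(area)
  if (tot <= 0) stop_degenerate("zero total surface area")
  centers <- (a + b + ccc) / 3
  colSums(centers * area) / tot
}

#' Rigid (rotation + translation) transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (!all(dim(rotation) == c(3L, 3L)))
    stop_input("rotation must be 3 x 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      det(rotation) < 0)
    stop_input("rotation must be orthonormal with det +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a mesh
#'
#' @param x Points (`n x 3`) or a [trimesh()].
#' @param transform A [rigid_transform()].
#' @return Transformed points or mesh.
#' @export
apply_rigid <- function(x, transform) {
  if (inherits(x, "trimesh")) {
    x$vertices <- apply_rigid(x$vertices, transform)
    return(x)
  }
  pts <- as_point_matrix(x)
  sweep(pts %*% t(transform$rotation), 2, -transform$translation)
}

#' Reflect points across a plane
#'
#' @inheritParams plane_distance
#' @return Mirrored points.
#' @export
reflect_across_plane <- function(points, plane) {
  pts <- as_point_matrix(points)
  d <- drop(pts %*% plane$normal) - plane$offset
  pts - 2 * outer(d, plane$normal)
}

#' Per-vertex surface area
#'
#' One third of the total area of the triangles incident to each vertex — the
#' standard barycentric area weight, used to make vertex subsampling
#' independent of local mesh density.
#'
#' @param mesh A [trimesh()].
#' @return Numeric vector, one area (mm^2) per vertex.
#' @export
vertex_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- tapply(area, f[, k], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  w / 3
}

# Extract the submesh spanned by a vertex-index set; faces with all three
# vertices in the set are kept and reindexed.
#' Submesh spanned by a vertex subset
#'
#' @param mesh A [trimesh()].
#' @param idx Vertex indices (1-based) of the subset.
#' @return A [trimesh()] containing only faces fully inside `idx`.
#' @export
submesh <- function(mesh, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) < 3L) stop_input("submesh needs at least 3 vertices")
  keep <- matrix(mesh$faces %in% idx, ncol = 3L)
  fsel <- mesh$faces[rowSums(keep) == 3L, , drop = FALSE]
  if (nrow(fsel) == 0L) stop_degenerate("vertex subset spans no faces")
  remap <- integer(nrow(mesh$vertices))
  remap[idx] <- seq_along(idx)
  trimesh(mesh$vertices[idx, , drop = FALSE],
          matrix(remap[fsel], ncol = 3L))
}
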