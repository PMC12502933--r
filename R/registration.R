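# Rigid registration machinery behind the symmetry-plane detector: Kabsch
# alignment on known correspondences and iterative closest point (ICP) on
# unknown ones.

# Least-squares rigid alignment of paired point sets (Kabsch/Procrustes).
kabsch <- function(moving, fixed) {
  mc <- colMeans(moving)
  fc <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, mc), sweep(fixed, 2, fc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, fc - drop(R %*% mc))
}

#' Rigid registration by iterative closest point
#'
#' Alternates closest-point matching against `fixed` with least-squares rigid
#' re-alignment of `moving`; the mean squared closest-point distance is
#' non-increasing across iterations.
#'
#' @param moving,fixed Point matrices (`n x 3`), each with at least 3 points.
#' @param init Initial [rigid_transform()] applied to `moving`.
#' @param max_iter Maximum iterations.
#' @param tol Relative improvement in RMS distance below which iteration
#'   stops.
#' @param trim Fraction of the worst-matching points discarded in each
#'   iteration (trimmed ICP); robustifies the alignment against features
#'   with no true counterpart, e.g. bilaterally asymmetric anatomy in
#'   mirror registration.
#' @return A list: `transform` ([rigid_transform()] mapping `moving` onto
#'   `fixed`), `rms` (final RMS closest-point distance over the kept
#'   matches, mm), `iterations`, `converged`.
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform(),
                           max_iter = 100L, tol = 1e-8, trim = 0) {
  moving <- as_point_matrix(moving)
  fixed <- as_point_matrix(fixed)
  if (nrow(moving) < 3L || nrow(fixed) < 3L)
    stop_input("registration needs at least 3 points per cloud")
  if (max(apply(moving, 2, function(x) diff(range(x)))) < 1e-12 ||
      max(apply(fixed, 2, function(x) diff(range(x)))) < 1e-12)
    stop_degenerate("registration input has no spatial extent")
  cur_tf <- init
  cur <- apply_rigid(moving, cur_tf)
  prev_rms <- Inf
  rms <- Inf
  it <- 0L
  converged <- FALSE
  n_keep <- max(3L, floor((1 - trim) * nrow(moving)))
  while (it < max_iter) {
    it <- it + 1L
    nn <- .closest_point_idx(cur, fixed)
    matched <- fixed[nn, , drop = FALSE]
    d2 <- rowSums((cur - matched)^2)
    keep <- if (n_keep < nrow(moving)) {
      order(d2)[seq_len(n_keep)]
    } else {
      seq_len(nrow(moving))
    }
    rms <- sqrt(mean(d2[keep]))
    if (is.finite(prev_rms) &&
        (prev_rms - rms) <= tol * max(prev_rms, 1e-300)) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    cur_tf <- kabsch(moving[keep, , drop = FALSE],
                     matched[keep, , drop = FALSE])
    cur <- apply_rigid(moving, cur_tf)
  }
  list(transform = cur_tf, rms = rms, iterations = it, converged = converged)
}

#' Detect the midsagittal symmetry plane of a head mesh
#'
#' Mirror-and-register symmetry detection: (1) candidate planes are the three
#' principal planes through the vertex centroid, and the one whose mirrored
#' point cloud is closest to the original is kept; (2) a vertex subsample is
#' reflected across that candidate and rigidly registered back onto the full
#' vertex set by ICP; (3) the composite reflection-then-rigid map is an
#' improper orthogonal map whose invariant plane is returned.
#'
#' @param head A [trimesh()] with at least 100 vertices.
#' @param settings A [measure_settings()] list (subsample size/seed, ICP
#'   iterations and tolerance).
#' @return A [plane3()] — the midsagittal plane. Normal sign is canonicalized
#'   to have its largest-magnitude component positive; consumers re-orient it.
#' @details The moving subsample is drawn with probability proportional to
#'   per-vertex surface area (one third of the incident triangle area), so the
#'   detected plane is independent of local mesh density: a small, densely
#'   meshed feature cannot outvote the rest of the surface.
#' @export
find_symmetry_plane <- function(head, settings = measure_settings()) {
  if (!inherits(head, "trimesh")) stop_input("head must be a trimesh")
  verts <- head$vertices
  if (nrow(verts) < 100L)
    stop_input("symmetry detection needs at least 100 vertices")
  w <- vertex_areas(head)
  sub_idx <- with_seed(settings$icp_seed,
                       sample.int(nrow(verts), settings$icp_subsample,
                                  replace = TRUE, prob = w))
  sub <- verts[sub_idx, , drop = FALSE]
  # area-weighted centroid and principal axes: candidate planes must reflect
  # the surface geometry, not the vertex density
  wn <- w / sum(w)
  ctr <- colSums(verts * wn)
  cen <- sweep(verts, 2, ctr)
  ev <- eigen(crossprod(cen, cen * wn), symmetric = TRUE)
  ax <- ev$vectors

  # Candidate normals: the three principal axes; when the two smallest
  # principal spreads are close (a head is nearly rotationally symmetric
  # about its long axis, so those eigenvectors are arbitrary mixtures), the
  # plane of near-degeneracy is swept densely enough that one candidate
  # lands inside the ICP basin of the true plane.
  cands <- lapply(1:3, function(k) ax[, k])
  if (ev$values[2] < 1.5 * ev$values[3]) {
    for (t in seq(7.5, 172.5, by = 7.5) * pi / 180) {
      cands[[length(cands) + 1L]] <- cos(t) * ax[, 2] + sin(t) * ax[, 3]
    }
  }
  score_sub <- sub[seq(1L, nrow(sub),
                       length.out = min(1500L, nrow(sub))), , drop = FALSE]
  score <- vapply(cands, function(nrm) {
    pl <- plane3(nrm, ctr)
    mir <- reflect_across_plane(score_sub, pl)
    nn <- .closest_point_idx(mir, verts)
    mean(rowSums((mir - verts[nn, , drop = FALSE])^2))
  }, 0)
  best <- plane3(cands[[which.min(score)]], ctr)

  mir <- reflect_across_plane(sub, best)
  reg <- register_rigid(mir, verts, max_iter = settings$icp_max_iter,
                        tol = settings$icp_tol, trim = settings$icp_trim)

  # composite map p -> R * S p + R * s + t, S = reflection across `best`
  S <- diag(3) - 2 * tcrossprod(best$normal)
  s_t <- 2 * best$offset * best$normal
  A <- reg$transform$rotation %*% S
  d <- drop(reg$transform$rotation %*% s_t) + reg$transform$translation

  # invariant plane: eigenvector of A with eigenvalue closest to -1
  ev <- eigen(A)
  k <- which.min(abs(ev$values + 1))
  n <- Re(ev$vectors[, k])
  n <- .unit(n)
  if (n[which.max(abs(n))] < 0) n <- -n
  offset <- sum(n * d) / 2
  plane3(n, offset * n)
}
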