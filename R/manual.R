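# Landmark-based "conventional" measurement path: distances and a 3-point
# angle computed from operator-placed anthropometric landmarks. Inclination
# and the positional parameters are not produced — placing landmarks for
# them is impractical, which is exactly the manual method's limitation.

.manual_landmarks <- c("superaurale", "subaurale", "preaurale", "postaurale",
                       "helix_lateral", "mastoid_base", "tragus")

#' Manual (landmark-based) auricle measurement
#'
#' Emulates landmark anthropometry on a 3D head model:
#' length = |superaurale - subaurale|, width = |preaurale - postaurale|,
#' protrusion = |helix_lateral - mastoid_base|, and the auriculocephalic
#' angle as the 3-point angle at the tragus between the mastoid base and the
#' lateral helix (the axial-plane triplet). Landmark definitions follow
#' standard anthropometric usage.
#'
#' @param landmarks Named list of length-3 points (mm) containing at least
#'   `superaurale`, `subaurale`, `preaurale`, `postaurale`, `helix_lateral`,
#'   `mastoid_base`, `tragus`.
#' @param frame Optional `head_frame` (unused by the distance formulas;
#'   accepted for interface symmetry with the automatic path).
#' @return List with `length`, `width`, `protrusion` (mm), `acangle`
#'   (degrees); `inclination`, `si_position`, `pa_position` are `NA`.
#' @export
manual_measurement <- function(landmarks, frame = NULL) {
  missing <- setdiff(.manual_landmarks, names(landmarks))
  if (length(missing) > 0L)
    stop_landmark(paste0("missing landmark(s): ",
                         paste(missing, collapse = ", ")))
  lm <- lapply(landmarks, as.numeric)
  dist3 <- function(a, b) .norm3(lm[[a]] - lm[[b]])
  v1 <- lm[["mastoid_base"]] - lm[["tragus"]]
  v2 <- lm[["helix_lateral"]] - lm[["tragus"]]
  ca <- sum(v1 * v2) / (.norm3(v1) * .norm3(v2))
  list(length = dist3("superaurale", "subaurale"),
       width = dist3("preaurale", "postaurale"),
       protrusion = dist3("helix_lateral", "mastoid_base"),
       acangle = rad2deg(acos(max(-1, min(1, ca)))),
       inclination = NA_real_,
       si_position = NA_real_,
       pa_position = NA_real_)
}
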