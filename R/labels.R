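# Vertex-region labels and named landmarks: the side-car annotations that
# turn a bare head mesh into a measurable input.

.reserved_regions <- c("head", "auricle_left", "auricle_right",
                       "mastoid_left", "mastoid_right")

#' Head mesh with region labels and optional landmarks
#'
#' The pipeline's input unit: a full head mesh plus vertex-index sets marking
#' the left/right auricle regions, optional mastoid regions, and optional
#' named anthropometric landmarks per side.
#'
#' @param mesh A [trimesh()] of the whole head (auricles included).
#' @param regions Named list of 1-based vertex index vectors. Must contain
#'   non-empty, mutually disjoint `auricle_left` and `auricle_right`;
#'   `mastoid_left` / `mastoid_right` are optional.
#' @param landmarks Optional list with elements `left` and/or `right`, each a
#'   named list (or `k x 3` matrix with rownames) of landmark coordinates (mm).
#' @return Object of class `labeled_head`.
#' @export
labeled_head <- function(mesh, regions, landmarks = NULL) {
  if (!inherits(mesh, "trimesh")) stop_input("mesh must be a trimesh")
  nv <- nrow(mesh$vertices)
  for (nm in c("auricle_left", "auricle_right")) {
    if (is.null(regions[[nm]]) || length(regions[[nm]]) == 0L)
      stop_input(paste0("region '", nm, "' is missing or empty"))
  }
  regions <- lapply(regions, function(ix) {
    ix <- sort(unique(as.integer(ix)))
    if (length(ix) && (min(ix) < 1L || max(ix) > nv))
      stop_input("region vertex index outside the head mesh")
    ix
  })
  if (length(intersect(regions$auricle_left, regions$auricle_right)) > 0L)
    stop_input("auricle_left and auricle_right regions overlap")
  structure(list(mesh = mesh, regions = regions, landmarks = landmarks),
            class = "labeled_head")
}

#' @export
print.labeled_head <- function(x, ...) {
  cat(sprintf("<labeled_head: %d vertices, %d faces; regions: %s>\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces),
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

#' Auricle submesh of a labeled head
#'
#' @param labeled A [labeled_head()].
#' @param side `"left"` or `"right"`.
#' @return The auricle [trimesh()] for that side.
#' @export
auricle_submesh <- function(labeled, side = c("left", "right")) {
  side <- match.arg(side)
  submesh(labeled$mesh, labeled$regions[[paste0("auricle_", side)]])
}

#' Read / write vertex-region labels
#'
#' CSV with columns `vertex_index` (1-based) and `region`; region names follow
#' the reserved vocabulary (`head`, `auricle_left`, `auricle_right`,
#' `mastoid_left`, `mastoid_right`).
#'
#' @param path CSV path.
#' @return `read_labels`: named list of vertex index vectors.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format(paste0("label file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "region") %in% names(df)))
    stop_format("label CSV needs columns vertex_index, region")
  split(as.integer(df$vertex_index), df$region)
}

#' @rdname read_labels
#' @param regions Named list of vertex index vectors.
#' @export
write_labels <- function(regions, path) {
  df <- do.call(rbind, lapply(names(regions), function(nm)
    data.frame(vertex_index = regions[[nm]], region = nm)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write named landmarks
#'
#' CSV with columns `name`, `x`, `y`, `z` (mm).
#'
#' @param path CSV path.
#' @return `read_landmarks`: named list of length-3 coordinate vectors.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_format(paste0("landmark file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(df)))
    stop_format("landmark CSV needs columns name, x, y, z")
  lm <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, c("x", "y", "z")]))
  names(lm) <- df$name
  lm
}

#' @rdname read_landmarks
#' @param landmarks Named list of length-3 coordinate vectors.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = names(landmarks),
                   x = vapply(landmarks, `[[`, 0, 1),
                   y = vapply(landmarks, `[[`, 0, 2),
                   z = vapply(landmarks, `[[`, 0, 3))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
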