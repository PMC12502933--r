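# Classed conditions so callers and tests can distinguish failure modes.
stop_cond <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("auriclesym_", class, "_error"),
                                     "auriclesym_error")))
}
stop_input      <- function(msg) stop_cond("input", msg)
stop_format     <- function(msg) stop_cond("format", msg)
stop_degenerate <- function(msg) stop_cond("degenerate", msg)
stop_fit        <- function(msg) stop_cond("fit", msg)
stop_config     <- function(msg) stop_cond("config", msg)
stop_landmark   <- function(msg) stop_cond("missing_landmark", msg)

# Run `code` with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-300) stop_degenerate("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Accept a single point (length-3 vector) or an n x 3 matrix/data.frame.
as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop_input("a point must have 3 coordinates")
    points <- matrix(points, nrow = 1L)
  }
  points <- unname(as.matrix(points))
  if (ncol(points) != 3L) stop_input("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop_input("point coordinates must be finite")
  points
}

# Deterministic subsample of row indices (without replacement).
subsample_idx <- function(n, size, seed) {
  if (n <= size) return(seq_len(n))
  with_seed(seed, sample.int(n, size))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
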