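# Readers/writers for the three standard surface-mesh dialects the pipeline
# consumes: PLY (ascii + binary little-endian), STL (ascii + binary) and OBJ
# (vertices/faces only). Coordinates are taken as millimetres as stored.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_binary_column <- function(raw_block, stride, offset, size, type, n) {
  sel <- as.vector(vapply(seq_len(n), function(i) {
    s <- (i - 1L) * stride + offset
    (s + 1L):(s + size)
  }, integer(size)))
  bytes <- raw_block[sel]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  vals <- readBin(bytes, what = what, n = n, size = size,
                  signed = if (size < 4L) signed else TRUE, endian = "little")
  vals
}

#' Load a triangle mesh from PLY, STL or OBJ
#'
#' @param path File path.
#' @param format Mesh dialect: `"ply"`, `"stl"`, `"obj"`, or `NULL` to infer
#'   from the file extension.
#' @return A [trimesh()].
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop_format(paste0("mesh file not found: ", path))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  mesh <- switch(format,
                 ply = .read_ply(path),
                 stl = .read_stl(path),
                 obj = .read_obj(path),
                 stop_format(paste0("unsupported mesh format '", format,
                                    "' for ", path)))
  if (nrow(mesh$vertices) == 0L) stop_input(paste0("empty mesh: ", path))
  mesh
}

#' Save a triangle mesh as PLY, STL or OBJ
#'
#' @param mesh A [trimesh()].
#' @param path Output path.
#' @param format Dialect (inferred from extension when `NULL`).
#' @param binary Write the binary flavour (PLY little-endian / binary STL).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (!inherits(mesh, "trimesh")) stop_input("mesh must be a trimesh")
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    switch(format,
           ply = .write_ply(mesh, path, binary),
           stl = .write_stl(mesh, path, binary),
           obj = .write_obj(mesh, path),
           stop_format(paste0("unsupported mesh format '", format, "'")))
    TRUE
  }, error = function(e) {
    if (inherits(e, "auriclesym_error")) stop(e)
    stop_cond("io", paste0("cannot write ", path, ": ", conditionMessage(e)))
  })
  invisible(path)
}

.read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  end_pos <- grepRaw("end_header\r?\n", raw)
  if (length(end_pos) == 0L)
    stop_format(paste0("not a valid PLY file: ", path))
  tag_len <- if (raw[end_pos[1] + 10L] == charToRaw("\r")) 12L else 11L
  header_len <- end_pos[1] + tag_len - 1L
  lines <- strsplit(rawToChar(raw[seq_len(header_len)]), "\r?\n")[[1]]
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop_format(paste0("not a valid PLY file: ", path))
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (length(fmt_line) != 1L) stop_format("PLY header missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop_format(paste0("unsupported PLY format: ", fmt))

  # parse elements / properties
  elements <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               item_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) stop_format("PLY file has no vertex element")

  if (fmt == "ascii") {
    body <- strsplit(rawToChar(raw[(header_len + 1L):length(raw)]), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    pos <- 1L
    verts <- NULL
    faces <- NULL
    for (el in elements) {
      rows <- body[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      toks <- strsplit(trimws(rows), "\\s+")
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        mat <- t(vapply(toks, function(t) as.numeric(t[seq_along(pnames)]),
                        numeric(length(pnames))))
        ix <- match(c("x", "y", "z"), pnames)
        if (anyNA(ix)) stop_format("PLY vertex element lacks x/y/z")
        verts <- mat[, ix, drop = FALSE]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(toks, function(t) {
          n <- as.integer(t[1])
          idx <- as.integer(t[2:(1 + n)]) + 1L
          if (n == 3L) matrix(idx, 1L) else
            cbind(idx[1], idx[2:(n - 1)], idx[3:n])   # fan-triangulate
        }))
      }
    }
  } else {
    cursor <- header_len
    verts <- NULL
    faces <- NULL
    for (el in elements) {
      if (el$name == "vertex") {
        types <- vapply(el$props, function(p) {
          if (p$list) stop_format("list property in PLY vertex element")
          p$type
        }, "")
        sizes <- .ply_type_size[types]
        stride <- sum(sizes)
        block <- raw[(cursor + 1L):(cursor + stride * el$count)]
        cursor <- cursor + stride * el$count
        offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
        pnames <- vapply(el$props, `[[`, "", "name")
        cols <- lapply(seq_along(sizes), function(k)
          .ply_read_binary_column(block, stride, offs[k], sizes[k],
                                  types[k], el$count))
        ix <- match(c("x", "y", "z"), pnames)
        if (anyNA(ix)) stop_format("PLY vertex element lacks x/y/z")
        verts <- cbind(cols[[ix[1]]], cols[[ix[2]]], cols[[ix[3]]])
      } else if (el$name == "face") {
        lp <- el$props[[1]]
        if (!lp$list) stop_format("PLY face element must be a list property")
        csz <- .ply_type_size[[lp$count_type]]
        isz <- .ply_type_size[[lp$item_type]]
        faces <- matrix(0L, el$count, 3L)
        for (i in seq_len(el$count)) {
          cnt <- readBin(raw[(cursor + 1L):(cursor + csz)], "integer",
                         size = csz, signed = csz >= 4L, endian = "little")
          cursor <- cursor + csz
          idx <- readBin(raw[(cursor + 1L):(cursor + isz * cnt)], "integer",
                         n = cnt, size = isz, endian = "little") + 1L
          cursor <- cursor + isz * cnt
          if (cnt != 3L) stop_format("non-triangular face in binary PLY")
          faces[i, ] <- idx
        }
      }
    }
  }
  if (is.null(faces)) faces <- matrix(integer(0), 0L, 3L)
  trimesh(verts, faces)
}

.write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(sprintf("%.10g", v), collapse = " ")), con)
    writeLines(apply(mesh$faces, 1, function(f)
      paste(c(3L, f - 1L), collapse = " ")), con)
  }
  invisible(path)
}

.read_stl <- function(path) {
  sz <- file.size(path)
  raw <- readBin(path, "raw", sz)
  is_binary <- FALSE
  if (sz >= 84L) {
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && sz == 84 + 50 * ntri) is_binary <- TRUE
  }
  if (is_binary) {
    ntri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    if (ntri < 1L) stop_input(paste0("empty STL: ", path))
    tri <- matrix(0, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      base <- 84L + (i - 1L) * 50L
      vals <- readBin(raw[(base + 1L):(base + 48L)], "double", n = 12L,
                      size = 4L, endian = "little")
      tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, byrow = TRUE)
    }
  } else {
    txt <- rawToChar(raw)
    m <- gregexpr("vertex\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)\\s+([-+0-9.eE]+)",
                  txt)[[1]]
    if (m[1] < 0) stop_format(paste0("not a valid STL file: ", path))
    chunks <- regmatches(txt, gregexpr(
      "vertex\\s+[-+0-9.eE]+\\s+[-+0-9.eE]+\\s+[-+0-9.eE]+", txt))[[1]]
    vals <- lapply(strsplit(chunks, "\\s+"), function(t) as.numeric(t[2:4]))
    tri <- do.call(rbind, vals)
    if (nrow(tri) %% 3L != 0L) stop_format("STL vertex count not divisible by 3")
  }
  # STL stores unstitched triangle soup: merge exactly coincident vertices to
  # recover topology.
  key <- apply(tri, 1, function(v) paste(sprintf("%.17g", v), collapse = "|"))
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces)
}

.write_stl <- function(mesh, path, binary = FALSE) {
  nf <- nrow(mesh$faces)
  if (nf < 1L) stop_input("STL requires at least one face")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], cc[i, ])), con,
               size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nf)) {
      writeLines(c(
        sprintf("  facet normal %.10g %.10g %.10g",
                nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.10g %.10g %.10g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.10g %.10g %.10g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.10g %.10g %.10g", cc[i, 1], cc[i, 2], cc[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L) stop_format(paste0("no vertices in OBJ: ", path))
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- matrix(integer(0), 0L, 3L)
  if (length(flines) > 0L) {
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
      idx <- as.integer(vapply(t[-1], function(s)
        strsplit(s, "/", fixed = TRUE)[[1]][1], ""))
      n <- length(idx)
      if (n == 3L) matrix(idx, 1L) else cbind(idx[1], idx[2:(n - 1)], idx[3:n])
    }))
  }
  trimesh(verts, faces)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(v)
    paste("v", paste(sprintf("%.10g", v), collapse = " "))), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(apply(mesh$faces, 1, function(f)
      paste("f", paste(f, collapse = " "))), con)
  invisible(path)
}
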