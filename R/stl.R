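#' Read a triangulated surface from STL
#'
#' Supports ASCII and binary little-endian STL (auto-detected). Coordinates
#' are taken as millimetres. Vertices are welded exactly (identical
#' coordinates collapse to one vertex) so boundary-loop detection works on
#' the result.
#'
#' @param path Path to an `.stl` file.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  close(con)
  txt_head <- rawToChar(head80[head80 != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt_head) && {
    # binary files may also start with "solid"; check the facet count
    sz <- file.info(path)$size
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    sz != 84 + 50 * n
  }
  tri_xyz <- if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    m <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    m
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rec <- readBin(con, "raw", 50L * n)
    dim(rec) <- c(50L, n)
    # each record: 12 floats (normal + 3 vertices) + 2 attribute bytes
    vals <- apply(rec[1:48, , drop = FALSE], 2, function(r)
      readBin(r, "numeric", 12L, size = 4L, endian = "little"))
    m <- t(vals)[, 4:12, drop = FALSE]
    matrix(t(m), ncol = 3, byrow = TRUE)
  }
  if (nrow(tri_xyz) %% 3 != 0) stop_domain("malformed STL: vertex count not a multiple of 3.")
  key <- apply(tri_xyz, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- tri_xyz[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  surface_mesh(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a surface mesh to ASCII STL
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param name Solid name written in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "hemoflow") {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  out <- c(sprintf("solid %s", name),
           unlist(lapply(seq_len(nrow(tr)), function(i) c(
             sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
             "    outer loop",
             sprintf("      vertex %.9g %.9g %.9g",
                     v[tr[i, ], 1], v[tr[i, ], 2], v[tr[i, ], 3]),
             "    endloop",
             "  endfacet"))),
           sprintf("endsolid %s", name))
  writeLines(out, path)
  invisible(path)
}

#' Read / write a neck-plane JSON sidecar
#'
#' Format: `{"point": [x, y, z], "normal": [x, y, z]}` in mm, normal
#' pointing into the dome.
#'
#' @param path JSON file path.
#' @return `read_neck_plane()` returns a [neck_plane()].
#' @export
read_neck_plane <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("point", "normal") %in% names(d)))
    stop_domain("neck plane JSON must have `point` and `normal`.")
  neck_plane(d$point, d$normal)
}

#' @rdname read_neck_plane
#' @param neck A [neck_plane()].
#' @export
write_neck_plane <- function(neck, path) {
  stopifnot(inherits(neck, "neck_plane"))
  jsonlite::write_json(list(point = neck$point, normal = neck$normal),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
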