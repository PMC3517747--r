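# PLY / STL mesh input and output. ASCII PLY is the canonical output
# format; binary-little-endian PLY and both STL flavours are accepted on
# input. All coordinates are interpreted as millimetres.

#' Write a mesh as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment", mesh$tag %||% "surface_mesh"),
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a PLY mesh (ASCII or binary little-endian)
#'
#' Only the vertex x/y/z properties and triangular faces are used; other
#' properties are skipped (ASCII) or stepped over (binary).
#'
#' @param path PLY file path.
#' @param tag optional structure tag to attach.
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path, tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY header")
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
  }
  fmt <- grep("^format", header, value = TRUE)[1]
  ascii <- grepl("ascii", fmt)
  if (!ascii && !grepl("binary_little_endian", fmt))
    stop("unsupported PLY format: ", fmt)
  elements <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1L]] <- tok[-1]
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex or face element")
  nv <- elements$vertex$n; nf <- elements$face$n
  vprops <- vapply(elements$vertex$props, function(p) p[length(p)], "")
  xyz <- match(c("x", "y", "z"), vprops)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z")
  if (ascii) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vlines <- txt[seq_len(nv)]
    flines <- txt[nv + seq_len(nf)]
    vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 nrow = nv, byrow = TRUE)
    vertices <- vm[, xyz, drop = FALSE]
    ftok <- strsplit(trimws(flines), "\\s+")
    faces <- t(vapply(ftok, function(tk) {
      cnt <- as.integer(tk[1])
      if (cnt != 3L) stop("only triangular PLY faces are supported")
      as.integer(tk[2:4])
    }, integer(3)))
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    ptypes <- vapply(elements$vertex$props, function(p) p[1], "")
    vertices <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv)) {
      row <- numeric(length(ptypes))
      for (j in seq_along(ptypes)) {
        ty <- ptypes[j]
        row[j] <- if (ty %in% c("float", "float32"))
          readBin(con, "numeric", 1L, size = 4L, endian = "little")
        else if (ty %in% c("double", "float64"))
          readBin(con, "numeric", 1L, size = 8L, endian = "little")
        else readBin(con, "integer", 1L, size = sizes[[ty]], endian = "little")
      }
      vertices[i, ] <- row[xyz]
    }
    fp <- elements$face$props[[1]]  # list <count type> <index type> name
    csize <- sizes[[fp[2]]]; isize <- sizes[[fp[3]]]
    faces <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, "integer", 1L, size = csize, endian = "little")
      idx <- readBin(con, "integer", cnt, size = isize, endian = "little")
      if (cnt != 3L) stop("only triangular PLY faces are supported")
      faces[i, ] <- idx
    }
  }
  surface_mesh(vertices, faces + 1L, tag = tag)
}

#' Write a mesh as ASCII STL
#' @inheritParams write_ply
#' @export
write_stl <- function(mesh, path) {
  tc <- triangle_corners(mesh)
  u <- tc$b - tc$a; v <- tc$c - tc$a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  name <- mesh$tag %||% "surface_mesh"
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(mesh$faces))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tc$a[i, 1], tc$a[i, 2], tc$a[i, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", tc$b[i, 1], tc$b[i, 2], tc$b[i, 3]),
                 sprintf("      vertex %.9g %.9g %.9g", tc$c[i, 1], tc$c[i, 2], tc$c[i, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an STL mesh (ASCII or binary)
#'
#' STL stores independent triangles; shared vertices are re-welded on read.
#'
#' @inheritParams read_ply
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path, tag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head5 <- readBin(path, "raw", 5L)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    # binary STL may also start with "solid": verify by size arithmetic
    con <- file(path, "rb"); on.exit(close(con))
    seek(con, 80L); ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    file.size(path) != 84 + 50 * ntri
  }
  if (is_ascii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    vm <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                            "\\s+"))), ncol = 3, byrow = TRUE)
  } else {
    con2 <- file(path, "rb")
    on.exit(close(con2), add = TRUE)
    seek(con2, 80L)
    ntri <- readBin(con2, "integer", 1L, size = 4L, endian = "little")
    vm <- matrix(NA_real_, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      rec <- readBin(con2, "numeric", 12L, size = 4L, endian = "little")
      vm[3L * i - 2L:0, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con2, "raw", 2L)
    }
  }
  if (nrow(vm) %% 3L != 0L) stop("malformed STL: vertex count not divisible by 3")
  faces <- matrix(seq_len(nrow(vm)), ncol = 3, byrow = TRUE)
  weld_vertices(surface_mesh(vm, faces, tag = tag))
}
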