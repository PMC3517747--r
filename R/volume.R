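# Label volumes: the voxel input of the pipeline.
#
# A label_volume is a 3D integer array of anatomical labels with strictly
# positive voxel spacing (mm) and a world-space origin. Voxel (i,j,k)
# (1-based array index) has its center at origin + spacing * (i-1, j-1, k-1);
# world coordinates are mm.

#' Anatomical label codes used by the pipeline
#'
#' @return named integer vector mapping structure names to voxel labels.
#' @export
knee_labels <- function() {
  c(background = 0L, femur = 1L, tibia = 2L, patella = 3L,
    tibia_plateau = 4L, trochlea = 5L, femur_shaft = 6L,
    condyle_medial = 7L, condyle_lateral = 8L)
}

#' Construct a label volume
#'
#' @param labels 3D array of integer anatomical labels (0 = background).
#' @param spacing voxel spacing per axis in mm (strictly positive).
#' @param origin world coordinate (mm) of the center of voxel (1,1,1).
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels != round(labels))) stop("non-integer labels", call. = FALSE)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be a finite length-3 vector (mm)")
  structure(list(labels = labels, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("label_volume: %s voxels @ %s mm, labels {%s}\n",
              paste(dim(x$labels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(sort(unique(as.vector(x$labels))), collapse = ",")))
  invisible(x)
}

#' Read a label volume from NIfTI
#'
#' Accepts axis-aligned volumes (diagonal, positive affine) with integer
#' voxel values; spacing is taken from the NIfTI pixdim and the origin from
#' the affine translation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume")
  aff <- RNifti::xform(img)
  offdiag <- aff[1:3, 1:3]; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6) || any(diag(aff[1:3, 1:3]) <= 0))
    stop("unsupported orientation: affine must be axis-aligned and positive")
  vals <- as.vector(img)
  if (any(vals != round(vals))) stop("non-integer labels", call. = FALSE)
  spacing <- diag(aff[1:3, 1:3])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid spacing metadata", call. = FALSE)
  label_volume(array(as.integer(round(vals)), dim(img)),
               spacing = spacing, origin = aff[1:3, 4])
}

#' Write a label volume as NIfTI
#'
#' @param volume a `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels)
  RNifti::pixdim(img) <- volume$spacing
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Tri-linearly upsample a label volume
#'
#' Each label's indicator field is interpolated tri-linearly on a grid
#' refined by an integer factor per axis and re-thresholded at 0.5
#' (ties between labels resolved by the larger interpolated indicator).
#' Interpolating indicators rather than raw label integers avoids blending
#' across label identities. The refined grid keeps the corner voxel centers
#' fixed: new dimensions are `(dim - 1) * factor + 1` and spacing is divided
#' by the factor.
#'
#' @param volume a `label_volume`.
#' @param factor integer upsampling factor, length 1 or 3, each >= 1.
#' @return upsampled `label_volume`.
#' @export
trilinear_upsample <- function(volume, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (any(is.na(factor)) || any(factor < 1L))
    stop("factor must be >= 1 on each axis", call. = FALSE)
  if (all(factor == 1L)) return(volume)
  labs <- setdiff(sort(unique(as.vector(volume$labels))), 0L)
  dims <- dim(volume$labels)
  newdims <- (dims - 1L) * factor + 1L
  best <- array(0, newdims)     # best indicator value so far
  out <- array(0L, newdims)
  for (lb in labs) {
    ind <- trilinear_interp3(array(as.double(volume$labels == lb), dims), factor)
    take <- ind >= 0.5 & ind > best
    out[take] <- lb
    best[take] <- ind[take]
  }
  label_volume(out, spacing = volume$spacing / factor, origin = volume$origin)
}

# Separable tri-linear interpolation of a 3D array onto the refined grid
# with dims (n-1)*f+1 per axis (corner-preserving).
trilinear_interp3 <- function(f, factor) {
  interp_axis <- function(a, ax, fac) {
    if (fac == 1L) return(a)
    n <- dim(a)[ax]
    xi <- seq(0, n - 1L, by = 1 / fac)      # old-index coordinates
    i0 <- pmin(floor(xi), n - 2)            # 0-based lower neighbour
    w <- xi - i0
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    res <- m[i0 + 1, , drop = FALSE] * (1 - w) + m[i0 + 2, , drop = FALSE] * w
    rd <- c(length(xi), d[2], d[3])
    aperm(array(res, rd), order(perm))
  }
  for (ax in 1:3) f <- interp_axis(f, ax, factor[ax])
  f
}

# 3x3x3 box-mean smoothing with zero padding (background outside the grid).
box_smooth3 <- function(f) {
  d <- dim(f)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- f
  acc <- array(0, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2)
    acc <- acc + pad[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
  acc / 27
}

#' Extract the surface of one label as a triangle mesh
#'
#' Isosurface of the label's indicator field at level 0.5, computed by
#' marching tetrahedra (each grid cell split into six tetrahedra around its
#' main diagonal, so facets match across cell boundaries). By default the
#' binary indicator is first smoothed with a 3x3x3 box mean, which removes
#' the voxel staircase and makes areas and distances of smooth structures
#' accurate to a fraction of a voxel; disable for structures thinner than
#' two voxels.
#'
#' @param volume a `label_volume`.
#' @param label integer label to extract (must be present).
#' @param smooth logical; apply the box smoothing before contouring.
#' @param upsample integer factor: the indicator field is tri-linearly
#'   interpolated onto a grid this many times finer before contouring
#'   (kept continuous, not re-thresholded, so the fine isosurface samples
#'   the interpolated surface with shorter chords).
#' @param tag optional tag for the resulting mesh.
#' @return a `surface_mesh` in world millimetres, welded and cleaned of
#'   degenerate faces, with outward-oriented triangles.
#' @export
extract_surface <- function(volume, label, smooth = TRUE, upsample = 1L,
                            tag = NULL) {
  upsample <- as.integer(rep_len(upsample, 3L))
  if (any(is.na(upsample)) || any(upsample < 1L))
    stop("upsample must be >= 1", call. = FALSE)
  hit <- volume$labels == label
  if (!any(hit)) stop("label ", label, " not present in volume", call. = FALSE)
  # crop to the label bounding box (plus margin) before contouring
  idx <- which(hit, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2, max) + 2L, dim(volume$labels))
  sub <- hit[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  field <- array(as.double(sub), dim(sub))
  spacing <- volume$spacing
  if (any(upsample > 1L)) {
    field <- trilinear_interp3(field, upsample)
    spacing <- spacing / upsample
  }
  if (smooth) field <- box_smooth3(field)
  origin <- volume$origin + volume$spacing * (lo - 1L)
  mesh <- marching_tetrahedra(field, spacing, origin, level = 0.5)
  if (nrow(mesh$faces) == 0L)
    stop("label ", label, " produced no surface (too thin after smoothing?)",
         call. = FALSE)
  mesh$tag <- tag
  mesh
}

# Marching tetrahedra on a scalar field sampled at voxel centers.
# Returns a welded surface_mesh with triangles oriented outward (normals
# pointing from values > level towards values <= level).
marching_tetrahedra <- function(field, spacing, origin, level = 0.5) {
  d <- dim(field)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  if (any(d < 2L)) return(empty)
  ncx <- nx - 1L; ncy <- ny - 1L; ncz <- nz - 1L
  ix <- rep.int(seq_len(ncx), ncy * ncz)
  iy <- rep.int(rep(seq_len(ncy), each = ncx), ncz)
  iz <- rep(seq_len(ncz), each = ncx * ncy)
  off <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  corner_vals <- function(m)
    field[(ix + off[m, 1]) + nx * ((iy + off[m, 2] - 1L) + ny * (iz + off[m, 3] - 1L))]
  V <- lapply(1:8, corner_vals)
  inside <- lapply(V, function(v) v > level)
  anyin <- Reduce(`|`, inside)
  allin <- Reduce(`&`, inside)
  act <- which(anyin & !allin)
  if (length(act) == 0L) return(empty)
  ix <- ix[act]; iy <- iy[act]; iz <- iz[act]
  V <- lapply(V, `[`, act)
  inside <- lapply(inside, `[`, act)
  corner_pos <- function(m, sel) {
    cbind(origin[1] + spacing[1] * (ix[sel] - 1L + off[m, 1]),
          origin[2] + spacing[2] * (iy[sel] - 1L + off[m, 2]),
          origin[3] + spacing[3] * (iz[sel] - 1L + off[m, 3]))
  }
  # six tetrahedra around the 1-7 diagonal; shared faces match neighbours
  tets <- rbind(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
                c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))
  tri_chunks <- list()
  edge_pt <- function(p, q, sel) {
    t <- (level - V[[p]][sel]) / (V[[q]][sel] - V[[p]][sel])
    pp <- corner_pos(p, sel)
    pp + t * (corner_pos(q, sel) - pp)
  }
  emit <- function(v1, v2, v3, pin) {
    # orient: normal away from the inside corner(s)
    e1 <- v2 - v1; e2 <- v3 - v1
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    ctr <- (v1 + v2 + v3) / 3
    flip <- rowSums(n * (ctr - pin)) < 0
    if (any(flip)) {
      tmp <- v2[flip, , drop = FALSE]
      v2[flip, ] <- v3[flip, , drop = FALSE]
      v3[flip, ] <- tmp
    }
    nr <- nrow(v1)
    out <- matrix(NA_real_, 3L * nr, 3L)
    out[seq(1L, 3L * nr, 3L), ] <- v1
    out[seq(2L, 3L * nr, 3L), ] <- v2
    out[seq(3L, 3L * nr, 3L), ] <- v3
    tri_chunks[[length(tri_chunks) + 1L]] <<- out
  }
  for (t in seq_len(nrow(tets))) {
    tc <- tets[t, ]
    code <- inside[[tc[1]]] + 2L * inside[[tc[2]]] +
      4L * inside[[tc[3]]] + 8L * inside[[tc[4]]]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (length(sel) == 0L) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      S <- tc[bits]; O <- tc[!bits]
      if (length(S) == 1L) {
        emit(edge_pt(S, O[1], sel), edge_pt(S, O[2], sel), edge_pt(S, O[3], sel),
             corner_pos(S, sel))
      } else if (length(S) == 3L) {
        emit(edge_pt(S[1], O, sel), edge_pt(S[2], O, sel), edge_pt(S[3], O, sel),
             corner_pos(S[1], sel))
      } else {
        q1 <- edge_pt(S[1], O[1], sel); q2 <- edge_pt(S[1], O[2], sel)
        q3 <- edge_pt(S[2], O[2], sel); q4 <- edge_pt(S[2], O[1], sel)
        pin <- corner_pos(S[1], sel)
        emit(q1, q2, q3, pin)
        emit(q1, q3, q4, pin)
      }
    }
  }
  vm <- do.call(rbind, tri_chunks)
  faces <- matrix(seq_len(nrow(vm)), ncol = 3, byrow = TRUE)
  weld_vertices(surface_mesh(vm, faces, clean = FALSE), tol = 1e-6)
}
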