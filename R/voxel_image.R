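#' HU-valued voxel image
#'
#' A 3-D scalar grid with isotropic-by-convention spacing and a world
#' origin.  The world coordinate of the centre of voxel `(i,j,k)` (0-based
#' indices) is `origin + (index + 1/2) * spacing`; axes are right-handed and
#' `origin` is the corner of the first voxel.
#'
#' @param values 3-D numeric or logical array.
#' @param spacing voxel edge length(s), mm; scalar or length-3, all > 0.
#' @param origin world position (mm) of the corner of voxel (0,0,0).
#' @return Object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3, length(origin) == 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_image: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# world coordinates of voxel centres along one axis
axis_centers <- function(img, axis) {
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - 0.5) * img$spacing[axis]
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

#' Read / write voxel images as NIfTI
#'
#' Images are stored with the voxel size in `pixdim` and an axis-aligned
#' sform whose offset encodes the origin (voxel-centre convention).
#' Values are written as signed 16-bit for HU volumes and unsigned 8-bit
#' for masks.
#'
#' @param img a `voxel_image`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `voxel_image`.
#' @export
write_volume <- function(img, path) {
  v <- img$values
  dtype <- if (is.logical(v)) { v <- array(as.integer(v), dim(v)); "uint8" }
           else { v <- array(as.integer(round(v)), dim(v)); "int16" }
  nif <- RNifti::asNifti(v, datatype = dtype)
  aff <- diag(4)
  diag(aff)[1:3] <- img$spacing
  aff[1:3, 4] <- img$origin + 0.5 * img$spacing
  nif <- RNifti::`sform<-`(nif, structure(aff, code = 2L))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  nif <- RNifti::readNifti(path)
  aff <- RNifti::xform(nif)
  spacing <- abs(diag(aff)[1:3])
  origin <- aff[1:3, 4] - 0.5 * spacing
  voxel_image(array(as.numeric(nif), dim(nif)[1:3]), spacing, origin)
}

# ---- 3-D binary morphology (vectorised array shifts) -----------------------

shift3 <- function(a, d, fill = FALSE) {
  # shift array contents by integer offset d (content moves +d), pad with fill
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) { src[[ax]] <- seq_len(dm[ax] - d[ax])
                      dst[[ax]] <- src[[ax]] + d[ax] }
    else            { src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
                      dst[[ax]] <- seq_len(dm[ax] + d[ax]) }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
}

dilate3 <- function(a, offsets) {
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift3(a, as.integer(offsets[i, ]))
  out
}

erode3 <- function(a, offsets) {
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift3(a, as.integer(offsets[i, ]), fill = TRUE)
  out
}

closing3 <- function(a, r) {
  if (r <= 0) return(a)
  off <- ball_offsets(r)
  erode3(dilate3(a, off), off)
}

face_offsets <- matrix(c(1,0,0, -1,0,0, 0,1,0, 0,-1,0, 0,0,1, 0,0,-1),
                       ncol = 3, byrow = TRUE)

# fill enclosed cavities: background voxels not 6-connected to the border
fill_cavities3 <- function(a) {
  bg <- !a
  reach <- array(FALSE, dim(a))
  d <- dim(a)
  reach[c(1, d[1]), , ] <- bg[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- bg[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- bg[, , c(1, d[3])]
  repeat {
    grown <- reach
    for (i in 1:6) grown <- grown | shift3(reach, face_offsets[i, ])
    grown <- grown & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  a | (bg & !reach)
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling with 26- (default) or 6-connectivity.  Intended for
#' masks with a small number of components (fragments of a segmented bone).
#'
#' @param mask `voxel_image` with logical values, or logical array.
#' @param connectivity 26 or 6.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  a <- if (inherits(mask, "voxel_image")) mask$values else mask
  offsets <- if (connectivity == 26) {
    g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    as.matrix(g[rowSums(abs(g)) > 0, ])
  } else face_offsets
  labels <- array(0L, dim(a))
  todo <- a
  lab <- 0L
  while (any(todo)) {
    lab <- lab + 1L
    seed <- which(todo)[1]
    comp <- array(FALSE, dim(a)); comp[seed] <- TRUE
    repeat {
      grown <- comp
      for (i in seq_len(nrow(offsets)))
        grown <- grown | shift3(comp, offsets[i, ])
      grown <- grown & todo
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    labels[comp] <- lab
    todo <- todo & !comp
  }
  labels
}
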