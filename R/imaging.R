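#' Density and modulus calibration
#'
#' HU-to-density and density-to-modulus mapping constants.  The defaults
#' treat HU as bone mineral density directly (identity calibration) and use
#' a generic power law `E = coefficient * (rho/reference)^exponent`; both
#' are study-specific settings meant to be overridden from configuration.
#'
#' @param hu_slope (mg HA/cm^3) per HU.
#' @param hu_intercept mg HA/cm^3.
#' @param modulus_coefficient MPa at the reference density.
#' @param modulus_exponent power-law exponent.
#' @param density_reference mg HA/cm^3.
#' @param modulus_floor minimum element modulus, MPa (keeps the stiffness
#'   matrix non-singular for zero-density elements).
#' @return Object of class `density_calibration`.
#' @export
density_calibration <- function(hu_slope = 1, hu_intercept = 0,
                                modulus_coefficient = 10000,
                                modulus_exponent = 1.5,
                                density_reference = 1000,
                                modulus_floor = 0.01) {
  stopifnot(modulus_coefficient > 0, modulus_exponent > 0,
            density_reference > 0, modulus_floor > 0)
  structure(as.list(environment()), class = "density_calibration")
}

#' Threshold-based bone segmentation
#'
#' Selects voxels with HU in the inclusive band `[lo, hi]`, then applies a
#' morphological closing with a ball of radius `r_close` voxels and fills
#' enclosed cavities (background regions not connected to the volume
#' border), the "smoothed and filled" step of the image pipeline.
#'
#' @param image a `voxel_image` (HU).
#' @param lo,hi inclusive HU bounds (defaults 400 and 4000).
#' @param r_close closing ball radius in voxels (0 disables).
#' @param fill fill enclosed cavities?
#' @param largest_component keep only the largest 26-connected component?
#' @return A `voxel_image` with logical values on the same grid.
#' @export
segment_bone <- function(image, lo = 400, hi = 4000, r_close = 2,
                         fill = TRUE, largest_component = FALSE) {
  stopifnot(lo < hi)
  m <- image$values >= lo & image$values <= hi
  if (!any(m))
    stop(sprintf("segmentation empty: no voxels within [%g, %g] HU", lo, hi))
  if (r_close > 0) m <- closing3(m, r_close)
  if (fill) m <- fill_cavities3(m)
  if (largest_component) {
    lab <- label_components(m, 26)
    keep <- which.max(tabulate(lab[lab > 0]))
    m <- lab == keep
  }
  voxel_image(m, image$spacing, image$origin)
}

# block-mean downsample by 2 (multi-resolution registration)
downsample2 <- function(img) {
  d <- dim(img$values)
  nb <- ceiling(d / 2)
  a <- array(NA_real_, nb * 2)
  a[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- img$values
  dim(a) <- c(2, nb[1], 2, nb[2], 2, nb[3])
  v <- apply(a, c(2, 4, 6), mean, na.rm = TRUE)
  voxel_image(v, img$spacing * 2, img$origin)
}

#' Resample an image under a rigid transform
#'
#' Returns the image moved by `tf`: the output voxel at world position `x`
#' takes the value of the input at `tf^{-1}(x)`, by trilinear
#' interpolation.  Voxels mapping outside the input grid become `fill`.
#'
#' @param img a `voxel_image`.
#' @param tf a `rigid_transform`.
#' @param grid `voxel_image` defining the output grid (default: same grid).
#' @param fill value for out-of-field voxels (default `NA`).
#' @return A `voxel_image` on `grid`.
#' @export
resample_image <- function(img, tf, grid = img, fill = NA_real_) {
  d <- dim(grid$values)
  xc <- axis_centers(grid, 1); yc <- axis_centers(grid, 2)
  zc <- axis_centers(grid, 3)
  pts <- cbind(rep(xc, times = d[2] * d[3]),
               rep(rep(yc, each = d[1]), times = d[3]),
               rep(zc, each = d[1] * d[2]))
  src <- apply_transform(invert_transform(tf), pts)
  ci <- sweep(sweep(src, 2, img$origin), 2, img$spacing, `/`) - 0.5  # 0-based
  di <- dim(img$values)
  i0 <- floor(ci)
  fr <- ci - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= di[1] - 2 &
        i0[, 2] >= 0 & i0[, 2] <= di[2] - 2 &
        i0[, 3] >= 0 & i0[, 3] <= di[3] - 2
  out <- rep(fill, nrow(pts))
  if (any(ok)) {
    i0k <- i0[ok, , drop = FALSE]; frk <- fr[ok, , drop = FALSE]
    base <- 1 + i0k[, 1] + di[1] * (i0k[, 2] + di[2] * i0k[, 3])
    v <- img$values
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) frk[, 1] else 1 - frk[, 1]) *
           (if (dy) frk[, 2] else 1 - frk[, 2]) *
           (if (dz) frk[, 3] else 1 - frk[, 3])
      acc <- acc + w * v[base + dx + di[1] * (dy + di[2] * dz)]
    }
    out[ok] <- acc
  }
  voxel_image(array(out, d), grid$spacing, grid$origin)
}

# normalized mutual information (H(A)+H(B))/H(A,B) over non-NA overlap
nmi_metric <- function(a, b, bins) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n < 2) return(list(nmi = 0, overlap = 0))
  av <- a[ok]; bv <- b[ok]
  cut01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] < 1e-12) return(rep(1L, length(v)))
    pmin(bins, 1L + as.integer((v - r[1]) / (r[2] - r[1]) * bins))
  }
  ia <- cut01(av); ib <- cut01(bv)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / n
  pa <- tabulate(ia, nbins = bins) / n
  pb <- tabulate(ib, nbins = bins) / n
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  list(nmi = (H(pa) + H(pb)) / max(H(joint), 1e-12),
       overlap = n / length(a))
}

#' Rigid registration by normalized mutual information
#'
#' Finds the 6-DOF rigid transform that, applied to `moving` (via
#' [resample_image()]), maximizes the normalized mutual information
#' `NMI = (H(A)+H(B))/H(A,B)` of the joint histogram against `fixed`.
#' Gradient-free Nelder--Mead search over (3 rotations about the fixed
#' image centre, 3 translations), coarse-to-fine over `levels`
#' resolutions.  The returned objective never falls below the value at the
#' initial transform.
#'
#' @param moving,fixed `voxel_image`s with overlapping fields of view.
#' @param bins joint-histogram bins per axis (>= 8).
#' @param initial starting `rigid_transform`.
#' @param com_init refine the initial translation by the intensity
#'   centre-of-mass offset (the standard moments initializer) before the
#'   search?  Protects the local optimizer from symmetry traps.
#' @param levels multi-resolution levels (1 = full resolution only).
#' @param maxit Nelder--Mead iterations per level (coarsest first).
#' @return List of class `registration_result`: `transform`, `nmi`,
#'   `nmi_initial`, `overlap` (fraction of fixed voxels covered at the
#'   optimum) and `low_overlap` flag (TRUE below 10%).
#' @export
register_rigid_nmi <- function(moving, fixed, bins = 32,
                               initial = rigid_transform(),
                               com_init = TRUE, levels = 2,
                               maxit = c(200, 60)) {
  stopifnot(bins >= 8)
  center <- fixed$origin + dim(fixed$values) * fixed$spacing / 2
  if (isTRUE(com_init)) {
    com <- function(img) {
      w <- pmax(img$values - min(img$values), 0)
      sw <- sum(w)
      c(sum(w * axis_centers(img, 1)[slice.index(w, 1)]),
        sum(w * axis_centers(img, 2)[slice.index(w, 2)]),
        sum(w * axis_centers(img, 3)[slice.index(w, 3)])) / sw
    }
    initial <- rigid_transform(initial$rotation,
                               initial$translation + com(fixed) -
                                 apply_transform(initial, com(moving)),
                               origin = initial$origin)
  }
  p2tf <- function(p) {
    R <- rotation_from_axis_angle(c(1, 0, 0), p[1]) %*%
         rotation_from_axis_angle(c(0, 1, 0), p[2]) %*%
         rotation_from_axis_angle(c(0, 0, 1), p[3])
    rigid_transform(R, p[4:6], origin = center)
  }
  # initial parameters: extract rotation/translation about `center`
  aa <- rotation_axis_angle(initial$rotation)
  p0 <- c(aa$axis * aa$angle, apply_transform(initial, center) - center)
  pyr <- list(list(m = moving, f = fixed))
  for (l in seq_len(max(0, levels - 1)))
    pyr <- c(pyr, list(list(m = downsample2(pyr[[length(pyr)]]$m),
                            f = downsample2(pyr[[length(pyr)]]$f))))
  maxit <- rep(maxit, length.out = levels)
  p <- p0
  for (l in rev(seq_len(levels))) {
    mv <- pyr[[l]]$m; fx <- pyr[[l]]$f
    obj <- function(p) {
      res <- resample_image(mv, p2tf(p), grid = fx)
      -nmi_metric(as.vector(res$values), as.vector(fx$values), bins)$nmi
    }
    # parscale sets the initial simplex (0.1 * parscale): about one degree
    # of rotation and one voxel of translation, enough to step across the
    # interpolation plateaus of the histogram metric
    opt <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit[l],
                                       parscale = c(rep(0.2, 3),
                                                    rep(10 * max(fx$spacing), 3))))
    p <- opt$par
    if (l == 1) {
      # polish with a tighter simplex at full resolution
      opt <- stats::optim(p, obj, method = "Nelder-Mead",
                          control = list(maxit = maxit[l],
                                         parscale = c(rep(0.02, 3),
                                                      rep(max(fx$spacing), 3))))
      p <- opt$par
    }
  }
  eval_p <- function(pp) {
    res <- resample_image(moving, p2tf(pp), grid = fixed)
    nmi_metric(as.vector(res$values), as.vector(fixed$values), bins)
  }
  final <- eval_p(p); init <- eval_p(p0)
  if (final$nmi < init$nmi) { p <- p0; final <- init }
  structure(list(transform = p2tf(p), nmi = final$nmi,
                 nmi_initial = init$nmi, overlap = final$overlap,
                 low_overlap = final$overlap < 0.10),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: NMI %.5f (initial %.5f), overlap %.1f%%%s\n",
              x$nmi, x$nmi_initial, 100 * x$overlap,
              if (x$low_overlap) " [LOW OVERLAP]" else ""))
  print(x$transform)
  invisible(x)
}

#' Crop a registered pre-op mask to the osteotomy pattern
#'
#' Removes the slab of voxels within `gap_size/2` of the gap plane and
#' partitions the remainder by the sign of the projection onto the gap
#' normal, yielding artifact-free proximal and distal fragment masks
#' (negative projection = proximal).
#'
#' @param preop_mask `voxel_image` (logical), registered into the post-op
#'   frame.
#' @param gap_center 3-D point on the fracture plane, mm.
#' @param gap_normal gap normal (unit vector, points distally).
#' @param gap_size gap width, mm.
#' @return List with `proximal` and `distal` masks (`voxel_image`).
#' @export
crop_to_osteotomy <- function(preop_mask, gap_center = c(0, 0, 0),
                              gap_normal = c(1, 0, 0), gap_size = 3) {
  stopifnot(is.logical(preop_mask$values))
  n <- gap_normal / sqrt(sum(gap_normal^2))
  d <- dim(preop_mask$values)
  px <- (axis_centers(preop_mask, 1) - gap_center[1]) * n[1]
  py <- (axis_centers(preop_mask, 2) - gap_center[2]) * n[2]
  pz <- (axis_centers(preop_mask, 3) - gap_center[3]) * n[3]
  proj <- outer(outer(px, py, `+`), pz, `+`)
  m <- preop_mask$values
  prox <- m & proj <= -gap_size / 2
  dist <- m & proj >= gap_size / 2
  if (gap_size == 0) { prox <- m & proj < 0; dist <- m & proj >= 0 }
  if (!any(prox) || !any(dist))
    stop("a fragment mask is empty after cropping")
  list(proximal = voxel_image(prox, preop_mask$spacing, preop_mask$origin),
       distal = voxel_image(dist, preop_mask$spacing, preop_mask$origin))
}

#' Map HU to bone mineral density inside a mask
#'
#' `rho = hu_slope * HU + hu_intercept` inside the mask, clamped at zero
#' below; zero outside the mask.
#'
#' @param image `voxel_image` (HU).
#' @param mask `voxel_image` (logical) on the same grid.
#' @param cal a [density_calibration()].
#' @return `voxel_image` of density, mg HA/cm^3.
#' @export
map_density <- function(image, mask, cal = density_calibration()) {
  stopifnot(same_grid(image, mask))
  rho <- cal$hu_slope * image$values + cal$hu_intercept
  rho[rho < 0] <- 0
  rho[!mask$values] <- 0
  voxel_image(rho, image$spacing, image$origin)
}

#' Density to elastic modulus power law
#'
#' `E = modulus_coefficient * (rho / density_reference)^modulus_exponent`,
#' floored at `modulus_floor`.
#'
#' @param rho density values, mg HA/cm^3 (vector or array).
#' @param cal a [density_calibration()].
#' @return Modulus, MPa, same shape as `rho`.
#' @export
density_to_modulus <- function(rho, cal = density_calibration()) {
  stopifnot(all(rho >= 0))
  pmax(cal$modulus_floor,
       cal$modulus_coefficient * (rho / cal$density_reference)^cal$modulus_exponent)
}
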