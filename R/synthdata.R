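#' Phantom specification for an osteotomized phalanx
#'
#' Describes the idealized hollow-cylinder phalanx phantom: a cortical tube
#' of the given outer radius and wall thickness along the x axis, marrow
#' inside, background outside, with a transverse osteotomy gap of width
#' `gap_size` centred at mid-length.  HU contrast is chosen so that the
#' standard 400--4000 HU segmentation band isolates the cortex.
#'
#' @param outer_radius outer cortical radius, mm.
#' @param cortical_thickness cortical wall thickness, mm (< outer_radius).
#' @param bone_length total bone length, mm.
#' @param gap_size osteotomy gap width, mm (>= 0; 3 mm emulates the
#'   mid-diaphyseal ostectomy of the experimental model).
#' @param cortical_hu,marrow_hu,background_hu intensities, HU; must satisfy
#'   `marrow_hu < 400 <= cortical_hu <= 4000`.
#' @param voxel_size isotropic voxel edge, mm; must resolve the cortex
#'   (`voxel_size <= cortical_thickness`).
#' @param noise_sd additive Gaussian noise, HU (0 = noiseless).
#' @param seed integer seed for the noise.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 3.2, cortical_thickness = 1.2,
                         bone_length = 30, gap_size = 3,
                         cortical_hu = 1500, marrow_hu = 150,
                         background_hu = 0, voxel_size = 0.25,
                         noise_sd = 25, seed = 1L) {
  if (gap_size < 0) stop("gap_size must be >= 0")
  if (!(cortical_thickness > 0 && cortical_thickness < outer_radius))
    stop("need 0 < cortical_thickness < outer_radius")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (voxel_size > cortical_thickness)
    stop("voxel_size larger than cortical_thickness: cortex unresolvable")
  if (!(marrow_hu < 400 && cortical_hu >= 400 && cortical_hu <= 4000))
    stop("need marrow_hu < 400 <= cortical_hu <= 4000 for segmentation")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate the phalanx phantom volume with ground-truth fragment masks
#'
#' Builds the HU volume of the hollow-cylinder phantom described by `spec`.
#' The osteotomy is a transverse slab of `background_hu` of width
#' `gap_size`, centred at mid-length; the volume grid is aligned so the
#' fracture mid-plane coincides with a voxel boundary, making the gap an
#' exact number of empty voxel planes.  Voxels are classified by their
#' centre point (partial-volume-free construction), then Gaussian noise is
#' added under the spec's seed.
#'
#' The bone long axis is x, the fracture plane is x = 0, proximal is x < 0.
#'
#' @param spec a `phantom_spec`.
#' @return List with `image` (`voxel_image`), `proximal_mask` and
#'   `distal_mask` (cortical voxels of each fragment, `voxel_image`
#'   logicals), and `spec`.
#' @export
make_phalanx_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  margin <- 2
  nx <- 2L * as.integer(ceiling((spec$bone_length / 2 + margin) / h))
  nyz <- 2L * as.integer(ceiling((spec$outer_radius + margin) / h))
  origin <- c(-nx / 2 * h, -nyz / 2 * h, -nyz / 2 * h)
  xc <- origin[1] + (seq_len(nx) - 0.5) * h
  yc <- origin[2] + (seq_len(nyz) - 0.5) * h
  zc <- yc
  r2 <- outer(yc^2, zc^2, `+`)
  R <- spec$outer_radius; ri <- R - spec$cortical_thickness
  cortex_cs <- r2 <= R^2 & r2 >= ri^2      # ny x nz cross-section
  marrow_cs <- r2 < ri^2
  in_bone <- abs(xc) <= spec$bone_length / 2
  in_gap <- abs(xc) < spec$gap_size / 2

  vals <- array(spec$background_hu, c(nx, nyz, nyz))
  keep <- which(in_bone & !in_gap)
  cs <- array(spec$background_hu, c(nyz, nyz))
  cs[marrow_cs] <- spec$marrow_hu
  cs[cortex_cs] <- spec$cortical_hu
  for (i in keep) vals[i, , ] <- cs

  if (spec$noise_sd > 0)
    vals <- vals + with_seed(spec$seed,
      array(stats::rnorm(length(vals), 0, spec$noise_sd), dim(vals)))

  mask_of <- function(xsel) {
    m <- array(FALSE, dim(vals))
    for (i in which(xsel)) m[i, , ] <- cortex_cs
    voxel_image(m, h, origin)
  }
  list(image = voxel_image(vals, h, origin),
       proximal_mask = mask_of(in_bone & xc < -spec$gap_size / 2),
       distal_mask = mask_of(in_bone & xc > spec$gap_size / 2),
       spec = spec)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Plate specification
#'
#' A de-featured rectangular fixation plate with four through-thickness
#' screw holes, two on either side of the fracture line, and two reference
#' divots on the top surface (one per fragment side, midway between that
#' side's holes).  The plate length runs along x with the fracture plane at
#' x = 0; thickness is the y direction.
#'
#' @param length,width,thickness plate dimensions, mm.
#' @param hole_diameter screw hole diameter, mm.
#' @param hole_spacing centre spacing of the two holes on one side, mm.
#' @param hole_offset_from_fracture distance of the inner holes from the
#'   fracture line, mm.
#' @param divot_positions 2 x 3 matrix of divot points on the plate top
#'   surface (proximal row first); default places them between the holes.
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(length = 24, width = 4, thickness = 1.5,
                       hole_diameter = 1.5, hole_spacing = 5,
                       hole_offset_from_fracture = 5,
                       divot_positions = NULL) {
  if (length <= 0 || width <= 0 || thickness <= 0 || hole_diameter <= 0)
    stop("degenerate plate dimensions")
  if (2 * (hole_offset_from_fracture + hole_spacing) + hole_diameter > length)
    stop("holes do not fit within the plate length")
  if (hole_spacing <= hole_diameter)
    stop("holes overlap: hole_spacing must exceed hole_diameter")
  if (is.null(divot_positions)) {
    xd <- hole_offset_from_fracture + hole_spacing / 2
    divot_positions <- rbind(c(-xd, thickness, 0), c(xd, thickness, 0))
  }
  divot_positions <- as.matrix(divot_positions)
  stopifnot(identical(dim(divot_positions), c(2L, 3L)))
  if (any(abs(divot_positions[, 2] - thickness) > 1e-9))
    stop("divots must lie on the plate top surface (y = thickness)")
  structure(list(length = length, width = width, thickness = thickness,
                 hole_diameter = hole_diameter, hole_spacing = hole_spacing,
                 hole_offset_from_fracture = hole_offset_from_fracture,
                 divot_positions = divot_positions),
            class = "plate_spec")
}

#' Hole centre x-coordinates of a plate
#' @param spec a `plate_spec`.
#' @return Numeric length-4, mm, ordered proximal to distal.
#' @export
plate_hole_centers <- function(spec) {
  o <- spec$hole_offset_from_fracture; s <- spec$hole_spacing
  c(-(o + s), -o, o, o + s)
}

#' Build the solid tetrahedral plate mesh
#'
#' Meshes the plate as a structured grid of cubes of edge `target_edge`,
#' each split into six quadratic tetrahedra; cubes whose footprint is at
#' least half inside a screw hole are removed.  The plate bottom face sits
#' at y = 0 (use [translate_mesh()] to seat it on the bone).  Four labelled
#' hole-boundary node sets and the two divot points are attached.
#'
#' @param spec a `plate_spec`.
#' @param target_edge cube edge length, mm (default 0.25, the plate
#'   meshing size established by the convergence study).
#' @param E,nu plate material constants (MPa / unitless); defaults are the
#'   PEEK values calibrated from the dog-bone data.
#' @return A `tet10_mesh` with node sets `hole_1` .. `hole_4`, and fields
#'   `divots` (2 x 3) and `plate_spec`.
#' @export
make_plate <- function(spec, target_edge = 0.25, E = 1740.5, nu = 0.3779) {
  stopifnot(inherits(spec, "plate_spec"))
  h <- target_edge
  ncx <- max(1L, as.integer(round(spec$length / h)))
  ncy <- max(1L, as.integer(round(spec$thickness / h)))
  ncz <- max(1L, as.integer(round(spec$width / h)))
  # snap the edge so the grid fits the plate exactly in each direction
  hx <- spec$length / ncx; hy <- spec$thickness / ncy; hz <- spec$width / ncz
  origin <- c(-spec$length / 2, 0, -spec$width / 2)
  cubes <- as.matrix(expand.grid(i = seq_len(ncx) - 1L,
                                 j = seq_len(ncy) - 1L,
                                 k = seq_len(ncz) - 1L))
  # hole removal: >= 50% of the cube's xz footprint inside a hole circle,
  # estimated on a 5x5 subsample of the footprint
  hx_c <- plate_hole_centers(spec)
  r <- spec$hole_diameter / 2
  sub <- (seq_len(5) - 0.5) / 5
  frac_in_hole <- numeric(nrow(cubes))
  for (hc in hx_c) {
    xs <- outer(origin[1] + (cubes[, 1] + 0) * hx, sub * hx, `+`)
    zs <- outer(origin[3] + (cubes[, 3] + 0) * hz, sub * hz, `+`)
    inside <- matrix(0, nrow(cubes), 1)
    cnt <- numeric(nrow(cubes))
    for (a in seq_len(5)) for (b in seq_len(5))
      cnt <- cnt + ((xs[, a] - hc)^2 + (zs[, b] - 0)^2 <= r^2)
    frac_in_hole <- pmax(frac_in_hole, cnt / 25)
  }
  keep <- frac_in_hole < 0.5
  if (!any(keep)) stop("degenerate plate: all cubes removed")
  mesh <- cubes_to_tet10(cubes[keep, , drop = FALSE],
                         edge = c(hx, hy, hz), origin = origin,
                         E = E, nu = nu)
  # hole-boundary node sets: surface nodes within half an edge of the
  # (stair-stepped) hole cylinder
  surf <- surface_nodes(mesh)
  xyz <- mesh$nodes
  for (i in 1:4) {
    d2 <- (xyz[surf, 1] - hx_c[i])^2 + (xyz[surf, 3] - 0)^2
    sel <- surf[d2 <= (r + 0.55 * max(hx, hz))^2]
    if (length(sel) == 0) stop("hole ", i, " has no boundary nodes at this resolution")
    mesh$node_sets[[paste0("hole_", i)]] <- sel
  }
  mesh$divots <- spec$divot_positions
  mesh$plate_spec <- spec
  mesh
}

#' Synthetic marker trajectory for two bone fragments
#'
#' Proximal markers stay fixed; distal markers follow a geodesic
#' interpolation (constant rotation axis, linearly scaled angle and
#' translation) from the identity at frame 0 to `final_transform` at the
#' last frame, with optional isotropic Gaussian position noise.
#'
#' @param final_transform `rigid_transform` of the distal fragment at the
#'   final frame (typically expressed about the distal divot).
#' @param n_frames number of frames including frame 0 (>= 2).
#' @param noise_sd marker position noise, mm.
#' @param seed integer seed for the noise.
#' @param proximal_markers,distal_markers m x 3 matrices (m >= 3,
#'   non-collinear) of marker positions at frame 0; defaults emulate
#'   markers on K-wires either side of the plate.
#' @return Data frame with columns `time_index`, `fragment`,
#'   `marker_label`, `x_mm`, `y_mm`, `z_mm`.
#' @export
make_marker_trajectory <- function(final_transform, n_frames = 11,
                                   noise_sd = 0, seed = 1L,
                                   proximal_markers = NULL,
                                   distal_markers = NULL) {
  stopifnot(n_frames >= 2)
  if (is.null(proximal_markers))
    proximal_markers <- rbind(c(-12, 8, 0), c(-14, 9, 2),
                              c(-10, 9, -2), c(-12, 11, 1))
  if (is.null(distal_markers))
    distal_markers <- rbind(c(12, 8, 0), c(14, 9, -2),
                            c(10, 9, 2), c(12, 11, -1))
  proximal_markers <- as.matrix(proximal_markers)
  distal_markers <- as.matrix(distal_markers)
  if (nrow(proximal_markers) < 3 || nrow(distal_markers) < 3)
    stop("need at least 3 markers per fragment")
  for (m in list(proximal_markers, distal_markers)) {
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] < 1e-9) stop("markers are collinear")
  }
  aa <- rotation_axis_angle(final_transform$rotation)
  frames <- lapply(seq_len(n_frames) - 1L, function(k) {
    f <- k / (n_frames - 1)
    Tk <- rigid_transform(rotation_from_axis_angle(aa$axis, f * aa$angle),
                          f * final_transform$translation,
                          origin = final_transform$origin)
    dk <- apply_transform(Tk, distal_markers)
    rbind(
      data.frame(time_index = k, fragment = "proximal",
                 marker_label = paste0("P", seq_len(nrow(proximal_markers))),
                 x_mm = proximal_markers[, 1], y_mm = proximal_markers[, 2],
                 z_mm = proximal_markers[, 3]),
      data.frame(time_index = k, fragment = "distal",
                 marker_label = paste0("D", seq_len(nrow(distal_markers))),
                 x_mm = dk[, 1], y_mm = dk[, 2], z_mm = dk[, 3]))
  })
  out <- do.call(rbind, frames)
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(3 * nrow(out), 0, noise_sd),
                                    ncol = 3))
    out$x_mm <- out$x_mm + noise[, 1]
    out$y_mm <- out$y_mm + noise[, 2]
    out$z_mm <- out$z_mm + noise[, 3]
  }
  rownames(out) <- NULL
  out
}

#' Write / read marker trajectories as CSV
#' @param markers data frame from [make_marker_trajectory()].
#' @param path CSV file path.
#' @export
write_marker_csv <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic PEEK dog-bone tension curve
#'
#' Engineering stress--strain curve of a bilinear elastic--plastic
#' material, constructed so that its 0.2%-offset yield stress equals
#' `offset_yield` exactly.  The elastic branch has slope `E` up to the kink
#' strain
#' \deqn{\varepsilon_k = \sigma_y / E - 0.002 H / (E - H)}
#' (the analytic solution of the offset-line intersection with the
#' hardening branch of slope `H`), after which stress continues with slope
#' `H`.  Lateral strain is `-nu * axial_strain` in the elastic region and
#' continues with slope -0.5 (incompressible flow) beyond the kink.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio (0, 0.5).
#' @param offset_yield 0.2%-offset yield stress, MPa.
#' @param hardening_modulus post-kink slope H, MPa (< E).
#' @param max_strain last axial strain sampled.
#' @param n_points number of samples (strain 0 .. max_strain).
#' @param noise_sd Gaussian stress noise, MPa.
#' @param seed integer seed for the noise.
#' @return Object of class `stress_strain_curve`: list of numeric vectors
#'   `axial_strain`, `axial_stress` (MPa), `lateral_strain`.
#' @export
make_dogbone_curve <- function(E = 1740.5, nu = 0.3779, offset_yield = 100.3,
                               hardening_modulus = 174, max_strain = 0.08,
                               n_points = 201, noise_sd = 0, seed = 1L) {
  stopifnot(E > 0, nu > 0, nu < 0.5, hardening_modulus < E,
            hardening_modulus >= 0)
  if (offset_yield / E + 0.002 >= max_strain)
    stop("curve never yields within max_strain")
  H <- hardening_modulus
  eps_k <- offset_yield / E - 0.002 * H / (E - H)
  sig_k <- E * eps_k
  eps <- seq(0, max_strain, length.out = n_points)
  if (eps_k > 0 && eps_k < max_strain)
    eps <- sort(unique(c(eps, eps_k)))  # sample the kink exactly
  sig <- ifelse(eps <= eps_k, E * eps, sig_k + H * (eps - eps_k))
  lat <- ifelse(eps <= eps_k, -nu * eps, -nu * eps_k - 0.5 * (eps - eps_k))
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(eps), 0, noise_sd))
  structure(list(axial_strain = eps, axial_stress = sig,
                 lateral_strain = lat,
                 kink = list(strain = eps_k, stress = sig_k)),
            class = "stress_strain_curve")
}

#' Write / read stress-strain curves as CSV
#' @param curve a `stress_strain_curve`.
#' @param path CSV file path.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(strain = curve$axial_strain,
                   stress_MPa = curve$axial_stress)
  if (!is.null(curve$lateral_strain)) df$lateral_strain <- curve$lateral_strain
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(axial_strain = df$strain, axial_stress = df$stress_MPa,
                 lateral_strain = df$lateral_strain),
            class = "stress_strain_curve")
}
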