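#' Rigid transform
#'
#' A proper rigid-body motion of 3-space, stored as a rotation matrix, a
#' translation vector and a rotation reference point (`origin`).  The
#' transform acts on a point `x` as
#' \deqn{x \mapsto R (x - o) + o + t}
#' so that `origin` is the point about which the rotation is taken; with the
#' default `origin = c(0,0,0)` this is the usual `R x + t` form.  Keeping the
#' reference point explicit lets fragment motions be expressed at a plate
#' divot (the measured landmark) rather than at the world origin.
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation length-3 numeric, mm.
#' @param origin length-3 numeric, mm; rotation reference point.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            origin = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)),
            length(translation) == 3, length(origin) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthogonal (R'R != I within 1e-9)")
  if (det(rotation) < 0)
    stop("rotation is a reflection (det < 0)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 origin = as.numeric(origin)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  aa <- rotation_axis_angle(x$rotation)
  cat(sprintf("rigid_transform: angle %.4f deg about (%.3f, %.3f, %.3f), t = (%.4f, %.4f, %.4f) mm\n",
              aa$angle * 180 / pi, aa$axis[1], aa$axis[2], aa$axis[3],
              x$translation[1], x$translation[2], x$translation[3]))
  if (any(x$origin != 0))
    cat(sprintf("  about reference point (%.3f, %.3f, %.3f) mm\n",
                x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform`.
#' @param points N x 3 matrix (or length-3 vector) of points, mm.
#' @return Transformed points, same shape.
#' @export
apply_transform <- function(tf, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p, 2, tf$origin) %*% t(tf$rotation)
  out <- sweep(out, 2, tf$origin + tf$translation, `+`)
  if (vec) drop(out) else out
}

# canonical world form: x -> R x + t_w
world_translation <- function(tf) {
  tf$origin + tf$translation - drop(tf$rotation %*% tf$origin)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` in world form (origin 0).
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% world_translation(b)) + world_translation(a))
}

#' Invert a rigid transform
#' @param tf A `rigid_transform`.
#' @return The inverse transform (world form).
#' @export
invert_transform <- function(tf) {
  tw <- world_translation(tf)
  rigid_transform(t(tf$rotation), drop(-t(tf$rotation) %*% tw))
}

#' Axis-angle decomposition of a rotation matrix
#'
#' @param R 3x3 proper orthogonal matrix.
#' @return List with unit `axis` and `angle` in radians (in `[0, pi]`).
#' @export
rotation_axis_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  angle <- acos(min(1, max(-1, ca)))
  if (angle < 1e-12)
    return(list(axis = c(0, 0, 1), angle = 0))
  if (pi - angle < 1e-6) {
    # near-pi: axis from the symmetric part, sign irrelevant
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(0, diag(B)))
    k <- which.max(axis)
    sgn <- sign(B[k, ])
    sgn[sgn == 0] <- 1
    axis <- axis * sgn / axis[k] * axis[k]
    axis <- axis / sqrt(sum(axis^2))
    return(list(axis = axis, angle = angle))
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(angle))
  list(axis = axis / sqrt(sum(axis^2)), angle = angle)
}

#' Rotation matrix from axis and angle (Rodrigues formula)
#'
#' @param axis length-3 direction (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Least-squares rigid fit between labelled point sets (Kabsch)
#'
#' Finds the proper rigid transform minimizing
#' \eqn{\sum_i \| R p_i + t - q_i \|^2} for corresponding points
#' `reference_points[i,]` -> `current_points[i,]`.  SVD-based with a
#' reflection guard: if the optimal orthogonal matrix has negative
#' determinant, the singular vector of the smallest singular value is
#' flipped so a proper rotation is always returned.
#'
#' @param reference_points N x 3 matrix, N >= 3 non-collinear points (mm).
#' @param current_points N x 3 matrix with the same row labelling.
#' @return List with `transform` (a `rigid_transform`, world form) and
#'   `rms_residual` (mm).
#' @export
fit_rigid_transform <- function(reference_points, current_points) {
  P <- as.matrix(reference_points)
  Q <- as.matrix(current_points)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("need at least 3 point correspondences")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(crossprod(P0, Q0))  # H = P0' Q0 ; R = V diag(1,1,s) U'
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("reference points are collinear: rotation about the line is unobservable")
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  t <- qc - drop(R %*% pc)
  res <- Q - (P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE))
  list(transform = rigid_transform(R, t),
       rms_residual = sqrt(mean(rowSums(res^2))))
}

#' Relative fragment transform expressed at the distal divot
#'
#' Removes the common-mode motion by forming
#' \eqn{T_{rel} = T_{prox}^{-1} \circ T_{dist}} — the distal fragment's
#' motion as seen from a frame riding on the proximal fragment — and
#' re-expresses it with the distal plate divot as the rotation reference
#' point, so the transform can directly drive the FE model (proximal side
#' fixed, distal side displaced about its divot).
#'
#' @param T_proximal,T_distal `rigid_transform` motions of the two fragments
#'   measured in a common (camera/world) frame.
#' @param frame A `divot_frame` (see [divot_frame()]).
#' @return A `rigid_transform` with `origin = frame$distal_divot`.
#' @export
relative_transform_at_divot <- function(T_proximal, T_distal, frame) {
  Trel <- compose_transforms(invert_transform(T_proximal), T_distal)
  d <- frame$distal_divot
  # re-root: find translation field such that x -> R(x-d)+d+t matches Trel
  t_tilde <- apply_transform(Trel, d) - d
  rigid_transform(Trel$rotation, t_tilde, origin = d)
}

#' Divot reference frame
#'
#' The two plate reference divots and the plate's long axis; fragment
#' motions are expressed at these landmarks.
#'
#' @param proximal_divot,distal_divot 3-D points (mm), distinct.
#' @param section_axis unit vector along the plate length.
#' @return Object of class `divot_frame`.
#' @export
divot_frame <- function(proximal_divot, distal_divot,
                        section_axis = c(1, 0, 0)) {
  stopifnot(length(proximal_divot) == 3, length(distal_divot) == 3)
  if (sqrt(sum((proximal_divot - distal_divot)^2)) < 1e-9)
    stop("divots must be distinct points")
  section_axis <- section_axis / sqrt(sum(section_axis^2))
  structure(list(proximal_divot = as.numeric(proximal_divot),
                 distal_divot = as.numeric(distal_divot),
                 section_axis = as.numeric(section_axis)),
            class = "divot_frame")
}

#' Evenly spaced displacement steps along a rigid motion
#'
#' Geodesic interpolation from the identity to `T_rel`: step `k` of `n`
#' carries rotation angle `(k/n) * theta` about the fixed rotation axis and
#' translation `(k/n) * t`, all about the same reference point.  Linear
#' matrix interpolation is deliberately avoided: it leaves SO(3).
#'
#' @param T_rel target `rigid_transform`.
#' @param n number of steps (>= 1).
#' @return List of `n` `rigid_transform`s; the last equals `T_rel`.
#' @export
make_displacement_steps <- function(T_rel, n = 10) {
  stopifnot(n >= 1)
  aa <- rotation_axis_angle(T_rel$rotation)
  if (aa$angle >= pi - 1e-9)
    stop("rotation angle >= 180 degrees: interpolation axis is ambiguous")
  lapply(seq_len(n), function(k) {
    f <- k / n
    R <- rotation_from_axis_angle(aa$axis, f * aa$angle)
    rigid_transform(R, f * T_rel$translation, origin = T_rel$origin)
  })
}

#' Serialize rigid transforms to JSON
#'
#' @param tfs a `rigid_transform` or list of them.
#' @param path output file.
#' @export
write_transforms_json <- function(tfs, path) {
  if (inherits(tfs, "rigid_transform")) tfs <- list(tfs)
  out <- lapply(tfs, function(tf) list(
    rotation = as.vector(t(tf$rotation)),  # row-major
    translation_mm = tf$translation,
    origin_mm = tf$origin))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read rigid transforms from JSON
#' @param path file written by [write_transforms_json()].
#' @return List of `rigid_transform`s.
#' @export
read_transforms_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(seq_along(raw[["rotation"]] %||% raw), function(i) {
    el <- if (is.null(raw[["rotation"]])) raw[[i]] else
      lapply(raw, function(col) col[[i]])
    rigid_transform(matrix(unlist(el$rotation), 3, 3, byrow = TRUE),
                    unlist(el$translation_mm),
                    unlist(el$origin_mm %||% c(0, 0, 0)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
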