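# Internal section resultants at a cut plane through the plate.
#
# The cut plane follows the deformed plate centerline: its normal is the
# centerline tangent at the chosen station, so the extracted transverse
# moment components are bending moments in the deformed configuration.
# Sign convention (fixed): the reported force/moment is the action of the
# distal side of the cut on the proximal side, with moments taken about
# the deformed section point.

#' Deformed plate centerline frame at a station
#'
#' The centerline is formed from centroids of thin transverse slabs of
#' plate nodes (binned along the undeformed long axis) displaced by the FE
#' field; the tangent is the normalized central difference at the station,
#' and the transverse axes follow by Gram--Schmidt against the plate width
#' direction.  Empty slabs are widened adaptively; an error is raised if a
#' slab must grow beyond a quarter of the plate length.
#'
#' @param mesh a `tet10_mesh` (combined or plate-only).
#' @param u N x 3 nodal displacements, mm.
#' @param station fraction of the plate length (0.5 = mid-plate).
#' @param plate_nodes node indices of the plate (default: the combined
#'   mesh's `plate_nodes`, else all nodes).
#' @param width_dir undeformed plate width direction.
#' @return List: `point` (deformed section point), `tangent`, `t1`, `t2`
#'   (orthonormal section axes).
#' @export
deformed_centerline_frame <- function(mesh, u, station = 0.5,
                                      plate_nodes = NULL,
                                      width_dir = c(0, 0, 1)) {
  if (is.null(plate_nodes))
    plate_nodes <- mesh$plate_nodes %||% seq_len(nrow(mesh$nodes))
  X <- mesh$nodes[plate_nodes, , drop = FALSE]
  U <- u[plate_nodes, , drop = FALSE]
  x <- X[, 1]
  xr <- range(x)
  L <- diff(xr)
  ux <- sort(unique(round(x, 9)))
  w0 <- 2 * stats::median(diff(ux))
  centroid_at <- function(xc) {
    w <- w0
    repeat {
      sel <- abs(x - xc) <= w / 2
      if (sum(sel) >= 3) break
      w <- 2 * w
      if (w > L / 4) stop("empty centerline slab wider than 25% of the plate")
    }
    colMeans(X[sel, , drop = FALSE] + U[sel, , drop = FALSE])
  }
  xs <- xr[1] + station * L
  c0 <- centroid_at(xs)
  cm <- centroid_at(max(xr[1], xs - w0))
  cp <- centroid_at(min(xr[2], xs + w0))
  tangent <- cp - cm
  tangent <- tangent / sqrt(sum(tangent^2))
  t1 <- width_dir - sum(width_dir * tangent) * tangent
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(tangent[2] * t1[3] - tangent[3] * t1[2],
          tangent[3] * t1[1] - tangent[1] * t1[3],
          tangent[1] * t1[2] - tangent[2] * t1[1])
  list(point = c0, tangent = tangent, t1 = t1, t2 = t2)
}

#' Section resultants at a cut plane (one load step)
#'
#' Free-body cut through the plate: elements are classified by the side of
#' the plane their deformed centroid falls on; the elastic nodal forces of
#' the proximal-side elements, summed over the nodes they share with the
#' distal side, give the force and moment the distal side exerts on the
#' proximal side.  Computing from the other side flips the sign exactly.
#'
#' @param system an `fe_system` whose mesh records `plate_elements`.
#' @param result an `fe_result` from [solve_step()].
#' @param frame section frame from [deformed_centerline_frame()].
#' @param from `"distal"` (default, distal-on-proximal convention) or
#'   `"proximal"` (opposite sign, for the equilibrium check).
#' @param deformed evaluate side classification and lever arms in the
#'   deformed configuration (default, the cut plane rides with the
#'   deformation)?  `FALSE` evaluates in the reference configuration, the
#'   strict small-strain convention under which the resultants are exactly
#'   linear in the load.
#' @return One-row data frame: `N` (axial force), `V1`, `V2` (shear),
#'   `M_axial` (torsion), `M_t1`, `M_t2` (bending components), `M_bend`
#'   (transverse moment magnitude); forces N, moments N mm.
#' @export
cut_plane_resultants <- function(system, result, frame, from = "distal",
                                 deformed = TRUE) {
  mesh <- system$mesh
  pe <- mesh$plate_elements %||% seq_len(nrow(mesh$elem))
  el <- mesh$elem[pe, , drop = FALSE]
  def <- if (deformed) mesh$nodes + result$u else mesh$nodes
  cen <- (def[el[, 1], ] + def[el[, 2], ] + def[el[, 3], ] + def[el[, 4], ]) / 4
  proj <- as.vector(sweep(cen, 2, frame$point) %*% frame$tangent)
  P_side <- pe[proj < 0]; D_side <- pe[proj >= 0]
  if (!length(P_side) || !length(D_side))
    stop("cut plane does not intersect the plate elements")
  shared <- intersect(unique(as.vector(mesh$elem[P_side, ])),
                      unique(as.vector(mesh$elem[D_side, ])))
  if (!is.null(system$ties) &&
      any(shared %in% c(system$ties$slave, system$ties$master)))
    stop("cut plane passes through a tie constraint: move the station")
  side_elems <- if (from == "distal") P_side else D_side
  fvec <- internal_forces_subset(system$op, as.vector(t(result$u)), side_elems)
  fm <- matrix(fvec, ncol = 3, byrow = TRUE)[shared, , drop = FALSE]
  lev <- sweep(def[shared, , drop = FALSE], 2, frame$point)
  Fsum <- colSums(fm)
  Msum <- colSums(cbind(lev[, 2] * fm[, 3] - lev[, 3] * fm[, 2],
                        lev[, 3] * fm[, 1] - lev[, 1] * fm[, 3],
                        lev[, 1] * fm[, 2] - lev[, 2] * fm[, 1]))
  data.frame(N = sum(Fsum * frame$tangent),
             V1 = sum(Fsum * frame$t1), V2 = sum(Fsum * frame$t2),
             M_axial = sum(Msum * frame$tangent),
             M_t1 = sum(Msum * frame$t1), M_t2 = sum(Msum * frame$t2),
             M_bend = sqrt(sum(Msum * frame$t1)^2 + sum(Msum * frame$t2)^2))
}

#' Moment curve over the load steps
#'
#' Re-evaluates the deformed centerline frame at each step (the cut plane
#' transforms with the deformation) and collects the section resultants.
#'
#' @param system an `fe_system`.
#' @param results list of `fe_result` (one per step).
#' @param station section station along the plate (0.5 = centre).
#' @param width_dir undeformed plate width direction.
#' @param deformed see [cut_plane_resultants()].
#' @return Object of class `moment_curve`: data frame with one row per
#'   step (columns `step`, then as in [cut_plane_resultants()]).
#' @export
moment_curve <- function(system, results, station = 0.5,
                         width_dir = c(0, 0, 1), deformed = TRUE) {
  rows <- lapply(results, function(res) {
    fr <- deformed_centerline_frame(system$mesh,
                                    if (deformed) res$u else 0 * res$u,
                                    station, width_dir = width_dir)
    cbind(step = res$step_index,
          cut_plane_resultants(system, res, fr, deformed = deformed))
  })
  structure(do.call(rbind, rows), class = c("moment_curve", "data.frame"))
}

#' Maximum bending moment of a moment curve
#'
#' Maximum over the steps of the transverse moment magnitude
#' `sqrt(M_t1^2 + M_t2^2)` (torsion about the tangent excluded).
#'
#' @param curve a `moment_curve`.
#' @return N mm (non-negative).
#' @export
max_bending_moment <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  max(curve$M_bend)
}

#' Write a moment curve as CSV
#' @param curve a `moment_curve`.
#' @param path output file.
#' @export
write_moment_csv <- function(curve, path) {
  utils::write.csv(format(as.data.frame(curve), digits = 10, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flexural capacity check for a rectangular fixation patch
#'
#' Compares a bending-moment demand with the allowable moment of a
#' rectangular section, `allowable = flexural_strength * b h^2 / 6`.
#'
#' @param demand bending moment demand, N mm.
#' @param width section width b, mm.
#' @param thickness section thickness h, mm.
#' @param flexural_strength MPa.
#' @return Object of class `capacity_report`: `demand_moment`,
#'   `allowable_moment` (N mm), `utilization`, `safety_factor`
#'   (`Inf` with `infinite_safety = TRUE` when demand is zero).
#' @export
capacity_check <- function(demand, width, thickness, flexural_strength) {
  stopifnot(demand >= 0, width > 0, thickness > 0, flexural_strength > 0)
  allowable <- flexural_strength * width * thickness^2 / 6
  sf <- if (demand == 0) Inf else allowable / demand
  structure(list(demand_moment = demand, allowable_moment = allowable,
                 utilization = 1 / sf, safety_factor = sf,
                 infinite_safety = !is.finite(sf)),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf("capacity_report: demand %.3g N mm vs allowable %.4g N mm -> safety factor %.3g\n",
              x$demand_moment, x$allowable_moment, x$safety_factor))
  invisible(x)
}
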