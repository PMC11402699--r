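#' Elastic modulus from the initial slope of a tension curve
#'
#' Ordinary least-squares slope (intercept free) of axial stress against
#' axial strain, restricted to the elastic strain window.
#'
#' @param curve a `stress_strain_curve`.
#' @param window strain interval `c(lo, hi)` used for the fit; the default
#'   0.05--0.25% strain stays well below typical polymer yield.
#' @return Young's modulus, MPa.
#' @export
fit_elastic_modulus <- function(curve, window = c(0.0005, 0.0025)) {
  sel <- curve$axial_strain >= window[1] & curve$axial_strain <= window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 samples in the elastic window")
  x <- curve$axial_strain[sel]; y <- curve$axial_stress[sel]
  unname(stats::cov(x, y) / stats::var(x))
}

#' Poisson's ratio from lateral vs axial strain
#'
#' Minus the least-squares slope of lateral strain against axial strain in
#' the elastic window.
#'
#' @inheritParams fit_elastic_modulus
#' @return Poisson's ratio.
#' @export
fit_poisson <- function(curve, window = c(0.0005, 0.0025)) {
  if (is.null(curve$lateral_strain))
    stop("curve has no lateral strain channel")
  sel <- curve$axial_strain >= window[1] & curve$axial_strain <= window[2]
  if (sum(sel) < 3)
    stop("fewer than 3 samples in the elastic window")
  x <- curve$axial_strain[sel]; y <- curve$lateral_strain[sel]
  -unname(stats::cov(x, y) / stats::var(x))
}

#' Offset yield stress
#'
#' Stress at the first intersection of the (piecewise-linear) curve with
#' the offset line `sigma = E * (eps - offset)`; both are linear between
#' samples, so the intersection is solved exactly within the bracketing
#' segment.
#'
#' @param curve a `stress_strain_curve`.
#' @param E Young's modulus, MPa.
#' @param offset strain offset (default 0.002, the 0.2% convention).
#' @return Yield stress, MPa.
#' @export
offset_yield <- function(curve, E, offset = 0.002) {
  eps <- curve$axial_strain; sig <- curve$axial_stress
  g <- sig - E * (eps - offset)   # positive below the offset line
  cross <- which(g[-1] < 0 & g[-length(g)] >= 0)
  if (!length(cross))
    stop("curve does not intersect the offset line (purely elastic in range)")
  i <- cross[1]
  t <- g[i] / (g[i] - g[i + 1])
  e_star <- eps[i] + t * (eps[i + 1] - eps[i])
  E * (e_star - offset)
}

#' Plastic strain table from a tension curve
#'
#' Converts post-yield samples to (plastic strain, stress) pairs with
#' `eps_p = eps - sigma/E`, prepending `(0, yield_stress)`.  Only samples
#' with stress above the yield stress enter the table.  Softening
#' (decreasing stress) is rejected or clipped to non-decreasing according
#' to `policy`.
#'
#' @param curve a `stress_strain_curve`.
#' @param E fitted Young's modulus, MPa.
#' @param offset strain offset for the yield point.
#' @param policy `"reject"` (error on softening) or `"clip"`.
#' @return Data frame with columns `plastic_strain`, `stress`.
#' @export
extract_plastic_table <- function(curve, E, offset = 0.002,
                                  policy = c("reject", "clip")) {
  policy <- match.arg(policy)
  ys <- offset_yield(curve, E, offset)
  sel <- curve$axial_stress > ys + 1e-12
  tab <- data.frame(plastic_strain = c(0, curve$axial_strain[sel] -
                                            curve$axial_stress[sel] / E),
                    stress = c(ys, curve$axial_stress[sel]))
  if (any(diff(tab$stress) < 0)) {
    if (policy == "reject")
      stop("softening detected in the plastic table (decreasing stress)")
    tab$stress <- cummax(tab$stress)
  }
  tab
}

#' Calibrated elastic--plastic material model
#'
#' @param youngs_modulus MPa (> 0).
#' @param poisson_ratio in (0, 0.5).
#' @param yield_stress MPa (> 0).
#' @param plastic_table data frame (plastic_strain, stress), stress
#'   non-decreasing; carried for reporting (the solver is elastic, with a
#'   yield-exceedance warning).
#' @return Object of class `material_model`.
#' @export
material_model <- function(youngs_modulus, poisson_ratio, yield_stress,
                           plastic_table = NULL) {
  stopifnot(youngs_modulus > 0, yield_stress > 0)
  if (!is.na(poisson_ratio) && !(poisson_ratio > 0 && poisson_ratio < 0.5))
    stop("poisson_ratio must lie in (0, 0.5)")
  if (!is.null(plastic_table) && any(diff(plastic_table$stress) < 0))
    stop("plastic_table stress must be non-decreasing")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 yield_stress = yield_stress,
                 plastic_table = plastic_table),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("material_model: E = %.1f MPa, nu = %.4f, yield = %.1f MPa, %d plastic points\n",
              x$youngs_modulus, x$poisson_ratio, x$yield_stress,
              if (is.null(x$plastic_table)) 0L else nrow(x$plastic_table)))
  invisible(x)
}

#' Fit the full material model from a dog-bone curve
#'
#' Convenience wrapper: elastic modulus, Poisson's ratio (when lateral
#' strain is present), offset yield and plastic table in one call.
#'
#' @inheritParams fit_elastic_modulus
#' @param offset yield offset strain.
#' @param policy softening policy for the plastic table.
#' @return A `material_model`.
#' @export
fit_material_model <- function(curve, window = c(0.0005, 0.0025),
                               offset = 0.002, policy = "clip") {
  E <- fit_elastic_modulus(curve, window)
  nu <- if (!is.null(curve$lateral_strain)) fit_poisson(curve, window) else NA
  ys <- offset_yield(curve, E, offset)
  tab <- extract_plastic_table(curve, E, offset, policy)
  material_model(E, nu, ys, tab)
}

#' Write a fitted material model as JSON
#' @param model a `material_model`.
#' @param path output file.
#' @export
write_material_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
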