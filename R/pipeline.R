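# End-to-end orchestration: phantom -> segmentation -> registration ->
# osteotomy crop -> meshing -> kinematics -> displacement-driven solve ->
# mid-plate bending moment, over a specimens x digits x repeats design.

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()].  Every field can be
#' overridden from a YAML file via [read_config()].  The synthetic design
#' induces specimen-to-specimen variation by seeded jitter of the phantom
#' radius and cortical intensity, and digit/repeat variation by jitter of
#' the imposed fragment motion, so the summary-statistics stage has real
#' group structure to work on.
#'
#' @param seed master seed; all per-run seeds derive from it.
#' @param n_specimens,n_digits,repeats design size.
#' @param phantom named list of [phantom_spec()] overrides.
#' @param plate named list of [plate_spec()] overrides.
#' @param calibration named list of [density_calibration()] overrides.
#' @param segmentation list: `lo`, `hi` (HU), `r_close` (voxels).
#' @param registration list: `enabled`, `bins`, `levels`, `maxit`.
#' @param motion list: `angle_deg` (relative fragment rotation at full
#'   flexion, about the plate width axis at the distal divot),
#'   `translation` (mm), `angle_jitter_deg`, `marker_noise_sd` (mm).
#' @param solver list: `n_steps`, `mode` ("linear"/"incremental"),
#'   `contact` ("off"/"penalty"), `bone_edge`, `plate_edge` (mm),
#'   `bone_nu`, `tie_radius` (mm).
#' @param material list: `E`, `nu`, `yield_stress` of the plate (MPa).
#' @param jitter list: `radius_sd` (mm), `hu_sd` (HU).
#' @param write_vtk write per-step VTK files?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_specimens = 2L, n_digits = 2L,
                            repeats = 3L,
                            phantom = list(), plate = list(),
                            calibration = list(),
                            segmentation = list(lo = 400, hi = 4000,
                                                r_close = 2),
                            registration = list(enabled = TRUE, bins = 32,
                                                levels = 2,
                                                maxit = c(40, 15)),
                            motion = list(angle_deg = 2,
                                          translation = c(0, -0.1, 0),
                                          angle_jitter_deg = 0.2,
                                          marker_noise_sd = 0),
                            solver = list(n_steps = 10L, mode = "linear",
                                          contact = "off", bone_edge = 1.0,
                                          plate_edge = 0.5, bone_nu = 0.3,
                                          tie_radius = 2),
                            material = list(E = 1740.5, nu = 0.3779,
                                            yield_stress = 100.3),
                            jitter = list(radius_sd = 0.15, hu_sd = 60),
                            write_vtk = FALSE) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_specimens >= 1, cfg$n_digits >= 1, cfg$repeats >= 1)
  if (!cfg$solver$mode %in% c("linear", "incremental"))
    stop("solver$mode must be 'linear' or 'incremental'")
  if (!cfg$solver$contact %in% c("off", "penalty"))
    stop("solver$contact must be 'off' or 'penalty'")
  if (cfg$solver$n_steps < 1) stop("solver$n_steps must be >= 1")
  noisy <- (cfg$motion$marker_noise_sd %||% 0) > 0 ||
    (cfg$phantom$noise_sd %||% 25) > 0
  if (noisy && is.null(cfg$seed)) stop("seed must be set when noise is enabled")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [pipeline_config()]; nested lists merge field-wise.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  validate_config(base)
  base
}

stage_log <- function(run_id, stage, t0, info = "") {
  message(sprintf("[%s] %-12s %6.2fs %s", run_id, stage,
                  as.numeric(Sys.time()) - t0, info))
}

#' Build the phantom plate--bone FE model
#'
#' Runs the imaging half of the pipeline for one synthetic specimen: the
#' intact ("pre-op") phantom is segmented, optionally NMI-registered to
#' the osteotomized ("post-op") phantom, cropped to the osteotomy, given
#' density-derived moduli, meshed, and tied to the positioned plate mesh.
#'
#' @param pspec a `phantom_spec` (its `gap_size` defines the osteotomy).
#' @param plspec a `plate_spec`.
#' @param config a `pipeline_config` (solver/segmentation/registration
#'   settings).
#' @param register run the NMI registration stage? (default from config).
#' @return List: `system` (an `fe_system`), `divots` (2 x 3, world),
#'   `registration` (result or NULL), `masks` (cropped fragments).
#' @export
build_phantom_model <- function(pspec, plspec, config = pipeline_config(),
                                register = config$registration$enabled) {
  ph_post <- make_phalanx_phantom(pspec)
  pre_spec <- pspec; pre_spec$gap_size <- 0
  ph_pre <- make_phalanx_phantom(pre_spec)

  seg <- segment_bone(ph_pre$image, lo = config$segmentation$lo,
                      hi = config$segmentation$hi,
                      r_close = config$segmentation$r_close)
  reg <- NULL
  image_reg <- ph_pre$image
  mask_reg <- seg
  if (isTRUE(register)) {
    reg <- register_rigid_nmi(ph_pre$image, ph_post$image,
                              bins = config$registration$bins,
                              levels = config$registration$levels,
                              maxit = config$registration$maxit)
    image_reg <- resample_image(ph_pre$image, reg$transform,
                                grid = ph_post$image,
                                fill = pspec$background_hu)
    mres <- resample_image(voxel_image(seg$values * 1, seg$spacing,
                                       seg$origin),
                           reg$transform, grid = ph_post$image, fill = 0)
    mask_reg <- voxel_image(mres$values >= 0.5, mres$spacing, mres$origin)
  }
  frags <- crop_to_osteotomy(mask_reg, gap_center = c(0, 0, 0),
                             gap_normal = c(1, 0, 0),
                             gap_size = pspec$gap_size)
  union_mask <- voxel_image(frags$proximal$values | frags$distal$values,
                            mask_reg$spacing, mask_reg$origin)
  cal <- do.call(density_calibration, config$calibration)
  dens <- map_density(image_reg, union_mask, cal)
  bone <- voxels_to_tet10(union_mask, dens,
                          target_edge = config$solver$bone_edge, cal = cal,
                          nu = config$solver$bone_nu,
                          align_point = c(pspec$gap_size / 2, 0, 0))
  plate <- make_plate(plspec, target_edge = config$solver$plate_edge,
                      E = config$material$E, nu = config$material$nu)
  plate <- translate_mesh(plate, c(0, pspec$outer_radius, 0))
  asm <- apply_ties(plate, bone, search_radius = config$solver$tie_radius)
  system <- build_system(asm)
  # gap-face node sets (for the optional penalty contact)
  x <- bone$nodes[, 1]
  dist_nodes <- which(x > 0); prox_nodes <- which(x < 0)
  system$gap_faces <- list(
    proximal = prox_nodes[x[prox_nodes] >= max(x[prox_nodes]) - 1e-6],
    distal = dist_nodes[x[dist_nodes] <= min(x[dist_nodes]) + 1e-6],
    plane_x = max(x[prox_nodes]))
  list(system = system, divots = plate$divots, registration = reg,
       masks = frags)
}

#' Reference-phantom bending moment at a given bone mesh resolution
#'
#' Builds the default noiseless phantom plate--bone model, imposes the
#' standard flexion-scale relative fragment motion (rotation about the
#' plate width axis at the distal divot plus a small transverse
#' translation) in `n_steps` evenly spaced steps, and returns the maximum
#' mid-plate bending moment.  This is the quantity used by the mesh
#' convergence study.
#'
#' @param bone_edge bone mesh target edge, mm.
#' @param config a `pipeline_config` (phantom/plate/solver settings; the
#'   default uses the noiseless reference phantom).
#' @param angle_deg,translation imposed relative motion at the distal
#'   divot.
#' @param register run the registration stage (off by default: the
#'   phantom volumes share one frame).
#' @return List: `moment` (N mm), `curve` (`moment_curve`), `model`.
#' @export
phantom_reference_moment <- function(bone_edge = 1.0,
                                     config = NULL,
                                     angle_deg = 2,
                                     translation = c(0, -0.1, 0),
                                     register = FALSE) {
  if (is.null(config)) {
    config <- pipeline_config()
    config$phantom <- list(noise_sd = 0)
  }
  config$solver$bone_edge <- bone_edge
  pspec <- do.call(phantom_spec, config$phantom)
  plspec <- do.call(plate_spec, config$plate)
  model <- build_phantom_model(pspec, plspec, config, register = register)
  tf <- rigid_transform(rotation_from_axis_angle(c(0, 0, 1),
                                                 angle_deg * pi / 180),
                        translation, origin = model$divots[2, ])
  steps <- make_displacement_steps(tf, config$solver$n_steps)
  res <- solve_steps(model$system, steps, mode = config$solver$mode,
                     yield_stress = config$material$yield_stress)
  curve <- moment_curve(model$system, res)
  list(moment = max_bending_moment(curve), curve = curve, model = model)
}

# solve all steps with optional bone-bone penalty contact at the gap
solve_model_steps <- function(system, steps, config, yield_stress = Inf) {
  if (config$solver$contact == "off" || is.null(system$gap_faces))
    return(solve_steps(system, steps, mode = config$solver$mode,
                       yield_stress = yield_stress))
  # penalty contact: re-solve with springs on gap-face nodes that cross
  # the opposing face plane
  gf <- system$gap_faces
  k_pen <- 100 * max(Matrix::diag(system$Kred))
  out <- vector("list", length(steps))
  factor <- NULL
  for (k in seq_along(steps)) {
    res <- solve_step(system, steps[[k]], step_index = k, factor = factor,
                      yield_stress = yield_stress)
    factor <- res$factor
    for (it in 1:5) {
      xd <- system$mesh$nodes[gf$distal, 1] + res$u[gf$distal, 1]
      pen <- gf$plane_x - xd    # > 0: crossed the opposing face
      act <- which(pen > 0)
      if (!length(act)) break
      nodes <- gf$distal[act]
      penalty <- list(dofs = 3L * (nodes - 1L) + 1L, k = k_pen,
                      target = gf$plane_x - system$mesh$nodes[nodes, 1])
      res <- solve_step(system, steps[[k]], step_index = k,
                        yield_stress = yield_stress, penalty = penalty)
    }
    out[[k]] <- res
  }
  out
}

run_single <- function(config, specimen, digit, rep_i, out_dir = NULL) {
  run_id <- sprintf("S%d_D%d_R%d", specimen, digit, rep_i)
  base_seed <- (config$seed %||% 1L) * 1000L + specimen * 100L +
    digit * 10L + rep_i
  # specimen-level geometry/intensity jitter; digit/repeat-level motion jitter
  jit <- with_seed((config$seed %||% 1L) * 100L + specimen,
                   stats::rnorm(2))
  ph_over <- config$phantom
  ph_over$outer_radius <- (ph_over$outer_radius %||% 3.2) +
    config$jitter$radius_sd * jit[1]
  ph_over$cortical_hu <- (ph_over$cortical_hu %||% 1500) +
    config$jitter$hu_sd * jit[2]
  ph_over$seed <- base_seed
  pspec <- do.call(phantom_spec, ph_over)
  plspec <- do.call(plate_spec, config$plate)

  t0 <- as.numeric(Sys.time())
  model <- build_phantom_model(pspec, plspec, config)
  stage_log(run_id, "model", t0,
            sprintf("%d nodes, %d elems",
                    nrow(model$system$mesh$nodes),
                    nrow(model$system$mesh$elem)))

  mj <- with_seed(base_seed + 500000L, stats::rnorm(1))
  angle <- (config$motion$angle_deg +
              config$motion$angle_jitter_deg * mj) * pi / 180
  divots <- model$divots
  final_tf <- rigid_transform(rotation_from_axis_angle(c(0, 0, 1), angle),
                              config$motion$translation,
                              origin = divots[2, ])
  markers <- make_marker_trajectory(final_tf,
                                    n_frames = config$solver$n_steps + 1L,
                                    noise_sd = config$motion$marker_noise_sd,
                                    seed = base_seed + 900000L)
  frame <- divot_frame(divots[1, ], divots[2, ])
  last <- max(markers$time_index)
  get_pts <- function(frag, ti) {
    m <- markers[markers$fragment == frag & markers$time_index == ti, ]
    as.matrix(m[order(m$marker_label), c("x_mm", "y_mm", "z_mm")])
  }
  T_prox <- fit_rigid_transform(get_pts("proximal", 0),
                                get_pts("proximal", last))$transform
  T_dist <- fit_rigid_transform(get_pts("distal", 0),
                                get_pts("distal", last))$transform
  T_rel <- relative_transform_at_divot(T_prox, T_dist, frame)
  steps <- make_displacement_steps(T_rel, n = config$solver$n_steps)

  t1 <- as.numeric(Sys.time())
  results <- solve_model_steps(model$system, steps, config,
                               yield_stress = config$material$yield_stress)
  stage_log(run_id, "solve", t1, sprintf("%d steps", length(results)))
  curve <- moment_curve(model$system, results)
  if (!is.null(out_dir)) {
    path <- file.path(out_dir, sprintf("moments_%s.csv", run_id))
    write_moment_csv(curve, path)
    if (isTRUE(config$write_vtk)) {
      last_res <- results[[length(results)]]
      write_mesh_vtk(model$system$mesh,
                     file.path(out_dir, sprintf("model_%s.vtk", run_id)),
                     point_data = list(displacement = last_res$u),
                     cell_data = list(modulus = model$system$mesh$E,
                                      von_mises = last_res$von_mises))
    }
  }
  list(run_id = run_id, curve = curve,
       max_bending_moment = max_bending_moment(curve))
}

#' Run the full pipeline over the study design
#'
#' Executes every specimen x digit x repeat combination, writes per-run
#' moment curves, a run-level summary table, aggregate statistics and a
#' provenance record to `out_dir`, and returns the summary.  Deterministic
#' under a fixed `config$seed`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing.
#' @return List of class `pipeline_summary`: `table` (one row per run),
#'   `aggregates`, `anova` (see [summarize_moments()]).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (s in seq_len(config$n_specimens))
    for (d in seq_len(config$n_digits))
      for (r in seq_len(config$repeats)) {
        res <- tryCatch(run_single(config, s, d, r, out_dir),
                        error = function(e)
                          stop(sprintf("stage failure in run S%d_D%d_R%d: %s",
                                       s, d, r, conditionMessage(e)),
                               call. = FALSE))
        rows[[length(rows) + 1L]] <-
          data.frame(specimen_id = s, digit = d, rep = r,
                     max_bending_moment = res$max_bending_moment)
      }
  table <- do.call(rbind, rows)
  summ <- summarize_moments(table)
  if (!is.null(out_dir)) {
    fmt <- function(df) {
      df[] <- lapply(df, function(c)
        if (is.numeric(c)) sprintf("%.10g", c) else c)
      df
    }
    utils::write.csv(fmt(table), file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(fmt(summ$aggregates),
                     file.path(out_dir, "aggregates.csv"),
                     row.names = FALSE, quote = FALSE)
    prov <- list(config = unclass(config),
                 package_version = as.character(utils::packageVersion("platebend")),
                 r_version = R.version.string,
                 solver_mode = config$solver$mode,
                 n_runs = nrow(table),
                 outputs = list.files(out_dir))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  structure(c(summ, list(table = table)), class = "pipeline_summary")
}

#' Summary statistics and one-way ANOVA of the maximum bending moments
#'
#' Mean and sample SD (n-1) by specimen, by digit and overall, plus
#' one-way ANOVA F and p across specimens and across digits.
#'
#' @param table data frame with columns `specimen_id`, `digit`, `rep`,
#'   `max_bending_moment`.
#' @return List: `aggregates` (long data frame of group means/SDs),
#'   `anova` (data frame: factor, F, p, degenerate flag).
#' @export
summarize_moments <- function(table) {
  v <- table$max_bending_moment
  agg_by <- function(g, label) {
    sp <- split(v, g)
    data.frame(grouping = label, group = names(sp),
               n = lengths(sp),
               mean = vapply(sp, mean, 0),
               sd = vapply(sp, stats::sd, 0))
  }
  aggregates <- rbind(agg_by(table$specimen_id, "specimen"),
                      agg_by(table$digit, "digit"),
                      data.frame(grouping = "grand", group = "all",
                                 n = length(v), mean = mean(v),
                                 sd = stats::sd(v)))
  one_way <- function(g, label) {
    g <- factor(g)
    if (nlevels(g) < 2 || any(tabulate(g) < 2))
      return(data.frame(factor = label, F = NA, p = NA, degenerate = TRUE))
    if (stats::var(v) < 1e-24)
      return(data.frame(factor = label, F = NA, p = NA, degenerate = TRUE))
    a <- stats::anova(stats::lm(v ~ g))
    data.frame(factor = label, F = a$`F value`[1], p = a$`Pr(>F)`[1],
               degenerate = FALSE)
  }
  list(aggregates = aggregates,
       anova = rbind(one_way(table$specimen_id, "specimen"),
                     one_way(table$digit, "digit")))
}

#' @export
print.pipeline_summary <- function(x, ...) {
  g <- x$aggregates[x$aggregates$grouping == "grand", ]
  cat(sprintf("pipeline_summary: %d runs, max bending moment %.3f +/- %.3f N mm\n",
              nrow(x$table), g$mean, g$sd))
  print(x$anova, row.names = FALSE)
  invisible(x)
}
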