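test_that("centerline frame tracks the plate pose", {
  plate <- fixture("plate_coarse", function()
    make_plate(plate_spec(), target_edge = 0.5))

  # zero displacement: tangent is the undeformed long axis
  fr0 <- deformed_centerline_frame(plate, 0 * plate$nodes)
  expect_equal(fr0$tangent, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr0$t1, c(0, 0, 1), tolerance = 1e-9)

  # rigid rotation of the whole plate rotates the tangent with it
  R <- rotation_from_axis_angle(c(0, 0, 1), 20 * pi / 180)
  u_rot <- plate$nodes %*% t(R) - plate$nodes
  frR <- deformed_centerline_frame(plate, u_rot)
  expect_equal(frR$tangent, as.vector(R %*% c(1, 0, 0)), tolerance = 1e-9)

  # pure-bending displacement field of curvature kappa: the tangent at
  # mid-span rotates by the beam-theory angle (within 1 degree)
  kappa <- 0.01
  x <- plate$nodes[, 1]; y <- plate$nodes[, 2]
  u_bend <- cbind(-kappa * x * y, kappa * x^2 / 2, 0)
  frB <- deformed_centerline_frame(plate, u_bend, station = 0.75)
  xs <- min(x) + 0.75 * diff(range(x))
  slope_exact <- atan(kappa * xs)
  slope_num <- atan2(frB$tangent[2], frB$tangent[1])
  expect_lt(abs(slope_num - slope_exact), pi / 180)
})

test_that("cut-plane resultants reproduce cantilever statics", {
  cs <- cantilever_solution()
  sys <- cs$system
  res <- structure(list(step_index = 1L,
                        u = matrix(cs$sol$u, ncol = 3, byrow = TRUE),
                        f = matrix(cs$sol$f, ncol = 3, byrow = TRUE)),
                   class = "fe_result")

  # zero displacement: zero resultants
  res0 <- structure(list(step_index = 1L, u = 0 * res$u, f = 0 * res$f),
                    class = "fe_result")
  fr0 <- deformed_centerline_frame(sys$mesh, res0$u)
  r0 <- cut_plane_resultants(sys, res0, fr0)
  expect_lt(max(abs(as.numeric(r0))), 1e-10)

  # tip force F at lever arm a from the plane: bending moment = F * a
  F_tip <- colSums(res$f[cs$tip, ])
  for (station in c(0.35, 0.5, 0.65)) {
    fr <- deformed_centerline_frame(sys$mesh, 0 * res$u, station = station)
    r <- cut_plane_resultants(sys, res, fr, deformed = FALSE)
    a <- cs$L - fr$point[1]
    expect_equal(abs(r$M_t1), abs(F_tip[2]) * a, tolerance = 0.02)
    expect_equal(abs(r$V1), 0, tolerance = 1e-6 * abs(F_tip[2]))
    expect_equal(abs(r$V2), abs(F_tip[2]), tolerance = 0.02)
  }

  # side-independence: equal magnitude, opposite sign
  fr <- deformed_centerline_frame(sys$mesh, res$u)
  rd <- cut_plane_resultants(sys, res, fr)
  rp <- cut_plane_resultants(sys, res, fr, from = "proximal")
  for (cc in c("N", "V1", "V2", "M_axial", "M_t1", "M_t2"))
    expect_equal(rd[[cc]], -rp[[cc]], tolerance = 1e-6 * max(1, abs(rd[[cc]])))
})

test_that("moment curves scale linearly and peak at the final step", {
  model <- small_model()
  tf <- rigid_transform(diag(3), c(0, -0.2, 0))   # translation-only ramp
  steps <- make_displacement_steps(tf, 10)
  res <- solve_steps(model$system, steps)

  # reference-configuration resultants are exactly linear in the ramp
  mc_ref <- moment_curve(model$system, res, deformed = FALSE)
  for (k in c(2, 5, 7))
    expect_equal(mc_ref$M_bend[k], (k / 10) * mc_ref$M_bend[10],
                 tolerance = 1e-6)

  # monotone ramp: the maximum sits at the final step (both conventions)
  mc_def <- moment_curve(model$system, res)
  expect_equal(max_bending_moment(mc_def), mc_def$M_bend[10])
  expect_equal(max_bending_moment(mc_ref), mc_ref$M_bend[10])

  # single step: the maximum is that step's value
  mc1 <- moment_curve(model$system, res[10])
  expect_equal(max_bending_moment(mc1), mc1$M_bend[1])

  # moment curve CSV is written with full columns
  path <- tempfile(fileext = ".csv")
  write_moment_csv(mc_def, path)
  back <- utils::read.csv(path)
  expect_named(back, c("step", "N", "V1", "V2", "M_axial", "M_t1", "M_t2",
                       "M_bend"))
  expect_equal(back$M_bend, mc_def$M_bend, tolerance = 1e-8)
})

test_that("frame covariance: a rigidly rotated problem reports the same moments", {
  cs <- cantilever_solution()
  res <- structure(list(step_index = 1L,
                        u = matrix(cs$sol$u, ncol = 3, byrow = TRUE),
                        f = matrix(cs$sol$f, ncol = 3, byrow = TRUE)),
                   class = "fe_result")
  fr <- deformed_centerline_frame(cs$mesh, res$u)
  r <- cut_plane_resultants(cs$system, res, fr)

  # rotate mesh, displacements, and forces rigidly by R
  R <- rotation_from_axis_angle(c(1, 2, 3), 0.7)
  mesh_rot <- cs$mesh
  mesh_rot$nodes <- cs$mesh$nodes %*% t(R)
  sys_rot <- cs$system
  sys_rot$mesh <- mesh_rot
  res_rot <- res
  res_rot$u <- res$u %*% t(R)
  res_rot$f <- res$f %*% t(R)
  fr_rot <- list(point = as.vector(R %*% fr$point),
                 tangent = as.vector(R %*% fr$tangent),
                 t1 = as.vector(R %*% fr$t1),
                 t2 = as.vector(R %*% fr$t2))
  # internal forces must be recomputed in the rotated frame; rotating the
  # element force vectors is equivalent for this congruent mesh, so compare
  # through the projected components directly
  r_rot <- local({
    mesh <- sys_rot$mesh
    pe <- seq_len(nrow(mesh$elem))
    def <- mesh$nodes + res_rot$u
    el <- mesh$elem
    cen <- (def[el[, 1], ] + def[el[, 2], ] + def[el[, 3], ] + def[el[, 4], ]) / 4
    proj <- as.vector(sweep(cen, 2, fr_rot$point) %*% fr_rot$tangent)
    P_side <- pe[proj < 0]; D_side <- pe[proj >= 0]
    shared <- intersect(unique(as.vector(el[P_side, ])),
                        unique(as.vector(el[D_side, ])))
    fm <- res_rot$f  # nodal forces rotate covariantly
    # for region sums use rotated original internal forces
    f_orig <- platebend:::internal_forces_subset(cs$system$op,
                                                 as.vector(t(res$u)),
                                                 P_side)
    fmat <- matrix(f_orig, ncol = 3, byrow = TRUE) %*% t(R)
    lev <- sweep(def[shared, , drop = FALSE], 2, fr_rot$point)
    Fs <- colSums(fmat[shared, , drop = FALSE])
    Ms <- colSums(cbind(
      lev[, 2] * fmat[shared, 3] - lev[, 3] * fmat[shared, 2],
      lev[, 3] * fmat[shared, 1] - lev[, 1] * fmat[shared, 3],
      lev[, 1] * fmat[shared, 2] - lev[, 2] * fmat[shared, 1]))
    c(N = sum(Fs * fr_rot$tangent), M_t1 = sum(Ms * fr_rot$t1),
      M_t2 = sum(Ms * fr_rot$t2))
  })
  expect_equal(unname(r_rot["N"]), r$N, tolerance = 1e-6)
  expect_equal(unname(r_rot["M_t1"]), r$M_t1, tolerance = 1e-6)
  expect_equal(unname(r_rot["M_t2"]), r$M_t2, tolerance = 1e-6)
})

test_that("capacity check implements the rectangular-section formula", {
  rep1 <- capacity_check(6.78, width = 6, thickness = 3,
                         flexural_strength = 69)
  expect_equal(rep1$allowable_moment, 621)
  expect_equal(rep1$safety_factor, 621 / 6.78, tolerance = 1e-12)
  expect_equal(rep1$utilization, 6.78 / 621, tolerance = 1e-12)

  # prior-study weakest patch vs the measured internal demand: ~107x
  expect_equal(728 / 6.78, 107.4, tolerance = 0.01)

  # doubling thickness quadruples the allowable moment
  rep2 <- capacity_check(6.78, 6, 6, 69)
  expect_equal(rep2$allowable_moment / rep1$allowable_moment, 4)

  # zero demand: infinite safety, flagged
  rep0 <- capacity_check(0, 6, 3, 69)
  expect_true(rep0$infinite_safety)
  expect_identical(rep0$safety_factor, Inf)
  expect_error(capacity_check(1, -6, 3, 69))
})
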