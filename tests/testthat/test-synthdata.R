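test_that("phantom geometry matches its analytic construction", {
  ph <- small_phantom()   # 0.5 mm voxels, noiseless, 3 mm gap
  spec <- ph$spec

  # gap = 3 mm at 0.5 mm voxels: exactly 6 empty transverse planes between
  # the fragment masks
  prox_x <- apply(ph$proximal_mask$values, 1, any)
  dist_x <- apply(ph$distal_mask$values, 1, any)
  gap_planes <- which(dist_x)[1] - max(which(prox_x)) - 1
  expect_equal(gap_planes, 6)

  # fragment masks are disjoint, cortical HU inside
  expect_false(any(ph$proximal_mask$values & ph$distal_mask$values))
  expect_true(all(ph$image$values[ph$proximal_mask$values] == spec$cortical_hu))

  # noiseless: thresholded voxel count matches the analytic annulus volume
  # within the voxel-centre discretization tolerance (2%)
  ph_def <- fixture("phantom_def_noiseless", function()
    make_phalanx_phantom(phantom_spec(noise_sd = 0)))
  s <- ph_def$spec
  n_band <- sum(ph_def$image$values >= 400 & ph_def$image$values <= 4000)
  v_analytic <- pi * (s$outer_radius^2 - (s$outer_radius - s$cortical_thickness)^2) *
    (s$bone_length - s$gap_size)
  expect_equal(n_band * s$voxel_size^3, v_analytic, tolerance = 0.02)

  # gap 0: one 26-connected cortical component
  ph0 <- make_phalanx_phantom(small_phantom_spec(gap_size = 0))
  band <- ph0$image$values >= 400 & ph0$image$values <= 4000
  expect_identical(max(label_components(band)), 1L)

  # invariant violations are rejected
  expect_error(phantom_spec(voxel_size = 2), "unresolvable")
  expect_error(phantom_spec(cortical_thickness = 5), "cortical_thickness")
  expect_error(phantom_spec(marrow_hu = 500), "marrow_hu")

  # bit-reproducible under the seed
  a <- make_phalanx_phantom(small_phantom_spec(noise_sd = 25, seed = 9L))
  b <- make_phalanx_phantom(small_phantom_spec(noise_sd = 25, seed = 9L))
  expect_identical(a$image$values, b$image$values)
})

test_that("plate mesh has the printed hole layout and analytic volume", {
  spec <- plate_spec()
  expect_equal(plate_hole_centers(spec), c(-10, -5, 5, 10))

  plate <- fixture("plate_default", function() make_plate(plate_spec()))
  expect_length(grep("^hole_", names(plate$node_sets)), 4)

  # hole node sets are mirror-symmetric under x -> -x and z -> -z
  key <- function(n) paste(round(n[, 1], 6), round(n[, 2], 6),
                           round(n[, 3], 6))
  all_keys <- key(plate$nodes)
  for (h in 1:4) {
    nd <- plate$nodes[plate$node_sets[[paste0("hole_", h)]], , drop = FALSE]
    mirror_x <- key(nd %*% diag(c(-1, 1, 1)))
    partner <- plate$node_sets[[paste0("hole_", 5 - h)]]
    expect_setequal(match(mirror_x, all_keys), partner)
    mirror_z <- key(nd %*% diag(c(1, 1, -1)))
    expect_setequal(match(mirror_z, all_keys),
                    plate$node_sets[[paste0("hole_", h)]])
  }

  # volume: box minus four hole cylinders, within 2%
  v_exact <- spec$length * spec$width * spec$thickness -
    4 * pi * (spec$hole_diameter / 2)^2 * spec$thickness
  expect_equal(mesh_volume(plate), v_exact, tolerance = 0.02)

  # divots on the top surface
  expect_equal(plate$divots[, 2], rep(spec$thickness, 2))

  expect_error(plate_spec(length = 0), "degenerate")
  expect_error(plate_spec(hole_spacing = 1), "overlap")
})

test_that("marker trajectories are rigid, geodesic and recoverable", {
  # identity motion: all frames identical
  mk0 <- make_marker_trajectory(rigid_transform(), n_frames = 4)
  f0 <- mk0[mk0$time_index == 0, c("x_mm", "y_mm", "z_mm")]
  for (k in 1:3)
    expect_equal(unname(as.matrix(mk0[mk0$time_index == k,
                                      c("x_mm", "y_mm", "z_mm")])),
                 unname(as.matrix(f0)), tolerance = 1e-12)

  # 10 degrees in 11 frames: frame k carries exactly k degrees
  tf <- rigid_transform(rotation_from_axis_angle(c(0, 0, 1), 10 * pi / 180),
                        c(0, 0, 0), origin = c(7.5, 4.7, 0))
  mk <- make_marker_trajectory(tf, n_frames = 11)
  d0 <- as.matrix(mk[mk$time_index == 0 & mk$fragment == "distal",
                     c("x_mm", "y_mm", "z_mm")])
  for (k in c(3, 7)) {
    dk <- as.matrix(mk[mk$time_index == k & mk$fragment == "distal",
                       c("x_mm", "y_mm", "z_mm")])
    fit <- fit_rigid_transform(d0, dk)
    expect_equal(rotation_axis_angle(fit$transform$rotation)$angle,
                 k * pi / 180, tolerance = 1e-9)
  }

  # noiseless trajectories are exactly rigid: inter-marker distances constant
  dists <- sapply(0:10, function(k) {
    dk <- as.matrix(mk[mk$time_index == k & mk$fragment == "distal",
                       c("x_mm", "y_mm", "z_mm")])
    as.vector(dist(dk))
  })
  expect_lt(max(abs(dists - dists[, 1])), 1e-9)

  # round-trip through the rigid fit reproduces the generator transform
  tf2 <- rigid_transform(rotation_from_axis_angle(c(0.2, 1, 0.1), 0.05),
                         c(0.3, -0.2, 0.1), origin = c(7.5, 4.7, 0))
  mk2 <- make_marker_trajectory(tf2, n_frames = 5)
  dA <- as.matrix(mk2[mk2$time_index == 0 & mk2$fragment == "distal",
                      c("x_mm", "y_mm", "z_mm")])
  dB <- as.matrix(mk2[mk2$time_index == 4 & mk2$fragment == "distal",
                      c("x_mm", "y_mm", "z_mm")])
  fit <- fit_rigid_transform(dA, dB)$transform
  pts <- matrix(rnorm(9), 3, 3)
  expect_lt(max(abs(apply_transform(fit, pts) - apply_transform(tf2, pts))),
            1e-9)

  expect_error(make_marker_trajectory(tf, n_frames = 4,
                                      proximal_markers = diag(3)[1:2, ]),
               "at least 3")
  # CSV round-trip
  path <- tempfile(fileext = ".csv")
  write_marker_csv(mk2, path)
  expect_equal(read_marker_csv(path)$x_mm, mk2$x_mm, tolerance = 1e-12)
})

test_that("dog-bone curve is bilinear with an exact 0.2% offset yield", {
  cv <- make_dogbone_curve()  # PEEK constants

  # elastic slope over the first 0.2% strain is exactly E
  sel <- cv$axial_strain <= 0.002 & cv$axial_strain > 0
  slopes <- cv$axial_stress[sel] / cv$axial_strain[sel]
  expect_equal(slopes, rep(1740.5, sum(sel)), tolerance = 1e-12)

  # analytic intersection of the offset line with the hardening branch
  E <- 1740.5; H <- 174; sy <- 100.3
  eps_k <- cv$kink$strain
  expect_equal(eps_k, sy / E - 0.002 * H / (E - H), tolerance = 1e-12)
  eps_y <- sy / E + 0.002
  sig_on_curve <- cv$kink$stress + H * (eps_y - eps_k)
  expect_equal(sig_on_curve, sy, tolerance = 1e-9)

  # lateral strain is -nu * axial in the elastic region
  expect_equal(cv$lateral_strain[sel], -0.3779 * cv$axial_strain[sel],
               tolerance = 1e-12)

  expect_error(make_dogbone_curve(offset_yield = 500, max_strain = 0.05),
               "never yields")
  # reproducible under seed
  n1 <- make_dogbone_curve(noise_sd = 0.5, seed = 4L)
  n2 <- make_dogbone_curve(noise_sd = 0.5, seed = 4L)
  expect_identical(n1$axial_stress, n2$axial_stress)
})
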