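test_that("cube splitting yields the enumerated tet10 topology", {
  m <- cubes_to_tet10(matrix(0L, 1, 3), 1)
  expect_identical(nrow(m$elem), 6L)
  # independent enumeration: 8 corners + midpoints of the 19 distinct tet
  # edges (12 cube edges + 6 face diagonals + 1 main diagonal)
  expect_identical(nrow(m$nodes), 27L)
  expect_equal(mesh_volume(m), 1, tolerance = 1e-12)
  expect_true(all(element_volumes(m) > 0))

  # mid-edge nodes at exact edge midpoints
  for (e in 1:6) {
    mid <- m$nodes[m$elem[e, 5:10], , drop = FALSE]
    pairs <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
    corner <- m$nodes[m$elem[e, 1:4], , drop = FALSE]
    expect_equal(mid, (corner[pairs[, 1], ] + corner[pairs[, 2], ]) / 2,
                 tolerance = 1e-12)
  }

  # a 2x3x4 grid: exact volume and no orphan nodes
  g <- as.matrix(expand.grid(0:1, 0:2, 0:3))
  mg <- cubes_to_tet10(g, 0.5)
  expect_equal(mesh_volume(mg), 24 * 0.5^3, tolerance = 1e-12)
  expect_setequal(unique(as.vector(mg$elem)), seq_len(nrow(mg$nodes)))
})

test_that("voxel coarsening preserves volume and maps density to modulus", {
  ph <- small_phantom()
  mask <- voxel_image(ph$proximal_mask$values | ph$distal_mask$values,
                      0.5, ph$image$origin)
  # uniform density on a fully occupied solid -> uniform modulus
  solid <- voxel_image(array(TRUE, c(8, 8, 8)), 0.5)
  dens_s <- voxel_image(array(1000, c(8, 8, 8)), 0.5)
  msolid <- voxels_to_tet10(solid, dens_s, target_edge = 1,
                            cal = density_calibration())
  expect_equal(unique(msolid$E), 10000)
  dens <- voxel_image(array(1000, dim(mask$values)), 0.5, mask$origin)
  mesh <- voxels_to_tet10(mask, dens, target_edge = 1,
                          cal = density_calibration())
  # mesh volume equals the occupied-block volume exactly
  f <- 2
  d <- dim(mask$values)
  blocks <- 0
  for (i in seq_len(d[1] / f)) for (j in seq_len(d[2] / f))
    for (k in seq_len(d[3] / f)) {
      sel <- mask$values[(i - 1) * f + 1:f, (j - 1) * f + 1:f,
                         (k - 1) * f + 1:f]
      if (mean(sel) >= 0.5) blocks <- blocks + 1
    }
  expect_equal(mesh_volume(mesh), blocks * 1, tolerance = 1e-9)
  # power-law property: doubling density scales modulus by 2^1.5
  dens2 <- voxel_image(array(2000, dim(mask$values)), 0.5, mask$origin)
  mesh2 <- voxels_to_tet10(mask, dens2, target_edge = 1,
                           cal = density_calibration())
  expect_equal(mesh2$E / mesh$E, rep(2^1.5, length(mesh$E)),
               tolerance = 1e-12)
  expect_error(voxels_to_tet10(voxel_image(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
})

test_that("assembled stiffness passes patch, rigid-mode and scaling checks", {
  m <- cubes_to_tet10(as.matrix(expand.grid(0:1, 0:1, 0:1)), 0.7,
                      E = 1200, nu = 0.33)
  op <- assemble(m)

  # rigid translations and rotations are zero-energy
  W <- matrix(c(0, -0.3, 0.1, 0.3, 0, -0.2, -0.1, 0.2, 0), 3, 3)
  u_rigid <- as.vector(t(sweep(m$nodes %*% t(W), 2, c(1, -2, 0.5), `+`)))
  kn <- max(abs(op$K))
  expect_lt(max(abs(op$K %*% u_rigid)) / kn, 1e-8)

  # patch test: arbitrary linear displacement field gives the exact
  # constant stress everywhere
  A <- matrix(c(2e-3, 3e-4, -1e-4, 5e-4, -1e-3, 2e-4, 1e-4, 0, 8e-4), 3, 3)
  u_lin <- as.vector(t(m$nodes %*% t(A)))
  S <- element_stresses(op, u_lin)
  eps <- (A + t(A)) / 2
  voigt <- c(diag(eps), 2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[1, 3])
  D <- platebend:::elasticity_matrix(0.33, 1200)
  expect_lt(max(abs(sweep(S, 2, as.vector(D %*% voigt)))), 1e-10)
  # and the patch field is in equilibrium at interior nodes (f = K u is
  # supported on the boundary only)
  f <- matrix(as.vector(op$K %*% u_lin), ncol = 3, byrow = TRUE)
  interior <- which(apply(m$nodes, 1, function(p)
    all(p > 1e-9 & p < 1.4 - 1e-9)))
  expect_lt(max(abs(f[interior, ])), 1e-9 * max(abs(f)))

  # scaling all moduli by c scales K by c
  m2 <- m; m2$E <- 3 * m$E
  expect_lt(max(abs(assemble(m2)$K - 3 * op$K)), 1e-9 * kn)
})

test_that("ties reproduce a merged mesh and keep rigid motions zero-energy", {
  f <- 0.5
  cubesA <- as.matrix(expand.grid(0:7, 0:1, 0:1))
  cubesB <- as.matrix(expand.grid(0:7, 2:3, 0:1))
  mA <- cubes_to_tet10(cubesA, f, E = 1000, nu = 0.3)
  mB <- cubes_to_tet10(cubesB, f, E = 1000, nu = 0.3)
  mM <- cubes_to_tet10(rbind(cubesA, cubesB), f, E = 1000, nu = 0.3)
  mB$node_sets$hole_1 <- which(abs(mB$nodes[, 2] - 1) < 1e-9)
  asm <- apply_ties(mB, mA, search_radius = 0.4)

  # coincident nodes: every slave couples to exactly one master at zero
  # distance; eliminated DOF count is 3 per slave node
  expect_equal(max(asm$ties$distance), 0)
  expect_identical(nrow(asm$ties), length(mB$node_sets$hole_1))
  sys <- build_system(asm)
  expect_identical(3L * nrow(asm$mesh$nodes) - ncol(sys$P),
                   3L * length(mB$node_sets$hole_1))

  # rigid motion of the tied assembly is zero-energy, and the coupling
  # projection reproduces it exactly
  W <- matrix(c(0, -0.3, 0.1, 0.3, 0, -0.2, -0.1, 0.2, 0), 3, 3)
  u_rigid <- as.vector(t(sweep(asm$mesh$nodes %*% t(W), 2, c(1, 2, 3), `+`)))
  expect_lt(max(abs(sys$op$K %*% u_rigid)) / max(abs(sys$op$K)), 1e-8)
  red_idx <- which(!is.na(sys$red_index))
  expect_lt(max(abs(as.numeric(sys$P %*% u_rigid[red_idx]) - u_rigid)), 1e-9)

  # tied solve equals the merged-mesh solve at every shared location
  x <- asm$mesh$nodes[, 1]
  clamp <- which(x < 1e-9); tip <- which(x > max(x) - 1e-9)
  pd <- c(dof_of(clamp, 1), dof_of(clamp, 2), dof_of(clamp, 3),
          dof_of(tip, 2))
  pv <- c(rep(0, 3 * length(clamp)), rep(0.1, length(tip)))
  solT <- solve_linear_system(sys, pd, pv)
  sysM <- build_system(mM)
  xM <- mM$nodes[, 1]
  clampM <- which(xM < 1e-9); tipM <- which(xM > max(xM) - 1e-9)
  solM <- solve_linear_system(sysM,
    c(dof_of(clampM, 1), dof_of(clampM, 2), dof_of(clampM, 3),
      dof_of(tipM, 2)),
    c(rep(0, 3 * length(clampM)), rep(0.1, length(tipM))))
  key <- function(n) paste(round(n[, 1], 6), round(n[, 2], 6),
                           round(n[, 3], 6))
  uT <- matrix(solT$u, ncol = 3, byrow = TRUE)
  uM <- matrix(solM$u, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(uT - uM[match(key(asm$mesh$nodes), key(mM$nodes)), ])),
            1e-8)

  # no master within reach is an error naming the set (lift the plate so
  # nothing is coincident, then shrink the footprint radius to nothing)
  mB_off <- translate_mesh(mB, c(0, 0.25, 0))
  mB_off$node_sets$hole_1 <- mB$node_sets$hole_1
  expect_error(apply_ties(mB_off, mA, search_radius = 0.05), "hole_1")
})

test_that("slender cantilever reproduces Euler-Bernoulli beam theory", {
  cs <- cantilever_solution()
  fm <- matrix(cs$sol$f, ncol = 3, byrow = TRUE)
  lev <- sweep(cs$mesh$nodes[cs$clamp, ], 2, c(0, 0.5, 0.5))
  Mz <- sum(lev[, 1] * fm[cs$clamp, 2] - lev[, 2] * fm[cs$clamp, 1])
  M_eb <- 3 * cs$E * cs$I * cs$delta / cs$L^2
  expect_equal(abs(Mz), M_eb, tolerance = 0.05)

  # global equilibrium: clamp reactions balance the tip loads
  expect_lt(max(abs(colSums(fm[cs$clamp, ]) + colSums(fm[cs$tip, ]))),
            1e-6 * max(abs(fm)))
  # all nodal forces live on constrained nodes only
  free <- setdiff(seq_len(nrow(cs$mesh$nodes)), c(cs$clamp, cs$tip))
  expect_lt(max(abs(fm[free, ])), 1e-6 * max(abs(fm)))
  # strain energy is positive
  expect_gt(0.5 * sum(cs$sol$u * cs$sol$f), 0)
})

test_that("displacement-driven steps behave linearly and detect yield", {
  model <- small_model()
  sys <- model$system

  # identity step: zero displacement, zero stress
  r0 <- solve_step(sys, rigid_transform())
  expect_lt(max(abs(r0$u)), 1e-10)
  expect_lt(max(abs(r0$element_stress)), 1e-10)

  # doubling a translation doubles displacements and stresses (linear mode)
  t1 <- rigid_transform(diag(3), c(0, -0.05, 0))
  t2 <- rigid_transform(diag(3), c(0, -0.10, 0))
  r1 <- solve_step(sys, t1)
  r2 <- solve_step(sys, t2, factor = r1$factor)
  expect_lt(max(abs(r2$u - 2 * r1$u)), 1e-9 * max(abs(r2$u)))
  expect_lt(max(abs(r2$element_stress - 2 * r1$element_stress)),
            1e-9 * max(abs(r2$element_stress)))

  # equilibrium: fixed-set reactions balance driven-set reactions
  fixed <- sys$mesh$node_sets$proximal_fixed
  driven <- sys$mesh$node_sets$distal_driver
  expect_lt(max(abs(colSums(r2$f[fixed, ]) + colSums(r2$f[driven, ]))),
            1e-6 * max(abs(r2$f)))

  # yield exceedance warning on an absurdly large motion
  expect_warning(solve_step(sys, rigid_transform(diag(3), c(0, -30, 0)),
                            yield_stress = 100.3),
                 "yield")
})

test_that("incremental mode approaches the linear solution for small motion", {
  mesh <- cubes_to_tet10(as.matrix(expand.grid(0:19, 0:1, 0:1)), 0.5,
                         E = 1740.5, nu = 0.3779)
  x <- mesh$nodes[, 1]
  mesh$node_sets$proximal_fixed <- which(x < 1e-9)
  mesh$node_sets$distal_driver <- which(x > max(x) - 1e-9)
  sys <- build_system(mesh)
  tf <- rigid_transform(diag(3), c(0, -0.02, 0))
  steps <- make_displacement_steps(tf, 2)
  lin <- solve_steps(sys, steps, mode = "linear")
  inc <- solve_steps(sys, steps, mode = "incremental")
  rel <- max(abs(inc[[2]]$u - lin[[2]]$u)) / max(abs(lin[[2]]$u))
  expect_lt(rel, 0.01)
})
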