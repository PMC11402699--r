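# Linear elasticity on quadratic tetrahedra.
#
# Isoparametric tet10 with straight sides: the geometric mapping is affine,
# so the Jacobian is constant per element and the 4-point Gauss rule
# integrates the (quadratic) strain energy exactly.  Voigt order is
# (xx, yy, zz, xy, yz, xz) with engineering shear strains.

tet4_gauss <- local({
  a <- 0.585410196624969; b <- 0.138196601125011
  rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
})

# unit-modulus isotropic elasticity matrix
elasticity_matrix <- function(nu, E = 1) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3][upper.tri(diag(3))] <- lam
  D[1:3, 1:3][lower.tri(diag(3))] <- lam
  D
}

# strain-displacement matrix (6 x 30) at barycentric point L (length 4)
tet10_B <- function(gradL, L) {
  dN <- matrix(0, 10, 3)
  for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * gradL[i, ]
  for (ei in 1:6) {
    p <- tet10_edge_pairs[ei, ]
    dN[4 + ei, ] <- 4 * (L[p[1]] * gradL[p[2], ] + L[p[2]] * gradL[p[1], ])
  }
  B <- matrix(0, 6, 30)
  ix <- 3 * (1:10) - 2
  B[1, ix]     <- dN[, 1]
  B[2, ix + 1] <- dN[, 2]
  B[3, ix + 2] <- dN[, 3]
  B[4, ix]     <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
  B[5, ix + 1] <- dN[, 3]; B[5, ix + 2] <- dN[, 2]
  B[6, ix]     <- dN[, 3]; B[6, ix + 2] <- dN[, 1]
  B
}

tet10_geometry <- function(Xc) {
  J <- t(Xc[2:4, ] - matrix(Xc[1, ], 3, 3, byrow = TRUE))  # columns = edges
  detJ <- det(J)
  if (!is.finite(detJ) || detJ <= 0) stop("non-positive Jacobian")
  gi <- solve(J)                 # rows = grad L2..L4
  gradL <- rbind(-colSums(gi), gi)
  list(gradL = gradL, vol = detJ / 6)
}

#' Stiffness matrix of a single tet10 element
#'
#' @param Xc 4 x 3 matrix of corner coordinates (mm); mid-edge nodes are
#'   implied at edge midpoints.
#' @param nu Poisson's ratio.
#' @param E Young's modulus, MPa (default 1: unit-modulus matrix, to be
#'   scaled by the element modulus at assembly).
#' @return 30 x 30 symmetric stiffness matrix (dof order: 3 per node,
#'   node-major).
#' @export
tet10_stiffness <- function(Xc, nu, E = 1) {
  g <- tet10_geometry(Xc)
  D <- elasticity_matrix(nu, E)
  Ke <- matrix(0, 30, 30)
  for (q in 1:4) {
    B <- tet10_B(g$gradL, tet4_gauss[q, ])
    Ke <- Ke + (g$vol / 4) * crossprod(B, D %*% B)
  }
  (Ke + t(Ke)) / 2
}

# dof index matrix (M x 30) for a mesh
dof_matrix <- function(mesh) {
  M <- nrow(mesh$elem)
  Dof <- matrix(0L, M, 30)
  for (l in 1:10) for (c in 1:3)
    Dof[, 3L * (l - 1L) + c] <- 3L * (mesh$elem[, l] - 1L) + c
  Dof
}

# group elements into congruence classes: elements that are translates of
# one another (and share nu) reuse one unit-modulus stiffness matrix
congruence_groups <- function(mesh) {
  el <- mesh$elem; nd <- mesh$nodes
  rel <- matrix(0, nrow(el), 9)
  for (cn in 2:4)
    rel[, (cn - 2) * 3 + 1:3] <-
      nd[el[, cn], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  sig <- apply(cbind(round(rel, 9), mesh$nu), 1, paste, collapse = ",")
  split(seq_len(nrow(el)), sig)
}

#' Assemble the global stiffness operator of a mesh
#'
#' 4-point Gauss integration per element; symmetric sparse result.  Before
#' constraints are applied the operator has exactly six zero-energy modes
#' (rigid translations and rotations).  Elements are grouped into
#' congruence classes (cube-split meshes have only six), and each class's
#' unit-modulus stiffness is computed once and scaled by the element
#' modulus.
#'
#' @param mesh a `tet10_mesh`.
#' @return List of class `fe_operator`: `K` (sparse dsCMatrix,
#'   3N x 3N), `groups` (per congruence class: element indices, unit
#'   stiffness, centroid strain-displacement matrix), `dof` (M x 30 dof
#'   index matrix), `mesh`.
#' @export
assemble <- function(mesh) {
  Dof <- dof_matrix(mesh)
  groups <- congruence_groups(mesh)
  ndof <- 3L * nrow(mesh$nodes)
  ii <- jj <- xx <- vector("list", length(groups))
  ginfo <- vector("list", length(groups))
  rsel <- rep(1:30, times = 30); csel <- rep(1:30, each = 30)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    Xc <- mesh$nodes[mesh$elem[idx[1], 1:4], , drop = FALSE]
    nu <- mesh$nu[idx[1]]
    Ke <- tet10_stiffness(Xc, nu)
    if (!all(is.finite(Ke)))
      stop("non-finite stiffness entries in element ", idx[1])
    geom <- tet10_geometry(Xc)
    Bc <- tet10_B(geom$gradL, rep(0.25, 4))
    ginfo[[gi]] <- list(idx = idx, Ke = Ke,
                        DB = elasticity_matrix(nu) %*% Bc, vol = geom$vol)
    ii[[gi]] <- as.vector(Dof[idx, rsel])
    jj[[gi]] <- as.vector(Dof[idx, csel])
    xx[[gi]] <- as.vector(outer(mesh$E[idx], as.vector(Ke)))
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  structure(list(K = Matrix::forceSymmetric(K), groups = ginfo,
                 dof = Dof, mesh = mesh),
            class = "fe_operator")
}

# element centroid stresses (M x 6 Voigt, MPa) for displacement vector u
element_stresses <- function(op, u) {
  M <- nrow(op$mesh$elem)
  S <- matrix(0, M, 6)
  for (g in op$groups) {
    Ue <- matrix(u[op$dof[g$idx, , drop = FALSE]], length(g$idx), 30)
    S[g$idx, ] <- (Ue %*% t(g$DB)) * op$mesh$E[g$idx]
  }
  colnames(S) <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")
  S
}

von_mises <- function(S) {
  sqrt(0.5 * ((S[, 1] - S[, 2])^2 + (S[, 2] - S[, 3])^2 +
              (S[, 3] - S[, 1])^2) + 3 * (S[, 4]^2 + S[, 5]^2 + S[, 6]^2))
}

# nodal forces (length 3N) from the elastic response of an element subset
internal_forces_subset <- function(op, u, elems) {
  f <- numeric(3L * nrow(op$mesh$nodes))
  sel <- rep(FALSE, nrow(op$mesh$elem)); sel[elems] <- TRUE
  for (g in op$groups) {
    idx <- g$idx[sel[g$idx]]
    if (!length(idx)) next
    Ue <- matrix(u[op$dof[idx, , drop = FALSE]], length(idx), 30)
    Fe <- (Ue %*% g$Ke) * op$mesh$E[idx]
    acc <- rowsum(as.vector(Fe), as.vector(op$dof[idx, , drop = FALSE]))
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }
  f
}

cross_mat <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1],
                                  v[2], -v[1], 0), 3, 3)

#' Tie plate screw holes to the bone surface
#'
#' Combines the plate and bone meshes and eliminates each plate
#' hole-boundary node's three DOFs in favour of bone *surface* DOFs
#' (master--slave multipoint elimination), emulating rigid screws
#' connecting the plate holes to the bone directly underneath.
#'
#' Each hole is coupled kinematically: a linearized rigid motion
#' (translation + small rotation) is least-squares fitted to the weighted
#' displacements of the bone surface patch within `search_radius` of the
#' hole's anchor point, and every hole-boundary node is constrained to
#' follow that fitted motion evaluated at its own position.  The
#' constraint is exact for a rigidly moving fragment regardless of the
#' bone discretization, so the coupled model converges under mesh
#' refinement (a nearest-node point tie does not).  A slave coincident
#' with a bone surface node (within 1e-6 mm) is tied to that node
#' directly, so coincident-interface assemblies reproduce the merged mesh
#' exactly.
#'
#' @param plate_mesh plate `tet10_mesh` with node sets `hole_1` .. `hole_4`
#'   (already positioned on the bone).
#' @param bone_mesh bone `tet10_mesh`.
#' @param search_radius patch footprint radius, mm.  The default (2 mm)
#'   spans the screw length through the plate into the bone surface.
#' @param hole_sets names of the plate node sets to tie.
#' @return List of class `fe_assembly`: `mesh` (combined), `ties` (data
#'   frame slave/master/weight/distance/set; the per-hole patch report),
#'   `coupling` (sparse slave-dof x full-dof constraint operator rows) and
#'   `slave_nodes`.
#' @export
apply_ties <- function(plate_mesh, bone_mesh, search_radius = 2,
                       hole_sets = grep("^hole_", names(plate_mesh$node_sets),
                                        value = TRUE)) {
  if (!length(hole_sets)) stop("plate mesh has no hole node sets")
  mesh <- combine_meshes(bone_mesh, plate_mesh)
  surf <- surface_nodes(bone_mesh)  # bone ids == combined ids (bone first)
  sp <- mesh$nodes[surf, , drop = FALSE]
  off <- nrow(bone_mesh$nodes)
  ndof <- 3L * nrow(mesh$nodes)
  ties <- NULL
  trip_i <- trip_j <- trip_x <- list()
  slave_nodes <- integer(0)
  row0 <- 0L
  for (hs in hole_sets) {
    slaves <- plate_mesh$node_sets[[hs]] + off
    if (any(slaves %in% slave_nodes))
      stop("a node appears as slave in more than one constraint")
    Ps <- mesh$nodes[slaves, , drop = FALSE]
    # global nearest surface node per slave (coincidence test + report)
    d2s <- outer(rowSums(Ps^2), rowSums(sp^2), `+`) - 2 * Ps %*% t(sp)
    nearest <- max.col(-d2s)
    ndist <- sqrt(pmax(0, d2s[cbind(seq_along(slaves), nearest)]))
    ties <- rbind(ties, data.frame(slave = slaves, master = surf[nearest],
                                   weight = 1, distance = ndist, set = hs))
    coin <- ndist < 1e-6
    patch <- NULL
    if (!all(coin)) {
      anchor <- c(mean(Ps[, 1]), min(Ps[, 2]), mean(Ps[, 3]))
      d <- sqrt(colSums((t(sp) - anchor)^2))
      within <- which(d <= search_radius)
      if (length(within) < 3)
        stop("no bone surface patch within ", search_radius, " mm for ", hs)
      w <- 1 - (d[within] / search_radius)^2
      w <- w / sum(w)
      Xm <- sp[within, , drop = FALSE]
      xbar <- colSums(Xm * w)
      Rm <- sweep(Xm, 2, xbar)
      M <- matrix(0, 3, 3)
      for (i in seq_along(within))
        M <- M + w[i] * (sum(Rm[i, ]^2) * diag(3) - tcrossprod(Rm[i, ]))
      if (rcond(M) < 1e-10)
        stop("degenerate (collinear) bone patch for ", hs)
      patch <- list(within = within, w = w, xbar = xbar, Rm = Rm,
                    Minv = solve(M),
                    mdofs = as.vector(t(cbind(3 * (surf[within] - 1) + 1,
                                              3 * (surf[within] - 1) + 2,
                                              3 * (surf[within] - 1) + 3))))
    }
    for (si in seq_along(slaves)) {
      sdof_rows <- row0 + 3L * (si - 1L) + 1:3
      if (coin[si]) {
        # coincident node: direct tie to its nearest master
        mnode <- surf[nearest[si]]
        trip_i[[length(trip_i) + 1L]] <- sdof_rows
        trip_j[[length(trip_j) + 1L]] <- 3L * (mnode - 1L) + 1:3
        trip_x[[length(trip_x) + 1L]] <- rep(1, 3)
        next
      }
      rs <- cross_mat(Ps[si, ] - patch$xbar)
      nb <- length(patch$within)
      blocks <- matrix(0, 3, 3 * nb)
      for (i in seq_len(nb))
        blocks[, 3 * (i - 1) + 1:3] <- patch$w[i] *
          (diag(3) - rs %*% patch$Minv %*% cross_mat(patch$Rm[i, ]))
      trip_i[[length(trip_i) + 1L]] <- rep(sdof_rows, times = ncol(blocks))
      trip_j[[length(trip_j) + 1L]] <- rep(patch$mdofs, each = 3)
      trip_x[[length(trip_x) + 1L]] <- as.vector(blocks)
    }
    slave_nodes <- c(slave_nodes, slaves)
    row0 <- row0 + 3L * length(slaves)
  }
  coupling <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                                   x = unlist(trip_x),
                                   dims = c(row0, ndof))
  structure(list(mesh = mesh, ties = ties, coupling = coupling,
                 slave_nodes = slave_nodes),
            class = "fe_assembly")
}

#' Build the solvable (tied, reduced) system
#'
#' Assembles the combined stiffness operator and the master--slave
#' projection; rigid-body motions of the tied assembly remain zero-energy.
#'
#' @param assembly an `fe_assembly` from [apply_ties()], or a bare
#'   `tet10_mesh` (no ties).
#' @return List of class `fe_system`: `op` (see [assemble()]), `P`
#'   (projection reduced dof -> full dof, carrying the coupling rows),
#'   `red_index` (full dof -> reduced dof, `NA` at eliminated slave dofs),
#'   `Kred`, `mesh`, `ties`.
#' @export
build_system <- function(assembly) {
  if (inherits(assembly, "tet10_mesh"))
    assembly <- list(mesh = assembly, ties = NULL)
  mesh <- assembly$mesh
  op <- assemble(mesh)
  ndof <- 3L * nrow(mesh$nodes)
  ties <- assembly$ties
  if (!is.null(assembly$coupling) && length(assembly$slave_nodes)) {
    slave_dofs <- as.vector(t(cbind(3L * (assembly$slave_nodes - 1L) + 1L,
                                    3L * (assembly$slave_nodes - 1L) + 2L,
                                    3L * (assembly$slave_nodes - 1L) + 3L)))
    red <- setdiff(seq_len(ndof), slave_dofs)
    red_index <- match(seq_len(ndof), red)   # NA at slave dofs
    ii <- which(!is.na(red_index))
    P <- Matrix::sparseMatrix(i = ii, j = red_index[ii], x = rep(1, length(ii)),
                              dims = c(ndof, length(red)))
    # coupling rows: slave dofs expressed in the retained (master) dofs
    Crows <- assembly$coupling[, red, drop = FALSE]
    S <- Matrix::sparseMatrix(i = slave_dofs,
                              j = seq_along(slave_dofs), x = 1,
                              dims = c(ndof, length(slave_dofs)))
    P <- P + S %*% Crows
  } else {
    red <- seq_len(ndof)
    red_index <- red
    P <- Matrix::sparseMatrix(i = red, j = red, x = 1, dims = c(ndof, ndof))
  }
  structure(list(op = op, P = P, red_index = red_index,
                 mesh = mesh, ties = ties,
                 coupling = assembly$coupling,
                 slave_nodes = assembly$slave_nodes,
                 Kred = Matrix::forceSymmetric(Matrix::crossprod(P, op$K %*% P))),
            class = "fe_system")
}

#' Solve a linear system under prescribed nodal displacements
#'
#' Direct sparse symmetric factorization of the free-free block; the
#' workhorse behind [solve_step()], exposed for oracle-style analyses
#' (e.g. driving individual DOFs of a cantilever).
#'
#' @param system an `fe_system`.
#' @param prescribed_dofs integer vector of full-system DOF indices
#'   (3*(node-1)+axis).
#' @param prescribed_values displacements at those DOFs, mm.
#' @param factor optional cached factorization from a previous call with
#'   the same prescribed set (list element `chol`).
#' @return List: `u` (full displacement vector), `f` (nodal elastic forces
#'   K u; equal to the reactions at constrained DOFs), `factor` for reuse.
#' @export
solve_linear_system <- function(system, prescribed_dofs, prescribed_values,
                                factor = NULL, penalty = NULL) {
  red <- system$red_index
  slav <- is.na(red[prescribed_dofs])
  if (any(slav)) {
    # a prescribed slave dof is legal only when it follows a single master
    # with unit weight (coincident-node tie): remap it to that master
    remap <- prescribed_dofs
    for (k in which(slav)) {
      d <- prescribed_dofs[k]
      node <- (d - 1L) %/% 3L + 1L; axis <- (d - 1L) %% 3L + 1L
      rows <- which(system$ties$slave == node)
      if (length(rows) != 1 || system$ties$distance[rows] > 1e-6)
        stop("cannot prescribe displacement on an interpolation-tied node")
      remap[k] <- 3L * (system$ties$master[rows] - 1L) + axis
    }
    prescribed_dofs <- remap
  }
  pd <- unique(red[prescribed_dofs])
  pv <- numeric(length(pd))
  pv[match(red[prescribed_dofs], pd)] <- prescribed_values
  nred <- ncol(system$P)
  free <- setdiff(seq_len(nred), pd)
  if (length(pd) < 6) stop("constraints cover fewer than 6 DOFs: structure floats")
  Kred <- system$Kred
  if (!is.null(penalty)) factor <- NULL  # penalty stiffness changes Kff
  if (is.null(factor)) {
    Kff <- Kred[free, free, drop = FALSE]
    if (!is.null(penalty)) {
      pdofs_red <- red[penalty$dofs]
      pos <- match(pdofs_red, free)
      keep <- !is.na(pos)
      if (any(keep))
        Kff <- Kff + Matrix::sparseMatrix(i = pos[keep], j = pos[keep],
                                          x = rep(penalty$k, sum(keep)),
                                          dims = dim(Kff))
    }
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                           super = TRUE)
    factor <- list(chol = ch, free = free, pd = pd)
  }
  rhs <- -Kred[factor$free, pd, drop = FALSE] %*% pv
  if (!is.null(penalty)) {
    pdofs_red <- red[penalty$dofs]
    pos <- match(pdofs_red, factor$free)
    keep <- !is.na(pos)
    if (any(keep)) {
      add <- numeric(length(factor$free))
      add[pos[keep]] <- penalty$k * penalty$target[keep]
      rhs <- rhs + add
    }
  }
  uf <- Matrix::solve(factor$chol, rhs)
  ured <- numeric(nred)
  ured[factor$free] <- as.numeric(uf)
  ured[pd] <- pv
  u <- as.numeric(system$P %*% ured)
  f <- as.numeric(system$op$K %*% u)
  # slaves transmit their elastic force to the master: report reduced
  # reactions mapped back so constrained-node forces are complete
  list(u = u, f = f, factor = factor)
}

#' Solve one displacement-driven load step
#'
#' Clamps the `proximal_fixed` node set to zero, displaces the
#' `distal_driver` node set rigidly according to `step_transform` (applied
#' about its stored reference point, normally the distal divot), and solves
#' the tied linear system.
#'
#' @param system an `fe_system` whose mesh carries node sets
#'   `proximal_fixed` and `distal_driver`.
#' @param step_transform a `rigid_transform`.
#' @param step_index integer label for the result.
#' @param factor cached factorization (see [solve_linear_system()]).
#' @param yield_stress if finite, a warning is emitted when any plate
#'   element's von Mises stress exceeds it (MPa).
#' @return Object of class `fe_result`: `step_index`, `u` (N x 3 mm),
#'   `element_stress` (M x 6 MPa), `von_mises`, `f` (N x 3 nodal elastic
#'   forces, N), `factor`.
#' @export
solve_step <- function(system, step_transform, step_index = 1L,
                       factor = NULL, yield_stress = Inf, penalty = NULL) {
  mesh <- system$mesh
  fixed <- mesh$node_sets$proximal_fixed
  driven <- mesh$node_sets$distal_driver
  if (is.null(fixed) || is.null(driven))
    stop("mesh lacks proximal_fixed / distal_driver node sets")
  Xd <- mesh$nodes[driven, , drop = FALSE]
  Ud <- apply_transform(step_transform, Xd) - Xd
  pdofs <- c(as.vector(t(cbind(3 * (fixed - 1) + 1, 3 * (fixed - 1) + 2,
                               3 * (fixed - 1) + 3))),
             as.vector(t(cbind(3 * (driven - 1) + 1, 3 * (driven - 1) + 2,
                               3 * (driven - 1) + 3))))
  pvals <- c(rep(0, 3 * length(fixed)), as.vector(t(Ud)))
  sol <- solve_linear_system(system, pdofs, pvals, factor = factor,
                             penalty = penalty)
  S <- element_stresses(system$op, sol$u)
  vm <- von_mises(S)
  if (is.finite(yield_stress) && !is.null(mesh$plate_elements) &&
      any(vm[mesh$plate_elements] > yield_stress))
    warning(sprintf("plate von Mises stress exceeds yield (%.1f MPa) at step %d",
                    yield_stress, step_index))
  structure(list(step_index = step_index,
                 u = matrix(sol$u, ncol = 3, byrow = TRUE),
                 element_stress = S, von_mises = vm,
                 f = matrix(sol$f, ncol = 3, byrow = TRUE),
                 factor = sol$factor),
            class = "fe_result")
}

#' Solve a sequence of displacement steps
#'
#' In `linear` mode (small-strain, default) the factorization is computed
#' once and reused across the steps.  In `incremental` mode the node
#' coordinates are updated with each step's incremental displacement and
#' the stiffness is re-assembled, approximating geometric nonlinearity;
#' stresses are accumulated over increments.
#'
#' @param system an `fe_system`.
#' @param steps list of `rigid_transform`s (from
#'   [make_displacement_steps()]).
#' @param mode `"linear"` or `"incremental"`.
#' @param yield_stress plate yield stress for the exceedance warning, MPa.
#' @return List of `fe_result`, one per step.
#' @export
solve_steps <- function(system, steps, mode = c("linear", "incremental"),
                        yield_stress = Inf) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    out <- vector("list", length(steps))
    factor <- NULL
    for (k in seq_along(steps)) {
      out[[k]] <- solve_step(system, steps[[k]], step_index = k,
                             factor = factor, yield_stress = yield_stress)
      factor <- out[[k]]$factor
    }
    return(out)
  }
  # incremental: re-assemble on updated coordinates each step (the tie
  # coupling operator is kept from the reference configuration)
  mesh0 <- system$mesh
  out <- vector("list", length(steps))
  u_tot <- matrix(0, nrow(mesh0$nodes), 3)
  S_tot <- NULL
  mesh_k <- mesh0
  for (k in seq_along(steps)) {
    sys_k <- if (k == 1) system else
      build_system(structure(list(mesh = mesh_k, ties = system$ties,
                                  coupling = system$coupling,
                                  slave_nodes = system$slave_nodes),
                             class = "fe_assembly"))
    # prescribed increment on the *original* driver coordinates
    driven <- mesh0$node_sets$distal_driver
    fixed <- mesh0$node_sets$proximal_fixed
    X0 <- mesh0$nodes[driven, , drop = FALSE]
    Uk <- apply_transform(steps[[k]], X0) - X0
    Ukm1 <- if (k == 1) 0 * Uk else
      apply_transform(steps[[k - 1]], X0) - X0
    dU <- Uk - Ukm1
    pdofs <- c(as.vector(t(cbind(3 * (fixed - 1) + 1, 3 * (fixed - 1) + 2,
                                 3 * (fixed - 1) + 3))),
               as.vector(t(cbind(3 * (driven - 1) + 1, 3 * (driven - 1) + 2,
                                 3 * (driven - 1) + 3))))
    pvals <- c(rep(0, 3 * length(fixed)), as.vector(t(dU)))
    sol <- solve_linear_system(sys_k, pdofs, pvals)
    du <- matrix(sol$u, ncol = 3, byrow = TRUE)
    u_tot <- u_tot + du
    dS <- element_stresses(sys_k$op, sol$u)
    S_tot <- if (is.null(S_tot)) dS else S_tot + dS
    mesh_k$nodes <- mesh0$nodes + u_tot
    vm <- von_mises(S_tot)
    out[[k]] <- structure(list(step_index = k, u = u_tot,
                               element_stress = S_tot, von_mises = vm,
                               f = matrix(as.numeric(sys_k$op$K %*% sol$u),
                                          ncol = 3, byrow = TRUE)),
                          class = "fe_result")
  }
  out
}
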