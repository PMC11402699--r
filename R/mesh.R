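# Quadratic tetrahedral meshes built from axis-aligned box grids.
#
# Local node ordering of a tet10 element (fixed throughout the package):
#   nodes 1-4  : corners
#   node  5    : mid-edge (1,2)
#   node  6    : mid-edge (2,3)
#   node  7    : mid-edge (3,1)
#   node  8    : mid-edge (1,4)
#   node  9    : mid-edge (2,4)
#   node 10    : mid-edge (3,4)
# Mid-edge nodes sit at exact edge midpoints (straight-sided elements), so
# the geometric mapping is affine and all Jacobians are constant per element.

tet10_edge_pairs <- rbind(c(1, 2), c(2, 3), c(3, 1),
                          c(1, 4), c(2, 4), c(3, 4))

# the six permutations of the axes defining the Kuhn (Freudenthal) split of
# a cube; based on global axis order, so face diagonals of neighbouring
# cubes coincide
kuhn_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
perm_sign <- c(1, -1, -1, 1, 1, -1)

#' Build a tet10 mesh from a set of grid cubes
#'
#' Each cube of the grid is split into six tetrahedra along the Kuhn
#' triangulation (consistent diagonals between neighbours, never inverted),
#' then promoted to quadratic tet10 elements by inserting globally
#' de-duplicated edge-midpoint nodes.
#'
#' @param cubes K x 3 integer matrix of 0-based cube indices.
#' @param edge cube edge length(s), mm (scalar or per-axis).
#' @param origin world position of the corner of cube (0,0,0).
#' @param E element Young's modulus, MPa: scalar or one value per cube.
#' @param nu Poisson's ratio (scalar).
#' @return Object of class `tet10_mesh`: `nodes` (N x 3 mm), `elem`
#'   (M x 10 indices), `E`, `nu` (per element), `edge`, `node_sets`.
#' @export
cubes_to_tet10 <- function(cubes, edge, origin = c(0, 0, 0), E = 1, nu = 0.3) {
  cubes <- matrix(as.integer(as.matrix(cubes)), ncol = 3)
  edge <- rep(edge, length.out = 3)
  K <- nrow(cubes)
  if (K == 0) stop("empty cube set")
  if (length(E) == 1) E <- rep(E, K)
  stopifnot(length(E) == K)

  # half-index node keys: corners at even coordinates 2*(cube+bit),
  # mid-edge nodes at the (integer) average of two corner keys
  bits <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # row b+1 = bit vector
  bit_id <- function(b) 1L + b[1] + 2L * b[2] + 4L * b[3]
  e3 <- diag(3)
  corner_local <- matrix(0L, 6, 4)  # bit-pattern id per kuhn tet corner
  for (p in seq_len(6)) {
    pr <- kuhn_perms[p, ]
    cs <- rbind(c(0, 0, 0), e3[pr[1], ], e3[pr[1], ] + e3[pr[2], ], c(1, 1, 1))
    if (perm_sign[p] < 0) cs <- cs[c(1, 3, 2, 4), ]  # restore positive volume
    corner_local[p, ] <- apply(cs, 1, bit_id)
  }

  # corner half-keys for every (cube, tet, corner): M x 4 x 3
  M <- 6L * K
  ckey <- array(0L, c(M, 4, 3))
  for (p in seq_len(6)) {
    rows <- seq.int(p, M, by = 6)
    for (cn in seq_len(4)) {
      b <- bits[corner_local[p, cn], ]
      for (ax in 1:3)
        ckey[rows, cn, ax] <- 2L * (cubes[, ax] + as.integer(b[ax]))
    }
  }
  key10 <- array(0L, c(M, 10, 3))
  key10[, 1:4, ] <- ckey
  for (ei in seq_len(6)) {
    pr <- tet10_edge_pairs[ei, ]
    key10[, 4 + ei, ] <- (ckey[, pr[1], ] + ckey[, pr[2], ]) %/% 2L
  }

  B <- 2L * max(cubes) + 4L
  flat <- key10[, , 1] + B * key10[, , 2] + B * B * key10[, , 3]  # M x 10
  uk <- unique(as.vector(flat))
  elem <- matrix(match(as.vector(flat), uk), M, 10)
  kz <- uk %/% (B * B); rem <- uk %% (B * B)
  ky <- rem %/% B; kx <- rem %% B
  nodes <- cbind(origin[1] + kx / 2 * edge[1],
                 origin[2] + ky / 2 * edge[2],
                 origin[3] + kz / 2 * edge[3])

  mesh <- structure(list(nodes = nodes, elem = elem,
                         E = rep(E, each = 6L), nu = rep(nu[1], M),
                         edge = edge, node_sets = list()),
                    class = "tet10_mesh")
  v <- element_volumes(mesh)
  if (any(v <= 0)) stop("internal error: non-positive Jacobian in cube split")
  mesh
}

#' @export
print.tet10_mesh <- function(x, ...) {
  cat(sprintf("tet10_mesh: %d nodes, %d elements, E in [%.3g, %.3g] MPa\n",
              nrow(x$nodes), nrow(x$elem), min(x$E), max(x$E)))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all elements (mm^3)
#' @param mesh a `tet10_mesh`.
#' @return Numeric vector, one value per element.
#' @export
element_volumes <- function(mesh) {
  n <- mesh$nodes; el <- mesh$elem
  a <- n[el[, 2], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  b <- n[el[, 3], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  d <- n[el[, 4], , drop = FALSE] - n[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Total mesh volume (mm^3)
#' @param mesh a `tet10_mesh`.
#' @export
mesh_volume <- function(mesh) sum(element_volumes(mesh))

#' Convert a voxel mask (with optional density map) to a tet10 mesh
#'
#' Voxels are coarsened into cubes of roughly `target_edge` (an integer
#' multiple of the voxel size); a cube is kept when at least half of its
#' voxels are inside the mask.  Each kept cube is split into six quadratic
#' tetrahedra.  The element modulus is obtained from the mean density of
#' the masked voxels in the parent block through the density--modulus
#' power law in `cal`; with no density map a uniform `E_default` is used.
#'
#' Node sets `proximal_fixed` and `distal_driver` hold the end-cap nodes at
#' the minimum and maximum extent along the bone long axis (x).
#'
#' @param mask `voxel_image` with logical values.
#' @param density optional `voxel_image` of density (mg HA/cm^3).
#' @param target_edge requested cube edge, mm.
#' @param cal a [density_calibration()].
#' @param nu bone Poisson's ratio.
#' @param E_default modulus when no density map is supplied, MPa.
#' @param align_point optional world point that the coarsening grid must
#'   treat as a block boundary (per axis).  Aligning the grid to the
#'   osteotomy face keeps the gap geometry identical across resolutions;
#'   without it, half-cut blocks can rebuild bone inside the gap at coarse
#'   edges.  The offsets are rounded to whole voxels.
#' @return A `tet10_mesh`.
#' @export
voxels_to_tet10 <- function(mask, density = NULL, target_edge = 1,
                            cal = density_calibration(), nu = 0.3,
                            E_default = 10000, align_point = NULL) {
  stopifnot(inherits(mask, "voxel_image"), is.logical(mask$values))
  if (!any(mask$values)) stop("mask is empty")
  h0 <- mask$spacing[1]
  f <- max(1L, as.integer(round(target_edge / h0)))
  d <- dim(mask$values)
  pre <- c(0L, 0L, 0L)
  if (!is.null(align_point) && f > 1L) {
    # pad empty voxel layers below the origin so that a block boundary
    # falls on the aligned point
    lay <- round((align_point - mask$origin) / mask$spacing)
    pre <- as.integer((f - (lay %% f)) %% f)
  }
  d <- d + pre
  nb <- ceiling(d / f)
  pad <- function(a, fillv) {
    out <- array(fillv, nb * f)
    out[pre[1] + seq_len(dim(a)[1]), pre[2] + seq_len(dim(a)[2]),
        pre[3] + seq_len(dim(a)[3])] <- a
    out
  }
  blocksum <- function(a) {
    dim(a) <- c(f, nb[1], f, nb[2], f, nb[3])
    apply(a, c(2, 4, 6), sum)
  }
  mcount <- blocksum(pad(mask$values, FALSE))
  occ <- mcount >= f^3 / 2
  if (!any(occ)) stop("mask too sparse for this target_edge")
  idx <- which(occ, arr.ind = TRUE) - 1L
  if (!is.null(density)) {
    stopifnot(same_grid(mask, density))
    # block-mean density (zero outside the mask): partial-volume blocks get
    # proportionally lower density and hence modulus, keeping the coarse
    # model's stiffness mass-consistent
    dsum <- blocksum(pad(density$values * mask$values, 0))
    rho <- dsum[occ] / f^3
    Ecube <- density_to_modulus(rho, cal)
  } else Ecube <- rep(E_default, nrow(idx))
  mesh <- cubes_to_tet10(idx, edge = f * mask$spacing,
                         origin = mask$origin - pre * mask$spacing,
                         E = Ecube, nu = nu)
  x <- mesh$nodes[, 1]
  tol <- 1e-6
  mesh$node_sets$proximal_fixed <- which(x <= min(x) + tol)
  mesh$node_sets$distal_driver <- which(x >= max(x) - tol)
  mesh
}

face_local <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
edge_index_of <- matrix(0L, 4, 4)
edge_index_of[1, 2] <- edge_index_of[2, 1] <- 5L
edge_index_of[2, 3] <- edge_index_of[3, 2] <- 6L
edge_index_of[1, 3] <- edge_index_of[3, 1] <- 7L
edge_index_of[1, 4] <- edge_index_of[4, 1] <- 8L
edge_index_of[2, 4] <- edge_index_of[4, 2] <- 9L
edge_index_of[3, 4] <- edge_index_of[4, 3] <- 10L

boundary_faces <- function(mesh) {
  el <- mesh$elem; M <- nrow(el); N <- nrow(mesh$nodes)
  fe <- integer(0); fl <- integer(0); keys <- numeric(0)
  allkeys <- matrix(0, M, 4)
  for (fi in seq_len(4)) {
    tri <- el[, face_local[[fi]], drop = FALSE]
    tri <- t(apply(tri, 1, sort))
    allkeys[, fi] <- (tri[, 1] - 1) + (tri[, 2] - 1) * N +
      (tri[, 3] - 1) * N^2
  }
  kv <- as.vector(allkeys)
  s <- sort(kv)
  once <- s[!(duplicated(s) | duplicated(s, fromLast = TRUE))]
  sel <- which(matrix(kv %in% once, M, 4), arr.ind = TRUE)
  data.frame(elem = sel[, 1], face = sel[, 2])
}

#' Surface (boundary) node indices of a mesh
#'
#' Nodes lying on boundary faces (faces belonging to exactly one element),
#' including the mid-edge nodes of those faces.
#'
#' @param mesh a `tet10_mesh`.
#' @return Sorted integer vector of node indices.
#' @export
surface_nodes <- function(mesh) {
  bf <- boundary_faces(mesh)
  out <- integer(0)
  for (fi in seq_len(4)) {
    rows <- bf$elem[bf$face == fi]
    if (!length(rows)) next
    fl <- face_local[[fi]]
    mids <- c(edge_index_of[fl[1], fl[2]], edge_index_of[fl[2], fl[3]],
              edge_index_of[fl[1], fl[3]])
    out <- c(out, as.vector(mesh$elem[rows, c(fl, mids)]))
  }
  sort(unique(out))
}

#' Translate a mesh (and any divot points) by a fixed vector
#' @param mesh a `tet10_mesh`.
#' @param v length-3 translation, mm.
#' @export
translate_mesh <- function(mesh, v) {
  mesh$nodes <- sweep(mesh$nodes, 2, v, `+`)
  if (!is.null(mesh$divots)) mesh$divots <- sweep(mesh$divots, 2, v, `+`)
  mesh
}

#' Concatenate two meshes into one (bone first, then plate)
#'
#' Node and element indices of the second mesh are offset; its node sets
#' are carried over with their names, and the combined mesh records which
#' elements and nodes belong to the plate.
#'
#' @param bone,plate `tet10_mesh` objects.
#' @return A combined `tet10_mesh` with fields `plate_elements`,
#'   `plate_nodes` and `divots` (from the plate).
#' @export
combine_meshes <- function(bone, plate) {
  off <- nrow(bone$nodes)
  moff <- nrow(bone$elem)
  mesh <- structure(list(
    nodes = rbind(bone$nodes, plate$nodes),
    elem = rbind(bone$elem, plate$elem + off),
    E = c(bone$E, plate$E),
    nu = c(bone$nu, plate$nu),
    edge = bone$edge,
    node_sets = c(bone$node_sets,
                  lapply(plate$node_sets, function(s) s + off))),
    class = "tet10_mesh")
  mesh$plate_elements <- moff + seq_len(nrow(plate$elem))
  mesh$plate_nodes <- off + seq_len(nrow(plate$nodes))
  mesh$divots <- plate$divots
  mesh
}
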