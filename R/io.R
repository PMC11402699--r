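# Plain-text mesh exports: legacy ASCII VTK unstructured grids and ASCII
# STL surfaces.  (No installed R package writes these formats; the writers
# emit text only and parse nothing.)

#' Write a tet10 mesh as a legacy ASCII VTK unstructured grid
#'
#' Cells are written as VTK quadratic tetrahedra (type 24); the package's
#' local node ordering already matches VTK's.  Optional nodal vectors
#' (e.g. displacements) and per-element scalars (modulus, von Mises
#' stress) are attached as POINT_DATA / CELL_DATA.
#'
#' @param mesh a `tet10_mesh`.
#' @param path output file (conventionally `.vtk`).
#' @param point_data named list of N x 3 matrices or length-N vectors.
#' @param cell_data named list of length-M vectors.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list(),
                           cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- nrow(mesh$nodes); M <- nrow(mesh$elem)
  writeLines(c("# vtk DataFile Version 3.0",
               "tet10 mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", N)), con)
  writeLines(apply(format(mesh$nodes, digits = 9, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", M, 11 * M), con)
  writeLines(apply(cbind(10L, mesh$elem - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", M), con)
  writeLines(rep("24", M), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(format(v, digits = 9, trim = TRUE,
                                scientific = FALSE), 1,
                         paste, collapse = " "), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 9, trim = TRUE, scientific = FALSE), con)
      }
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", M), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], digits = 9, trim = TRUE,
                        scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Write the boundary surface of a mesh as ASCII STL
#'
#' Boundary corner-node triangles with outward-facing normals.
#'
#' @param mesh a `tet10_mesh`.
#' @param path output file.
#' @param name solid name in the STL header.
#' @export
write_surface_stl <- function(mesh, path, name = "mesh") {
  bf <- boundary_faces(mesh)
  nd <- mesh$nodes
  fl_mat <- t(vapply(bf$face, function(fi) face_local[[fi]], integer(3)))
  a <- nd[mesh$elem[cbind(bf$elem, fl_mat[, 1])], , drop = FALSE]
  b <- nd[mesh$elem[cbind(bf$elem, fl_mat[, 2])], , drop = FALSE]
  cc <- nd[mesh$elem[cbind(bf$elem, fl_mat[, 3])], , drop = FALSE]
  opp_loc <- 10L - rowSums(fl_mat)  # the corner not on the face (1..4 sum 10)
  opp <- nd[mesh$elem[cbind(bf$elem, opp_loc)], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # orient outward: the opposite corner lies behind the face
  flip <- rowSums(nrm * (opp - a)) > 0
  tmp <- b[flip, , drop = FALSE]
  b[flip, ] <- cc[flip, , drop = FALSE]
  cc[flip, ] <- tmp
  nrm[flip, ] <- -nrm[flip, ]
  nn <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(nn, 1e-300)
  v <- function(m) sprintf("      vertex %g %g %g", m[, 1], m[, 2], m[, 3])
  block <- rbind(sprintf("  facet normal %g %g %g",
                         nrm[, 1], nrm[, 2], nrm[, 3]),
                 "    outer loop", v(a), v(b), v(cc),
                 "    endloop", "  endfacet")
  writeLines(c(sprintf("solid %s", name), as.vector(block),
               sprintf("endsolid %s", name)), path)
  invisible(path)
}
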