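# Constrained minimum-curvature implicit smoothing of hard segmentations.
#
# For one object label, the sign field v (+1 inside, -1 outside) and margin
# field m (0 at label boundaries, 1 elsewhere) define the feasible set
# v_i * f_i >= m_i.  Among feasible fields, we minimize the sum of squared
# axial second differences, with the Z term divided by rho^4 to account for
# section thickness.  The zero level set of the solution is the smoothed
# surface; the label volume itself is never modified.

#' Build smoothing constraints for one object label
#'
#' @param labels a [label_volume()].
#' @param object_label id of the label to smooth (must be in the label
#'   table).
#' @param rho anisotropy factor of the volume (Z weighting is `1/rho^4`).
#' @return an object of class `ConstraintField` with elements `v` (+1/-1
#'   array), `m` (0/1 array) and `rho`.
#' @export
build_constraints <- function(labels, object_label, rho = 1) {
  stopifnot(inherits(labels, "LabelVolume"))
  if (!object_label %in% labels$label_table) {
    stop(sprintf("label id %d is not in the label table", object_label),
         call. = FALSE)
  }
  inside <- labels$labels == object_label
  v <- array(ifelse(inside, 1, -1), dim = dim(labels$labels))
  m <- array(1, dim = dim(v))
  d <- dim(v)
  differs <- array(FALSE, dim = d)
  # 6-neighbor sign changes (border voxels have no neighbor beyond the edge)
  cmp <- function(idx_a, idx_b) v[idx_a] != v[idx_b]
  if (d[1] > 1) {
    ne <- v[-1, , , drop = FALSE] != v[-d[1], , , drop = FALSE]
    differs[-d[1], , ] <- differs[-d[1], , , drop = FALSE] | ne
    differs[-1, , ] <- differs[-1, , , drop = FALSE] | ne
  }
  if (d[2] > 1) {
    ne <- v[, -1, , drop = FALSE] != v[, -d[2], , drop = FALSE]
    differs[, -d[2], ] <- differs[, -d[2], , drop = FALSE] | ne
    differs[, -1, ] <- differs[, -1, , drop = FALSE] | ne
  }
  if (d[3] > 1) {
    ne <- v[, , -1, drop = FALSE] != v[, , -d[3], drop = FALSE]
    differs[, , -d[3]] <- differs[, , -d[3], drop = FALSE] | ne
    differs[, , -1] <- differs[, , -1, drop = FALSE] | ne
  }
  m[differs] <- 0
  structure(list(v = v, m = m, rho = rho), class = "ConstraintField")
}

#' Smooth the implicit field under the sign constraints
#'
#' Minimizes the anisotropy-weighted sum of squared axial second differences
#' subject to `v_i * f_i >= m_i`, by damped Jacobi iterations with a
#' projection step after every sweep (violated coordinates are reset to
#' `v_i * m_i`).  The field is initialized at `f = v`.  Boundaries are
#' natural (free): second differences are accumulated only where both axial
#' neighbors exist, so constant fields and linear ramps have exactly zero
#' energy.  The constraints hold exactly at the output by construction.
#'
#' @param constraints a `ConstraintField` from [build_constraints()].
#' @param tol stop when the largest absolute per-voxel update falls below
#'   this (default 1e-4).
#' @param max_iter iteration cap (default 1000); non-convergence is reported
#'   via the `converged` flag, never as an error.
#' @param omega Jacobi damping factor (default 2/3).
#' @return an object of class `SmoothField` with elements `f`, `converged`,
#'   `iterations`, `energy`, `rho`.
#' @export
smooth_field <- function(constraints, tol = 1e-4, max_iter = 1000L,
                         omega = 2 / 3) {
  stopifnot(inherits(constraints, "ConstraintField"))
  d <- dim(constraints$v)
  wz <- 1 / constraints$rho^4
  res <- .jacobi_smooth(as.double(constraints$v), as.double(constraints$m),
                        as.integer(d), wz, tol, as.integer(max_iter), omega)
  f <- array(res$f, dim = d)
  structure(list(f = f, converged = res$converged,
                 iterations = res$iterations,
                 energy = .smooth_energy(as.double(f), as.integer(d), wz),
                 rho = constraints$rho),
            class = "SmoothField")
}

#' @export
print.SmoothField <- function(x, ...) {
  d <- dim(x$f)
  cat(sprintf(
    "SmoothField %d x %d x %d, energy %.4g, %d iterations (%sconverged)\n",
    d[1], d[2], d[3], x$energy, x$iterations,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Smoothing energy of a field
#'
#' Sum of squared second differences along X, Y and Z, with the Z term
#' weighted by `1/rho^4`; only stencils with both neighbors inside the
#' volume contribute (natural boundaries).
#'
#' @param f 3D numeric array.
#' @param rho anisotropy factor.
#' @return scalar energy.
#' @export
smoothing_energy <- function(f, rho = 1) {
  stopifnot(is.array(f), length(dim(f)) == 3L)
  .smooth_energy(as.double(f), as.integer(dim(f)), 1 / rho^4)
}

#' Extract the zero level set as a triangle mesh
#'
#' Marching tetrahedra (6-tetrahedron cube decomposition, a marching-cubes
#' variant that needs no case table) triangulate the `f = 0` surface;
#' vertices on shared cell edges are merged, so the mesh is watertight
#' wherever the positive region stays inside the volume.  Triangles are
#' oriented with outward normals (pointing toward `f < 0`).  Vertex
#' coordinates are in nm: voxel indices scaled by the voxel size.
#'
#' @param field a `SmoothField` (or any 3D numeric array; values > 0 are
#'   inside).
#' @param voxel_size `(sx, sy, sz)` in nm.
#' @return an object of class `TriangleMesh` with `vertices` (n x 3 matrix,
#'   nm) and `faces` (m x 3 integer matrix, 1-based); empty mesh when the
#'   field has only one sign.
#' @export
extract_surface <- function(field, voxel_size = c(1, 1, 1)) {
  f <- if (inherits(field, "SmoothField")) field$f else field
  stopifnot(is.array(f), length(dim(f)) == 3L)
  check_voxel_size(voxel_size)
  if (all(f > 0) || all(f <= 0)) {
    return(structure(list(vertices = matrix(numeric(0), 0, 3),
                          faces = matrix(integer(0), 0, 3)),
                     class = "TriangleMesh"))
  }
  res <- .marching_tetrahedra(as.double(f), as.integer(dim(f)))
  verts <- res$vertices
  verts[, 1] <- verts[, 1] * voxel_size[1]
  verts[, 2] <- verts[, 2] * voxel_size[2]
  verts[, 3] <- verts[, 3] * voxel_size[3]
  structure(list(vertices = verts, faces = res$faces),
            class = "TriangleMesh")
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Smooth one label and extract its surface
#'
#' Convenience wrapper: builds constraints for `object_label`, smooths the
#' implicit field, and extracts the mesh.  Each label is smoothed
#' independently; the label volume is left untouched.
#'
#' @param labels a [label_volume()].
#' @param object_label label id to smooth.
#' @param voxel_size `(sx, sy, sz)` in nm (also sets the anisotropy factor).
#' @param ... passed to [smooth_field()].
#' @return a `TriangleMesh`; the `SmoothField` is attached as attribute
#'   `field`.
#' @export
smooth_label_surface <- function(labels, object_label,
                                 voxel_size = c(1, 1, 1), ...) {
  cons <- build_constraints(labels, object_label,
                            rho = anisotropy_factor(voxel_size))
  fld <- smooth_field(cons, ...)
  mesh <- extract_surface(fld, voxel_size)
  attr(mesh, "field") <- fld
  mesh
}

#' Write a triangle mesh to PLY or STL
#'
#' `write_ply` writes binary little-endian PLY by default (or ASCII);
#' `write_stl` writes ASCII STL.
#'
#' @param mesh a `TriangleMesh`.
#' @param path output file.
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "TriangleMesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    if (nv) writeBin(as.vector(t(mesh$vertices)), con, size = 4,
                     endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    if (nv) writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
    if (nf) writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                             mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @param name solid name written into the STL file.
#' @export
write_stl <- function(mesh, path, name = "vemseg") {
  stopifnot(inherits(mesh, "TriangleMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  v <- mesh$vertices
  for (i in seq_len(nrow(mesh$faces))) {
    a <- v[mesh$faces[i, 1], ]; b <- v[mesh$faces[i, 2], ]
    c_ <- v[mesh$faces[i, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("      vertex %g %g %g", c_[1], c_[2], c_[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}
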