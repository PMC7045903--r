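# Unit cells as parameter sextuples and as edge-vector bases.

#' Construct a unit cell from its six parameters
#'
#' A unit cell is described by three edge lengths (Angstrom) and three
#' interaxial angles (degrees): `alpha` between **b** and **c**, `beta`
#' between **a** and **c**, `gamma` between **a** and **b**.  The six
#' parameters must define a positive-definite metric (Gram) matrix:
#' each angle smaller than the sum of the other two and the three angles
#' summing to less than 360 degrees.
#'
#' @param a,b,c edge lengths in Angstrom, strictly positive.
#' @param alpha,beta,gamma interaxial angles in degrees, each strictly
#'   inside (0, 180).  Alternatively `a` may be a single numeric vector of
#'   all six parameters.
#' @return An object of class `"unit_cell"`: a named numeric vector
#'   `(a, b, c, alpha, beta, gamma)`.
#' @seealso [cell_to_basis()], [cell_to_s6()], [parse_cryst1()]
#' @export
#' @examples
#' unit_cell(61.3, 61.3, 171.3, 90, 90, 90)
#' unit_cell(c(5.1, 6.2, 7.3, 77, 88, 99))
unit_cell <- function(a, b = NULL, c = NULL, alpha = NULL, beta = NULL,
                      gamma = NULL) {
  if (length(a) == 6L && is.null(b)) {
    p <- as.numeric(a)
  } else {
    p <- as.numeric(c(a, b, c, alpha, beta, gamma))
  }
  if (length(p) != 6L || any(!is.finite(p))) {
    stop("a unit cell needs six finite parameters (a, b, c, alpha, beta, gamma)",
         call. = FALSE)
  }
  names(p) <- c("a", "b", "c", "alpha", "beta", "gamma")
  validate_cell(p)
  structure(p, class = "unit_cell")
}

# raise an informative error when the parameters do not describe a lattice
validate_cell <- function(p) {
  if (any(p[1:3] <= 0)) {
    stop("invalid cell: edge lengths must be strictly positive", call. = FALSE)
  }
  ang <- p[4:6]
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("invalid cell: angles must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  }
  g <- cell_gram(p)
  # positive definiteness <=> det(G) > 0 given positive lengths and sane angles;
  # tolerance is absolute on det(G) scaled by (abc)^2
  if (det3(g) <= 1e-9 * prod(p[1:3])^2) {
    stop(paste0("invalid cell: the metric (Gram) matrix is not positive ",
                "definite (each angle must be less than the sum of the other ",
                "two and the three angles must sum to less than 360 degrees)"),
         call. = FALSE)
  }
  invisible(p)
}

#' Metric (Gram) matrix implied by cell parameters
#'
#' @param cell a [unit_cell()] (or any numeric sextuple in the same order).
#' @return 3x3 symmetric matrix of dot products of the cell edge vectors, in
#'   square Angstrom.
#' @export
#' @examples
#' cell_gram(unit_cell(3, 4, 5, 90, 90, 120))
cell_gram <- function(cell) {
  p <- as.numeric(cell)
  a <- p[1]; b <- p[2]; cc <- p[3]
  ca <- cos(deg2rad(p[4])); cb <- cos(deg2rad(p[5])); cg <- cos(deg2rad(p[6]))
  matrix(c(a * a,       a * b * cg, a * cc * cb,
           a * b * cg,  b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3L, 3L)
}

#' Construct a cell basis from three edge vectors
#'
#' A cell basis stacks the edge vectors **a**, **b**, **c** as the rows of a
#' 3x3 matrix.  The auxiliary vector **d** = -**a** - **b** - **c** is always
#' derived, never stored.  Transformation matrices act on a basis by left
#' multiplication of the stacked rows.
#'
#' @param m 3x3 numeric matrix with rows a, b, c (Angstrom).
#' @param check reject rank-deficient bases (default).  `check = FALSE`
#'   admits the degenerate single-direction cells used to build the
#'   S6 lift and is not meant for ordinary lattices.
#' @return An object of class `"cell_basis"`.
#' @seealso [cell_to_basis()], [basis_to_cell()], [apply_matrix3()]
#' @export
#' @examples
#' cell_basis(diag(3))
cell_basis <- function(m, check = TRUE) {
  m <- as_matrix3(m, "m")
  if (check) {
    scale <- max(abs(m), 1e-300)
    if (abs(det3(m)) <= 1e-12 * scale^3) {
      stop("invalid basis: the three edge vectors are linearly dependent",
           call. = FALSE)
    }
  }
  dimnames(m) <- list(c("a", "b", "c"), NULL)
  structure(m, class = c("cell_basis", "matrix"))
}

#' Convert cell parameters to the canonical edge-vector basis
#'
#' Places the cell in the canonical right-handed frame: **a** along +x,
#' **b** in the xy-plane with positive y component, **c** with positive z
#' component.  Any proper rotation of the result describes the same lattice;
#' this one representative is fixed for reproducibility.
#'
#' @param cell a [unit_cell()].
#' @return A [cell_basis()] whose row norms and pairwise angles reproduce the
#'   cell parameters.
#' @export
#' @examples
#' cell_to_basis(unit_cell(1, 1, 1, 60, 60, 60))
cell_to_basis <- function(cell) {
  if (!inherits(cell, "unit_cell")) cell <- unit_cell(cell)
  p <- as.numeric(cell)
  a <- p[1]; b <- p[2]; cc <- p[3]
  ca <- cos(deg2rad(p[4])); cb <- cos(deg2rad(p[5]))
  cg <- cos(deg2rad(p[6])); sg <- sin(deg2rad(p[6]))
  bx <- b * cg; by <- b * sg
  cx <- cc * cb
  cy <- cc * (ca - cb * cg) / sg
  cz2 <- cc * cc - cx * cx - cy * cy
  if (cz2 <= 0) {
    stop("invalid cell: angles do not close a three-dimensional cell (c_z^2 <= 0)",
         call. = FALSE)
  }
  cell_basis(rbind(c(a, 0, 0), c(bx, by, 0), c(cx, cy, sqrt(cz2))))
}

#' Recover cell parameters from an edge-vector basis
#'
#' Lengths come from the row norms, angles from the pairwise dot products.
#' The result is invariant under any proper rotation of the basis, so
#' `basis_to_cell(cell_to_basis(u))` returns `u` and any rotated copy of a
#' basis maps to the same cell.
#'
#' @param basis a [cell_basis()] (full rank).
#' @return A [unit_cell()].
#' @export
#' @examples
#' basis_to_cell(cell_basis(diag(c(2, 3, 4))))
basis_to_cell <- function(basis) {
  if (!inherits(basis, "cell_basis")) basis <- cell_basis(basis)
  m <- unclass(basis)
  scale <- max(abs(m), 1e-300)
  if (abs(det3(m)) <= 1e-12 * scale^3) {
    stop("invalid basis: rank < 3, cannot recover cell parameters",
         call. = FALSE)
  }
  len <- sqrt(rowSums(m * m))
  ang <- function(u, v) rad2deg(acos(max(-1, min(1, sum(u * v) / sqrt(sum(u * u) * sum(v * v))))))
  unit_cell(len[1], len[2], len[3],
            ang(m[2, ], m[3, ]), ang(m[1, ], m[3, ]), ang(m[1, ], m[2, ]))
}

#' Apply a 3x3 transformation matrix to a cell basis
#'
#' The matrix acts by left multiplication of the stacked row vectors:
#' the new **a** is `m[1,1]*a + m[1,2]*b + m[1,3]*c`, and so on.  The cell
#' volume scales by `|det(m)|`.
#'
#' @param m 3x3 numeric matrix, invertible.
#' @param basis a [cell_basis()].
#' @return The transformed [cell_basis()] (unchecked, so that determinant-1
#'   transforms of borderline cells do not error spuriously).
#' @export
#' @examples
#' apply_matrix3(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3, byrow = TRUE),
#'               cell_basis(diag(3)))
apply_matrix3 <- function(m, basis) {
  m <- as_matrix3(m, "m")
  if (abs(det3(m)) <= 1e-12 * max(abs(m), 1)^3) {
    stop("'m' is singular: a lattice transformation must be invertible",
         call. = FALSE)
  }
  if (!inherits(basis, "cell_basis")) basis <- cell_basis(basis)
  cell_basis(m %*% unclass(basis), check = FALSE)
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.6g b=%.6g c=%.6g  alpha=%.6g beta=%.6g gamma=%.6g\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

#' @export
print.cell_basis <- function(x, ...) {
  cat("cell basis (rows a, b, c; Angstrom):\n")
  print(unclass(x), ...)
  invisible(x)
}
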