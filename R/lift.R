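# Lifting a 3x3 cell transformation to the equivalent 6x6 matrix on S6.

# The +1 unit vectors of S6 cannot come from real edge vectors (a dot product
# of +1 between unit vectors forces contradictory geometry with d), so the
# construction targets the NEGATIVES of the S6 unit vectors.  Six degenerate
# "basis cells", each made of collinear rows along x, map under e3_to_s6 to
# exactly -e_j.
.basis_cell_rows <- list(
  rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)),  # b.c = -1
  rbind(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)),  # a.c = -1
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 0)),  # a.b = -1
  rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),   # a.d = -1 (d = -a)
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),   # b.d = -1
  rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))    # c.d = -1
)

#' The six degenerate basis cells of the S6 lift
#'
#' Returns the six rank-one cells whose Selling scalars are the negatives of
#' the S6 unit vectors: `e3_to_s6(basis_j)` has a single nonzero component,
#' -1, at position j.  The defining property is re-verified on every call.
#'
#' @return A list of six degenerate [cell_basis()] objects (built with
#'   `check = FALSE`; they are rank 1 by design).
#' @seealso [lift_matrix3()]
#' @export
#' @examples
#' e3_to_s6(selling_basis_cells()[[4]])  # [0, 0, 0, -1, 0, 0]
selling_basis_cells <- function() {
  cells <- lapply(.basis_cell_rows, cell_basis, check = FALSE)
  for (j in 1:6) {
    s <- as.numeric(e3_to_s6(cells[[j]]))
    want <- numeric(6); want[j] <- -1
    if (!identical(s, want)) {
      stop(sprintf("internal error: basis cell %d does not map to -e%d", j, j))
    }
  }
  cells
}

#' Lift a 3x3 cell transformation to the equivalent 6x6 S6 matrix
#'
#' Given a matrix `m` acting on cell bases (rows a, b, c, by left
#' multiplication), computes the unique 6x6 matrix `S` such that for every
#' basis `B`, `e3_to_s6(apply_matrix3(m, B)) == S %*% e3_to_s6(B)`.
#' Column j of `S` is `-e3_to_s6(m %*% basis_j)` over the six degenerate
#' basis cells; because the Selling scalars are quadratic in the entries of
#' `m`, an integer `m` yields an integer `S` and the arithmetic is exact.
#'
#' The construction works for any 3x3 matrix; `S` is invertible exactly when
#' `m` is, with `det(S) = det(m)^4`.
#'
#' @param m 3x3 numeric matrix (integer in all catalog uses).
#' @return 6x6 numeric matrix acting on S6 vectors by left multiplication.
#' @seealso [selling_basis_cells()], [delone_catalog()]
#' @export
#' @examples
#' lift_matrix3(diag(3))  # the 6x6 identity
#' lift_matrix3(matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 2), 3, 3, byrow = TRUE))
lift_matrix3 <- function(m) {
  m <- as_matrix3(m, "m")
  out <- matrix(0, 6L, 6L)
  for (j in 1:6) {
    out[, j] <- -as.numeric(e3_to_s6(m %*% .basis_cell_rows[[j]]))
  }
  out
}
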