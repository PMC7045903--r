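# The S6 representation: Selling scalars of a lattice.

#' Construct an S6 vector of Selling scalars
#'
#' The six Selling scalars of a lattice basis a, b, c with auxiliary vector
#' d = -a - b - c are the pairwise dot products, ordered
#' `[b.c, a.c, a.b, a.d, b.d, c.d]` (square Angstrom).  A lattice is
#' Selling-reduced when all six are zero or negative.
#'
#' @param x numeric vector of length 6 in the order above.
#' @return An object of class `"s6"`.
#' @seealso [e3_to_s6()], [s6_to_basis()], [is_reduced()]
#' @export
#' @examples
#' s6_vector(c(0, 0, 0, -1, -1, -1))  # the unit cube
s6_vector <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 6L || any(!is.finite(x))) {
    stop("an S6 vector needs six finite scalars [b.c, a.c, a.b, a.d, b.d, c.d]",
         call. = FALSE)
  }
  structure(x, names = paste0("s", 1:6), class = "s6")
}

#' Selling scalars of a cell basis
#'
#' Computes `[b.c, a.c, a.b, a.d, b.d, c.d]` with d = -a - b - c derived
#' internally.  Dot products are rotation invariant, so every rotated copy of
#' a basis maps to the same S6 vector.  Degenerate (rank-deficient) bases are
#' accepted: the lift construction relies on them.
#'
#' @param basis a [cell_basis()] (or plain 3x3 matrix with rows a, b, c).
#' @return An [s6_vector()].
#' @export
#' @examples
#' e3_to_s6(cell_basis(diag(3)))  # [0, 0, 0, -1, -1, -1]
e3_to_s6 <- function(basis) {
  m <- if (inherits(basis, "cell_basis")) unclass(basis) else as_matrix3(basis, "basis")
  a <- m[1, ]; b <- m[2, ]; cc <- m[3, ]
  d <- -(a + b + cc)
  s6_vector(c(sum(b * cc), sum(a * cc), sum(a * b),
              sum(a * d), sum(b * d), sum(cc * d)))
}

# squared norms |a|^2, |b|^2, |c|^2, |d|^2 implied by the scalars
s6_norms <- function(s) {
  s <- as.numeric(s)
  c(a = -(s[2] + s[3] + s[4]),
    b = -(s[1] + s[3] + s[5]),
    c = -(s[1] + s[2] + s[6]),
    d = -(s[4] + s[5] + s[6]))
}

#' Gram matrix reconstructed from an S6 vector
#'
#' @param s an [s6_vector()].
#' @return The 3x3 Gram matrix of the generating basis (a, b, c): diagonal
#'   from the derived squared norms, off-diagonals from s3, s2, s1.
#' @export
s6_gram <- function(s) {
  s <- as.numeric(s)
  n <- s6_norms(s)
  matrix(c(n[1], s[3], s[2],
           s[3], n[2], s[1],
           s[2], s[1], n[3]), 3L, 3L)
}

# validity of an S6 vector as a lattice: positive derived squared norms and a
# positive-definite reconstructed Gram matrix (principal minors, 1e-12
# relative slack).  Returns NULL or a diagnostic string.
s6_violation <- function(s) {
  s <- as.numeric(s)
  n <- s6_norms(s)
  scale <- max(abs(s), n, 1e-300)
  for (i in 1:4) {
    if (n[i] <= scale * 1e-12) {
      return(sprintf("derived squared norm |%s|^2 = %.6g is not positive",
                     names(n)[i], n[i]))
    }
  }
  g <- s6_gram(s)
  m2 <- g[1, 1] * g[2, 2] - g[1, 2] * g[2, 1]
  if (m2 <= scale^2 * 1e-12) {
    return("reconstructed Gram matrix fails the 2x2 principal-minor test")
  }
  if (det3(g) <= scale^3 * 1e-12) {
    return("reconstructed Gram matrix is not positive definite (det <= 0)")
  }
  NULL
}

#' Is an S6 vector a valid lattice?
#'
#' Checks that the four derived squared norms are positive and that the
#' reconstructed Gram matrix is positive definite.  Zero scalars at the
#' reduction boundary are allowed; the test is on the Gram matrix, not on
#' scalar signs.
#'
#' @param s an [s6_vector()].
#' @return `TRUE` or `FALSE`.
#' @export
s6_is_valid <- function(s) is.null(s6_violation(s))

#' Reconstruct the canonical-frame basis from an S6 vector
#'
#' Inverts [e3_to_s6()] up to rotation: there are infinitely many bases with
#' the same Selling scalars, and this function returns the canonical-frame
#' representative (**a** along +x, **b** in the xy-plane with positive y,
#' **c** with positive z).  Explicitly: `|a| = sqrt(-s2-s3-s4)`,
#' `a = (|a|,0,0)`; `b_x = s3/|a|`, `b_y = +sqrt(|b|^2 - b_x^2)`;
#' `c_x = s2/|a|`, `c_y = (s1 - b_x c_x)/b_y`,
#' `c_z = +sqrt(|c|^2 - c_x^2 - c_y^2)`.  Positive square roots fix the
#' representative.
#'
#' @param s an [s6_vector()] describing a valid lattice.
#' @return A [cell_basis()] with `e3_to_s6(result)` equal to `s`.
#' @export
#' @examples
#' s6_to_basis(s6_vector(c(0, 0, 0, -1, -1, -1)))
s6_to_basis <- function(s) {
  if (!inherits(s, "s6")) s <- s6_vector(s)
  bad <- s6_violation(s)
  if (!is.null(bad)) stop("invalid S6 vector: ", bad, call. = FALSE)
  v <- as.numeric(s)
  n <- s6_norms(v)
  la <- sqrt(n[1])
  bx <- v[3] / la
  by <- sqrt(n[2] - bx * bx)
  cx <- v[2] / la
  cy <- (v[1] - bx * cx) / by
  cz <- sqrt(n[3] - cx * cx - cy * cy)
  cell_basis(rbind(c(la, 0, 0), c(bx, by, 0), c(cx, cy, cz)))
}

#' Selling scalars of a unit cell
#'
#' @param cell a [unit_cell()].
#' @return An [s6_vector()].
#' @export
#' @examples
#' cell_to_s6(unit_cell(2, 2, 2, 90, 90, 90))
cell_to_s6 <- function(cell) e3_to_s6(cell_to_basis(cell))

#' Cell parameters of an S6 vector
#'
#' @param s an [s6_vector()] describing a valid lattice.
#' @return A [unit_cell()].
#' @export
s6_to_cell <- function(s) basis_to_cell(s6_to_basis(s))

#' Is an S6 vector Selling-reduced?
#'
#' A lattice is reduced when all six Selling scalars are zero or negative.
#' The tolerance admits small positive scalars from floating-point noise at
#' the boundary.
#'
#' @param s an [s6_vector()].
#' @param tol absolute tolerance; by default `1e-9 * max(|s|)` so that
#'   near-boundary zeros count as reduced.
#' @return `TRUE` iff `max(s) <= tol`.
#' @export
#' @examples
#' is_reduced(s6_vector(c(0, 0, 0, -1, -1, -1)))
is_reduced <- function(s, tol = NULL) {
  s <- as.numeric(s)
  if (is.null(tol)) tol <- 1e-9 * max(abs(s), 1e-300)
  max(s) <= tol
}

#' @export
print.s6 <- function(x, ...) {
  cat("S6 [b.c, a.c, a.b, a.d, b.d, c.d]:",
      paste(sprintf("%.6g", as.numeric(x)), collapse = " "), "\n")
  invisible(x)
}
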