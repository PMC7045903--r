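# The 24 canonical Delone types and their primitive-to-centered
# transformation matrices in E3x3 and S6.

# Matrices in the Burzlaff & Zimmermann (1985) orientation, acting on row
# bases by left multiplication.  |det| equals the centering multiplicity:
# 1 (P), 2 (I- and S/base-centered), 3 (rhombohedral R), 4 (F).
.delone_m3 <- list(
  C1  = rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)),
  C3  = rbind(c(1, 1, 0), c(1, -1, 0), c(1, 1, 2)),
  C5  = diag(3),
  R1  = rbind(c(1, -1, 0), c(0, 1, -1), c(1, 1, 1)),
  R3  = rbind(c(1, 0, 0), c(0, 0, 1), c(1, 3, 2)),
  T1  = rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)),
  T2  = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 2)),
  T5  = diag(3),
  O1A = rbind(c(1, 1, 0), c(1, -1, 0), c(1, 1, 2)),
  O1B = rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)),
  O2  = rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 2)),
  O3  = rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)),
  O4  = rbind(c(1, -1, 0), c(1, 1, 0), c(0, 0, 1)),
  O5  = diag(3),
  M1A = rbind(c(-1, -1, -1), c(1, -1, 0), c(0, 0, 1)),
  M1B = rbind(c(0, 1, 1), c(1, 1, 0), c(-1, 0, -1)),
  M2A = rbind(c(-1, -1, -2), c(0, 1, 0), c(1, 0, 0)),
  M2B = rbind(c(0, 1, 1), c(1, 1, 0), c(-1, 0, -1)),
  M3  = rbind(c(-1, -1, -2), c(0, 1, 0), c(1, 0, 0)),
  M4  = diag(3),
  A1  = diag(3),
  A2  = diag(3),
  A3  = diag(3),
  H4  = diag(3)
)

.delone_lattice <- c(
  C1 = "cI", C3 = "cF", C5 = "cP", R1 = "hR", R3 = "hR",
  T1 = "tI", T2 = "tI", T5 = "tP",
  O1A = "oF", O1B = "oI", O2 = "oI", O3 = "oI", O4 = "oS", O5 = "oP",
  M1A = "mS", M1B = "mS", M2A = "mS", M2B = "mS", M3 = "mS", M4 = "mP",
  A1 = "aP", A2 = "aP", A3 = "aP", H4 = "hP"
)

# centering multiplicity by the centering letter of the lattice character
.centering_multiplicity <- c(P = 1, I = 2, S = 2, F = 4, R = 3)

#' The 24 Delone-type symbols
#'
#' @return Character vector of the valid symbols, in catalog order.
#' @export
delone_symbols <- function() names(.delone_m3)

#' Look up one Delone type
#'
#' The 24 canonical Delone types classify Bravais lattices by the pattern of
#' zero and equal Selling scalars of the reduced cell.  Each entry carries
#' the transformation from the Delone-reduced primitive cell to the
#' conventional centered cell, both as a 3x3 matrix on edge vectors (`m3`)
#' and as its lifted 6x6 matrix on S6 vectors (`m6`).  Symbols follow the
#' modernized scheme: cubic C (formerly K), tetragonal T (formerly Q),
#' triclinic A (formerly T).
#'
#' @param symbol one of [delone_symbols()], case-insensitive
#'   (e.g. `"C1"`, `"m1a"`).
#' @return An object of class `"delone_entry"`: list with `symbol`,
#'   `lattice` (lattice character, e.g. `"cI"`), `multiplicity`
#'   (= `|det(m3)|`), `m3` and `m6`.
#' @seealso [delone_catalog()], [center_cell()]
#' @export
#' @examples
#' delone_entry("C1")$m3
#' delone_entry("T2")$m6
delone_entry <- function(symbol) {
  key <- toupper(trimws(as.character(symbol)[1]))
  if (!key %in% names(.delone_m3)) {
    stop("unknown Delone symbol '", symbol, "'; valid symbols are: ",
         paste(delone_symbols(), collapse = ", "), call. = FALSE)
  }
  m3 <- .delone_m3[[key]]
  lattice <- .delone_lattice[[key]]
  structure(list(symbol = key,
                 lattice = lattice,
                 multiplicity = .centering_multiplicity[[substr(lattice, 2, 2)]],
                 m3 = m3,
                 m6 = lift_matrix3(m3)),
            class = "delone_entry")
}

#' The full catalog of 24 Delone types
#'
#' @return A named list of 24 [delone_entry()] objects, in catalog order
#'   (cubic, rhombohedral, tetragonal, orthorhombic, monoclinic, triclinic,
#'   hexagonal).
#' @export
#' @examples
#' length(delone_catalog())
#' sum(vapply(delone_catalog(), function(e) all(e$m3 == diag(3)), logical(1)))
delone_catalog <- function() {
  out <- lapply(delone_symbols(), delone_entry)
  names(out) <- delone_symbols()
  out
}

#' Apply a Delone centering transformation to an S6 vector
#'
#' Left-multiplies the S6 vector by the 6x6 centering matrix of the given
#' type.  This is equivalent to transforming the generating basis with the
#' 3x3 matrix and recomputing the Selling scalars, but stays entirely in S6.
#' The input should normally be Selling-reduced (see [selling_reduce()]),
#' since the catalog matrices are defined relative to the reduced primitive
#' cell.
#'
#' @param symbol a Delone symbol, see [delone_symbols()].
#' @param s an [s6_vector()] (or a [unit_cell()], converted on the fly).
#' @return The centered cell as an [s6_vector()].
#' @export
#' @examples
#' center_cell("C1", s6_vector(c(0, 0, 0, -1, -1, -1)))
center_cell <- function(symbol, s) {
  entry <- delone_entry(symbol)
  if (inherits(s, "unit_cell")) s <- cell_to_s6(s)
  if (!inherits(s, "s6")) s <- s6_vector(s)
  bad <- s6_violation(s)
  if (!is.null(bad)) stop("invalid S6 vector: ", bad, call. = FALSE)
  s6_vector(as.numeric(entry$m6 %*% as.numeric(s)))
}

#' @export
print.delone_entry <- function(x, ...) {
  cat(sprintf("Delone type %s (lattice %s, centering multiplicity %d)\n",
              x$symbol, x$lattice, x$multiplicity))
  cat("E3x3 matrix:\n"); print(x$m3)
  cat("S6 matrix:\n"); print(x$m6)
  invisible(x)
}
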