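# Internal numeric helpers.

#' Determinant of a square matrix by fraction-free (Bareiss) elimination
#'
#' For integer input every intermediate value is an integer, so the result is
#' exact as long as it stays below 2^53.  Used wherever catalog and lift
#' determinant identities must hold with integer equality rather than to
#' floating-point tolerance.
#'
#' @param m square numeric matrix.
#' @return The determinant as a length-one numeric (an exact integer when
#'   `m` is integral).
#' @export
#' @examples
#' det_exact(diag(3))
#' det_exact(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))  # 2
det_exact <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  a <- m
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (a[k, k] == 0) {
      piv <- which(a[(k + 1L):n, k] != 0)
      if (length(piv) == 0L) return(0)
      i <- k + piv[1L]
      tmp <- a[k, ]; a[k, ] <- a[i, ]; a[i, ] <- tmp
      sign <- -sign
    }
    for (i in (k + 1L):n) {
      for (j in (k + 1L):n) {
        a[i, j] <- (a[i, j] * a[k, k] - a[i, k] * a[k, j]) / prev
      }
      a[i, k] <- 0
    }
    prev <- a[k, k]
  }
  sign * a[n, n]
}

# closed-form 3x3 determinant (exact for integer input)
det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

# coerce a user-supplied 3x3 matrix argument, with a clear error
as_matrix3 <- function(m, arg = "m") {
  if (is.numeric(m) && length(m) == 9L && !is.matrix(m)) {
    m <- matrix(m, 3L, 3L, byrow = TRUE)
  }
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a numeric 3x3 matrix", arg), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  }
  storage.mode(m) <- "double"
  unname(m)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
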