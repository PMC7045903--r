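# Shared fixtures: random rotations, integer matrices, comparison helpers.

# proper rotation via QR of a Gaussian matrix, sign-fixed to det +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(c(1, 1, det(q)))
}

# random integer matrix with nonzero determinant
random_int_mat3 <- function(maxabs = 3) {
  repeat {
    m <- matrix(sample(-maxabs:maxabs, 9, replace = TRUE), 3, 3)
    if (det_exact(m) != 0) return(m)
  }
}

# random unimodular (det +-1) integer matrix: product of elementary shears,
# row swaps and sign flips
random_unimodular <- function(n_ops = 6) {
  m <- diag(3)
  for (k in seq_len(n_ops)) {
    op <- sample(3, 1)
    i <- sample(3, 1); j <- sample(setdiff(1:3, i), 1)
    if (op == 1) {            # shear: row_i += f * row_j
      e <- diag(3); e[i, j] <- sample(c(-2, -1, 1, 2), 1)
    } else if (op == 2) {     # swap rows i and j
      e <- diag(3); e[c(i, j), ] <- e[c(j, i), ]
    } else {                  # negate one row
      e <- diag(3); e[i, i] <- -1
    }
    m <- e %*% m
  }
  m
}

# max componentwise difference relative to the overall scale of the pair
rel_err <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  max(abs(x - y)) / max(abs(x), abs(y), 1e-12)
}

# a random Selling-reduced S6 vector (via the generator)
random_reduced_s6 <- function(length_range = c(2, 50)) {
  cell_to_s6(generate_cells(1, length_range = length_range,
                            reduced_only = TRUE)[[1]])
}

# every S6 matrix row that is printed unambiguously in the catalog listing,
# keyed by Delone symbol; used both by the unit tests and the acceptance test
printed_s6_rows <- function() {
  list(
    C1  = list("4" = c(0, 0, 0, 0, 2, 2), "5" = c(0, 0, 0, 2, 0, 2), "6" = c(0, 0, 0, 2, 2, 0)),
    R1  = list("6" = c(0, 0, 0, 2, 1, 0)),
    R3  = list("3" = c(0, 1, 0, 0, 0, 0), "5" = c(0, 1, 0, 0, 0, 3), "6" = c(0, 1, 2, 2, 9, 6)),
    T1  = list("4" = c(0, 0, 0, 0, 2, 2), "5" = c(0, 0, 0, 2, 0, 2), "6" = c(0, 0, 0, 2, 2, 0)),
    T2  = list("3" = c(0, 0, 1, 0, 0, 0), "4" = c(0, 0, 0, 2, 0, 0), "5" = c(0, 0, 0, 0, 2, 0), "6" = c(0, 0, 0, 2, 2, 4)),
    O1B = list("4" = c(0, 0, 0, 0, 2, 2), "5" = c(0, 0, 0, 2, 0, 2), "6" = c(0, 0, 0, 2, 2, 0)),
    O2  = list("3" = c(0, 0, 1, 0, 0, 0), "4" = c(0, 0, 0, 2, 0, 0), "5" = c(0, 0, 0, 0, 2, 0), "6" = c(0, 0, 0, 2, 2, 4)),
    O3  = list("4" = c(0, 0, 0, 0, 2, 2), "5" = c(0, 0, 0, 2, 0, 2), "6" = c(0, 0, 0, 2, 2, 0)),
    O4  = list("1" = c(1, 1, 0, 0, 0, 0), "4" = c(1, 1, 4, 2, 0, 0)),
    M1A = list("2" = c(0, 0, 0, 0, 0, 1), "4" = c(0, 0, 0, 0, 2, 0), "5" = c(2, 0, 4, 0, 2, 0), "6" = c(2, 0, 0, 0, 0, 0)),
    M1B = list("4" = c(0, 0, 2, 0, 2, 0), "5" = c(2, 0, 0, 0, 2, 0), "6" = c(2, 0, 2, 0, 0, 0)),
    M2A = list("1" = c(0, 0, 1, 0, 0, 0), "4" = c(2, 2, 0, 0, 0, 4), "5" = c(2, 0, 0, 0, 0, 0), "6" = c(0, 2, 0, 0, 0, 0)),
    M2B = list("4" = c(0, 0, 2, 0, 2, 0), "5" = c(2, 0, 0, 0, 2, 0), "6" = c(2, 0, 2, 0, 0, 0)),
    M3  = list("1" = c(0, 0, 1, 0, 0, 0), "4" = c(2, 2, 0, 0, 0, 4), "5" = c(2, 0, 0, 0, 0, 0), "6" = c(0, 2, 0, 0, 0, 0))
  )
}
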