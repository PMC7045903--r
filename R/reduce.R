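# Selling reduction: drive all six scalars nonpositive by vector exchanges.

# One exchange step per scalar index.  If scalar s_i = p.q is positive, the
# step negates p and adds p to the two vectors other than p and q, keeping
# a + b + c + d = 0.  Expressed on the stacked rows (a, b, c) these are the
# induced 3x3 matrices (d is implied throughout):
#   s1 = b.c : negate b;  a -> a+b, d -> d+b
#   s2 = a.c : negate a;  b -> b+a, d -> d+a
#   s3 = a.b : negate a;  c -> c+a, d -> d+a
#   s4 = a.d : negate a;  b -> b+a, c -> c+a
#   s5 = b.d : negate b;  a -> a+b, c -> c+b
#   s6 = c.d : negate c;  a -> a+c, b -> b+c
.selling_steps <- list(
  rbind(c(1, 1, 0), c(0, -1, 0), c(0, 0, 1)),
  rbind(c(-1, 0, 0), c(1, 1, 0), c(0, 0, 1)),
  rbind(c(-1, 0, 0), c(0, 1, 0), c(1, 0, 1)),
  rbind(c(-1, 0, 0), c(1, 1, 0), c(1, 0, 1)),
  rbind(c(1, 1, 0), c(0, -1, 0), c(0, 1, 1)),
  rbind(c(1, 0, 1), c(0, 1, 1), c(0, 0, -1))
)

#' Selling reduction of a lattice
#'
#' Iteratively applies the Selling exchange until all six scalars are zero or
#' negative.  Each step picks the most positive scalar `s_i = p.q` (lowest
#' index on ties), negates the first-named vector `p` of the pair and adds it
#' to the two vectors other than `p` and `q`; the sum of the four squared
#' vector norms strictly decreases by `2 * p.q`, so the iteration terminates.
#' All bookkeeping is done through the induced 3x3 basis change and its S6
#' lift, so the accumulated transforms map the input to the output in either
#' space.
#'
#' @param s an [s6_vector()] (or [unit_cell()]/[cell_basis()], converted) for
#'   a valid lattice.
#' @param tol absolute scalar tolerance for "nonpositive"; default
#'   `1e-9 * max(|s|)` so near-boundary zeros terminate.
#' @param max_steps iteration cap; reaching it signals invalid input rather
#'   than slow convergence and raises an error.
#' @param trace keep a per-step record (index chosen, scalar value, norm sum
#'   before/after) as the `trace` element of the result.
#' @return An object of class `"selling_reduction"`: list with
#'   `s_reduced` (reduced [s6_vector()]), `m3_total` (accumulated 3x3 basis
#'   change, `|det| = 1`), `m6_total` (its lift, so
#'   `m6_total %*% s == s_reduced`), `steps`, and optionally `trace`.
#' @seealso [is_reduced()], [lift_matrix3()]
#' @export
#' @examples
#' r <- selling_reduce(cell_to_s6(unit_cell(2, 2, 2, 60, 70, 80)))
#' r$steps
#' is_reduced(r$s_reduced)
selling_reduce <- function(s, tol = NULL, max_steps = 1000L, trace = FALSE) {
  if (inherits(s, "unit_cell")) s <- cell_to_s6(s)
  if (inherits(s, "cell_basis")) s <- e3_to_s6(s)
  if (!inherits(s, "s6")) s <- s6_vector(s)
  basis <- unclass(s6_to_basis(s))  # errors on invalid input
  if (is.null(tol)) tol <- 1e-9 * max(abs(as.numeric(s)), 1e-300)

  m3 <- diag(3)
  steps <- 0L
  rec <- if (trace) vector("list", 64L) else NULL
  repeat {
    sv <- as.numeric(e3_to_s6(basis))
    i <- which.max(sv)  # most positive scalar; which.max takes lowest index on ties
    if (sv[i] <= tol) break
    if (steps >= max_steps) {
      stop("Selling reduction did not converge within ", max_steps,
           " steps; the input is unlikely to describe a valid lattice",
           call. = FALSE)
    }
    if (trace) {
      d <- -colSums(basis)
      before <- sum(basis * basis) + sum(d * d)
      rec[[steps + 1L]] <- c(index = i, scalar = sv[i], norm_sum_before = before)
    }
    step <- .selling_steps[[i]]
    basis <- step %*% basis
    m3 <- step %*% m3
    steps <- steps + 1L
  }

  out <- list(s_reduced = e3_to_s6(basis),
              m3_total = m3,
              m6_total = lift_matrix3(m3),
              steps = steps)
  if (trace && steps == 0L) {
    out$trace <- data.frame(step = integer(0), index = numeric(0),
                            scalar = numeric(0), norm_sum_before = numeric(0),
                            norm_sum_after = numeric(0))
  } else if (trace) {
    rec <- rec[seq_len(steps)]
    d <- -colSums(basis)
    ends <- c(vapply(rec[-1L], function(r) r[["norm_sum_before"]], 0),
              sum(basis * basis) + sum(d * d))
    out$trace <- data.frame(step = seq_len(steps),
                            index = vapply(rec, function(r) r[["index"]], 0),
                            scalar = vapply(rec, function(r) r[["scalar"]], 0),
                            norm_sum_before = vapply(rec, function(r) r[["norm_sum_before"]], 0),
                            norm_sum_after = ends)
  }
  class(out) <- "selling_reduction"
  out
}

#' @export
print.selling_reduction <- function(x, ...) {
  cat("Selling reduction:", x$steps, "exchange step(s)\n")
  print(x$s_reduced)
  cat("accumulated 3x3 basis change (det ", det3(x$m3_total), "):\n", sep = "")
  print(x$m3_total)
  invisible(x)
}
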