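# Random-cell fixture generator used by the test suite and the CLI.

#' Generate random valid unit cells
#'
#' Draws edge lengths uniformly from `length_range` and angle triples
#' uniformly from (40, 140) degrees, rejection-sampling until the implied
#' Gram matrix is positive definite.  With `reduced_only` each cell is
#' Selling-reduced before being returned, so every result satisfies
#' [is_reduced()] by construction.
#'
#' @param n number of cells (> 0).
#' @param length_range numeric `(min, max)` edge lengths in Angstrom,
#'   `0 < min <= max`.
#' @param seed optional integer; when given, results are reproducible
#'   (the global RNG state is restored afterwards).
#' @param reduced_only return Selling-reduced cells.
#' @return A list of `n` [unit_cell()] objects.
#' @export
#' @examples
#' generate_cells(3, seed = 1)
generate_cells <- function(n, length_range = c(2, 50), seed = NULL,
                           reduced_only = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  if (length(length_range) != 2L || length_range[1] <= 0 ||
      length_range[1] > length_range[2]) {
    stop("'length_range' must satisfy 0 < min <= max", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      p <- c(stats::runif(3, length_range[1], length_range[2]),
             stats::runif(3, 40, 140))
      cell <- tryCatch(unit_cell(p), error = function(e) NULL)
      if (!is.null(cell)) break
    }
    if (reduced_only) {
      cell <- s6_to_cell(selling_reduce(cell_to_s6(cell))$s_reduced)
    }
    out[[i]] <- cell
  }
  out
}
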