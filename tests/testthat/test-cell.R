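test_that("canonical frame reproduces closed-form bases", {
  # orthonormal cube
  b <- cell_to_basis(unit_cell(1, 1, 1, 90, 90, 90))
  expect_equal(unclass(b), diag(3), ignore_attr = TRUE, tolerance = 1e-12)

  # rhombohedral 60/60/60: closed form from the dot products a.b = cos 60 etc.
  b <- cell_to_basis(unit_cell(1, 1, 1, 60, 60, 60))
  expect_equal(b[2, ], c(0.5, sqrt(3) / 2, 0), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(b[3, ], c(0.5, 1 / (2 * sqrt(3)), sqrt(2 / 3)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sqrt(sum(b[3, ]^2)), 1, tolerance = 1e-12)

  # Gram matrix of the returned vectors matches the parameter-implied Gram
  u <- unit_cell(3, 4, 5, 90, 90, 120)
  b <- unclass(cell_to_basis(u))
  g <- b %*% t(b)
  expect_equal(g, cell_gram(u), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g[1, 2], 3 * 4 * cos(2 * pi / 3), tolerance = 1e-12)
  expect_equal(g[1, 3], 0, tolerance = 1e-12)
  expect_equal(g[2, 3], 0, tolerance = 1e-12)
})

test_that("basis/cell round trip and rotation invariance", {
  expect_equal(as.numeric(basis_to_cell(cell_basis(diag(c(2, 3, 4))))),
               c(2, 3, 4, 90, 90, 90), tolerance = 1e-12)
  set.seed(42)
  for (cell in generate_cells(200, seed = 7)) {
    back <- basis_to_cell(cell_to_basis(cell))
    expect_lt(rel_err(back, cell), 1e-10)
    # any proper rotation of the edge vectors describes the same cell
    # (rows rotate on the right in the row-vector convention)
    b <- unclass(cell_to_basis(cell))
    rot <- cell_basis(b %*% t(random_rotation()))
    expect_lt(rel_err(basis_to_cell(rot), cell), 1e-9)
  }
})

test_that("matrix action follows the row convention and scales volume by |det|", {
  cube <- cell_basis(diag(3))
  expect_equal(unclass(apply_matrix3(diag(3), cube)), diag(3),
               ignore_attr = TRUE)
  m <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  expect_equal(unclass(apply_matrix3(m, cube)), m, ignore_attr = TRUE)

  # |det| = 3 transform triples the cell volume (triple product of the rows)
  m <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 3, 2))
  expect_identical(abs(det_exact(m)), 3)
  b <- cell_to_basis(unit_cell(5.1, 6.2, 7.3, 77, 88, 99))
  v0 <- abs(det(unclass(b)))
  expect_equal(abs(det(unclass(apply_matrix3(m, b)))), 3 * v0,
               tolerance = 1e-12 * v0)

  expect_error(apply_matrix3(matrix(1, 3, 3), cube), "singular")
})

test_that("invalid cells and degenerate bases are rejected with clear errors", {
  expect_error(unit_cell(-1, 1, 1, 90, 90, 90), "positive")
  expect_error(unit_cell(1, 1, 1, 190, 90, 90), "inside \\(0, 180\\)")
  # alpha > beta + gamma: Gram not positive definite
  expect_error(unit_cell(1, 1, 1, 170, 40, 40), "positive definite")
  expect_error(cell_basis(rbind(c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))),
               "linearly dependent")
  # the unchecked constructor admits the degenerate lift cells
  expect_s3_class(cell_basis(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                             check = FALSE), "cell_basis")
})
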