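test_that("catalog has 24 types with the expected structure", {
  cat24 <- delone_catalog()
  expect_length(cat24, 24)
  expect_identical(names(cat24), delone_symbols())

  is_id <- vapply(cat24, function(e) all(e$m3 == diag(3)), logical(1))
  expect_identical(sum(is_id), 8L)
  expect_setequal(names(cat24)[is_id],
                  c("C5", "T5", "O5", "M4", "A1", "A2", "A3", "H4"))

  for (e in cat24) {
    expect_identical(abs(det_exact(e$m3)), as.numeric(e$multiplicity))
    expect_true(e$multiplicity %in% 1:4)
    expect_identical(e$m6, lift_matrix3(e$m3))
  }
  # multiplicity follows the centering letter
  mult <- vapply(cat24, `[[`, numeric(1), "multiplicity")
  lat <- vapply(cat24, `[[`, character(1), "lattice")
  expect_identical(unname(mult[lat %in% c("cP", "tP", "oP", "mP", "aP", "hP")]),
                   rep(1, 8))
  expect_identical(unname(mult[lat %in% c("cI", "tI", "oI")]), rep(2, 6))
  expect_identical(unname(mult[lat %in% c("oS", "mS")]), rep(2, 6))
  expect_identical(unname(mult[lat == "hR"]), rep(3, 2))
  expect_identical(unname(mult[lat %in% c("cF", "oF")]), rep(4, 2))
})

test_that("every published S6 row is reproduced exactly by the lift", {
  for (sym in names(printed_s6_rows())) {
    m6 <- delone_entry(sym)$m6
    for (row in names(printed_s6_rows()[[sym]])) {
      expect_identical(m6[as.integer(row), ], printed_s6_rows()[[sym]][[row]])
    }
  }
})

test_that("types sharing a transformation matrix share the lifted matrix", {
  groups <- list(c("C1", "T1", "O1B", "O3"), c("C3", "O1A"),
                 c("M1B", "M2B"), c("M2A", "M3"))
  for (g in groups) {
    ref <- delone_entry(g[1])
    for (sym in g[-1]) {
      expect_identical(delone_entry(sym)$m3, ref$m3)
      expect_identical(delone_entry(sym)$m6, ref$m6)
    }
  }
})

test_that("centering in S6 agrees with transforming the basis in E3", {
  expect_identical(as.numeric(center_cell("C5", s6_vector(c(0, 0, 0, -1, -1, -1)))),
                   c(0, 0, 0, -1, -1, -1))
  set.seed(31)
  for (e in delone_catalog()) {
    for (k in 1:5) {
      s <- random_reduced_s6()
      via_s6 <- center_cell(e$symbol, s)
      via_e3 <- e3_to_s6(apply_matrix3(e$m3, s6_to_basis(s)))
      expect_lt(rel_err(via_s6, via_e3), 1e-9)
      # centered volume = multiplicity x primitive volume
      expect_equal(abs(det(unclass(s6_to_basis(via_s6)))),
                   e$multiplicity * abs(det(unclass(s6_to_basis(s)))),
                   tolerance = 1e-9 * abs(det(unclass(s6_to_basis(s)))))
    }
  }
  # row-6 closed form for the tI body-centering transform
  for (k in 1:10) {
    s <- as.numeric(random_reduced_s6())
    expect_equal(as.numeric(center_cell("T2", s6_vector(s)))[6],
                 2 * s[4] + 2 * s[5] + 4 * s[6], tolerance = 1e-12)
  }
})

test_that("lookups are case-insensitive and reject unknown symbols", {
  expect_identical(delone_entry("m1a")$symbol, "M1A")
  expect_identical(delone_entry("C1")$m3,
                   rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_identical(delone_entry("C1")$lattice, "cI")
  expect_error(delone_entry("K1"), "valid symbols")
})
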