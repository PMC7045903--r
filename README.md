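# s6lift

Crystallographic lattices in the six-space of Selling scalars, and the
conversion of 3×3 unit-cell transformation matrices into their equivalent
6×6 matrices acting on that space.

## The problem

A unit cell (a, b, c, α, β, γ) can be represented by three edge vectors
**a**, **b**, **c**; with the auxiliary vector **d** = −**a**−**b**−**c**,
the six pairwise dot products

```
s = [b·c, a·c, a·b, a·d, b·d, c·d]   ∈  S⁶   (Å²)
```

are the **Selling scalars**. They are rotation invariant, Selling/Delone
reduction drives them all nonpositive, and the 24 Delone types classify
Bravais lattices by their zero/equality patterns — which makes S⁶ a
convenient space for lattice reduction, comparison and database searching.
But the standard lattice transformations (in particular the
primitive→centered matrices of the Bravais lattices) are published as 3×3
matrices on edge vectors. `s6lift` computes, for any 3×3 matrix *M*, the
unique 6×6 matrix *S* with

```
E3toS6(M · B) = S · E3toS6(B)       for every basis B,
```

by applying *M* to six degenerate "basis cells" whose Selling scalars are
the negatives of the S⁶ unit vectors: column *j* of *S* is
−E3toS6(M·Bⱼ). Entries of *S* are quadratic in the entries of *M*, so
integer matrices lift to integer matrices exactly, with
lift(AB) = lift(A)·lift(B) and det lift(M) = (det M)⁴.

The package is for crystallographers and structural-biology software
authors who keep lattices in S⁶ and need centering/basis-change matrices
without round-tripping through edge vectors. It provides:

* cell ↔ basis ↔ S⁶ conversions with a fixed canonical frame
  (`unit_cell`, `cell_to_basis`, `e3_to_s6`, `s6_to_basis`, …);
* the lift itself (`lift_matrix3`, `selling_basis_cells`);
* Selling reduction with full transform bookkeeping in both spaces
  (`selling_reduce`);
* the catalog of the 24 Delone types with their primitive→centered
  matrices in E³ˣ³ and S⁶ (`delone_catalog`, `delone_entry`,
  `center_cell`);
* parsers for plain-text/JSON cells and matrices and PDB CRYST1 records,
  a random-cell fixture generator, and a command-line interface.

## Worked example

```r
library(s6lift)

u <- parse_cryst1("CRYST1   61.300   61.300  171.300  90.00  90.00  90.00 P 43 21 2     8")
u
#> unit cell: a=61.3 b=61.3 c=171.3  alpha=90 beta=90 gamma=90

s <- cell_to_s6(unit_cell(3, 4, 5, 80, 85, 95))
s
#> S6 [b.c, a.c, a.b, a.d, b.d, c.d]: 3.47296 1.30734 -1.04587 -9.26147 -18.4271 -29.7803
```

Two scalars are positive, so this cell is not Selling-reduced. Reduce it,
keeping the accumulated transformation in both spaces:

```r
r <- selling_reduce(s)
r
#> Selling reduction: 3 exchange step(s)
#> S6 [b.c, a.c, a.b, a.d, b.d, c.d]: -1.30734 -3.47296 -1.04587 -11.4812 -6.64679 -20.2197
#> accumulated 3x3 basis change (det -1):
#>      [,1] [,2] [,3]
#> [1,]    0   -1    0
#> [2,]   -1    0    0
#> [3,]    0    0    1
```

All six scalars are now nonpositive; `r$m6_total %*% as.numeric(s)`
reproduces `r$s_reduced` without ever leaving S⁶. The 6×6 matrix for the
body-centered tetragonal transformation (Delone type T2) comes from the
lift of its published 3×3 matrix:

```r
lift_matrix3(delone_entry("T2")$m3)
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,]    1    0    0    0   -1    0
#> [2,]    0    1    0   -1    0    0
#> [3,]    0    0    1    0    0    0
#> [4,]    0    0    0    2    0    0
#> [5,]    0    0    0    0    2    0
#> [6,]    0    0    0    2    2    4
```

Row 6 says: the new c·d scalar is 2(a·d) + 2(b·d) + 4(c·d) of the
primitive cell. Applying the type to the reduced cell and converting back
shows the centered cell (twice the primitive volume for an I lattice):

```r
s6_to_cell(center_cell("T2", r$s_reduced))
#> unit cell: a=4 b=3 c=10.1876  alpha=79.9385 beta=78.6666 gamma=95
```

The command-line interface wraps the same functions
(`lift`, `cell2s6`, `s62cell`, `reduce`, `center`, `catalog`, `fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","s6lift.R",package="s6lift"))')" \
    lift '[[1,0,0],[0,1,0],[1,1,2]]'
```

See the vignette `vignettes/s6-lattice-transformations.Rmd` for the model,
conventions (row vectors, left multiplication, Burzlaff–Zimmermann 1985
orientation) and numerical choices.

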