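---
title: "Lattices as Selling scalars: the S6 representation and the 3x3 to 6x6 lift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattices as Selling scalars: the S6 representation and the 3x3 to 6x6 lift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s6lift)
```

## The model

A crystallographic unit cell is usually written as six parameters
$[a, b, c, \alpha, \beta, \gamma]$ (edge lengths in angstrom, interaxial
angles in degrees), or as three edge vectors
$\mathbf{a}, \mathbf{b}, \mathbf{c}$ stacked as the rows of a $3\times 3$
matrix. Introduce the auxiliary vector
$\mathbf{d} = -\mathbf{a}-\mathbf{b}-\mathbf{c}$; the four vectors sum to
zero by construction. The *Selling scalars* are the six pairwise dot
products, ordered

$$
\mathbf{s} = [\,\mathbf{b}\cdot\mathbf{c},\;
\mathbf{a}\cdot\mathbf{c},\; \mathbf{a}\cdot\mathbf{b},\;
\mathbf{a}\cdot\mathbf{d},\; \mathbf{b}\cdot\mathbf{d},\;
\mathbf{c}\cdot\mathbf{d}\,] \in S^6 ,
$$

in units of square angstrom. Selling (Delone) reduction drives all six
scalars to be zero or negative; the all-nonpositive region is the valid
domain in which the 24 Delone types classify Bravais lattices by the
pattern of zero and equal scalars. The scalars are dot products, so they
are invariant under any proper rotation of the edge vectors: a point of
$S^6$ stands for a whole rotation class of bases, which is exactly the
equivalence that "same lattice, different orientation" calls for.

Two conventions are fixed package-wide and logged by the CLI:

* **Row vectors, left multiplication.** A $3\times 3$ transformation $M$
  acts on the stacked rows, $\mathbf{a}' = m_{11}\mathbf{a} +
  m_{12}\mathbf{b} + m_{13}\mathbf{c}$, and the catalog matrices below are
  stated in the orientation of Burzlaff & Zimmermann (1985), the same
  convention used by *International Tables for Crystallography* (a later
  1992 listing is the transpose). The $6\times 6$ matrices likewise act on
  $S^6$ columns from the left.
* **Canonical frame.** Where a single basis must be produced from
  parameters or from $S^6$, the representative is $\mathbf{a}$ along $+x$,
  $\mathbf{b}$ in the $xy$-plane with $b_y > 0$, and $c_z > 0$. Any proper
  rotation of it is equivalent; one member of the class is fixed so that
  results are reproducible bit for bit.

## The lift: a 6x6 matrix equivalent to a 3x3 matrix

Transformations between unit cells — in particular the
primitive-to-centered transformations of the Bravais lattices — are
published as $3\times 3$ matrices on edge vectors. Pipelines that work in
$S^6$ would otherwise have to convert back to vectors, transform, and
convert again. Since the composite map
$\mathbf{s} \mapsto E^3toS^6(M \cdot B)$ is linear in $\mathbf{s}$, it is
a $6\times 6$ matrix $S$, determined column by column from images of basis
vectors.

The $+1$ unit vectors of $S^6$ are *not* images of real edge vectors: a
dot product of $+1$ between unit vectors would force two basis vectors to
coincide, and then $\mathbf{d}$ could not be orthogonal to both. The
construction therefore uses the **negatives** of the unit vectors, each of
which is realized by a degenerate, rank-one "basis cell" whose rows are
collinear with $x$:

```{r}
cells <- selling_basis_cells()
unclass(cells[[1]])          # b = +x, c = -x: only b.c = -1 survives
as.numeric(e3_to_s6(cells[[1]]))
```

Column $j$ of $S$ is then $-\,E^3toS^6(M \cdot B_j)$ over the six
degenerate cells. The entries of $S$ are quadratic in the entries of $M$,
so an integer $M$ gives an integer $S$ and the arithmetic is exact; no
symbolic algebra is needed. Useful identities, all tested in the suite:
$\mathrm{lift}(I_3) = I_6$, $\mathrm{lift}(AB) =
\mathrm{lift}(A)\,\mathrm{lift}(B)$, and $\det \mathrm{lift}(M) = (\det
M)^4$ (each scalar is a product of two vectors, each transforming with one
factor of $M$; a polarization/diagonalization argument gives the fourth
power).

```{r}
m <- parse_matrix3("[[1,0,0],[0,1,0],[1,1,2]]")  # tI body centering
lift_matrix3(m)
```

## The 24 Delone types

`delone_catalog()` carries one entry per canonical Delone type (modern
symbols: cubic C, tetragonal T, rhombohedral R, orthorhombic O, monoclinic
M, triclinic A, hexagonal H), each with its lattice character, its
$3\times 3$ primitive-to-centered matrix, and the lifted $6\times 6$
matrix. Eight types (C5, T5, O5, M4, A1, A2, A3, H4) are already
primitive: their matrix is the identity. For the rest,
$|\det M|$ equals the centering multiplicity: 2 for body- and
base-centered (I, S), 3 for rhombohedral R, 4 for face-centered F.
Several types share one matrix (C1/T1/O1B/O3, C3/O1A, M1B/M2B, M2A/M3);
entries are stored per symbol because the Delone type is the lookup key.

The transcription of the catalog was validated three ways, and the package
treats the combination as the definition of correctness:

1. every unambiguous published row of the $S^6$ listings is reproduced by
   `lift_matrix3(m3)` with integer equality;
2. $|\det m3|$ equals the centering multiplicity of the lattice character;
3. for random reduced lattices, acting with `m6` in $S^6$ agrees with
   transforming the basis in $E^3$ and reconverting (the commutation
   property that defines the lift).

Where a published row alone did not pin down a matrix, the stated
constraints do: the monoclinic entries are the unique integer matrices
with entries in $[-2, 2]$ satisfying (1)–(2); O4 is the standard
base-centering $(\mathbf{a}-\mathbf{b},\ \mathbf{a}+\mathbf{b},\
\mathbf{c})$; R1 is the standard rhombohedral-to-hexagonal matrix
$(\mathbf{a}-\mathbf{b},\ \mathbf{b}-\mathbf{c},\
\mathbf{a}+\mathbf{b}+\mathbf{c})$; and C3/O1A maps the Selling-reduced
primitive face-centered basis onto the conventional cube, which fixes its
middle row as $\mathbf{a}-\mathbf{b}$.

## Selling reduction

`selling_reduce()` brings any valid lattice into the all-nonpositive
domain. While some scalar $s_i = \mathbf{p}\cdot\mathbf{q}$ is positive,
the exchange replaces $\mathbf{p} \to -\mathbf{p}$ and adds $\mathbf{p}$
to the two vectors other than $\mathbf{p}$ and $\mathbf{q}$, keeping the
four-vector sum at zero. The sum of the four squared norms drops by
exactly $2\,\mathbf{p}\cdot\mathbf{q} > 0$ per step, which bounds the
number of steps for any valid input. Choices the literature leaves open
are fixed as follows:

* the **most positive** scalar is exchanged first, lowest index on ties —
  a deterministic order, not a claim about optimality;
* within the pair, the vector named first in the scalar ordering is the
  one negated ($s_1 = \mathbf{b}\cdot\mathbf{c}$ negates $\mathbf{b}$,
  $s_4 = \mathbf{a}\cdot\mathbf{d}$ negates $\mathbf{a}$, ...);
* the stopping tolerance is $10^{-9} \max_i |s_i|$ (relative), so exact
  zeros on the domain boundary terminate despite floating-point noise;
* each step's induced basis change (determinant $\pm 1$; $-1$ is accepted,
  since the lattice is preserved and the canonical frame restores
  handedness at reconstruction) is accumulated as `m3_total`, and
  `m6_total = lift_matrix3(m3_total)` maps the input scalars to the
  reduced scalars directly in $S^6$;
* no canonical *ordering* of the reduced scalars is applied afterwards:
  the reduced multiset is a lattice invariant, the component order is not
  normalized beyond what the exchanges produce.

```{r}
r <- selling_reduce(cell_to_s6(unit_cell(2, 2, 2, 60, 70, 80)))
r
```

## Numerical choices and degenerate inputs

* **Cell validity.** Parameters must give a positive-definite Gram matrix;
  the test is $\det G > 10^{-9} (abc)^2$, an absolute tolerance on the
  scaled determinant, which catches angle triples that fail the
  triangle-like conditions.
* **S6 validity.** An $S^6$ vector is accepted when the four derived
  squared norms $|\mathbf{a}|^2 = -(s_2+s_3+s_4)$ (and cyclic) are
  positive and the reconstructed Gram matrix passes a principal-minor test
  with $10^{-12}$ relative slack. Validity is decided by the Gram matrix,
  not by scalar signs: zero scalars on the reduction boundary are fine,
  and the test agrees with a brute-force eigenvalue check (asserted in the
  suite).
* **Inverse construction.** `s6_to_basis()` uses the explicit square-root
  construction ($|a| = \sqrt{-s_2-s_3-s_4}$, $b_x = s_3/|a|$, ...), with
  positive roots selecting the canonical-frame representative. Any other
  member of the rotation class would serve equally; tests compare cells
  and scalars, never orientations.
* **Degenerate cells.** Ordinary `cell_basis()` rejects rank-deficient
  input; the rank-one basis cells of the lift are built through an
  unchecked constructor and are valid only as inputs to `e3_to_s6()`.
* **Exact determinants.** Catalog identities ($|\det m3|$, $\det
  \mathrm{lift} = \det^4$) are checked with a fraction-free Bareiss
  elimination, which is exact for integer matrices, rather than a
  floating-point LU factorization.

## The fixture generator

`generate_cells()` supplies the random lattices used throughout the test
suite: edge lengths uniform on a range (default 2–50 angstrom, the span of
typical small-molecule through protein cells; termination stress tests
use 1–100, a 100:1 axis ratio), angles uniform on (40, 140) degrees with
rejection until the Gram matrix is positive definite, and optional
Selling reduction of each draw. It emulates *geometry* only: uniform
draws over parameter ranges, with no symmetry, no clustering near
high-symmetry cells, and no measurement error model. Passing tests
therefore demonstrate algebraic correctness over the valid domain, not
robustness to the near-degenerate, almost-symmetric cells that real
diffraction data can produce; the exact-arithmetic identities are the
stronger guarantee there. Problem sizes in the shipped tests (500
matrix/lattice pairs for the commutation property, 200 matrices for the
homomorphism laws, 1000 cells for round trips and reduction) were chosen
so the whole suite exercises every code path at well beyond the catalog's
own size while remaining quick to run routinely.

## Known limitations

* The package converts and transforms; it does **not** identify which
  Delone type a given cell belongs to, compute $S^6$ distances or
  boundary projections, or perform Niggli ($G^6$) reduction.
* Space-group symmetry, fractional coordinates, and anything beyond the
  lattice itself are out of scope; the CRYST1 parser reads the cell and
  ignores the space-group fields.
* `s6_to_basis()` returns one representative of a rotation class; code
  that compares bases elementwise across sources must first reduce both
  to cells or scalars.
* Exactness claims hold for integer matrices whose intermediates stay
  below $2^{53}$; catalog matrices are far below that, but user-supplied
  large integer matrices can lose exactness.
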