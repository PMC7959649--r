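---
title: "Row-action reconstruction from limited-angle projections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Row-action reconstruction from limited-angle projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artomo)
```

## The problem

Classical computed tomography assumes projections from view angles spanning
the full half-circle. When only two opposite faces of an object are
accessible — the motivating case is probing a coal seam for rock inclusions
or compressed-gas pockets from two parallel headings — every usable ray runs
from one wall to the other, all view directions fall inside a right angle,
and analytical reconstruction (filtered backprojection and relatives) breaks
down. Algebraic methods still work: discretize the object, write one linear
equation per ray, and solve the resulting sparse system iteratively. They
converge far more slowly on such limited-angle data than on complete data,
which motivates the block-parallel variant this package implements.

## Discretization and the system matrix

The object lives in the square \(E = [-1, 1]^2\), divided into \(N = n^2\)
congruent pixels on which the density \(f(x, y)\) is assumed constant
(`build_grid()`). A ray contributes one equation: the measured projection
\(p = \ln(I_0 / I)\) equals the sum over pixels of (path length of the ray
in the pixel) × (density of the pixel). Collecting all rays gives
\(A X = B\) with \(A\) sparse and non-negative.

Two acquisition geometries are generated:

* **Opposite walls, `make_one_by_one(pkt)`** — `pkt` sources equally spaced
  (corners included) on the wall \(x = -1\), `pkt` detectors likewise on
  \(x = +1\), every source paired with every detector. The two pairs whose
  segment runs along the horizontal edges \(y = \pm 1\) — i.e. along the
  pixel mesh, where path lengths are ill-defined — are rejected, leaving
  exactly \(pkt^2 - 2\) rays. Rays are ordered source-major,
  detector-minor; the order is arbitrary but fixed, because row-action
  solvers are order-dependent and reproducibility requires one canonical
  enumeration.
* **Complete parallel-beam, `make_parallel_beam(angles, rays)`** — equally
  spaced view directions over \([0, 180)\) degrees, with perpendicular
  offsets at the centres of equal cells spanning the circumscribed extent
  \([-\sqrt 2, \sqrt 2]\); offsets that miss the square at a given angle are
  dropped. This is the reference "complete data" configuration against
  which the limited-angle difficulty is measured.

Path lengths are computed by sorted parametric boundary crossings (the
Siddon construction): the crossing parameters of the segment with all mesh
lines are sorted, and each inter-crossing piece is attributed to the pixel
containing its midpoint. This realises a half-open pixel convention without
explicit tie-breaking, double-counts nothing, and is bit-reproducible. A
row has at most \(2n - 1\) nonzeros, and its sum equals the ray's chord
length through \(E\) — both properties are enforced as test invariants,
alongside agreement with a brute-force segment-sampling oracle.

## Phantoms and synthetic projections

Test objects are piecewise-constant rectangle phantoms (`phantom_regions()`),
matching the high-contrast discrete density distributions of the target
application. Two built-ins, `phantom_f1()` and `phantom_f2()`, carry four
rectangles of densities 1–4 on a zero background.

`rasterize()` converts a phantom to a truth vector by exact area-weighted
averaging (rectangle-overlap areas; pixel-centre sampling is available as
`method = "center"`). Area weighting was chosen as the default because it
makes the truth independent of how points exactly on a region edge are
classified; when region edges align with the mesh the two methods coincide.
Overlaps are computed in pixel units with region edges snapped to mesh lines
when within \(10^{-9}\) pixel, so aligned-edge phantoms rasterize to exactly
their nominal densities.

Projections are synthesized noiselessly, \(B = A x_{\mathrm{truth}}\), so
the systems are consistent by construction. An additive-Gaussian hook
(`add_projection_noise()`) exists for robustness studies but no reference
experiment uses it.

**What this emulates and what it does not.** The generator reproduces the
geometry, sparsity structure, and scale of limited-angle acquisition, which
is what the solvers are sensitive to. It does not emulate measurement
noise, detector blur, polychromatic attenuation, or model mismatch between
the continuous object and its pixelization (except on grids where region
edges fall inside pixels). Convergence results on these phantoms therefore
show algorithmic behaviour on ideal data; on real data the iterates stop
improving at an error floor set by the data's inconsistency instead of
converging indefinitely.

## The solvers

**Kaczmarz** (`kaczmarz_solve()`) cycles through the equations, orthogonally
projecting the iterate onto each row's hyperplane. **ART** (`art_solve()`)
scales each projection step by a relaxation coefficient \(\lambda\):

\[
x^{(k+1)} = x^{(k)} + \lambda\,
\frac{p_i - a^i \circ x^{(k)}}{\lVert a^i \rVert^2}\, a^i,
\]

convergent for constant \(0 < \lambda < 2\); \(\lambda = 1\) recovers
Kaczmarz exactly, and the two code paths are verified to produce identical
iterates. Because densities are physically non-negative, a constraining
operator clamps negative entries to zero (`constrain()`). By default it is
applied after every projection step (`constraint_timing = "per_step"`),
reading the update's index \(k\) as the step counter; clamping once per full
sweep (`"per_iteration"`) is available, and on the reference problems the
two differ only modestly. Per-step clamping is implemented by clamping the
entries the row touches, which is equivalent to clamping the whole vector
when the iterate enters the sweep non-negative (guaranteed inductively from
a clamped start).

**Parallel-block PB** (`pb_solve()`) partitions the rows into \(M\)
contiguous blocks of near-equal size (`partition_rows()`; the first
`m %% M` blocks get the extra row). Every block performs a full ART sweep
over its own rows, in ascending row order, starting from the shared iterate;
the block results are recombined as

\[
x^{(k+1)} = \sum_{i=1}^{M} W_i\, y^{(k+1, i)},
\qquad
W_i = \operatorname{diag}(w^i_1, \dots, w^i_N),
\qquad
w^i_j = \frac{\sum_{q \in B_i} a_{q,j}}{\sum_{q} a_{q,j}},
\]

with the denominator running over all rows, so the weights form a partition
of unity on every column and the recombination is a true weighted average
(`block_weights()`). Pixels untouched by any ray get \(w^i_j = 1/M\),
preserving \(\sum_i W_i = I\) globally; such pixels are never updated from
the initial solution anyway. With \(M = 1\) the single weighting matrix is
the identity on all touched pixels and PB reduces bitwise to ART.

Design choices worth recording:

* **Determinism under parallelism.** Blocks communicate only their full
  block solutions at an end-of-iteration barrier, and the weighted sum is
  accumulated in ascending block order. The numbers are therefore
  bit-identical whatever the `workers` count; parallelism changes wall time
  only. This is tested.
* **Weighting schemes.** The column-sum weighting above is the default. A
  plain averaging scheme, \(W_i = I/M\) (`scheme = "uniform"`), is also
  provided: it is the naive "average the block solutions" recombination.
  The column-sum weighting converges in markedly fewer iterations as blocks
  are added — intuitively, a block containing most of a pixel's ray mass
  should dominate that pixel's update, while plain averaging dilutes every
  block's progress by \(1/M\). The test suite checks this ordering on a
  small problem. Descriptions of block-parallel methods of this family
  differ in which recombination they use, and reported iteration growth
  with \(M\) depends strongly on the choice; see the block-scaling
  discussion below.
* **Initial solution** \(x^{(0)} = 0\) (any vector is admissible;
  configurable via `solver_config(x0 = )`).
* **Stop rules** — an iteration cap, a max-abs-error target (requires the
  truth), or a relative-residual target — are evaluated at iteration
  boundaries only, matching the convention that one iteration is one pass
  over all \(m\) rows.
* **Constant \(\lambda\) only.** A variable schedule \(\lambda_k\) has a
  known convergence condition but no reference experiment uses one; it is
  out of scope.
* **Double precision throughout.**

## Error metric and experiments

Reconstruction quality is the maximum absolute pixel error
\(\Delta = \max_i |f(pik_i) - \tilde f(pik_i)|\) (`max_abs_error()`) — a
deliberately strict metric: one bad pixel fails the reconstruction. It
requires the truth, which is the point of phantom studies: calibrate, on
known objects, how many iterations a given \((n, pkt, \lambda, M)\) needs
for a given precision, before deploying on real data where \(\Delta\) is
unavailable.

`sweep_lambda()` maps iterations-to-target over a \((pkt, \lambda)\) grid;
runs are censored at an iteration cap (default 5,000). Iteration counts,
not seconds, are the reported quantity: at fixed problem shape, time is
proportional to iterations, and iterations are hardware-independent;
elapsed seconds are logged for information. `optimal_lambda()` returns the
\(\lambda\) minimizing iterations, ties broken toward the smaller value.
The λ grids mirror the two-stage search practice: a coarse 0.1-step pass
over \((0, 2]\), then a fine 0.01-step pass near the coarse optimum. Values
\(\lambda \ge 2\) are accepted with a warning — sweeps deliberately probe
the divergence region, and censoring there reproduces the theoretical
boundary.

`block_scaling()` runs PB at \(M = 1, \dots, M_{max}\) to a fixed
\(\Delta\) target, fits iterations versus \(M\) by ordinary least squares,
and reports the slope and the ratio slope / iterations(\(M = 1\)): the
per-block iteration cost as a fraction of the single-block cost. Splitting
the system leaves each block with poorer information, so iterations grow
with \(M\); with the default column-sum weighting the growth is mild
(each added block costs a small fraction of the single-block iteration
count on the reference configuration), whereas with uniform averaging each
added block costs roughly one full single-block count — the recombination
choice, not the block partition, dominates the scaling. Block counts that
fail to converge within the cap are flagged and excluded from the fit.

## Reference configurations and test scale

The packaged studies use the configurations the tests and
`scripts/acceptance.R` execute:

* complete data: parallel beam, 100 angles × 121 rays, \(n = 40\),
  \(\lambda = 1\), constraint on — converges to \(\Delta < 0.05\) in a
  handful of iterations;
* limited angle: \(n = 40\), \(pkt = 50\) (2,498 rays), \(\lambda = 1.5\),
  PB with \(M = 3\) — order of a thousand iterations for the same target,
  the central contrast between complete and incomplete data;
* relaxation sweep: step 0.1 over \((0, 2]\), single block, target
  \(\Delta < 0.01\), cap 5,000;
* block scaling: \(n = 100\), \(pkt = 150\) (22,498 rays × 10,000
  unknowns), \(\lambda = 1\), target \(\Delta < 0.1\), \(M = 1..10\).

Module tests run the same operations on smaller grids (\(n \le 16\),
\(pkt \le 20\)) chosen so the whole suite exercises every code path in
seconds; the large configurations above appear once each.

## Known limitations

* Only the two generated geometries; the four-wall variant (sources and
  detectors on both pairs of opposite walls) is not implemented, though the
  geometry container admits it.
* No fan/cone beams, no detector physics, no noise model beyond the
  additive-Gaussian hook; rectangle phantoms only.
* Row ordering and block contiguity are fixed conventions; row-sorting or
  randomized-order variants, asynchronous block updates, and other ART
  relatives (MART, SIRT, SART) are out of scope.
* Convergence on real (inconsistent) data stalls at a noise-dependent error
  floor that these consistent-data studies do not measure.
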