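---
title: "Modeling serotonergic fiber densities with reflected fractional Brownian motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling serotonergic fiber densities with reflected fractional Brownian motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberfbm)
```

## The model

Serotonergic axons densely innervate the whole brain, with regional density
differences that are usually attributed to region-specific chemical cues.
This package implements the competing null model: individual fibers are
*reflected fractional Brownian motion* (rFBM) paths, and regional density
differences emerge solely from the interaction of the fibers' step
statistics with the three-dimensional brain shape.

A fiber advances by the recursion $r_{n+1} = r_n + \xi_n$. The steps
$\xi_n$ form a three-component discrete fractional Gaussian noise: the
$x, y, z$ components are independent, stationary, mean-zero Gaussian
sequences with autocovariance

$$\gamma(n) = \tfrac{\sigma^2}{2}\left(|n+1|^{2H} - 2|n|^{2H} +
  |n-1|^{2H}\right),$$

so each component's partial sums have variance $\sigma^2 n^{2H}$ exactly.
For $H = 0.5$ this is ordinary Brownian motion (uncorrelated steps); for
$H > 0.5$ the steps are persistent and the motion superdiffusive. Any step
whose endpoint would leave the allowed tissue volume is *not carried out*:
the increment is consumed, the fiber stays put for that time unit. This
boundary rule is deliberately minimal — reflection-rule details only matter
within a few steps of a wall — and it is what makes superdiffusive walkers
accumulate against borders, the key phenomenology the model produces.

### Assumptions worth stating

- Fibers are independent: no fasciculation, branching, or fiber–fiber
  interaction.
- The geometry is static; the model does not grow.
- One fixed $H$ per simulation; no regional modulation of the step
  statistics.
- Time is discrete and steps are counted even when rejected, so trajectory
  length is fixed at `n_steps + 1` positions.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `hurst` | 0.8 | — | Hurst index; 0.8 matches trajectory-level estimates for serotonergic fibers, superdiffusive regime |
| `sigma` | 0.4 | grid units | RMS step per component; 2.6 µm at calibration, below one cell so a step cannot jump a wall |
| `length` | 2^18 | steps | per-fiber walk length; full-scale runs use 2^25 (~0.8 GB of increments per fiber in three components) |
| `n_fibers` | 960 | — | cohort size of the full-scale experiment |
| `cell_um` | 6.6 | µm | physical side of one grid cell |
| `subdivisions` | 12 | — | virtual slices per 80 µm physical section (80/6.6 ≈ 12) |
| `bin_cells` | 2 | cells | density bins pool 2×2×2 voxels to suppress counting noise |
| `k` | $10^{8.3}$ | — | optical-density constant, tuned for the full-scale bin count |

The start region is a cuboid standing in for the rostral raphe region; at
full scale 680 × 1200 × 400 µm³, i.e. about 103 × 182 × 61 cells
(`start_region_from_um()`).

Because $d_s$ is normalized to sum one over *all* bins, the sensible
dynamic range of the optical transform depends on how many bins a geometry
has. Desk-scale grids have far fewer bins than the full-scale brain, so a
fixed $k = 10^{8.3}$ saturates; `density_grid(..., k = "auto")` instead
chooses $k = \ln 2 / \mathrm{median}(d_s > 0)$ so the median occupied bin
maps to $d_o = 0.5$. Rank order of bins is preserved by any such monotone
choice, which is what downstream comparisons rely on.

## Noise generation and its validation

The increments of FBM cannot be generated incrementally (the process is
non-Markovian), so each fiber's whole increment series is generated up
front. Two constructions are implemented, on the circulant embedding of the
target covariance on a grid of twice the next power of two above the
requested length:

- `generate_fgn_fourier()` — *Fourier filtering*: real white Gaussian noise
  is filtered in the frequency domain by the square root of the circulant
  eigenvalue spectrum; the first `length` values are returned.
- `generate_fgn_exact()` — *circulant embedding* (Davies–Harte): Hermitian
  complex Gaussian variates weighted by the same square-root spectrum and
  transformed by a single FFT.

Both have exactly the closed-form covariance at every lag below the grid
half-length (the embedding is non-negative definite for all $0 < H < 1$;
tiny negative eigenvalues from roundoff are clamped to zero), but they
consume randomness differently, so they act as independent cross-checks.
The test suite validates both against `fgn_covariance()` at lags 0–64 and
against the $\sigma^2 n^{2H}$ partial-sum law, using exact Gaussian
(Bartlett-type) standard errors with the full triangular-weighted sums —
for $H > 3/4$ the sample autocovariance converges slower than
$1/\sqrt{n}$, and truncated error formulas are badly anticonservative.

Seeding: every stream seed is derived from
`(master_seed, fiber_index, component)` by a fixed Lehmer-style mixing rule,
so cohorts are reproducible regardless of execution order, and density-mode
results are bit-identical whether fibers run forward, backward, or in
parallel. Each component of each fiber uses its own independent stream.

## Geometry

A brain shape is a stack of coronal sections; each closed contour is stored
as consecutive dorsoventral rows `(y, x_left, x_right)`. Dorsoventrally
oriented concavities cannot be represented by one such contour and are
coded as separate *forbidden* contours (ventricles, the dorsomedial notch).
Conventions the format itself does not fix, chosen here once:

- 0-based integer grid; cell $(i,j,k)$ occupies the half-open box
  $[i,i+1)\times[j,j+1)\times[k,k+1)$; $x$ mediolateral, $y$ dorsoventral
  (increasing ventral), $z$ rostrocaudal (increasing caudal).
- A point is inside iff its floor cell is covered by an allowed row and not
  by a forbidden row; multiple allowed contours union, forbidden contours
  subtract. Out-of-range $z$ is outside, which is exactly what makes the
  rostral and caudal ends reflecting.
- Virtual slice $k$ interpolates physical sections
  $\lfloor k/12 \rfloor$ and $\lfloor k/12 \rfloor + 1$ at fraction
  $(k \bmod 12)/12$; the caudal-most section's twelve slices are copies of
  it (no extrapolation), giving `z_extent = 12 × n_sections`.
- Interpolation matches contours by (kind, rank) and rows by $y$; a row or
  whole contour present in only one neighbour is kept iff the interpolation
  fraction lies nearer that section, with ties kept rostrally. This avoids
  topology jumps where a ventricle begins or ends, at the cost of a
  half-step quantization of such transitions. A `strict = TRUE` mode
  refuses unmatched contours instead.
- An interpolated forbidden row protruding beyond the interpolated allowed
  extent is clipped to it (with a warning); rows falling entirely outside
  are dropped.

The volume is rasterized once into a logical voxel mask, giving the O(1)
inside test the walker needs; the test suite verifies the mask
cell-for-cell against brute-force scanning of the slice contours.

## Walker details

- Only the step *endpoint* is tested against the geometry — no swept
  segment. With `sigma = 0.4 < 1` cell this cannot tunnel through a wall of
  one-cell thickness or more, which the contour format guarantees for
  the geometries built here.
- A rejected step advances the step counter and records the unchanged
  position, so all trajectories have exactly `length + 1` positions. Those
  duplicate positions are tallied in the density by default (time spent
  pressed against a border is real dwell time); `count_rejected = FALSE`
  exposes the sensitivity analysis.
- Start positions sample uniformly from the start cuboid, with bounded
  resampling if a draw lands outside the allowed region (possible only for
  a misconfigured cuboid, which errors after 100 tries).
- Whether "segments in a cell" should mean endpoints or swept line segments
  is ambiguous at the format level; endpoints are counted, and with
  $\sigma$ well below one cell the distinction is negligible.

## Phantom geometries

`make_slab()`, `make_sphere_stack()` and `make_brain_phantom()` generate
deterministic synthetic geometries so that every stage of the pipeline is
testable without any external data. The brain-like phantom reproduces the
*structural* features that matter to the walker — an elongated tapering
allowed volume, paired internal forbidden slots (lateral-ventricle-like), a
dorsomedial forbidden notch over a contiguous run of sections, and a
raphe-like start cuboid in the caudal third — at roughly 1/10 the linear
scale of the real embryonic-brain model. It makes no attempt at anatomical
realism: no hippocampal folding, no nuclei, no real contour data. Passing
tests on phantoms therefore demonstrate correctness of the machinery, not
anatomical fidelity of any particular density map; a loader for real
contour stacks in the same `stack.json` dialect is the intended route for
real geometries.

## Analysis choices

- **Hurst estimation** is half the log–log slope of the ensemble- and
  time-averaged MSD over lags 8–512 (about 25 log-spaced lags). It is a
  validation instrument for the generator/walker chain, exact on power
  laws; it requires free-space (unreflected) trajectories and refuses
  reflected ones in strict mode, because confinement saturates the MSD.
- **Border profiles** group density bins by Chebyshev distance (in bins) to
  the nearest non-allowed bin; Chebyshev is cheap and direction-agnostic at
  this resolution. The shells partition the allowed bins, which the tests
  assert exactly.
- **Convergence**: trajectory lengths "sufficient for steady state" have no
  universal criterion; `density_tv_distance()` between first- and
  second-half densities is provided as a diagnostic, with no threshold
  imposed.

## Numerical notes

- FFT grids are powers of two (length $2L$, $L$ the next power of two at or
  above the requested length); generation of $10^6$ values takes well under
  a second.
- The walker accumulates positions in C++ doubles in step order; with
  boundaries removed it reproduces plain sequential summation bit for bit.
  (R's `cumsum()` accumulates in extended precision and is *not* the
  bit-level reference.)
- Density counts are 32-bit integers; the largest cohorts used in the tests
  tally ~4×10^6 positions, far from overflow. Normalization sums in double
  precision and is asserted to 1 within 1e-9 on every run.
- Grid dimensions not divisible by the bin size keep their trailing partial
  bins, so no position is ever dropped.

## Problem sizes used in the tests

The suite runs desk-scale versions of the full experiment: noise validation
on sequences of $2^{18}$–$2^{20}$, Hurst recovery from 32 free fibers ×
$2^{16}$ steps, confinement on a brain-phantom cohort of 16 fibers ×
$2^{18}$ steps, border accumulation on a radius-16 sphere with 8 fibers ×
$2^{16}$ steps at $H = 0.8$ versus $H = 0.3$, and symmetry on slab cohorts
of 256 fibers × $2^{12}$ steps. These sizes were chosen so the whole suite
completes in a few minutes while keeping Monte-Carlo error well inside the
asserted bands; the full-scale configuration (960 fibers × $2^{25}$ steps)
is reachable through the same interfaces.

## Known limitations

- The boundary rule, endpoint-only collision test, and endpoint counting
  are all justified by $\sigma < 1$ cell; configuring $\sigma > 1$ breaks
  those justifications (the walker warns but does not stop you).
- The nearest-section rule quantizes contour appearance/disappearance to
  half physical steps.
- No multifractional FBM (position-dependent $H$), no growing geometry, no
  deterministic bundle routing: fibers here are exchangeable.
- Real-data comparisons (atlas registration, semi-quantitative regional
  scoring) are out of scope; the package produces the density volumes and
  profiles such comparisons would consume.
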