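---
title: "Designing and validating digital nanodot gradients"
author: "dngrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating digital nanodot gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dngrad)
```

## The design problem

A digital nanodot gradient encodes a one-dimensional density profile
$D(l) \in (0, 0.9999]$ as the areal coverage of identical square nanodots
(edge $e$, area $A_{dot} = e^2$) over a rectangular field: the gradient
runs along $x$ (length $L$), density is constant along $y$ (width $W$),
and all coordinates are micrometres from the bottom-left corner. Cells
plated on the printed protein pattern experience the dot density as a
graded concentration of substrate-bound cue, so the designer needs (i)
layouts whose *realized* density faithfully tracks the programmed profile
and (ii) a defensible statement about whether a "random" layout really is
random at the length scales a cell samples.

Density 1 is unreachable by construction — an ordered unit cell would have
to shrink to the dot itself and a random layout would need infinitely many
dots — so every evaluated density is clamped to $[0, 0.9999]$.

## Density profiles

`density_spec()` supports linear, exponential, sinusoid-on-trend and
custom profiles. Monotonic profiles are pinned to both endpoints,
$D(0) = D_{min}$ and $D(L) = D_{max}$; for the exponential with decay
constant $k$ the unique single-exponential form with that property is

$$D(l) = D_{min} + (D_{max} - D_{min})\,
  \frac{e^{k l / L} - 1}{e^{k} - 1},$$

degenerating smoothly to the linear ramp as $k \to 0$ (and explicitly at
$k = 0$). Non-monotonic profiles superpose a sinusoid on a trend:

$$D(l) = \mathrm{trend}(l;\,k_1) + A\, g(l;\,k_2)\,
  \sin\!\left(\frac{2 \pi B l}{L}\right),$$

with $B$ oscillations over the length and an amplitude envelope $g$. The
source that motivated this design states the envelope's parameters
($A$, $B$, $k_1$, $k_2$) but not its printed algebra, so the envelope here
is a design choice made once: $g$ shares the endpoint-normalized
exponential shape with constant $k_2$, extended to $g = l/L$ at $k_2 = 0$
(linearly growing amplitude) and $g \equiv 1$ when $k_2$ is `NA` (constant
amplitude). These three regimes cover the zero-slope controls and
growing-amplitude designs of the bundled 100-gradient table. A flat trend
(`sinusoid_flat`) requires `D_min == D_max`, which *is* the level.
Negative excursions are clamped at 0 — a density cannot be negative — and
custom profiles are clamped but never normalized.

## The ordered generator

`generate_ordered()` realizes local density with a virtual unit cell of
side $d = \sqrt{A_{dot}/D}$ holding one dot. Columns are placed
iteratively: the first at $l_0 = 0$, each next at the cumulative sum
$l_{i+1} = l_i + d_i$ with $d_i = \sqrt{A_{dot}/D(l_i)}$, stopping at the
last column whose full cell fits inside $L$ (no partial trailing cell).
Within a column, $n_i = \mathrm{round}(W/d_i)$ dots (at least 1, at most
$\lfloor W/e \rfloor$) are re-spaced equally over the width with equal
margins at both edges, keeping the layout symmetric. Dot centres sit at
$l_i + e/2$, so dots never protrude past the low-$x$ field edge.

Two consequences matter for interpretation:

- Each cell spans $[l_i, l_i + d_i)$ but realizes the density sampled at
  its *left edge*. Measured profiles therefore lag the programmed curve by
  half a cell; the relative error is about $D'(l)\, d / (2 D)$, negligible
  at moderate density but up to tens of percent where the profile is steep
  *and* the density (hence $1/d$) is small. This is intrinsic to the
  cumulative-sum construction, not a measurement artifact, and it is why
  the ordered fidelity R² saturates near 0.9998–0.9999 rather than 1.
- At `D = 0.4444` with 200 nm dots the cell side is 300 nm, i.e. a 100 nm
  edge-to-edge gap — the e-beam resolution limit that caps the density of
  the bundled array designs.

## The random generator and overlap compensation

`generate_random()` subdivides the field into full-width boxes of
`box_width` (default 1 µm) along the gradient axis and seeds each box
independently with uniformly distributed dot centres. Random dots overlap,
and overlap grows with density, so seeding the naive count
$D \cdot A_{box}/A_{dot}$ would systematically under-cover. For
independently placed dots the probability that a point of the box escapes
all $N$ dots is $(1 - A_{dot}/A_{box})^N$, giving expected union coverage

$$\mathbb{E}[\mathrm{coverage}] = 1 - (1 - A_{dot}/A_{box})^N
\quad\Longrightarrow\quad
N = \left\lceil \frac{\ln(1 - D)}{\ln(1 - A_{dot}/A_{box})} \right\rceil,$$

the count `compensated_count()` seeds (`ceiling` so the target is never
undershot; the overshoot is below one dot's coverage). The count diverges
as $D \to 1$ — the reason for the 0.9999 cap, where a 400 × 1 µm box takes
92,099 dots in place of the naive 9,999.

Box density is sampled at the box midpoint (symmetric, and it reproduces
published dot budgets for linear ramps within a tenth of a percent). A
final truncated box uses its actual area. Dot centres span the **full box
along the gradient axis**, so dots may straddle interior box seams; they
keep $e/2$ clearance only at the four field edges so every dot lies inside
the field. The alternative — shrinking every box by a dot edge — was
rejected after measurement: with 1 µm boxes it starves a $\pm e/2$ strip
at every seam and biases realized coverage low by up to
$O(e/\mathrm{box\_width})$, which would cap fidelity R² around 0.9995.
With straddling allowed, per-box coverage is unbiased up to $O(e/W)$ edge
terms, and `coverage_check()` (below) confirms it. A consequence worth
knowing: the two *end* boxes of a field squeeze their dots into
$\mathrm{box\_width} - e/2$, so their local intensity runs ~$e/2$-worth
high; validation windows should sit in the field interior.

`grid_threshold_pattern()` provides the halftoning alternative: dots on a
fixed $e$-pitch grid, each switched on when a uniform draw falls below the
local density. Positions are ordered, values random; it is included as the
comparison generator, not as a substitute for true positional randomness.
(Here a capped density of 0.9999 switches a cell on deterministically —
the cap exists for the diverging seeded count, which a grid cell does not
have.)

All generators derive every random draw from `spec$seed` and restore the
caller's RNG state, so identical specs give bit-identical layouts.

## Rasterization and density fidelity

`rasterize()` marks a pixel covered exactly when its centre lies inside a
dot square (half-open on the high edge, no anti-aliasing): density
measurement is black/white pixel counting. With the default
`pixel_size = dot_edge/10` the dot edge is an exact multiple of the pixel
size, so every interior dot covers exactly $10 \times 10$ pixels wherever
it sits — counted dot area is exact, and profile residuals reflect the
pattern, not the raster.

`measure_density_profile()` reports, per full-width window along the
gradient, covered pixels over window area, and summarizes fidelity as
$R^2 = 1 - SS_{res}/SS_{tot}$ of measured against *programmed* values (no
refitted line; a constant profile reproduced exactly reports $R^2 = 1$).
The programmed reference is the mean of $D$ over each window — identical
to the centre value for narrow windows, unbiased when windows are wide or
the profile oscillates. Windowing conventions, chosen once:

- **Ordered patterns**: windows are whole unit-cell columns
  (`ordered_breaks()`, grown to a ≥ 1 µm target). Fixed windows cutting
  through cells see a biased dot count (R² collapses to ~0.93 at 2 µm
  pitch with 1 µm windows); averaging over whole columns is also how the
  realized density is defined. The benchmark 0.01→0.30 linear design
  measures R² = 0.99986 this way.
- **Random patterns**: windows equal to the seeding boxes (1 µm). A single
  design carries irreducible Boolean-coverage noise per box
  (SD ≈ $\sqrt{D(1-D) A_{dot}/A_{box}}$, about 0.009 at $D = 0.3$ in a
  100 µm² box), putting single-seed R² near 0.9995–0.9997. Replicate
  designs are independent, so fidelity of the *generator* is assessed on
  the measured profile averaged over five replicate seeds, reaching
  R² ≈ 0.9999 for the exponential benchmark and ≈ 0.9997 for the
  non-monotonic one.

`coverage_check()` closes the loop on the compensation formula end to end:
it generates a five-box constant-density field, rasterizes at 20 px per
dot edge, and measures the union coverage of the middle box (whose
neighbours are interior boxes, as in any gradient interior) over
independent seeds. At $D \in \{0.1, 0.5, 0.9\}$ with 50 seeds the measured
mean sits within ±2 standard errors of the target.

## Ripley's K and the CSR envelope

Randomness can only be assessed where intensity is stationary — along
strips of constant density, perpendicular to the gradient. `ripley_k()`
uses the standard estimator

$$\hat K(s) = \frac{A}{n(n-1)} \sum_{i \ne j} \mathbf{1}[d_{ij} \le s],$$

with expectation $\pi s^2$ under complete spatial randomness. No analytic
edge correction is applied; instead `csr_envelope()` simulates uniform
point sets *in the same rectangle with the same count* (default 10
simulations, band = mean ± 1.96 SD), so edge bias cancels in the
comparison. Pair counting is compiled (Rcpp) with a sorted sweep over the
short coordinate, keeping 20,000-point strips at millisecond cost.

Calibration facts, verified in the test suite: $\hat K/(\pi s^2)$ is
within 10% of 1 at small radii for CSR; the envelope centre is the mean of
its own simulations and tightens as $1/\sqrt{n_{sims}}$. One caveat stated
plainly: a band built from an SD *estimated from 10 simulations* is
narrower than its nominal 95% — a single CSR curve escapes it at roughly
10% of radii, not 5% (the nominal rate is recovered when the envelope uses
enough simulations for the SD to stabilize, e.g. 100). Classification is
therefore comparative, and stable summaries average the estimate over
replicate patterns: the seed-averaged CSR curve and the box-seeded
generator's average both stay inside the band at ≥ 95% of radii, while
the ordered grid at the same density leaves it at almost every radius —
the qualitative ordered/random separation the envelope exists to show.
Strips should be interior (see the end-box caveat above), and the largest
radius should stay well below the strip's short side.

## Print-fidelity QC

The overlay pipeline quantifies how well a printed pattern reproduces its
design. `simulate_print()` provides a ground-truthed stand-in for a
fluorescence micrograph: it removes a seeded random subset of the design's
connected dot components, blurs with a Gaussian PSF (EBImage), scales to 8
bits and adds clipped Gaussian noise, recording the removed components.
`threshold_binarize()` keeps pixels in a gray band (default 31–255), and
`overlay_count_missing()` flags a design component as missing when fewer
than `min_overlap = 0.25` of its pixels are covered in the binarized print
— a quantitative proxy for counting unprinted dots by eye on a merged
overlay. Registration is assumed done (synthetic prints are generated
pre-aligned).

With PSF width up to half a dot edge and noise SD up to ~10 gray levels,
injected dropout counts of 0, 5, 21 and 100 on a ~1000-dot design are
recovered exactly across seeds; the 21-of-992 scenario reports 97.9%
fidelity. The proxy's limits: it does not quantify spot size or intensity,
and heavily overlapping designs merge into fewer connected components, so
"dots considered" counts components, not seeded dots.

## The 100-gradient array

`load_array_table()` reads a CSV of per-gradient parameters and
`build_array()` places the generated patterns on a grid (10 × 10 at 190 µm
spacing fits one hundred 400 µm gradients in ~35 mm²), writing a
multi-symbol CIF and a manifest of per-gradient dot counts, seeds, offsets
and dynamic range $\log_{10}(D_{max}/D_{min})$. The bundled table spans
ordered/random linear and exponential ramps (densities 0.0002–0.4444,
dynamic range up to 3.35 decades) and the sinusoid taxonomy: zero-slope
controls with growing or constant amplitude, and linear/exponential trends
with constant or growing amplitude. The full build is minutes-scale
(tens of millions of dots); tests exercise scaled-down subsets and verify
per-gradient counts individually.

CIF files use 1 unit = 10 nm, which represents 200 nm dots and 100 nm
pitches exactly; coordinates round-trip to within half a unit. Rasters
round-trip losslessly through 8-bit PNG with the physical pixel size in a
JSON sidecar.

## Problem sizes and numerical conventions

- Default study geometry: 400 × 400 µm fields with 0.2 µm dots and 1 µm
  boxes for designs; 100 × 100 µm for fidelity benchmarks; rasters at 10
  px per dot edge (20 for coverage checks); Ripley strips of 10 × 400 µm
  at density 0.20 with radii to 2 µm. Test-suite replicate counts: 50
  seeds for coverage, 10 for envelopes, 5 for profile averaging.
- Half-open interval conventions make pixel counts exact for grid-aligned
  dot edges; a shared $10^{-9}$ guard keeps `ceiling` stable against
  floating-point ties.
- `compensated_count` uses `log1p` for accuracy near the cap and a
  $10^{-9}$ slack inside `ceiling` so exact-integer ratios do not round
  up spuriously.
- Degenerate inputs: zero density is a domain error for the ordered
  generator (the unit cell diverges); a unit cell wider than the field
  emits one centred dot per column with a single warning; an empty
  pattern is refused by the CIF writer; a constant programmed profile
  matched exactly reports $R^2 = 1$ (undefined otherwise, with a
  warning).

## Known limitations

- Density profiles are one-dimensional; no two-dimensional density fields
  or perpendicular superposition.
- The ordered generator's half-cell sampling lag bounds achievable R²
  where profiles are steep at low density (see above).
- Ripley analysis offers no analytic edge correction and no L-function or
  pair-correlation variants; conclusions rest on same-geometry envelopes.
- The print simulator models dropout, Gaussian blur and additive noise
  only — no spot-size variation, intensity gradients, or registration
  error; real micrographs must be registered before overlay.
- The synthetic print stands in for real fluorescence data: passing QC
  here validates the pipeline's bookkeeping, not any particular printing
  process.
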