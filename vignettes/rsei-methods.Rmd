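---
title: "RSEI mapping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RSEI mapping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rseimap)
```

This vignette is the package's own account of the science it implements:
the index model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The index model

The Remote Sensing Ecological Index condenses four per-pixel indicators of
ecological state into one score:

* **Greenness** — NDVI, $(\rho_{NIR}-\rho_{red})/(\rho_{NIR}+\rho_{red})$,
  in $[-1,1]$; negative over water, near 1 over dense vegetation.
* **Dryness** — NDBSI, the mean of the index-based built-up index (IBI)
  and the bare-soil index (SI), in $[-1,1]$; negative over vegetation,
  positive over impervious or bare surfaces.
* **Heat** — land surface temperature in °C, decoded from thermal-product
  digital numbers as $0.02\,\mathrm{ND} - 273.15$.
* **Wetness** — the tasseled-cap wetness component, a fixed linear
  combination of the seven reflectance bands
  ($0.1147\rho_{red} + 0.2489\rho_{NIR1} + 0.2408\rho_{blue} +
  0.3132\rho_{green} + 0.3122\rho_{NIR2} - 0.6416\rho_{SWIR1} -
  0.5087\rho_{SWIR2}$).

Each indicator is min-max normalized *per year* over the valid pixels,
$(I - I_{min})/(I_{max} - I_{min})$, placing all four on $[0,1]$ before
they are mixed. The difference form of the denominator is used because it
is the only affine rescaling that guarantees the stated $[0,1]$ range.
PCA is then run on the covariance matrix of the four normalized indicators
(pixels as observations) and PC1 becomes the index. Using the covariance
— not correlation — matrix of the already-normalized indicators follows
the index's original recipe: normalization has equalized scales, and the
residual variance differences are information the index should keep.

Three structural guarantees follow from the construction and are asserted
in the tests:

* the normalized index attains both 0 and 1 every non-degenerate year;
* the four explained-variance fractions sum to 1;
* the index correlates positively with normalized greenness.

### Orientation

An eigenvector's sign is arbitrary, so PC1 must be oriented before it can
mean "larger is better". The rule: if the greenness and wetness loadings
(the ecology-positive indicators) are negative, the component points away
from ecological quality and the score is flipped ($1 - PC1$); the
subsequent min-max rescaling makes the choice of flip constant immaterial.
When the two loadings disagree in sign — possible when indicators are
nearly uncorrelated — the greenness loading alone decides, and a warning
is issued, since vegetation vigor is the least ambiguous ecological
signal of the four. Before the rule is applied, the eigen-solver's sign is
made deterministic by forcing the largest-magnitude loading positive.

### Classification

The $[0,1]$ index is divided into five equal classes: Poor $[0,0.2)$,
Fair $[0.2,0.4)$, Moderate $[0.4,0.6)$, Good $[0.6,0.8)$, Excellent
$[0.8,1]$. Boundaries belong to the upper class and the top interval is
closed, which makes the scheme exhaustive and deterministic. Values
outside $[0,1]$ are treated as errors rather than clamped: they indicate
a normalization bug upstream, not data.

A configurable alternative — normalizing each pixel over its own temporal
min/max instead of scene-wise per year — is deliberately *not* the
default: scene-wise normalization keeps the mapped classes spatially
comparable within a year, which is what the class maps are for.

## Compositing and masking

Annual composites cover September 1 (of year $Y-1$) through March 31 (of
year $Y$), the austral spring–summer window, and carry the label $Y$.
The per-cell statistic is the **median** by default (robust to residual
cloud contamination that slips past the QA mask); the mean is selectable.
Heat is composited on the digital numbers and converted afterwards — the
conversion is affine, so it commutes with the mean, and the median
commutes with any monotone map, so the order is exact either way.

Quality control uses per-pixel integer bit words. A bit specification is
a list of bit-field tests (`qa_bits_mod09a1()` mirrors the MODIS surface
reflectance state flags: cloud-state bits 0–1 must be clear and shadow
bit 2 unset; `qa_bits_single()` is the one-bit convention of the
synthetic generator). Masking never alters retained values — pass-through
is bit-exact — and a composite cell is valid only if every layer received
at least one usable observation.

Thermal rasters arrive on a coarser grid than reflectance (the 1 km vs
500 m product pairing) and are resampled **nearest-neighbor** onto the
common analysis grid: each destination cell takes the value of the source
cell with the nearest center, so no new values are invented. Equidistant
ties resolve to the northern, then western, candidate — an arbitrary but
deterministic preference, checked against an exhaustive nearest-center
search in the tests.

## Trend and change-point mapping

Per pixel over the annual index series:

* **Theil-Sen slope** $\beta$: the median of all pairwise slopes
  $(x_j - x_i)/(t_j - t_i)$, $i<j$, in index units per year. The median —
  not the mean — of pairwise slopes is the Theil-Sen estimator and is
  what makes the slope robust; the mean remains available as an option
  for comparison.
* **Mann–Kendall**: $S$ counts concordant minus discordant pairs;
  $\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$ with the
  tie correction; $Z$ is continuity-corrected ($S\mp1$) and zero at
  $S=0$. Two-tailed classes at the 90/95/99% levels use critical values
  $1.645$, $1.96$ and $2.574$; the last is a slightly conservative
  rounding of the $2.5758$ normal quantile, kept as the default for
  comparability with common practice in this literature and configurable
  via `z_crit`.
* **Pettitt**: $U_t = \sum_{i \le t}\sum_{j > t} \mathrm{sgn}(x_j - x_i)$
  computed by the recursive update (verified equal to the direct double
  sum, exhaustively, in the tests); $K = \max_t |U_t|$; the change year
  $\tau$ is the argmax, earliest on ties, reported as the **last year of
  the first segment**; $p \approx 2\exp(-6K^2/(T^3+T^2))$, clamped to 1,
  significant at $\alpha = 0.10$.

Cells with fewer than `min_years` (default 10) valid years are nodata
rather than a noisy test. Missing years are skipped, never imputed; for
the rank-based Pettitt statistic the series is compressed to its $n$
valid observations, which ignores unequal spacing — acceptable for a
rank statistic, but worth remembering when many years are missing.

## The synthetic generator

`make_scenario()` fixes a land-cover class map (five classes: urban,
dense vegetation, agriculture, water, bare soil) as a *deterministic*
function of the grid; the seed governs only noise and cloud draws. Each
class has a mean 7-band reflectance signature and a mean LST chosen to be
MODIS-plausible (e.g. water has $\rho_{NIR} < \rho_{red}$ so NDVI is
negative; urban runs hot and bright in SWIR). Rendering adds, per scene
date: linear per-class drift (units per year), an optional step change at
a known year inside a known region, and additive Gaussian noise truncated
to the valid reflectance range (default sd 0.02 reflectance, 0.8 °C for
LST — modest relative to the inter-class contrasts, as in good-quality
composited imagery). Cloud flags are Bernoulli per cell and date (default
fraction 0.15, a plausible post-QA loss rate for an 8-day product in a
coastal tropical region); the thermal scene of a date shares the
reflectance QA draw to mimic co-located cloudiness, and is rendered on a
2× coarser grid so the pipeline's resampling path is exercised.

What the generator does **not** emulate: radiative-transfer or BRDF
effects, spatially correlated noise and cloud fields, sensor drift,
mixed pixels at class boundaries, or seasonal phenology within the
compositing window. Passing tests therefore demonstrate correctness of
the algorithms and their wiring, not performance on real archives —
real-data behavior (e.g. how much variance PC1 explains) will differ.

### Recovery test bed

Trend and change-point *recovery* is scored on `make_index_cube()`, which
generates the annual index cube directly: base 0.5, drift $+0.01$ yr⁻¹
inside a region, a $+0.15$ step at a known year, Gaussian noise sd 0.05,
25 years. The conditions are stated at the index level because the
scene-level pipeline renormalizes each year to $[0,1]$, so a band-level
drift maps onto the final index nonlinearly and no exact index-level
drift could be injected through it. At these conditions the Mann–Kendall
map flags ≥ 80% of drifted cells as increasing at the 90% level with a
false-positive rate statistically compatible with $\alpha = 0.10$, and
Pettitt recovers the break within ±1 year in ≥ 80% of affected cells.
One convention matters when scoring: a step first applied in year $Y$
has its true change-point label $Y-1$ (the last pre-change year), since
that is what $\tau$ estimates.

## Numerical and I/O choices

* Zero denominators in the spectral indices yield nodata, not ±Inf:
  composites over water or fill can legitimately produce zero sums.
* Constant rasters cannot be min-max normalized and raise an error
  (degenerate input), as does PCA input with zero total variance or
  fewer than 5 valid pixels.
* Explained-variance fractions are checked to sum to 1 within $10^{-9}$;
  the PC1 loadings are verified in tests against an explicit-summation
  covariance and eigen-decomposition to $10^{-8}$.
* Rasters travel as uncompressed GeoTIFFs (float32 for continuous
  layers, int32/uint8 for codes) with georeferencing tags, a nodata tag,
  and scene metadata as JSON in the image description. The codec is
  implemented in the package and cross-checked against an independent
  TIFF implementation in the tests. Scaled-integer reflectance (the
  common archive convention, scale $10^{-4}$) is converted on read when
  the file metadata or the reader argument says so.
* Float32 storage rounds to ~7 significant digits; the tests that
  round-trip scenes through disk assert agreement at storage precision,
  and byte-identical reproducibility is asserted for the CSV/JSON
  products.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances — grids of 10–20 cells a side, 1–25 index years, 2–4 scenes per
season, and exhaustive statistical-core checks on all series of length
≤ 8 over a three-letter alphabet — sizes chosen so the full suite
completes in well under a minute per file while still exercising every
code path at realistic parameter values. All quantities scale linearly in
pixels × years except the pairwise statistics, which are quadratic in the
number of years (trivial at 25).

## Known limitations

* Single coordinate system: geographic WGS84 grids with square cells in
  degrees; no reprojection.
* One change point per series; no prewhitening or autocorrelation
  correction in the trend test (annual composites keep serial
  correlation modest, but it is not zero).
* Scene-wise normalization couples a pixel's index value to the year's
  scene extremes; comparing absolute RSEIn values *across* years relies
  on those extremes being stable, which holds for the synthetic scenes
  and should be checked on real data.
* The Pettitt $p$-value is an asymptotic approximation; for very short
  series it is conservative.
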