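---
title: "Processing and analysis methods of the tlstation toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and analysis methods of the tlstation toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlstation)
```

# The measurement setting

`tlstation` processes point-cloud time series from a fixed, automated
terrestrial laser scanning (TLS) station: a scanner mounted ~30 m above the
ground on a tower, repeatedly scanning the same forest scene on a fixed
angular grid (0.006° steps over an 87° × 151° window, detection range
138 m, up to 8 returns per pulse, 21-minute scans every hour). Because the
scanner never moves, consecutive scans are pixel-aligned by construction,
and structural change over time — spring leaf-out, stem growth, circadian
branch movement — can be read directly from the aligned clouds without
registration.

The package covers the processing chain (coordinate enrichment, LAS 1.4
export, rasterization, weather gating) and three analyses (voxel-based
crown densification, RANSAC cylinder DBH series, cluster-median movement
tracking), plus a ground-truthed scene simulator that stands in for the
scanner in all tests.

# Coordinate conventions

All per-point geometry lives in a scanner-centric Cartesian frame: origin
at the scanner optical centre, Z up, coordinates in metres. Spherical
coordinates are the range $\rho = \sqrt{X^2+Y^2+Z^2}$, the polar angle
$\theta = \arccos(Z/\rho)$ measured from +Z, and the azimuth $\varphi$.
Angles are kept in degrees throughout, matching every printed configuration
value; radians appear only inside conversions.

Two conventions deserve a note:

* **Azimuth.** A single-argument arctangent of $Y/X$ is ambiguous by 180°,
  and the station's 151° horizontal window spans several quadrants. The
  azimuth is therefore the four-quadrant `atan2(Y, X)` wrapped to
  [0°, 360°).
* **The 0°/360° seam.** A scan window may legitimately sit across the
  azimuth seam. `pixel_of()` computes column offsets modulo 360°, so a
  window may be declared with a negative `phi_min` (e.g. [−5°, 20°]) and
  points at 358° land in the correct column. Scenes that *span* more than
  half a turn around the seam should instead pass an explicit window.

The equirectangular raster maps angles linearly to pixels:
$r = \lfloor(\theta - \theta_{\min})/\alpha\rfloor$,
$c = \lfloor(\varphi - \varphi_{\min})/\alpha\rfloor$, with 0-based indices
and half-open pixels $[k\alpha, (k+1)\alpha)$; a point exactly on the upper
window bound falls in the last pixel, so the window is fully covered.
Image dimensions are $\lceil \mathrm{span}/\alpha \rceil$ per axis (with a
$10^{-9}$ relative guard so exact multiples do not gain a pixel).

The published description of the raster products is internally
inconsistent: a pixel size of 0.0019° is stated alongside image dimensions
of 8,013 × 4,618 pixels for the 87° × 151° window, which imply
≈ 0.0188° per pixel — and neither matches the 0.006° scan step. The pixel
size is therefore a free configuration parameter here; the published
dimensions are reproduced per axis by the pixel sizes 87°/4618 and
151°/8013. The raster frame is anchored at the *configured* window bounds,
not at each scan's own minimum angles, so images in a time series stay
pixel-aligned; the per-scan-minimum variant can be had by passing a window
computed from the scan itself.

# Analysis-ready point clouds

A `scan_cloud` carries X/Y/Z plus return number, number of returns (the
schema allows 1–15; the scanner emits at most 8), normalized intensity,
reflectance (dB), pulse-shape deviation, and the derived columns range,
theta, phi, row, col. `enrich()` recomputes the derived columns from the
coordinates, so enrichment is idempotent, and flags out-of-window points in
a boolean `in_window` column instead of dropping or clamping them.

Files are ASPRS LAS 1.4, point data record format 6, with the derived and
radiometric attributes stored as named extra-bytes dimensions
(`reflectance_db`, `deviation`, `range_m`, `theta_deg`, `phi_deg` as
32-bit floats; `scan_row`, `scan_col` as 32-bit unsigned integers with
no-data sentinel 2147483647 for out-of-window indices). Coordinates use a
1 mm storage scale. Intensity is stored in LAS's native 16-bit field scaled
by 65535 from the normalized 0–1 value; the number is preserved without
committing to a physical unit. The reader rejects LAS versions before 1.4
explicitly and degrades gracefully — a file without the extra-bytes
descriptor loads with a warning and simply lacks the derived columns.
Compressed LAZ output is not produced; files are written uncompressed.

# Rasterization

`rasterize()` produces one image plane per return number 1–4 (extendable
to 8); later returns are so rare at the station that they are dropped by
default. When several points of the same return fall into a pixel, the
point nearest the scanner wins, and — important for consistency — the
range, reflectance and deviation stacks all take *that same winning
point's* value, so the three products describe one surface per pixel, the
way a camera image would. Mean and max reducers are available where
aggregate values are wanted. A per-channel count plane preserves
multiplicity, giving the conservation property used throughout the tests:
the count planes sum to the number of in-window points with return ≤ 4.

TIFF storage uses 32-bit float samples. The TIFF writer available to the
package stores float samples on a normalized [0, 1] scale, so each band is
mapped affinely from its finite value range into [0.05, 1] with 0 reserved
for no-data; the per-band ranges, window geometry and attribute name
travel in a JSON sidecar next to the image. At float32 resolution the
normalization preserves better than $10^{-5}$ of the band span —
micrometres on a range image — and count planes round-trip exactly.
Quicklooks map a display window (default 5–139 m, the station's range
display) linearly to gray levels 0–255, rounding halves away from zero,
with no-data rendered black.

# Point-cloud cleanup

Two filters precede the movement analysis, with the station's settings as
defaults:

* **Isolated-point removal** keeps a point iff at least 3 *other* points
  lie within a 5 cm 3-D neighbourhood. The published wording ("at least 3
  points within 5 cm") does not say whether the point counts itself; the
  self-excluding reading is used because a fully isolated point trivially
  contains itself, which would weaken the filter. `count_self = TRUE`
  flips the reading.
* **Minimum-distance subsampling** enforces a 5 mm minimum spacing by a
  greedy sequential pass: a point is kept iff it is ≥ 5 mm from every
  previously kept point. This honours the "minimum distance between
  points" phrasing exactly (a voxel-grid thinning would not guarantee it).
  The result depends on scan order, so the cloud is first sorted by
  (row, col) when the raster indices are present; the output's minimum
  pairwise distance is then a hard invariant, and re-subsampling is a
  no-op.

# Weather gating

Scans enter the long-term analyses only when acquired in calm conditions:
maximum wind over the scan window strictly below 3 m/s (calm to light
breeze on the Beaufort scale) and zero precipitation (equality to 0 mm
within $10^{-9}$, not a "trace" threshold). The criterion is evaluated on
the *maximum* wind over the full 21-minute window rather than at a single
instant, because one gust anywhere in a scan corrupts it; mean-wind and
start-instant statistics are available behind a flag, and only the
published monthly pass counts are treated as ground truth. Window
statistics come from the 1-minute records with linear interpolation at the
window edges; precipitation intensity (mm/h) is integrated trapezoidally
into a depth.

# Crown densification (leaf sprout)

Epoch comparison voxelizes tree clouds on a 0.10 m cubic grid:
voxel index $= \lfloor(\mathrm{coord} - \mathrm{origin})/\mathrm{edge}\rfloor$
per axis. Two grids are comparable only when they share edge *and* origin,
so the origin is anchored at the floor of the union bounding-box minimum
of the compared epochs, snapped to an edge multiple — alignment is not
stated in the source material, and a shared anchor is the minimal
assumption that makes the comparison well defined. The summary reports
total points, occupied voxels, mean points per occupied voxel, and the
relative changes $(b-a)/a \times 100\%$; swapping the epochs flips the
sign up to that denominator convention. "The half of the tree facing the
scanner" is implemented as the points at or below the cloud's median
range — a reproducible proxy for the informal description.

# Stem diameter series

The DBH pipeline cuts a slab at 1.3 m ± 0.30 m above ground (ground
defaulting to the 1st percentile of Z), then drops detached foliage by
keeping the largest XY-connected component at 5 cm single linkage — an
automated stand-in for what is otherwise manual cleanup. The cylinder fit
is RANSAC: minimal samples of 3 points define candidate circles in the
horizontal plane (the axis is initialized vertical, since stems are
near-plumb at breast height), the consensus set at a 1 cm surface
tolerance picks the winner, and the winner is refined by a Gauss–Newton
least-squares fit on its inliers — optionally with two small axis-tilt
parameters (`axis = "free"`). Inliers are re-evaluated once under the
refined model and the fit repeated. A fit whose consensus covers less than
30% of the slab fails loudly rather than returning a guess.

The per-fit dispersion σ is reported as the standard deviation of the
inlier point-to-surface residuals — the only statistic consistent with the
millimetre magnitudes quoted alongside published radii. DBH is twice the
fitted radius, reported in mm to one decimal. Against a caliper reference
the package reports the arithmetic mean of the measurements and *both* the
population and sample standard deviations, labelled: the four published
caliper values (181, 166, 170, 175 mm) have population sd 5.6 mm and
sample sd 6.5 mm while the source quotes "5 mm", so neither is forced to
match.

# Circadian movement tracking

The short-term monitor follows the cluster approach: on a cleaned,
subsampled initial scan, seeds are drawn by random rejection (a seeded
random visiting order, accepting a point iff ≥ 0.15 m from every accepted
seed), every point is assigned to its nearest seed *within* 0.15 m, and
clusters below 100 points dissolve, their points reassigned to the nearest
surviving seed within the cap — cascading until all survivors meet the
minimum. The assignment cap is a design decision: the source states a
"maximum initial cluster diameter" without a mechanism, and an uncapped
nearest-seed assignment could not enforce it.

Labels propagate to each subsequent scan by nearest neighbour against the
previous scan, again capped at 0.15 m so labels cannot bleed across
branches; unassigned labels propagate as unassigned. Per scan and cluster
the component-wise (marginal) median of member coordinates is compared
with the initial median; the Euclidean norm is the movement amplitude.
The marginal median matches "median coordinates are calculated for each
cluster" most literally and is independent of point order. Clusters whose
membership falls below 20% of the initial count are flagged; a cluster
that vanishes produces flagged `NA` rows, not an exception.

A known limitation, visible in the tests: chained nearest-neighbour label
transfer on *continuous* surfaces (a stem, a long branch) lets cluster
boundaries drift a few millimetres per step, a random walk that can move a
cluster median by a centimetre over tens of scans even in a static scene.
On compact, well-separated structures — foliage clusters at branch tips,
which is where movement is measured — the effect is negligible, and the
amplitude of an imposed motion is recovered to millimetres. Quantitative
claims should therefore be based on clusters that cover an isolated
structure, and flagged rows should be excluded.

# The scene simulator

`build_scene()` expands parametric trees — a vertical stem cylinder,
thin branch cylinders, porous foliage discs at branch tips — into a
primitive set fully determined by (specification, seed). `scan_scene()`
casts rays on the scanner's angular grid with per-primitive candidate
selection by angular bounding box (long cylinders are subdivided so a
diagonal branch does not claim a whole rectangle of rays): stems, branches
and walls are opaque and terminate the ray; a foliage disc registers an
echo with probability $\min(1, d \cdot s^2)$ — where $d$ is the foliage
density (points per m² of leaf surface) and $s$ the beam spacing at that
range — and always lets the ray continue, so pulses through a crown yield
multiple returns with increasing return numbers, capped at the scanner's
maximum. The linear thinning keeps an expected echo count proportional to
$d$, which is what makes the sprout factor exactly recoverable from count
ratios. Gaussian range noise (default 3 mm, the scanner's nominal distance
precision) perturbs echoes along their rays; reflectance and deviation are
drawn per material class. Every scan carries a ground-truth sidecar
(primitive, material, tree, true range, applied displacement), sufficient
to score displacement, radius and densification recovery without any
external reference.

What the simulator does *not* model: beam-divergence footprint mixing
(0.27 mrad at the real instrument), partial-hit waveform effects,
radiometric calibration, wind-induced mechanical motion, understory, and
terrain. Passing tests demonstrate algorithmic correctness against
generative truth under these idealisations, not instrument-level fidelity.

Three auxiliary generators serve specific analyses:

* `sample_scene_points()` samples primitive surfaces directly
  (Poisson counts, uniform on each surface) when only positions matter;
  `simulate_scan_sequence()` then re-observes those *same* base points
  with fresh per-scan measurement noise and the motion law — the "same
  target, resampled noise" regime of a fixed scanner, which is what makes
  a sub-5 mm static noise floor meaningful.
* `sample_cylinder_slab()` generates stem-surface points on a visibility
  arc (half-visible by default, as a tower-mounted scanner sees a stem)
  with radial surface noise and optional gross outliers, for cylinder-fit
  validation.
* `synth_weather()` builds per-minute records in which each hour block is
  calm with a set probability, with a mild diurnal wind cycle, strictly
  sub-3 m/s winds in calm blocks and gusts or rain otherwise — so gate
  pass rates are binomially controlled.

The sinusoidal displacement law (default 5 cm amplitude, 24 h period,
applied to branches and foliage) emulates the few-centimetre overnight
branch movements the station observes; 30-minute scan cadences over 60
scans reproduce the published monitoring segment.

# Fixed parameters and their defaults

| Parameter | Default | Origin |
|---|---|---|
| angular step α | 0.006° | station configuration |
| scan window | 87° × 151° | station configuration |
| max range | 138 m | station configuration |
| scan duration | 21 min | station configuration |
| range noise sd (simulator) | 3 mm | instrument distance precision |
| isolated-point filter | ≥ 3 neighbours in 5 cm | short-term pipeline |
| subsampling spacing | 5 mm | short-term pipeline |
| wind gate | max < 3 m/s | long-term selection criterion |
| precipitation gate | = 0 mm | long-term selection criterion |
| voxel edge | 0.10 m | crown change analysis |
| slab band | 1.3 ± 0.30 m | DBH segmentation |
| RANSAC inlier tolerance | 1 cm | fit robustness at 3 mm noise |
| RANSAC iterations | 2000 | consensus stability at n ≈ 10³ |
| cluster minimum size | 100 points | tracking pipeline |
| cluster max diameter | 0.15 m | tracking pipeline |

# Numerical choices and problem sizes

Randomness is always confined to an explicit seed argument; functions save
and restore the global RNG state so a seeded call is reproducible and does
not disturb the caller. Pixel binning uses `floor()` on half-open
intervals; degenerate inputs fail with named errors (zero-norm points
report their index, undersized slabs report their count, a cylinder
consensus below 30% reports the fraction). Ties in the near-half median
split are kept on the near side within $10^{-9}$ m.

The test suite runs on deliberately modest problem sizes — 10⁴-point
round-trip checks, 10³-point brute-force filter oracles, slabs of 2–3
thousand points, tracking sequences of 10–60 scans with a few thousand
points each, simulated scans of a few tens of thousands of points at
coarsened angular steps (0.03–0.05°) over auto-fitted windows. These sizes
exercise every code path while keeping the full suite under a minute; all
algorithms are linear or near-linear in point count (the neighbourhood
queries use a grid-hash index in compiled code), and the same code
processes full-resolution scans unchanged.
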