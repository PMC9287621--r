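---
title: "The arcuate model: fitting fiber-bundle trajectories to RNFL defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The arcuate model: fitting fiber-bundle trajectories to RNFL defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcuatefit)
```

## The model

Retinal ganglion cell axons travel to the optic nerve head (ONH) in bundles
whose curved paths determine the arc shape of glaucomatous defects on OCT
retinal nerve fiber layer (RNFL) probability maps. `arcuatefit` models one
bundle path in polar coordinates about the ONH as

$$\varphi(\varphi_0, r) = \varphi_0 + b(\varphi_0)\,(r - r_0)^{c(\varphi_0)},$$

where $r$ is the radius from the ONH center (degrees of visual angle),
$\varphi$ the angle about it (0 along the nasal horizontal ray pointing away
from the fovea, counterclockwise positive), and $\varphi_0$ the initial angle
at the starting radius $r_0$. The auxiliary functions, with separate superior
($60^\circ \le \varphi_0 \le 180^\circ$) and inferior
($-180^\circ < \varphi_0 \le -60^\circ$) forms, are

$$c_{Sup} = 1.9 + 1.4\tanh\{(\varphi_0-121)/14\},\qquad
  c_{Inf} = 1.0 + 0.5\tanh\{(-\varphi_0-90)/25\},$$
$$b_{Sup} = \exp(\beta_{Sup} + 3.9\tanh\{-(\varphi_0-121)/14\}),\qquad
  b_{Inf} = -\exp(\beta_{Inf} + 1.5\tanh\{-(-\varphi_0-90)/25\}).$$

$c$ locates the curvature along the path and $b$ sets its amount; the free
parameter $\beta$ rescales the curvature, with empirical ranges
$\beta_{Sup} \in [-2.5, -1.3]$ (population mean $-1.90$) and
$\beta_{Inf} \in [0.1, 1.3]$ (mean $0.70$). $b_{Sup} > 0$ and $b_{Inf} < 0$
always, so superior trajectories bend counterclockwise and inferior ones
clockwise, both toward the temporal raphe. Nasal starting angles
($-60^\circ < \varphi_0 < 60^\circ$) are traced as straight radial rays
perpendicular to the circle scan; the full nasal extension of the original
model is out of scope here.

Anchoring to an eye's scan uses five adaptations of the original
formulation:

1. trajectories are computed in a model frame with the fovea at the origin
   and the ONH at the assumed eccentricity $(15^\circ, 2^\circ)$, then
   re-centered on the eye's recorded Bruch's membrane opening (BMO) center;
2. the starting radius is the eye's circle-scan radius, $r_0 = r_c$
   (plain polar coordinates about the ONH; the circle scan and model ONH
   coincide after re-centering);
3. trajectories are rotated about the fovea by the *relative* fovea--disc
   (FD) angle, recorded minus assumed ($-7.59^\circ$), absorbing head tilt
   and cyclotorsion;
4. the horizontal line through the fovea -- rotated by the same relative FD
   angle -- terminates every trajectory: on the temporal side of the fovea
   it is the anatomical raphe, on the nasal side the FD line. Crossings are
   located by linear interpolation between radial samples;
5. nasal bundles are approximated by radial rays (above).

Left eyes are mirrored across the vertical axis into a common right-eye
frame, with the FD angle negated; all analysis happens in that frame.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `beta` | $-1.90$ / $0.70$ | -- | curvature scale per hemifield (grid-searched) |
| `r_c` | 6 | deg | circle-scan radius (3.5 mm diameter at $\approx$ 0.291 mm/deg) |
| `r_step` | 0.05 | deg | radial sampling step, sub-pixel at 0.25 deg/px rasters |
| `r_max` | 34 | deg | field cutoff; the far corner of a macula-centered 30 x 25 deg field lies about 33 deg from the ONH, so a smaller cutoff would truncate defects inside the field |
| `bin_width` | 0.25 | deg | radial quantization for border building and RMS matching |
| `phi0_step` | 0.25 | deg | grid spacing of the initial-angle search |

The 11-point $\beta$ grids span the empirical ranges end to end
(superior $-1.3, -1.42, \ldots, -2.5$; inferior $1.3, 1.18, \ldots, 0.1$).
Inferior initial angles are computed internally in $(-180, -60]$ as the
equations require and reported externally in $(180, 300]$, so the combined
search range reads 60--300 degrees; the search never includes nasal starts.

## Border extraction

A probability map is binarized at the $\le 1\%$ category (everything else,
including $\le 5\%$-only pixels, becomes background). The arcuate component
is then isolated: 8-connected labeling, with defect fragments separated only
by the scan-field boundary treated as one component (an arcuate that leaves
and re-enters the 30 x 25 degree field is one defect, not several). Without
a seed point the largest component whose angular extent about the BMO center
exceeds 20 degrees is kept; a seed point -- the automated analogue of a
clinician clicking the defect -- overrides that choice. The perimeter is the
set of component pixels with a 4-neighbor background pixel.

Perimeter pixels become border points by a local geometric rule rather than
per-bin angular extremes: for each perimeter pixel the offsets to its
8-neighbors inside the component are summed as a radial part and an angular
arc part. A predominantly angular interior offset marks a true angular
boundary (interior at larger $\varphi$: lower border; at smaller $\varphi$:
upper border), while a predominantly radial one marks the circle-scan arc or
a radial end cap, which are not bundle borders and are dropped. Pixels on or
adjacent to the field boundary are likewise dropped: there the defect is cut
off by the field of view. Finally, each point is refined by half a pixel
along the outward boundary normal, because the outermost defect pixel center
sits on average half a pixel inside the true boundary; this removes the
systematic inward bias of pixel-center borders, which is on the order of
$\arctan(\text{px}/2r) \approx 1^\circ$ near the circle scan and would
otherwise masquerade as curvature. Per-bin extreme selection was tried first
and discarded: bins crossed by a single oblique border curve produce false
"two-sided" splits, and discarding one-sided bins wastes much of a
field-clipped border.

## Fitting

The fit statistic between a border and a trajectory quantizes both by radius
(bins of `bin_width` about the BMO center), averages the angular positions
per bin on the hemifield's unwrapped branch (superior $[0, 360)$, inferior
$(-360, 0]$ -- the branch cut lies on the nasal horizontal, which no arcuate
reaches), and takes the root mean square of the per-bin differences over
bins present in both. Bins beyond the trajectory's raphe/FD clipping are
unmatched and excluded; the matched fraction is reported as `coverage`, and
fits with coverage below 0.5 are flagged. Plain angular means rather than
circular means are deliberate: on an unwrapped branch they are equivalent in
practice and keep the grid scan exactly equal to a brute-force tabulation
(see below). The difference metric is angular (degrees at matched radius)
rather than chord distance, which would overweight peripheral bins by a
factor $r$.

For each grid $\beta$, the best initial angle minimizes this RMS over an
exhaustive $0.25^\circ$ scan of the hemifield range, ties breaking toward
the smaller angle. The scan evaluates $\varphi(\varphi_0, r)$ analytically
on the same radial sampling grid, bin definition and clipping rule as the
traced trajectories, so it is exactly the brute-force loop, only vectorized;
the equivalence is asserted in the test suite. The 11 per-$\beta$ RMS values
of one arcuate are normalized to z-scores (sample SD) and mapped to
percentiles through the standard normal CDF (if the SD is zero all
percentiles are 50); percentile normalization makes arcuates of different
sizes comparable before cohort summaries. One arcuate contributes one curve:
its two borders are fitted separately per $\beta$ and pooled as the RMS over
all matched bins of both. Cohort summaries report the 2.5th, 50th and 97.5th
empirical percentiles (linear-interpolation quantiles) of the normalized
values per $\beta$.

## From fits to the cpRNFL profile

The two best-fit initial angles bound the defect on the circle scan. They
map to the TSNIT axis by $t = (180 - \varphi) \bmod 360$ (temporal 0,
superior 90, nasal 180, inferior 270) and to clock hours by the analogous
12-hour mapping (superior 12, nasal 3 in the right-eye frame). The
trajectory-determined region is the arc between the two bounds inside the
arcuate's hemifield; the complementary arc through the opposite hemifield is
anatomically meaningless. Per-position normative thickness is modeled as
Gaussian with supplied mean and SD (vendor normative databases are not
distributable), classifying positions below the 1% and 5% quantiles; the
headline statistic is the fraction of region positions at or below each
level, with positions weighted equally (an angular measure, not rendered
plot area).

## The synthetic generator

`simulation_spec()` / `generate_arcuate_pmap()` rasterize the region between
two model trajectories (from the circle scan outward, bounded by the
raphe/FD line) as the $\le 1\%$ category on a 121 x 101 raster
(0.25 deg/px over 30 x 25 degrees, macula-centered, ONH at the nasal edge),
with an optional $\le 5\%$ halo. Noise is controlled and seeded: Gaussian
angular jitter applied to the border curves per radial bin, and independent
pixel flips. Matching cpRNFL profiles use a smooth double-hump normative
mean ($72 + 38\sin^2 t$ um, constant SD 10 um, 0.5 deg spacing), with
thickness depressed below the 1% line over a designed fraction of the
trajectory-determined region. All randomness flows from the recorded seed,
and left-eye fixtures are exact mirrors of their right-eye counterparts.

What the generator emulates: geometry, category structure, field clipping
(defects genuinely leave the 30 x 25 degree field, fragment, and re-enter,
as on real scans), and controlled localization noise. What it does not:
OCT speckle, vessel shadows, segmentation failures, artifact arcuates of
healthy eyes, or between-eye anatomical variability in the true bundle
paths. Passing recovery tests therefore demonstrates the correctness of the
implementation under the model's own assumptions, not clinical performance.

## Numerical choices and degenerate inputs

* Angles are stored wrapped to $(-180, 180]$; computations unwrap onto
  hemifield branches. Radial bins are indexed by `floor(r / bin_width)`;
  borders are binned by their stored radii so that floating-point round
  trips cannot shift a point across a bin edge.
* Clipping treats a sample exactly on the fovea-latitude line as crossed;
  a trajectory whose polyline would be empty after clipping raises a
  classed `degenerate_trajectory` condition. Similar classed conditions
  mark absent arcuates (`no_arcuate`), unusable perimeters
  (`degenerate_border`), radially disjoint comparisons (`no_overlap`),
  failed scans (`fit_failure`) and zero-length regions
  (`degenerate_region`), so callers and the command line can distinguish
  scientific failure modes from programming errors.
* $\beta$ outside the printed empirical range is rejected unless explicitly
  overridden (`allow_beta_outside`).
* The clock-hour wrap is implemented as $12 - ((-x) \bmod 12)$, which maps
  onto $(0, 12]$ for all inputs; the naive $((x-1) \bmod 12) + 1$ fails for
  fractional hours below 1.

## Problem sizes in the test suite

The recovery experiments run at sizes chosen to exercise every stage while
staying desk-scale: a 5 x 5 design of grid $\beta$ times on-grid
$\varphi_0$ pairs (width 30 degrees, noise-free) for exact recovery, a
20-arcuate superior cohort with 0.5-degree border jitter for the cohort
percentile summary, and 6-eye cohorts for the cpRNFL fraction statistic.
The published clinical cohort (31 eyes) is not distributable, so its group
values are not reproduced here; the synthetic experiments stand in for them
with known ground truth.

## Known limitations

* The original formulation's "modified polar coordinate system" is not
  reproduced; plain polar coordinates about the assumed ONH center are used
  throughout (with $r_0 = r_c$). Bit-level replication of the original
  trajectories would require the original coordinate definition.
* Single-pixel-wide defects are rejected as degenerate rather than fitted.
* Artifact arcuates (as seen in a few percent of healthy eyes) are not
  discriminated from glaucomatous ones; extraction is purely geometric.
* The raphe is modeled as exactly horizontal through the fovea; real raphe
  angles vary between eyes.
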