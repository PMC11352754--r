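---
title: "Methods: simulating selection, photo-crosslinking and sorting of uniform spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating selection, photo-crosslinking and sorting of uniform spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidfab)
```

## The problem this package models

Automated spheroid-production platforms image a biofabrication chamber in
two channels — darkfield, which shows every object (tumour spheroids and
debris alike), and fluorescence, where a Calcein stain marks only viable
spheroids. Software then picks which spheroids to encapsulate in gelatine
discs by selective 405 nm photo-crosslinking; the resulting
gelatine-encapsulated spheroids (GESs) are sorted by size in a two-stage
microfluidic slot array, verified one by one at a fluorescence point
detector, and dispensed into a 96-well plate for drug screening.

`spheroidfab` implements that computational chain end to end as testable
software: segmentation and morphometry, the selection-filter cascade,
photomask generation, and digital twins of the sorter, detector and
dispenser. No public chamber-image datasets exist, so the package also ships
a seeded synthetic generator with exact ground truth; every claim the test
suite makes is checked against that truth.

## Coordinate and intensity conventions

Physical coordinates are micrometres with the origin at the chamber's
top-left corner, x to the right and y down. Images are numeric matrices
(row = y, column = x); the pixel in row *r*, column *c* is centred at
((c − 0.5)·p, (r − 0.5)·p) for pixel size *p* µm/px. Intensities are
arbitrary units on a 16-bit scale; images are written as 16-bit TIFF.

## The synthetic chamber generator

Objects are drawn as radial cosine perturbations of a disc,

$$ r(\theta) = R\,\Big(1 + a \sum_{k=4}^{8} w_k \cos(k\theta + \phi_k)\Big),
   \qquad \textstyle\sum_k w_k = 1 , $$

a star-shaped outline that is always one connected component. The harmonic
weights and phases are drawn per object from its seed; the amplitude $a$ is
*calibrated by bisection against the package's own circularity estimator*
so that the rendered shape measures within 0.05 of the requested
circularity (inner bisection tolerance 0.015), and the radius is
renormalised once so the measured equivalent diameter lands within 5% of
the requested one. Harmonics start at $k = 4$ because lower frequencies
cannot reach circularity 0.5 within an amplitude that keeps outlines inside
the collision margins used for placement; the amplitude is capped at 0.55
inside chambers (bounding each outline by 1.55 R) and 0.75 for standalone
shapes. A target that remains unreachable after bisection — e.g.
circularity 0.3 for an object only 4 px across — raises an explicit
calibration error; when the chamber renderer meets such a truth value (tiny
debris) it renders the closest achievable shape instead, since debris
morphology is irrelevant downstream.

Populations are placed by rejection sampling with centres at least
1.7·(r₁ + r₂) apart and equally clear of the walls, so perturbed outlines
can never touch; saturation after 10,000 attempts is an error suggesting a
larger chamber. The darkfield channel renders every object at the
foreground level, the fluorescence channel only viable objects, and both
receive additive Gaussian noise (default σ = 2% of the dynamic range —
the simplest model that exercises threshold robustness; there is no point
spread function, scatter physics or vignetting, so passing tests say
nothing about optical artefacts in real data).

Detector traces are a noisy baseline plus one Gaussian spike per arrival;
`spike_width` is the FWHM, and arrivals closer than one FWHM are rejected
as overlapping. Trace duration defaults to the last arrival plus one
second.

## Detection and morphometry

Segmentation is deliberately plain: Otsu's threshold on the darkfield
channel (or a fixed threshold), connected-component labelling, optional
hole filling, and an area floor (default 100 µm²) — all via EBImage.
Touching objects are not split; crowded regions are rejected later by the
proximity filter, which is where the platform's logic actually handles
them. Two degenerate cases return zero labels with a warning instead of
failing: a constant image, and an image where the Otsu threshold marks more
than 25% of pixels as foreground. The latter guard matters because Otsu on
a pure-noise (empty-chamber) image splits the noise distribution itself,
and at that density binary noise percolates into huge spurious components;
real darkfield chambers are sparse, so a >25% foreground fraction reliably
signals "nothing there".

Per object the package reports centroid, area (pixel count · p²),
perimeter, equivalent-circle diameter $2\sqrt{A/\pi}$, circularity
$4\pi A / P^2$ clipped at 1, and mean fluorescence inside the darkfield
mask (the viability readout; the fluorescence channel is never
re-segmented). The perimeter comes from a sub-pixel marching-squares
contour: the binary mask is smoothed with a σ = 1 px Gaussian and contoured
at 0.5. Raw mid-crack contours of digital discs bias circularity to
~0.87–0.90; the smoothed contour measures 0.99–1.03 across radii 5–200 px,
which is why the estimator needs only a clip at 1.0 rather than a
radius-dependent correction. Equivalent diameter (not Feret) was chosen
because it is stable under boundary noise and makes the size and area
windows of the cascade mutually consistent.

## The selection cascade

Filters run in a fixed order — viability gate, spheroid filter, proximity
filter, overlap filter, boundary filter — and each rejected object carries
exactly one reason code, the first criterion it failed, so rejection tables
always total to the detected count. Thresholds (all overridable):

| parameter | default | meaning |
|---|---|---|
| `fluor_threshold` | 5000 a.u. | viability gate on mean Calcein signal (≥ passes); midway between rendered background and fluorescence levels |
| `diameter_min/max` | 200 / 215 µm | accepted equivalent-diameter window, the platform's published output band |
| `area_min/max` | disc-equivalents of the diameter window | kept separately configurable for instruments measuring area independently |
| `circularity_min` | 0.8 | morphology floor |
| `ges_footprint_diameter` | 550 µm | gel disc each selection will occupy; centre of the sorter's 400–700 µm collection band |
| `min_edge_gap` | 50 µm | minimum gap between neighbouring gel discs |
| `boundary_margin` | footprint/2 + 50 µm | clearance from chamber walls |

The proximity filter rejects a candidate if *any* other detected object —
including non-viable debris — would sit inside its gel footprint
(centre distance < footprint/2 + the other object's radius): a stray
fragment crosslinked into a disc is as undesirable as a second spheroid.
The overlap filter then de-conflicts the candidates themselves: two
conflict when their centres are closer than footprint + gap, and survivors
are chosen greedily by quality (circularity, then diameter, then id). A
maximum-independent-set formulation would keep at most a handful more
candidates at NP-hard cost and unpredictable tie behaviour, and was
rejected.

One property worth stating precisely: tightening a per-object threshold
can never enlarge any individual filter's pass set, and the suite verifies
this stage by stage. The *final* selected set, however, is not monotone —
removing a high-quality candidate from the greedy ordering can free two of
its conflict neighbours, so a tighter morphology floor can occasionally
select *more* spheroids. The end-to-end guarantee the suite asserts is the
true weakening: a tightened configuration never selects an object that the
baseline configuration had rejected for viability, size/area/morphology,
or proximity. Directly assertable on any result, regardless of
configuration: selected centres are pairwise ≥ footprint + gap apart and
≥ margin from every wall.

## Fabrication

The photomask is one disc of `spot_diameter` per selected coordinate on
the chamber raster; the cascade's pairwise guarantee keeps spots disjoint
whenever the spot does not exceed the footprint. Power density (3 mW/cm²),
exposure time (75 s) and wavelength (405 nm) are carried as metadata into
every downstream record — photochemistry is explicitly not modelled, and
the crosslinked disc size produced by a given dose is unknown, so
`spot_diameter` is a free parameter. Gel diameters are drawn
Normal(spot, cv·spot) truncated at ±3σ with cv defaulting to 0.05, a
plausible spread for a projection-defined feature; nothing in the model
couples gel size to exposure.

## Sorter, detector and dispenser twins

Routing is a step function of effective diameter: below d1 (400 µm) to
retention region 1, between d1 and d2 (700 µm) to collection, above d2 to
waste. Both gate values route *inclusive to collection*: the published
description ("between 400 and 700") is ambiguous at the endpoints, and
inclusive-collect is the convention documented and tested here. Slot
machining tolerance (±50 µm) is metadata; all physical imperfection is
modelled as Gaussian noise on the effective diameter (`measurement_sigma`,
default 10 µm in the pipeline). With ≥50 µm margins between population and
gates that noise level leaves ≥5σ of headroom, which is what makes the
≥97% routing-accuracy figure a Gaussian-tail certainty rather than a tuned
outcome; accuracy reaches 1.0 exactly as σ → 0.

Spike calling estimates baseline and noise scale by median/MAD (robust to
the spikes themselves), takes strictly-upward crossings of
baseline + k·σ (k = 5 by default), and suppresses crossings within a
refractory dead time (default 2× the spike FWHM in the module, 0.5 s in
the pipeline) — the physical detector halts flow after each GES, so one
passage must yield one event. Strict crossings make a perfectly flat trace
(MAD = 0) yield zero events. Dispensing fills wells row-major from A1 at
one GES per well (the screening density); overflow beyond 96·per_well is
an error reporting the excess.

## Dose–response analysis

The four-parameter logistic model
$v(c) = \text{bottom} + (\text{top} - \text{bottom}) / (1 + (c/\text{IC}_{50})^{h})$
is fitted by unweighted least squares on log10 concentration with
Levenberg–Marquardt (minpack.lm), replicates entering pointwise.
Initialisation takes top/bottom from the extremes of the dose-averaged
response, IC50 from the dose nearest the midpoint, and h = 1 — a robust
default for monotone screens. Data whose dose-averaged response is flat
(range below 10⁻³ of scale) raise a "no dose effect" error; optimizer
failures return a result flagged `converged = FALSE`. Fitting on the log
axis makes the scale equivariance exact: multiplying all concentrations by
s multiplies the fitted IC50 by s. `fold_change()` reports the IC50 ratio
and its nearest integer fold for model-to-model comparisons.

```{r dose-example}
truth <- fourpl(bottom = 0, top = 100, ic50 = 0.71, hill = 1)
dat <- simulate_dose_response(truth, n_replicates = 3, noise_frac = 0.05,
                              seed = 8)
fit_fourpl(dat)
fold_change(0.83, 0.17)
```

## Problem sizes and numerical choices

The package's own study conditions, used by the tests and the acceptance
script:

* Sorter twin: 1,000 objects (600 in-band 450–650 µm, 300 undersize
  50–350 µm, 100 oversize 750–900 µm), σ = 10 µm.
* Selection uniformity: 200 spheroids, diameters uniform 100–300 µm,
  circularities uniform 0.5–1.0, 80% viable, rendered into the full
  250 mm² chamber window (15.8 × 15.8 mm) at 4 µm/px. A desk-scale 4 mm
  chamber cannot hold 200 non-colliding spheroids of that size, and at
  higher densities the proximity filter empties the candidate set — the
  full window is the realistic geometry for a 200-object load, and the
  default cascade then selects roughly 3–10 spheroids per run.
* Morphology characterisation: 500 standalone shapes at 207 µm, 2 µm/px.
* Demo pipeline: 80 spheroids + 30% debris in a 6 × 6 mm window at
  3 µm/px.
* Dose–response recovery: 200 simulated screens, 8-dose 10-fold dilution
  from 1 mM, 3 replicates, 5% noise.

Determinism: every stochastic operation takes a seed and restores the
caller's RNG state; a pipeline's global seed spawns per-stage sub-seeds so
stages can be re-run independently yet reproduce the full run bit for bit.
Tie-breaks in the overlap filter (quality, then diameter, then id) are
total, so selection is deterministic for any input.

## Known limitations

The generator emulates geometry, intensity levels and additive noise — not
optics. Real darkfield images have halos, uneven illumination and focus
gradients; real Calcein signal is graded rather than binary; real
spheroids touch, which this package handles by rejection rather than
declumping. The sorter twin abstracts all hydrodynamics into one noise
parameter, so its accuracy figure measures the gate logic under stated
noise, not chip physics. The 4PL module fits single curves; multi-group
inference beyond the fold change is out of scope.
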