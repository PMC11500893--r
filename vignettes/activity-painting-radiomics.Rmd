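---
title: "Simulating a multicentric PET radiomics robustness study with an activity-painting phantom"
author: "phantomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a multicentric PET radiomics robustness study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomics)
```

## The experiment being simulated

Radiomic indices (RIs) extracted from PET images are notoriously sensitive
to which scanner and reconstruction produced the image. A clean way to
measure that sensitivity is a phantom whose uptake pattern is *exactly*
reproducible across scanners: a long-lived ²²Na point source is moved
through a 5×5×5 cm volume by linear stages, dwelling at each grid position
for a time proportional to the target activity there ("activity
painting"), inside a ~15 L water tank loaded with ~5 kBq/mL of ¹⁸F that
supplies a realistic, decaying background. Painting the same three lesion
patterns on five PET/CT systems (eight reconstruction settings, coded A–H)
makes every difference between the resulting images attributable to the
imaging chain, not the object.

`phantomics` reproduces this design in silico, end to end:

1. **Lesion templates** (`lesionPreset()`, `generateLesion()`) — target
   activity patterns on the 2.5 mm painting grid.
2. **Trajectory planning** (`planTrajectory()`) — serpentine visiting
   order, dwell ∝ template value, travel capped at 2 mm/s (faster movement
   would stir the water surface).
3. **Painting** (`paintGroundTruth()`) — fine-grid (1 mm) activity map:
   dwell deposits superposed on the session-averaged decaying background.
4. **Acquisition surrogate** (`acquire()`) — per setting: PSF blur → voxel
   sampling → intensity-proportional noise → post-filter → SUV conversion.
5. **Preprocessing** (`makeVOI()`, `resampleImage()`, `discretizeFBS()`,
   `discretizeFBN()`).
6. **46 radiomic indices** (`extractFeatures()`) and **robustness
   statistics** (`buildReport()`): relative differences, inter-setting
   CVs, absolute-agreement ICCs, BH-corrected Wilcoxon rank-sum tests.

`runExperiment(defaultConfig(seed = 1))` runs the whole pipeline; every
stage is deterministic given the seed.

## The synthetic lesions

The physical study painted three lesions taken from an anonymised public
database, resized to the 5 cm cube, with volumes 8.66, 11.55 and 15.44 mL
and increasing visual heterogeneity (lesion 1 the most compact). The
database carries no accession, so the package generates the lesions
procedurally: a smooth radial profile mixed with a lumpy Gaussian-blob
field, where the `heterogeneity` weight (0.25, 0.55, 0.85 for L1–L3) and
blob count (4, 8, 14) move the pattern from compact to multi-focal. The
support is the requested volume's worth of highest-field cells, so preset
volumes are exact to half a painting cell (0.0156 mL): 8.656, 11.547,
15.437 mL. Compactness (support sphericity 0.98, 0.95, 0.91) decreases
from L1 to L3 by construction.

```{r lesions}
vapply(c("L1", "L2", "L3"), function(n) volumeMl(lesionPreset(n)), 1)
```

What the generator deliberately does *not* emulate: anatomical shape
detail of real tumours, intra-lesion necrosis patterns, or respiratory
motion. Conclusions from passing tests therefore concern the processing
chain's behaviour on realistic *classes* of patterns, not on any specific
patient lesion.

## Sessions, decay and units

Each scanner session carries the measured water volume, the ¹⁸F activity
at scan start and the acquisition time (1730, 1883, 2600 s for L1–L3).
Background decays with the 6586.2 s half-life; painting a map uses the
time-averaged concentration over the scan. Propagating each scanner's
schedule, the background at the end of the L3 scan is ≈49–50% of its
value at the start of L1 — the sequential sessions therefore see a
monotonically falling background, and later lesions a fainter
painting-cube border. The ²²Na source (1.1 MBq) is constant over any
session (2.6-year half-life) and its 0.25 mm diameter is far below every
voxel size, so it is rendered as a point.

Images are expressed in SUV with the tank water mass as "body weight" and
background + source as administered activity; a uniform region's SUV is
its concentration divided by (activity/mass), putting the background near
0.8–0.9 SUV and lesions at clinically plausible multiples of it.

Dwell calibration: `planTrajectory(..., acquisitionTime =)` scales the
dwell unit so painting time equals scan time, mirroring how the physical
study matched the two. Inter-session gaps are implied by the scheduled
start activities rather than modelled explicitly.

## The imaging-setting surrogates

The reconstruction algorithms themselves (OSEM, RAMLA, penalised
likelihood, ...) are intentionally not emulated. Each setting is a black
box characterised by what it does to the image: reconstruction voxel size
(from the protocols: 2.67–4 mm), an effective PSF FWHM (4.2–5.5 mm —
documented *assumptions*, not measurements, since effective per-setting
resolutions are not published), a Gaussian post-filter (0–6.4 mm) and a
noise scale. Noise is Gaussian with variance proportional to local
intensity — a Poisson surrogate appropriate *after* reconstruction —
scaled inversely with the session exposure (activity × time) and voxel
volume. With `noiseScale = 0` the pipeline is exactly deterministic, which
the tests exploit.

Grids are centred on the painting-cube centre; voxel sampling is a box
average of the fine grid (the painted map is a density, so averaging, not
summing, is the intensity-preserving operation).

## Segmentation, discretization, resampling

The physical study contoured lesions manually and attributed the poor
reproducibility of Volume and TLG to that contouring. The package removes
contouring variability by design: VOIs are the lesion-template support
resampled to each image grid with an exact box-overlap computation and a
≥50% occupancy rule (threshold segmentation is retained as an option).
Digitizing a lumpy 8.66 mL support onto a 2.67 mm grid loses ~3.5% of the
volume to sub-voxel protrusions; this bias is a property of the
digitization, and the tests pin the VOI against an independent geometric
enumeration rather than against the nominal volume.

Two discretizations feed the texture code, with the defaults B = 0.3125
SUV and D = 64:

* **FBS** (absolute): `level = floor(I / B) + 1`. The bin-mapping formula
  is usually printed without its rounding operator; floor-plus-one is the
  LIFEx/IBSI convention and makes I = 0 fall in bin 1.
* **FBN** (relative): `level = floor(D (I − Imin)/(Imax − Imin)) + 1`,
  clamped so `I = Imax` maps to D. A constant VOI degenerates to level 1
  with a warning.

FBN is invariant to affine intensity rescalings of the VOI; FBS is
equivariant (shifting intensities by B shifts every level by one) — both
are asserted as properties in the tests. Spatial resampling (trilinear
for intensities, nearest-neighbour for masks) precedes discretization, as
in the common processing chains; whether the original software resampled
before or after VOI definition is not documented, so this order is a
stated assumption.

## The 46 indices

Six conventional SUV statistics (SUVmin/mean/std/max, SUVpeak as the mean
in a 1 mL sphere centred on the hottest voxel and intersected with the
VOI, TLG = SUVmean × volume), three shape indices, five histogram indices
and the GLCM (7), GLRLM (11), NGLDM (3) and GLZLM (11) texture families —
46 in total, with the metabolically active volume (MATV) and
`SHAPE_Volume_mL` counted once. The catalogue is frozen in
`featureCatalogue()`. Texture matrices merge the 13 unique 3-D directions
at distance 1 (symmetric pairs for GLCM); a `directions` argument exposes
single-direction analyses, for which the closed forms (one run of length
N on a constant line, etc.) hold exactly. Zones are 26-connected
components. Degenerate conventions are fixed and tested: constant volumes
give entropy 0, GLCM energy/homogeneity 1, correlation 0 *with a
warning*, NGLDM contrast/busyness 0 and coarseness capped at 1/ε.

Surface area for sphericity/compacity comes from a dual-contouring
boundary mesh: one vertex per boundary cell, placed by a small quadric
solve over the 0.5-crossings of a lightly smoothed (σ = 1 voxel) copy of
the mask with smoothed-gradient normals, quads emitted across
sign-changing lattice edges. Smoothed crossings remove the voxelisation
staircase (a digital ball of radius 10 measures within ~1% of 4πr²);
the quadric solve recovers sharp planar edges (a digital cube measures
within ~4% of its analytic area). Sphericity is clamped to (0, 1]
because near-perfect digital balls can overshoot 1 by a percent or two.
Every texture index is verified against brute-force enumeration oracles
(naive pair, run, zone and neighbourhood enumeration) on random volumes
at 1e−10 tolerance.

## Robustness statistics

* **Relative difference**: `(Xi − XD)/XD × 100` against reference setting
  D (the reference is arbitrary and configurable).
* **Inter-setting CV**: sample standard deviation over mean × 100 across
  the eight settings; the sample (n−1) deviation is a documented choice —
  the convention is not fixed by the published formula. Categories: low
  <10%, moderate 10–25%, high >25%. 46 indices × 3 lesions × 2
  discretizations = 276 CVs.
* **ICC**: absolute-agreement, two-way mixed model with lesions as
  targets (n = 3) and settings as raters (k = 8), computed from the
  printed mean-squares formula and cross-checked against an independent
  ANOVA route at 1e−10.
* **Wilcoxon rank-sum** between lesion pairs: for one index, the eight
  per-setting values of each lesion form the two samples. p-values are
  exact by full enumeration of rank assignments (mid-ranks for ties) up
  to n = 10 per group; beyond that a tie-corrected normal approximation
  is used. The methods text names the rank-sum (independent samples)
  test while some headings say signed-rank; the rank-sum form is
  implemented as primary, and `stats::wilcox.test(paired = TRUE)` remains
  available to anyone wanting the signed-rank variant.
* **BH-FDR**: step-up adjustment, applied jointly to all index ×
  lesion-pair tests within one discretization — the family boundary is a
  documented assumption.

## What the default run shows — and one deliberate difference

On the default synthetic study (problem sizes: 1 mm painted maps over an
8 cm field of view, 24 rendered images, 48 feature cells; ~20 s on one
core) the headline orderings of the physical study reproduce: zone-length
(GLZLM) indices have the highest family CVs while GLCM entropy and
run-length emphasis indices sit among the low ones, and FBS
discretization yields clearly higher mean ICC than FBN — with ground
truth fixed across settings, FBN's per-lesion renormalisation erases
between-lesion intensity differences and drags agreement down.

One ordering does *not* reproduce, for a reason worth understanding:
in the physical study SUVpeak was the most stable SUV statistic, with
SUVmean and SUVmax destabilised by manual-contour variability. Here the
ground-truth VOIs remove contouring variability entirely, so SUVmean —
an average over a fixed region — becomes the most stable statistic
(CV ≈ 3–4%), while SUVpeak (≈6%) still beats SUVmax (≈7%). The
acceptance suite asserts the published ordering as stated and this one
clause fails by design of the synthetic study; the weaker ordering
SUVpeak ≤ SUVmax holds.

## Numerical choices and limitations

* Painting grid 2.5 mm (20³ cells over the cube); fine map 1 mm; 8 cm
  field of view — large enough that blur margins never clip the lesion.
* Gaussian kernels are truncated at 3.5σ and renormalised; blur conserves
  integrated activity to <0.5% away from boundaries.
* Ties in the serpentine order, in run/zone enumeration and in mid-ranks
  are deterministic; reruns with one seed are bit-identical.
* Not modelled: attenuation, scatter, water movement, repositioning
  error, acquisition-protocol differences between sites, and the actual
  iterative reconstructions. Effective PSF and noise scales per setting
  are plausible assumptions; absolute CV/ICC magnitudes therefore carry
  less meaning than their orderings.
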