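---
title: "Methods: models, estimators and design choices in nucleomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in nucleomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

nucleomech quantifies how the mechanical state of the nucleus changes when
cells respond to substrate stiffness or to perturbation of
mechanotransduction signalling. It implements seven measurement pipelines
that are usually scattered across ad hoc microscope-side scripts --
particle-tracking microrheology, spectral FRET tension readout,
FLIM chromatin compaction, nuclear-envelope morphometry, nuclear polarity
mapping, scalar per-cell quantifications, and 2D motility -- plus a
synthetic-data generator that provides ground truth for every one of them.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, so a maintainer can tell deliberate
choices from accidents.

## Particle-tracking microrheology

Thermal motion of sub-micron beads embedded in the cytoplasm reports on the
local viscoelastic environment. The pipeline is detection, linking, MSD.

**Detection.** Beads are segmented by a global Otsu threshold per frame
(parameter-free and reproducible; an absolute threshold is available) and
each 8-connected above-threshold region is reduced to its intensity-weighted
centroid, giving subpixel positions. The `min_mass` floor rejects
single-pixel noise. A flat or saturated frame yields an empty detection set
with a warning rather than an error, so one bad frame does not kill a movie.

**Linking.** The proximity principle: the closest positions in successive
frames belong to the same particle. We implement it as *mutual*
nearest-neighbour matching per consecutive frame pair, with links longer
than `max_disp` forbidden, unmatched detections starting new tracks, and no
gap closing (a particle that blinks away and returns gets a new identity).
Greedy mutual matching rather than global optimal assignment is a
deliberate choice: it is exactly the stated principle, is deterministic
(distance ties resolve to the lower index), and its failure mode --
fragmentation under crowding -- is visible rather than silent. The default
`max_disp` is 5x the median frame step when not set explicitly.

**MSD.** For a track sampled uniformly at interval dt, the time-averaged
mean squared displacement at lag tau = k dt is

    MSD(tau) = < [x(t) - x(t - tau)]^2 + [y(t) - y(t - tau)]^2 >_t

averaged over all overlapping start times. Lags are limited to 25% of the
track length by default because the number of independent displacement
pairs collapses at long lags and the estimator variance explodes.
`compute_msd_ensemble` pools displacement pairs across particles (each pair
weighted equally); both per-track and pooled curves are reported because
conventions differ between labs. For free 2D diffusion MSD(tau) = 4 D tau;
`fit_diffusivity` fits an ordinary least-squares line and reports the
intercept separately, since static localisation noise adds a constant
4 sigma_loc^2 that should not be folded into D. A negative fitted D is
reported as-is with a warning: it is informative (sub-resolution motion),
not an error.

## Spectral FRET tension index

The nuclear-envelope tension sensor is a truncated Nesprin-1 with an
orientation-based FRET pair (cpCerulean donor, ~480 nm; cpVenus acceptor,
~530 nm). Emission is acquired every 10 nm from 460 to 600 nm (15
channels). The readout is the *inverted FRET index*: donor peak over
acceptor peak. More tension extends the sensor, transfer drops, donor
emission recovers -- higher index means higher tension.

The "peak" is the maximum sampled channel within a +/-10 nm window around
the nominal band centre, not a fitted band maximum: the acquisition grid is
10 nm, and curve fitting would introduce model choices (band shape,
baseline) that the measurement definition does not contain. Background is
the per-channel mean of a user-designated cell-free region, subtracted and
clamped at zero. Mean spectra are ratioed per region
(spectrum-then-ratio); a per-pixel mode (ratio each pixel, average the
indices) is available behind a flag because it was genuinely unclear which
the original macros used -- on uniform regions the two agree exactly.
Nuclear-envelope regions are *inputs* (label masks); automatic NE
segmentation is out of scope.

The index is invariant under multiplication of the whole spectrum by a
positive scalar (illumination) and under any constant offset that the
background subtraction removes; both invariances are tested.

## FLIM chromatin compaction

Histone H2B carries a GFP donor and an mCherry acceptor; chromatin
compaction brings nucleosomes close enough for FRET, shortening the donor
lifetime. The readout is one "overall lifetime" per region: higher
lifetime, lower compaction.

Photon arrivals in a TCSPC window [0, T] are modelled as a
mono-exponential decay truncated to the window. The MLE solves

    mean(arrivals) = tau - T exp(-T/tau) / (1 - exp(-T/tau)),

whose right side is strictly increasing in tau with supremum T/2: a sample
mean at or above T/2 means no decay is resolvable inside the window and the
fit is refused (non-identifiable) rather than returned as a huge number.
The equation is solved monotonically to relative tolerance 1e-6. Bin
midpoints stand in for raw arrival tags because the interchange format is
a binned histogram; halving the bin width moves the estimate by < 0.5% at
10^5 photons (tested).

Design choices: mono-exponential with no instrument-response
deconvolution, because the readout is a single comparative lifetime and no
IRF is part of the assay definition; pool-then-fit within each region
("overall" lifetime, stable at low counts) rather than per-pixel fitting,
with a photon floor (default 100) below which a region is reported missing
instead of fitted badly.

## Nuclear-envelope morphometry (EOP)

The excess of perimeter is the total traced envelope length -- outer
contour plus internal invagination folds, as drawn by Lamin A/C staining --
divided by the perimeter of the convex envelope. A smooth convex nucleus
scores exactly 1; wrinkles and invaginations raise it. The package reports
the ratio itself (so convex = 1.0) and, as an extra column, the excess
(ratio - 1).

Two entry points exist because source data differ:

* **Polygon mode**: an outline polygon plus optional open polylines for
  internal folds. Each polyline's length counts once; an open slit whose
  two walls are both drawn belongs in the outline instead (the synthetic
  generator records both conventions in its ground truth).
* **Skeleton mode**: a binary NE-trace image plus the nucleus mask. The
  skeleton length is measured by 8-connected chain steps with calibrated
  weights (0.948 per orthogonal step, 1.340 per diagonal, diagonal
  shortcuts across an occupied corner pixel excluded). Raw 1/sqrt(2)
  counting overestimates digitised curve length by ~5% averaged over
  orientations, which would swamp the 3% recovery target; the calibrated
  weights bring smooth curves below 1%. The convex hull is taken from the
  nucleus-mask boundary pixels. A skeleton with no pixels near the mask
  boundary triggers a warning and the ring is approximated by the mask
  boundary.

EOP is invariant under rigid motion and uniform scaling and is
non-decreasing in internal fold length; both are tested, and polygon mode
is checked against an independent arc-length summation to 1e-12.

## Nuclear polarity maps and distribution tests

On line-patterned cells the front is defined by the Golgi (Giantin
staining): `orient_front` rotates each cell so the nucleus-centroid to
Golgi-centroid direction lies along +x, or uses an explicit pattern axis
with the Golgi choosing the sign. Per cell, the top 20% of in-mask signal
pixels are selected -- exactly ceiling(0.2 n) pixels, ties broken by
intensity then raster order, threshold per cell because the macro-style
definition is per image. Selected pixels map into a common frame: centroid
at the origin, per-axis half-extent scaling so the nucleus spans [-1,1]^2.
Half-extent scaling (not area normalisation) preserves the front/rear
split under nuclear elongation, which matters on line patterns. The map is
the mean across cells of the per-cell binarised occupancy grid, and the
normalised x-coordinates are pooled for testing.

**Front-vs-rear test.** The statistic is the two-sided Kolmogorov-Smirnov
distance between the pooled axis samples and their mirror image
(x -> -x). Two points deserve emphasis because they are easy to get
wrong:

1. The mirror sample is a deterministic transform of the data, so the
   usual two-sample KS null distribution does not apply -- using it
   rejects a true null about twice the nominal rate. Under a symmetric
   continuous null, sqrt(n) D converges to the supremum of |Brownian
   motion| on [0,1] (the mirror empirical process is a reflected Brownian
   motion, not a bridge).
2. The axis samples are not an iid draw: they are the top-quantile subset
   of each mask's pixels, i.e. a without-replacement sample of a fixed
   fraction (20%) of a finite population, which shrinks the empirical
   fluctuations by the classical finite-population factor, and they live
   on the pixel lattice, which makes any sup-distance test slightly
   conservative.

The default test for a `polarity_map` therefore does not use an asymptotic
formula at all: it resamples the null directly. Under spatially
unstructured intensities the selected pixels are a uniform k-subset of the
mask, so null copies of D are drawn by redrawing uniform subsets from the
per-cell pixel populations that the map retains, and the p-value is the
(mid-p) exceedance fraction. This is exact up to resampling error and
automatically accounts for the finite sampling fraction and the lattice
discreteness. The mid-p rule is used because D lives on a 1/n lattice and
plain exceedance counting would re-introduce tie conservatism. The
asymptotic reflected-BM p-value (with the finite-population correction) is
available as `null = "asymptotic"` and is the default for plain numeric
input, where no selection structure is known. Calibration of the full
pipeline at the null is itself part of the acceptance suite.

**Condition-vs-condition test.** Two-sample Cramér-von Mises per Anderson
(1962) on the pooled axis samples of two conditions, with the asymptotic
limiting distribution of the criterion (Bessel-K series). Here the two
samples are genuinely independent, so the textbook test applies; the
implementation was cross-checked against an independent reference
implementation (statistic exact, p to series accuracy).

## Scalar per-cell quantifications

* **Nuclear/cytoplasmic ratio** (YAP-style): mean background-subtracted
  intensity in the nucleus over the mean in cell-minus-nucleus. Background
  defaults to the median intensity outside the cell mask -- a robust choice
  made here because the original scripts are unpublished. A cytoplasm mean
  at or below zero after subtraction is an error, not a huge ratio.
* **Dots per area** (heterochromatin foci): local maxima above threshold,
  above-threshold pixels split between dots by nearest-marker assignment
  (a marker-based simplification of watershed, adequate for the separated
  foci this assay quantifies); density is summed background-subtracted dot
  intensity over the nuclear area in um^2, with the raw count alongside.
* **Focal adhesion count**: 8-connected components of above-threshold
  vinculin signal inside the cell mask with area >= 0.25 um^2 (inclusive
  at the boundary). Otsu within the mask by default; verified against a
  brute-force flood fill on binary fixtures.
* **Actin coherency**: structure tensor (Gaussian-smoothed outer product
  of gradients, scale 2 px by default), coherency = (l1 - l2)/(l1 + l2)
  averaged over mask pixels with non-zero trace. 1 for aligned filaments,
  0 for isotropic texture; rotation and intensity-scale invariant.
* **Spreading ratio**: area(t1)/area(t0) from masks; pure arithmetic.

One metric is deliberately absent: a stress-fibre ("actin number") count
appears in the source material without any stated definition, and guessing
one would manufacture a measurement; the omission is recorded rather than
papered over.

## Motility

Nuclei are detected per frame (nucleus-scale smoothing, then the same
centroid detection as for beads) and linked with the same
mutual-nearest-neighbour rule; the default acquisition grid is one frame
every 10 min for 18 h, and tracks shorter than 12 frames are dropped.
Per-cell metrics: mean speed = path length / elapsed time; path
persistence = net displacement / path length (the directionality ratio,
in [0,1] by the triangle inequality, defined as 0 for a zero-length
path). "Persistence" is ambiguous in the literature, so the mean cosine
between consecutive step directions is reported as an alternative column
rather than silently substituted. `rose_plot_data` recentres every
trajectory at the origin for overlay plots.

## Synthetic data: what it emulates, what it does not

Every generator reproduces the acquisition *regime* of its assay --
500-frame bead movies at 100 fps, 15-channel spectral stacks on the
460-600 nm grid with ~480/~530 nm bands, truncated-exponential TCSPC
decays, elliptical nuclei with radial slit invaginations rasterised at
0.1 um/px, polarised nuclei with a Golgi marker on the front side,
four-channel cell images (nucleus / YAP-like / vinculin blobs / actin
texture), and persistent random walks sampled every 10 min for 18 h
(109 samples). Parameters the assays leave implicit (true D, true
lifetime, band width, noise levels) are defaults chosen once at realistic
values and recorded in each fixture's ground-truth record, which is
sufficient to regenerate the fixture bit-identically from its seed.

Deliberate simplifications, so a green test is read correctly: no
photobleaching or blinking, no 3D PSF, no camera gain/offset model, no
instrument response function in the decays, emission bands truncated at
+/-3 sigma (which keeps the donor and acceptor windows free of cross-talk
and makes the noiseless index *exactly* the amplitude ratio -- real
fluorophores have overlapping tails and real indices are cross-talk
biased), nuclei that are ellipses rather than segmented real shapes, and a
persistent random walk as the motion model (chosen because it has a
tunable true persistence; no claim is made that real cells follow it).
Parameter-recovery tests therefore establish correctness of the
estimators, not robustness to every artefact of real microscopy.

## Numerical and interface choices

* Coordinates are 0-based pixel indices, x = column, y = row; subpixel
  positions are continuous in the same frame; physical units enter only
  through `pixel_size_um`. 8-connectivity everywhere.
* TIFF (uncompressed baseline, greyscale 8/16-bit, multi-page) is the
  only image dialect; the reader/writer is deliberately minimal and
  rejects anything else loudly. Metadata comes from a sidecar key-value
  file or explicit arguments, arguments winning on conflict.
* All randomness flows from one per-invocation seed recorded in output
  metadata; identical config + seed gives byte-identical CSV output,
  which the acceptance suite enforces for every CLI subcommand. The
  resampling p-value in `front_rear_test` derives its internal seed
  deterministically from the data, preserving that guarantee.
* The truncated-exponential solver brackets the root monotonically and
  refuses non-identifiable inputs; the CvM limiting CDF truncates its
  Bessel-K series at k = 10, far past double-precision relevance for
  p-values above 1e-12.

## Known limitations

No gap closing or merge/split handling in tracking; no spectral unmixing
or sensor force calibration (the index is comparative); no IRF
deconvolution or multi-exponential decays; no automatic NE/nucleus/cell
segmentation (masks are inputs); polarity maps operate on the projected
plane, not 3D stacks; the motility tracker terminates parent tracks at
division rather than building lineages.
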