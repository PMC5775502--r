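---
title: "Quantifying RyR signaling nanodomains from DNA-PAINT localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RyR signaling nanodomains from DNA-PAINT localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopaint)
library(dplyr)
```

## The problem

Cardiac ryanodine receptors (RyR2) cluster in nanometer-scale signaling
domains at junctions between the surface membrane and the sarcoplasmic
reticulum. How many channels a cluster holds, how far apart they sit, and
which accessory proteins (here junctophilin-2, JPH2) co-cluster with them
all shape calcium release. DNA-PAINT localization microscopy resolves
individual labeled proteins as punctate localization densities and, through
qPAINT, counts molecules from binding-event kinetics rather than from
fluorophore photophysics.

`nanopaint` implements the full quantitative chain downstream of single
molecule localization: density rendering, event-density cluster
segmentation, punctum detection, nearest-neighbor (NND) and
average-4-neighbor (4ND) distance statistics, Euclidean distance (gap)
maps, qPAINT counting with in-situ quantal calibration, and exchange-PAINT
co-clustering analyses. Because raw microscope data of this kind are rarely
shareable, the package also ships the synthetic-data generator that the
analyses are validated against: every stage can be exercised in a
parameter-recovery experiment where the ground truth is known.

All tables are tibbles in canonical units - nm for distances, seconds for
times, 0-based integer frames - so stages chain with the pipe.

## The cluster self-assembly model

Clusters are grown site by site. Each new site is placed in a uniformly
random direction at a step distance drawn from Normal(40 nm, 7.4 nm),
subject to a 30 nm hard-core exclusion approximating the RyR tetramer
footprint. Cluster sizes follow a ceiling-rounded exponential law with mean
8.8, truncated at 40 RyRs.

Two aspects of the growth rule are genuinely open and are exposed as
parameters:

* **Which site anchors the next placement.** The default is the last
  placed site; `anchor = "uniform"` picks any already-placed site.
* **Whether the drawn step is the nearest-neighbor spacing.** With the
  default `nearest_spacing = TRUE`, a placement is accepted only when the
  anchor is the nearest existing site, so the Gaussian step law is the law
  of the new site's nearest-neighbor distance - the quantity whose
  distribution is actually measured from data.

These defaults were chosen because they jointly reproduce the measured
summary statistics of real peripheral RyR clusters - a pooled NND mean near
40 nm and a pooled 4ND mean near 59 nm for clusters with at least five
sites - while producing irregular cluster shapes with emergent gaps.
Uniform-anchor growth without the nearest-spacing constraint yields more
compact clusters whose 4ND is several nanometers shorter; purely sequential
growth without the constraint yields chain-like shapes. A placement that
cannot satisfy the constraints within `max_placement_retries` raises an
`infeasible-geometry` error; ensemble generators regrow such clusters with
fresh draws (about 1% of clusters at default parameters).

```{r assembly}
sites <- simulate_field(40, assembly_params(), seed = 1)
mean(nearest_neighbor_distances(sites)$nnd_nm)
mean(four_neighbor_distances(sites)$fournd_nm)
```

## The binding-kinetics simulator

Each detected docking site runs an alternating renewal process: dark times
are exponential with mean `1 / site_binding_rate`, bright times exponential
with mean `mean_bright_time`. The on-rate constant and imager concentration
enter only through their product, so they are collapsed into the single
per-site rate. Discretization to camera frames uses a half-frame rule: a
frame is bright when a bright interval overlaps at least half of it, and
every bright frame yields exactly one localization at the site position
plus isotropic Gaussian noise (`loc_precision_sigma`, default 5 nm, fixed
per run; photon counts are Poisson metadata). Two consequences of this
convention matter downstream and are accounted for explicitly:

* **Sub-frame events can vanish.** A bright interval shorter than half a
  frame (or unluckily split across a frame boundary) emits no localization.
  The visible fraction is the same for every site, so it cancels wherever a
  calibration is taken from the same data - but absolute single-site rates
  read low by that fraction (about 6% at the default bright time of 2.5
  frames).
* **Dark times below the merging window are unobservable.** Event
  reconstruction merges localizations separated by up to `max_frame_gap`
  missing frames, so dark times shorter than
  `(max_frame_gap + 1) * frame_time` never appear.

Detection of incomplete labeling is modeled separately:
`apply_detection_fraction()` flags each site observable with a fixed
probability, and only detected sites emit events. Background (unbound
imager) localizations are not simulated.

## Rendering and segmentation

`render_density()` converts events into a raster whose pixel intensity is
linearly proportional to local marker density. The default method sums
unit-mass Gaussian kernels (sigma per event from its localization
precision), so the raster integral equals the event count exactly; a
jittered Delaunay triangulation renderer (intensity inversely proportional
to triangle area, averaged over `n_passes = 10` jitter passes) is provided
as an alternative. Rasters default to 1 nm pixels and are written as 16-bit
TIFF with the intensity scale recorded in a JSON sidecar.

`segment_clusters()` thresholds the raster at a local event density and
labels 8-connected components; components supported by fewer than
`min_events = 10` localizations are discarded as debris. No watershed
splitting is attempted: touching super-threshold regions count as one
cluster. The threshold is the one genuinely free parameter. When none is
given, a scale-free default of 5% of the 99.9th-percentile intensity is
used; areas are reported as pixel counts times pixel area. For
segmentation (as opposed to punctum detection) a wider rendering kernel is
useful so that a cluster forms one connected region rather than one blob
per punctum - the pipeline default renders the segmentation raster with
`sigma = 12` nm at 2 nm pixels.

## Puncta and distance statistics

`detect_puncta()` smooths the member events of each cluster with a 7 nm
Gaussian, takes local maxima above 10% of the cluster maximum with
non-maximum suppression within 20 nm, assigns each localization to its
nearest surviving maximum, and reports event-mean centroids for candidates
supported by at least 10 localizations. These defaults resolve a simulated
30 nm square lattice at 5 nm localization precision into at least 90% of
its sites, the package's resolvability benchmark; they are deliberately
conservative for sparser arrangements.

Distance statistics are computed on punctum centroids only, per cluster:
`nearest_neighbor_distances()` (clusters with at least `min_cluster_size`
puncta; default 5, matching the headline statistics, with 2 as the
inclusive variant) and `four_neighbor_distances()` (at least 5, so four
neighbors exist). Reported distributions use 5 nm bins over 0-200 nm.
`gap_map()` evaluates the exact Euclidean distance from every in-mask pixel
center to the nearest centroid - no distance-transform approximation - and
reports connected regions beyond a 100 nm threshold as intra-cluster gaps.

A caveat established by the detection-fraction sweep
(`detection_fraction_experiment()`): subsampling sites to 60% detection
right-shifts the *mean* NND by 15-20% because a deleted nearest neighbor is
replaced by the next order statistic, while the 40-nm *mode* of the NND
histogram is unaffected and the 4ND mean grows much faster. Mean-based NND
comparisons across detection efficiencies should therefore be read with
care; the mode is the robust location summary.

## qPAINT counting

Within a segmented region, localizations are merged into binding events
(`merge_binding_events()`): consecutive-frame localizations within
`max_jump = 20` nm of the running event position are one event, with up to
`max_frame_gap = 2` missing frames tolerated; simultaneous events at
distinct positions are kept apart. Dark times are the positive gaps between
consecutive events.

`estimate_mean_dark_time()` fits the exponential CDF to the empirical
dark-time CDF by least squares (the cumulative-histogram method). The fit
accounts for the left truncation of the merging window: observable dark
times are distributed as `t0 + Exp(tau)` with
`t0 = (max_frame_gap + 1) * frame_time` by memorylessness, and the model
fitted is `1 - exp(-(t - t0)/tau)`. The correction is negligible for
sparse regions and removes a saturation bias in dense ones. The plain
sample mean is always reported alongside as a cross-check.

The qPAINT index of a region is the inverse mean dark time, proportional to
the number of docking sites. `qpaint_indices()` offers two estimators: the
CDF fit (default, faithful to the histogram method) and a binding-event
*rate* estimator, `(n_events - 1)` over the time spanned by the event
starts. The two agree for sparse regions; in dense regions the rate
estimator is exactly proportional to the site count even in the presence of
sub-frame event losses and bright-time occupancy, because the observed
event stream is a superposition of identically thinned per-site processes.
The counting recovery experiment therefore uses the rate estimator.

`calibrate_quantal_unit()` estimates the single-molecule index unit from
the smallest clusters (selected by `select_calibration_clusters()` on area
and punctum count): a Gaussian kernel density with Silverman's bandwidth is
computed over their indices, the first mode with at least 10% relative
prominence is the unit (refined as the mean of first-peak indices), and
higher modes must sit within 25% of integer multiples of the unit or a
calibration warning is attached. Counts are `index / unit`, raw and
rounded. The time base of the unit (per second, via `frame_time`) is
carried in the objects rather than assumed: printed index values are
meaningful only together with their acquisition parameters.

`density_regression()` regresses count on cluster area through the origin
(a zero-area cluster holds zero molecules; the free-intercept fit is
reported alongside) and converts the slope to a mean linear packing
distance `1/sqrt(slope)`. The recovery experiment
(`qpaint_recovery_experiment()`) simulates regions of 1-48 sites plus 100
single-site calibration regions with roughly 600 binding events per site,
giving a counting standard error of about `sqrt(N/600)` molecules at site
count `N`; at that precision the calibrated, rounded counts reproduce the
true site number for well over 90% of regions and the index-versus-N
regression has R^2 above 0.99.

```{r qpaint-example}
fit <- density_regression(c(10000, 25000, 60000), 0.00032 * c(10000, 25000, 60000))
glance(fit)
```

## Exchange-PAINT co-clustering

`match_puncta()` pairs puncta across imaging rounds greedily in increasing
distance order under a cutoff, each punctum used once - deterministic and,
at realistic punctum densities, identical to exhaustive optimal assignment
(verified in the test suite against a dynamic-programming oracle on
instances up to 12 puncta). Median displacement and the fractions
reproduced within 5 and 10 nm quantify round-to-round reproducibility.
Exchange rounds are assumed drift-corrected into one frame upstream;
`register_puncta()` offers a rigid-translation refinement for synthetic
tests.

`radial_density()` bins the junction mask pixels by their exact Euclidean
distance to the nearest RyR centroid and divides marker counts by the
measured per-bin pixel areas - bin areas come from the discrete distance
field, not ideal annuli, avoiding truncation bias at mask borders (10 nm
bins by default). A uniform-random control with the same number of events
over the same mask is always computed alongside. With the default
two-population JPH2 generator (80% of markers within 20 nm of an RyR, the
rest uniform over a junction three times the cluster hull area), the
density within 50 nm of RyR centroids exceeds the density beyond by well
over five-fold.

`molecular_ratio()` applies the RyR cluster masks to both channels,
computes per-channel calibrated qPAINT counts, and reports
`r_J_R = N_J / N_R` for clusters with more than 15 RyRs. The ratio is JPH2
per RyR. Because the sparse JPH2 pool extends beyond the RyR mask, the
mask can be dilated (`dilate_nm`) to cover the junction; with an 80 nm
dilation the generator's ensemble ratio is recovered within a few percent.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale problem sizes
chosen so each statistic is estimated well inside its tolerance: 1,200
clusters (about 10,000 contributing sites) for the distance statistics;
150 clusters for the radial-density ensemble; site counts 1-48 with about
600 events per site for the counting recovery; 4x4 lattices for
resolvability. Ties in punctum detection are broken by intensity order;
degenerate inputs (empty tables, all-below-threshold rasters, clusters
below size floors) return empty results rather than errors wherever the
empty result is meaningful, and signal classed conditions otherwise.

## What the synthetic data do not emulate

The generator reproduces clustered geometry, first-order binding kinetics,
Gaussian localization noise, partial detection, and the two-population
JPH2 arrangement. It does not simulate raw camera frames or PSF fitting,
stage drift or focus error, unbound-imager background, day-to-day kinetic
drift between exchange rounds, 3D geometry (peripheral couplings are
treated as flat), or antibody labeling stoichiometry. Passing recovery
tests therefore validate the analysis chain given its stated input model,
not the upstream localization pipeline; on real data the absolute
calibration unit is dataset-specific and must come from the same
acquisition it is applied to.
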