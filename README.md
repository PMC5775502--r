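# nanopaint

Quantitative analysis of ryanodine-receptor (RyR) signaling nanodomains
from DNA-PAINT localization microscopy, in tidy R.

Cardiac RyR2 channels cluster in nanometer-scale release sites whose
geometry — channel number, spacing, gaps, and co-clustering with the
tether protein junctophilin-2 (JPH2) — governs calcium signaling.
DNA-PAINT resolves individual labeled proteins as punctate localization
densities, and qPAINT counts molecules from binding kinetics: under
first-order imager binding, the mean dark time τ_d between binding events
in a region is inversely proportional to its number of docking sites, so
the *qPAINT index* 1/τ_d, calibrated against the quantal index unit of
single-protein regions, yields absolute molecule counts.

`nanopaint` starts from localization event tables (x, y in nm, frame,
photons, precision, channel; CSV or HDF5) and provides:

- **Synthetic data** — a Monte Carlo cluster self-assembly model
  (Gaussian nearest-neighbor steps, mean 40 nm, σ 7.4 nm, 30-nm hard
  core; truncated-exponential cluster sizes, mean 8.8), a two-population
  JPH2 placement model, and an alternating-renewal binding-kinetics
  simulator that produces realistic event streams with known ground truth.
- **Rendering** — density rasters with intensity linearly proportional to
  local marker density (Gaussian kernels, or jittered Delaunay
  triangulation), written as 16-bit TIFF.
- **Segmentation** — event-density thresholding, 8-connected cluster
  regions, areas, overlap percentages.
- **Puncta** — single-protein punctum detection, per-punctum
  nearest-neighbor (NND) and average-4-neighbor (4ND) distances, exact
  Euclidean distance maps and >100-nm gap regions, detection-fraction
  sweeps.
- **qPAINT** — binding-event reconstruction, dark-time CDF fits, quantal
  calibration, molecule counts, and the cluster area-versus-count packing
  regression (slope → mean linear spacing via 1/√slope).
- **Exchange-PAINT co-clustering** — cross-round punctum matching (median
  displacement, % within 5/10 nm), JPH2 radial density versus distance to
  RyR centroids with a uniform-random control, and per-cluster JPH2:RyR
  molecular ratios.

Everything takes a data frame first and returns a tibble; fitted objects
have `tidy()`/`glance()` methods and result types have `autoplot()`
methods.

## Worked example

```r
library(nanopaint)
library(dplyr)

# simulate a field of RyR clusters and its DNA-PAINT event stream
sites  <- simulate_field(40, assembly_params(), seed = 7)
kin    <- kinetics_params(site_binding_rate = 0.01, n_frames = 30000)
events <- simulate_paint_events(filter(sites, detected), kin, seed = 8)

# render, segment, detect single-RyR puncta
raster   <- render_density(events, pixel_size = 2, sigma = 12)
clusters <- segment_clusters(raster, events)
clusters
#> <cluster_set> 40 clusters, 27939/27939 events assigned (threshold 0.01278)
puncta <- detect_puncta(clusters)

# distance statistics on punctum centroids
nnd <- nearest_neighbor_distances(puncta)
fnd <- four_neighbor_distances(puncta)
c(nnd_mean = mean(nnd$nnd_nm), fournd_mean = mean(fnd$fournd_nm))
#>    nnd_mean fournd_mean
#>    37.70854    56.61992

# qPAINT: per-cluster indices and the packing regression
est <- qpaint_indices(clusters, frame_time = kin$frame_time)
fit <- density_regression(tidy(clusters)$area_nm2, est$qpaint_index / 0.01)
glance(fit)
#> # A tibble: 1 × 4
#>   slope_per_1000nm2 spacing_nm r_squared     n
#>               <dbl>      <dbl>     <dbl> <int>
#> 1             0.348       53.6     0.992    40
```

The detected puncta recover the generator's spacing statistics (pooled NND
mean ≈ 37.7 nm, 4ND ≈ 56.6 nm), and the qPAINT counts scale linearly with
cluster area: ≈ 0.35 RyR per 1,000 nm², i.e. a mean linear spacing of
≈ 54 nm between channels — about a third of the density of a dense
crystalline lattice (31.5 nm lattice constant, 992 nm² per RyR).

An end-to-end driver with a YAML-configurable parameter set is available
as `run_pipeline(pipeline_config(...), out_dir)`; it writes ground truth,
localizations, raster, per-cluster/per-punctum tables and a JSON summary,
reproducibly from `(config, seed)`.

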