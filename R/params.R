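#' Parameters of the cluster self-assembly model
#'
#' RyR clusters are grown by a Monte Carlo self-assembly rule: starting from a
#' seed site, each new site is placed in a uniformly random direction at a
#' step distance drawn from `Normal(step_mean, step_sigma)` from an anchor
#' site, subject to a hard-core exclusion of `min_separation` between any two
#' site centers. With `nearest_spacing = TRUE` (the default) a placement is
#' additionally accepted only when the anchor is the nearest existing site,
#' so the drawn step is the new site's nearest-neighbor spacing.
#'
#' @param step_mean Mean nearest-neighbor step distance in nm (default 40).
#' @param step_sigma SD of the step distance in nm (default 7.4).
#' @param min_separation Hard-core exclusion distance between site centers in
#'   nm (default 30, roughly the RyR tetramer footprint).
#' @param max_placement_retries Resampling budget per site before the cluster
#'   geometry is declared infeasible.
#' @param size_mean Mean of the (approximately exponential) cluster-size law,
#'   in RyRs per cluster (default 8.8).
#' @param size_max Cap on RyRs per cluster (default 40).
#' @param detection_fraction Probability that a true site carries a functional
#'   marker and is observable.
#' @param anchor Which already-placed site anchors the next placement:
#'   `"last"` (default) or `"uniform"`.
#' @param nearest_spacing If `TRUE`, require the anchor to be the nearest
#'   existing site to the new placement.
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(step_mean = 40, step_sigma = 7.4,
                            min_separation = 30,
                            max_placement_retries = 1000L,
                            size_mean = 8.8, size_max = 40L,
                            detection_fraction = 1,
                            anchor = c("last", "uniform"),
                            nearest_spacing = TRUE) {
  anchor <- arg_match(anchor)
  assert_number(step_mean, "step_mean", strict_lower = TRUE, lower = 0)
  assert_number(step_sigma, "step_sigma", lower = 0)
  assert_number(min_separation, "min_separation", strict_lower = TRUE, lower = 0)
  if (min_separation >= step_mean) {
    abort("`min_separation` must be smaller than `step_mean`.")
  }
  assert_number(size_mean, "size_mean", strict_lower = TRUE, lower = 0)
  assert_number(size_max, "size_max", lower = 1)
  assert_number(detection_fraction, "detection_fraction", lower = 0, upper = 1)
  assert_number(max_placement_retries, "max_placement_retries", lower = 1)
  structure(list(
    step_mean = step_mean, step_sigma = step_sigma,
    min_separation = min_separation,
    max_placement_retries = as.integer(max_placement_retries),
    size_mean = size_mean, size_max = as.integer(size_max),
    detection_fraction = detection_fraction,
    anchor = anchor, nearest_spacing = isTRUE(nearest_spacing)
  ), class = "assembly_params")
}

#' Parameters of the DNA-PAINT binding-kinetics simulator
#'
#' Imager binding at each docking site is a first-order alternating renewal
#' process: dark intervals are exponential with mean
#' `1 / site_binding_rate`, bright intervals exponential with mean
#' `mean_bright_time`. The on-rate constant and imager concentration are
#' collapsed into the single per-site rate because only their product is
#' identifiable from localization data.
#'
#' @param site_binding_rate Binding events per second per docking site.
#' @param mean_bright_time Mean bright (bound) time in seconds.
#' @param frame_time Seconds per camera frame.
#' @param n_frames Number of acquired frames.
#' @param loc_precision_sigma Isotropic localization precision (sigma, nm).
#' @param photons_mean Mean photon count per localization (metadata only).
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(site_binding_rate = 0.005,
                            mean_bright_time = 0.25,
                            frame_time = 0.1,
                            n_frames = 40000L,
                            loc_precision_sigma = 5,
                            photons_mean = 1000) {
  assert_number(site_binding_rate, "site_binding_rate", strict_lower = TRUE, lower = 0)
  assert_number(mean_bright_time, "mean_bright_time", strict_lower = TRUE, lower = 0)
  assert_number(frame_time, "frame_time", strict_lower = TRUE, lower = 0)
  assert_number(n_frames, "n_frames", lower = 1)
  assert_number(loc_precision_sigma, "loc_precision_sigma", lower = 0)
  assert_number(photons_mean, "photons_mean", strict_lower = TRUE, lower = 0)
  structure(list(
    site_binding_rate = site_binding_rate,
    mean_bright_time = mean_bright_time,
    frame_time = frame_time,
    n_frames = as.integer(n_frames),
    loc_precision_sigma = loc_precision_sigma,
    photons_mean = photons_mean
  ), class = "kinetics_params")
}

#' Parameters of the two-population JPH2 placement model
#'
#' JPH2 markers are placed as two pools: a bound pool located within
#' `bound_radius` of randomly chosen RyR sites, and a sparse pool distributed
#' uniformly over a junction region obtained by scaling the convex hull of
#' the RyR sites to `sparse_region_scale` times the cluster hull area.
#'
#' @param ratio_mean Expected JPH2 per RyR per cluster (default 1.38).
#' @param bound_fraction Fraction of JPH2 in the bound pool (default 0.8).
#' @param bound_radius Radius in nm around an RyR within which a bound JPH2
#'   is placed uniformly (default 20).
#' @param sparse_region_scale Junction area as a multiple of the RyR cluster
#'   hull area (default 3).
#' @return An object of class `jph_params`.
#' @export
jph_params <- function(ratio_mean = 1.38, bound_fraction = 0.8,
                       bound_radius = 20, sparse_region_scale = 3) {
  assert_number(ratio_mean, "ratio_mean", strict_lower = TRUE, lower = 0)
  assert_number(bound_fraction, "bound_fraction", lower = 0, upper = 1)
  assert_number(bound_radius, "bound_radius", strict_lower = TRUE, lower = 0)
  assert_number(sparse_region_scale, "sparse_region_scale", lower = 1)
  structure(list(
    ratio_mean = ratio_mean, bound_fraction = bound_fraction,
    bound_radius = bound_radius, sparse_region_scale = sparse_region_scale
  ), class = "jph_params")
}

#' @export
print.assembly_params <- function(x, ...) {
  cat("<assembly_params>\n")
  cat(sprintf("  step: %g nm (sigma %g), hard core %g nm\n",
              x$step_mean, x$step_sigma, x$min_separation))
  cat(sprintf("  sizes: exponential mean %g, max %d; detection %g\n",
              x$size_mean, x$size_max, x$detection_fraction))
  cat(sprintf("  anchor: %s, nearest-spacing: %s\n", x$anchor, x$nearest_spacing))
  invisible(x)
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("<kinetics_params>\n")
  cat(sprintf("  binding rate %g /s/site, bright %g s\n",
              x$site_binding_rate, x$mean_bright_time))
  cat(sprintf("  %d frames x %g s, precision %g nm\n",
              x$n_frames, x$frame_time, x$loc_precision_sigma))
  invisible(x)
}

#' @export
print.jph_params <- function(x, ...) {
  cat("<jph_params>\n")
  cat(sprintf("  ratio %g JPH2/RyR; %g%% bound within %g nm; junction %gx hull\n",
              x$ratio_mean, 100 * x$bound_fraction, x$bound_radius,
              x$sparse_region_scale))
  invisible(x)
}
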