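# Detection of single-protein puncta inside clusters, and the point-pattern
# statistics computed on their centroids: NND, 4ND, Euclidean distance (gap)
# maps, and detection-fraction sweeps.

# Local maxima of a matrix: strictly greater than half the 8-neighborhood,
# at least equal to the other half (so flat two-pixel peaks yield one max).
local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) {
    pad <- matrix(-Inf, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- m
    m <- pad; nr <- nr + 2L; nc <- nc + 2L
    unpad <- TRUE
  } else unpad <- FALSE
  sh <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- (1L + max(0L, dr)):(nr + min(0L, dr))
    cs <- (1L + max(0L, dc)):(nc + min(0L, dc))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  ge <- m >= sh(1, 0) & m >= sh(0, 1) & m >= sh(1, 1) & m >= sh(1, -1)
  gt <- m > sh(-1, 0) & m > sh(0, -1) & m > sh(-1, -1) & m > sh(-1, 1)
  mx <- ge & gt
  if (unpad) mx <- mx[2:(nr - 1L), 2:(nc - 1L)]
  which(mx, arr.ind = TRUE)
}

# Greedy non-maximum suppression: keep peaks in decreasing intensity order,
# dropping any peak within `min_sep` of an already kept one.
suppress_peaks <- function(peaks_xy, intensity, min_sep) {
  ord <- order(intensity, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d2 <- (peaks_xy[kept, 1] - peaks_xy[i, 1])^2 +
          (peaks_xy[kept, 2] - peaks_xy[i, 2])^2
    if (min(d2) >= min_sep^2) kept <- c(kept, i)
  }
  sort(kept)
}

detect_puncta_region <- function(ev, cluster_id, smoothing_sigma,
                                 min_separation, rel_threshold,
                                 min_events, pixel_size) {
  empty <- tibble(
    cluster_id = integer(0), punctum_id = integer(0),
    x_nm = numeric(0), y_nm = numeric(0), n_events = integer(0)
  )
  if (nrow(ev) < min_events) return(empty)
  extent <- default_extent(ev, pixel_size, pad = 4 * smoothing_sigma)
  binned <- bin_events(ev$x_nm, ev$y_nm, extent, pixel_size)
  sm <- smooth_matrix(binned, smoothing_sigma / pixel_size)
  pk <- local_maxima(sm)
  if (!nrow(pk)) return(empty)
  inten <- sm[pk]
  keep <- inten >= rel_threshold * max(sm)
  pk <- pk[keep, , drop = FALSE]; inten <- inten[keep]
  if (!nrow(pk)) return(empty)
  px <- extent[1] + (pk[, 2] - 0.5) * pixel_size
  py <- extent[3] + (pk[, 1] - 0.5) * pixel_size
  sel <- suppress_peaks(cbind(px, py), inten, min_separation)
  cand <- cbind(px[sel], py[sel])
  # assign each event to its nearest candidate punctum
  d <- cross_dist(cbind(ev$x_nm, ev$y_nm), cand)
  assign <- max.col(-d, ties.method = "first")
  res <- tibble(
    cluster_id = cluster_id,
    punctum = assign
  ) %>%
    count(.data$cluster_id, .data$punctum, name = "n_events")
  cx <- tapply(ev$x_nm, assign, mean)
  cy <- tapply(ev$y_nm, assign, mean)
  res$x_nm <- as.numeric(cx[as.character(res$punctum)])
  res$y_nm <- as.numeric(cy[as.character(res$punctum)])
  res <- res %>% filter(.data$n_events >= min_events)
  if (!nrow(res)) return(empty)
  res %>%
    mutate(punctum_id = row_number()) %>%
    select("cluster_id", "punctum_id", "x_nm", "y_nm", "n_events")
}

#' Detect single-protein puncta
#'
#' Detects punctate labeling densities: the event density is smoothed with a
#' Gaussian of `smoothing_sigma`, local maxima exceeding `rel_threshold`
#' times the region maximum are kept with non-maximum suppression within
#' `min_separation`, each localization is assigned to its nearest candidate,
#' and each punctum's centroid is the mean of its assigned localizations.
#' Puncta supported by fewer than `min_events` localizations are dropped.
#'
#' @param x A `cluster_set` (puncta detected per cluster) or a localization
#'   tibble (treated as a single region).
#' @param smoothing_sigma Gaussian smoothing sigma in nm (default 7).
#' @param min_separation Minimum distance between punctum centers, nm
#'   (default 20).
#' @param rel_threshold Relative intensity floor for candidate maxima
#'   (default 0.1 of the region maximum).
#' @param min_events Minimum supporting localizations per punctum
#'   (default 10).
#' @param pixel_size Grid resolution of the internal smoothed density, nm.
#' @param ... Passed between methods.
#' @return Tibble of puncta: `cluster_id`, `punctum_id`, `x_nm`, `y_nm`,
#'   `n_events`.
#' @export
detect_puncta <- function(x, ...) UseMethod("detect_puncta")

#' @rdname detect_puncta
#' @export
detect_puncta.cluster_set <- function(x, smoothing_sigma = 7,
                                      min_separation = 20,
                                      rel_threshold = 0.1, min_events = 10,
                                      pixel_size = 1, ...) {
  ev <- x$events %>% filter(!is.na(.data$cluster_id))
  ev %>%
    group_by(.data$cluster_id) %>%
    dplyr::group_map(function(df, key) {
      detect_puncta_region(df, key$cluster_id, smoothing_sigma,
                           min_separation, rel_threshold, min_events,
                           pixel_size)
    }) %>%
    bind_rows()
}

#' @rdname detect_puncta
#' @export
detect_puncta.data.frame <- function(x, smoothing_sigma = 7,
                                     min_separation = 20,
                                     rel_threshold = 0.1, min_events = 10,
                                     pixel_size = 1, ...) {
  detect_puncta_region(x, 1L, smoothing_sigma, min_separation,
                       rel_threshold, min_events, pixel_size)
}

# k smallest distances from each point to the others, within one cluster.
knn_dists <- function(xy, k) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  t(apply(d, 1, function(r) sort(r)[seq_len(k)]))
}

#' Nearest-neighbor centroid distances within clusters
#'
#' For each punctum in a cluster with at least `min_cluster_size` puncta, the
#' Euclidean distance to its closest other punctum in the same cluster.
#'
#' @param puncta Tibble with `x_nm`, `y_nm`, `cluster_id` (puncta or
#'   ground-truth sites).
#' @param min_cluster_size Minimum puncta per cluster to contribute
#'   (default 5, matching the headline distance statistics; set 2 for the
#'   inclusive variant).
#' @return Tibble `cluster_id`, `x_nm`, `y_nm`, `nnd_nm`.
#' @export
nearest_neighbor_distances <- function(puncta, min_cluster_size = 5) {
  if (min_cluster_size < 2) abort("`min_cluster_size` must be >= 2.")
  puncta %>%
    group_by(.data$cluster_id) %>%
    filter(n() >= min_cluster_size) %>%
    mutate(nnd_nm = if (n() == 0) numeric(0) else {
      d <- as.matrix(dist(cbind(.data$x_nm, .data$y_nm)))
      diag(d) <- Inf
      as.numeric(apply(d, 1, min))
    }) %>%
    ungroup() %>%
    select("cluster_id", "x_nm", "y_nm", "nnd_nm")
}

#' Average distance to the four nearest neighbors
#'
#' For each punctum in a cluster with at least `min_cluster_size` puncta
#' (minimum 5, so four neighbors exist), the mean of its four smallest
#' center-to-center distances. This statistic is right-shifted relative to
#' the NND and is sensitive to missed detections.
#'
#' @inheritParams nearest_neighbor_distances
#' @return Tibble `cluster_id`, `x_nm`, `y_nm`, `fournd_nm`.
#' @export
four_neighbor_distances <- function(puncta, min_cluster_size = 5) {
  if (min_cluster_size < 5) abort("`min_cluster_size` must be >= 5.")
  puncta %>%
    group_by(.data$cluster_id) %>%
    filter(n() >= min_cluster_size) %>%
    mutate(fournd_nm = if (n() == 0) numeric(0) else {
      d <- as.matrix(dist(cbind(.data$x_nm, .data$y_nm)))
      diag(d) <- Inf
      as.numeric(apply(d, 1, function(r) mean(sort(r)[1:4])))
    }) %>%
    ungroup() %>%
    select("cluster_id", "x_nm", "y_nm", "fournd_nm")
}

# A raster-aligned logical mask with geometry metadata.
new_raster_mask <- function(mask, pixel_size, origin) {
  structure(list(mask = mask, pixel_size = pixel_size, origin = origin),
            class = "raster_mask")
}

#' Extract the pixel mask of one segmented cluster
#'
#' @param clusters A `cluster_set`.
#' @param cluster_id Which cluster.
#' @param crop Crop the mask to the cluster bounding box (default `TRUE`).
#' @param pad_px Padding in pixels around the cropped bounding box.
#' @return A `raster_mask` (logical matrix plus `pixel_size` and `origin`).
#' @export
cluster_mask <- function(clusters, cluster_id, crop = TRUE, pad_px = 2L) {
  stopifnot(inherits(clusters, "cluster_set"))
  m <- clusters$labels == cluster_id
  if (!any(m)) abort(sprintf("Cluster %s has no pixels.", format(cluster_id)))
  org <- clusters$raster$origin
  ps <- clusters$raster$pixel_size
  if (crop) {
    w <- which(m, arr.ind = TRUE)
    r0 <- max(1L, min(w[, 1]) - pad_px); r1 <- min(nrow(m), max(w[, 1]) + pad_px)
    c0 <- max(1L, min(w[, 2]) - pad_px); c1 <- min(ncol(m), max(w[, 2]) + pad_px)
    m <- m[r0:r1, c0:c1, drop = FALSE]
    org <- c(org[1] + (c0 - 1L) * ps, org[2] + (r0 - 1L) * ps)
  }
  new_raster_mask(m, ps, org)
}

#' Dilate a raster mask by a physical radius
#'
#' Morphological dilation with a disc brush, e.g. to extend an RyR cluster
#' mask over the surrounding junction region.
#'
#' @param mask A `raster_mask`.
#' @param radius_nm Dilation radius in nm.
#' @return The dilated `raster_mask` (same grid).
#' @export
dilate_mask <- function(mask, radius_nm) {
  stopifnot(inherits(mask, "raster_mask"))
  if (radius_nm <= 0) return(mask)
  size <- 2L * round(radius_nm / mask$pixel_size) + 1L
  m <- EBImage::dilate(mask$mask * 1, EBImage::makeBrush(size, "disc")) > 0
  new_raster_mask(matrix(m, nrow(mask$mask), ncol(mask$mask)),
                  mask$pixel_size, mask$origin)
}

#' Rasterize a polygon into a mask
#'
#' @param poly Two-column matrix of polygon vertices (nm).
#' @param pixel_size Pixel size in nm.
#' @param pad_nm Padding around the polygon bounding box.
#' @return A `raster_mask`.
#' @export
polygon_mask <- function(poly, pixel_size = 2, pad_nm = 2) {
  x0 <- floor((min(poly[, 1]) - pad_nm) / pixel_size) * pixel_size
  y0 <- floor((min(poly[, 2]) - pad_nm) / pixel_size) * pixel_size
  nc <- ceiling((max(poly[, 1]) + pad_nm - x0) / pixel_size)
  nr <- ceiling((max(poly[, 2]) + pad_nm - y0) / pixel_size)
  cx <- x0 + (seq_len(nc) - 0.5) * pixel_size
  cy <- y0 + (seq_len(nr) - 0.5) * pixel_size
  g <- expand.grid(y = cy, x = cx)
  m <- matrix(point_in_polygon(g$x, g$y, poly), nr, nc)
  new_raster_mask(m, pixel_size, c(x0, y0))
}

# Exact Euclidean distance from every mask pixel center to the nearest
# punctum centroid (continuous coordinates).
mask_distance_field <- function(mask, centroids) {
  w <- which(mask$mask, arr.ind = TRUE)
  px <- mask$origin[1] + (w[, 2] - 0.5) * mask$pixel_size
  py <- mask$origin[2] + (w[, 1] - 0.5) * mask$pixel_size
  dmin <- min_cross_dist(cbind(px, py), centroids)
  field <- matrix(NA_real_, nrow(mask$mask), ncol(mask$mask))
  field[w] <- dmin
  field
}

#' Euclidean distance map and gap regions of a cluster
#'
#' Computes the exact Euclidean distance from every pixel of the cluster mask
#' to the nearest punctum centroid, and reports the connected components
#' where the distance exceeds `gap_threshold` - the sub-nanodomain boundaries
#' (gaps) within the cluster.
#'
#' @param puncta Tibble of puncta (needs `x_nm`, `y_nm`); must be non-empty.
#' @param mask A `raster_mask` (e.g. from [cluster_mask()]).
#' @param gap_threshold Distance threshold in nm defining a gap (default 100).
#' @return A `gap_map` object: `distance_field` (`density_raster`-like, nm;
#'   `NA` outside the mask), `gap_regions` tibble (`gap_id`, `area_nm2`,
#'   `max_distance_nm`), and the threshold.
#' @export
gap_map <- function(puncta, mask, gap_threshold = 100) {
  stopifnot(inherits(mask, "raster_mask"))
  if (!nrow(puncta)) abort("`puncta` must contain at least one punctum.")
  field <- mask_distance_field(mask, cbind(puncta$x_nm, puncta$y_nm))
  gap <- !is.na(field) & field > gap_threshold
  lab <- if (any(gap)) label_components_8(gap) else
    matrix(0L, nrow(gap), ncol(gap))
  ids <- seq_len(max(lab))
  regions <- tibble(
    gap_id = ids,
    area_nm2 = tabulate(lab, nbins = length(ids)) * mask$pixel_size^2,
    max_distance_nm = map_dbl(ids, function(i) max(field[lab == i]))
  )
  structure(list(
    distance_field = new_density_raster(field, mask$pixel_size, mask$origin),
    gap_regions = regions, gap_threshold = gap_threshold
  ), class = "gap_map")
}

#' @export
print.gap_map <- function(x, ...) {
  cat(sprintf("<gap_map> %d gap region(s) beyond %g nm\n",
              nrow(x$gap_regions), x$gap_threshold))
  invisible(x)
}

#' Sensitivity of distance statistics to the detection fraction
#'
#' Simulates a field of clusters once, then subsamples the ground-truth sites
#' at each detection fraction and recomputes the NND and 4ND statistics on
#' detected sites only. Lower detection fractions leave the NND approximately
#' constant but right-shift the 4ND distribution.
#'
#' @param params An [assembly_params()] object.
#' @param fractions Detection fractions in `(0, 1]`.
#' @param n_clusters Number of simulated clusters.
#' @param seed Optional integer seed.
#' @param min_cluster_size Cluster-size floor for the distance statistics.
#' @return A `detection_sweep` object with `values` (per-site tibble:
#'   `fraction`, `cluster_id`, `nnd_nm`, `fournd_nm`) and `summary`
#'   (per-fraction means and counts).
#' @export
detection_fraction_experiment <- function(params = assembly_params(),
                                          fractions = c(1, 0.9, 0.6),
                                          n_clusters = 1000, seed = NULL,
                                          min_cluster_size = 5) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must lie in (0, 1].")
  }
  with_seed_if(seed, {
    base <- assembly_params(
      step_mean = params$step_mean, step_sigma = params$step_sigma,
      min_separation = params$min_separation,
      max_placement_retries = params$max_placement_retries,
      size_mean = params$size_mean, size_max = params$size_max,
      detection_fraction = 1, anchor = params$anchor,
      nearest_spacing = params$nearest_spacing
    )
    sites <- simulate_field(n_clusters, base)
    values <- map(fractions, function(f) {
      det <- if (f >= 1) sites else apply_detection_fraction(sites, f)
      det <- det %>% filter(.data$detected)
      nnd <- nearest_neighbor_distances(det, min_cluster_size)
      fnd <- four_neighbor_distances(det, max(5, min_cluster_size))
      tibble(
        fraction = f,
        nnd_nm = list(nnd$nnd_nm),
        fournd_nm = list(fnd$fournd_nm)
      )
    }) %>% bind_rows()
    summary <- values %>%
      mutate(
        mean_nnd_nm = map_dbl(.data$nnd_nm, mean),
        mean_fournd_nm = map_dbl(.data$fournd_nm, mean),
        n_nnd = map_int(.data$nnd_nm, length),
        n_fournd = map_int(.data$fournd_nm, length)
      ) %>%
      select("fraction", "mean_nnd_nm", "mean_fournd_nm", "n_nnd", "n_fournd")
    structure(list(values = values, summary = summary, sites = sites),
              class = "detection_sweep")
  })
}

#' @export
print.detection_sweep <- function(x, ...) {
  cat("<detection_sweep>\n")
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.detection_sweep <- function(object, binwidth = 5, ...) {
  df <- object$values %>%
    tidyr::pivot_longer(c("nnd_nm", "fournd_nm"),
                        names_to = "statistic", values_to = "value") %>%
    tidyr::unnest("value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value, fill = .data$statistic)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.5, boundary = 0) +
    ggplot2::facet_wrap(~fraction, ncol = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 200)) +
    ggplot2::labs(x = "distance (nm)", y = "count")
}
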