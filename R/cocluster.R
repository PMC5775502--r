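# Exchange-PAINT analyses: cross-round punctum matching, JPH2 radial density
# relative to RyR centroids with a uniform control, and per-cluster JPH2:RyR
# molecular ratios from calibrated qPAINT.

#' Match puncta between exchange rounds
#'
#' Greedy globally-closest-pair matching: all cross-set pairs within `cutoff`
#' are accepted in increasing distance order, each punctum used at most once.
#' Reports the median displacement and the fraction of matched puncta
#' reproduced within the given tolerances.
#'
#' @param set_a,set_b Punctum tibbles (`x_nm`, `y_nm`) in the same coordinate
#'   frame.
#' @param cutoff Maximum pairing distance in nm (default 50).
#' @param tolerances Displacement tolerances (nm) for the reproducibility
#'   fractions (default 5 and 10).
#' @return A `match_result`: `pairs` tibble (`idx_a`, `idx_b`,
#'   `displacement_nm`), `median_displacement_nm`, `fraction_within` (named),
#'   `n_a`, `n_b`.
#' @export
match_puncta <- function(set_a, set_b, cutoff = 50, tolerances = c(5, 10)) {
  if (!nrow(set_a) || !nrow(set_b)) {
    abort("Both punctum sets must be non-empty.",
          class = "nanopaint_empty_input")
  }
  d <- cross_dist(cbind(set_a$x_nm, set_a$y_nm),
                  cbind(set_b$x_nm, set_b$y_nm))
  cand <- which(d <= cutoff, arr.ind = TRUE)
  pairs <- tibble(idx_a = integer(0), idx_b = integer(0),
                  displacement_nm = numeric(0))
  if (nrow(cand)) {
    ord <- order(d[cand])
    cand <- cand[ord, , drop = FALSE]
    used_a <- logical(nrow(set_a)); used_b <- logical(nrow(set_b))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ia <- cand[i, 1]; ib <- cand[i, 2]
      if (!used_a[ia] && !used_b[ib]) {
        keep[i] <- TRUE
        used_a[ia] <- TRUE; used_b[ib] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    pairs <- tibble(
      idx_a = as.integer(cand[, 1]),
      idx_b = as.integer(cand[, 2]),
      displacement_nm = d[cand]
    )
  }
  frac <- vapply(tolerances, function(tol) {
    if (nrow(pairs)) mean(pairs$displacement_nm <= tol) else NA_real_
  }, numeric(1))
  structure(list(
    pairs = pairs,
    median_displacement_nm = if (nrow(pairs)) median(pairs$displacement_nm)
                             else NA_real_,
    fraction_within = setNames(frac, paste0(tolerances, "nm")),
    n_a = nrow(set_a), n_b = nrow(set_b), cutoff = cutoff
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs (of %d x %d), median displacement %.3g nm\n",
    nrow(x$pairs), x$n_a, x$n_b, x$median_displacement_nm
  ))
  fw <- x$fraction_within
  cat(sprintf("  within %s: %.1f%%\n", names(fw), 100 * fw), sep = "")
  invisible(x)
}

#' Rigid-translation registration of two punctum sets
#'
#' Estimates the translation aligning `set_b` onto `set_a` by matching under
#' a generous cutoff and iterating on the median displacement vector.
#'
#' @param set_a,set_b Punctum tibbles.
#' @param cutoff Search radius in nm (default 50).
#' @param iterations Refinement iterations (default 3).
#' @return List: `shift` (nm, to add to `set_b`), `set_b_registered`.
#' @export
register_puncta <- function(set_a, set_b, cutoff = 50, iterations = 3) {
  shift <- c(0, 0)
  b <- set_b
  for (i in seq_len(iterations)) {
    m <- match_puncta(set_a, b, cutoff = cutoff)
    if (!nrow(m$pairs)) break
    dx <- median(set_a$x_nm[m$pairs$idx_a] - b$x_nm[m$pairs$idx_b])
    dy <- median(set_a$y_nm[m$pairs$idx_a] - b$y_nm[m$pairs$idx_b])
    b$x_nm <- b$x_nm + dx; b$y_nm <- b$y_nm + dy
    shift <- shift + c(dx, dy)
    if (abs(dx) < 0.01 && abs(dy) < 0.01) break
  }
  list(shift = shift, set_b_registered = b)
}

# Bin mask pixels and marker events by distance to the nearest RyR centroid.
# Returns per-bin pixel areas and event counts.
radial_bins_one <- function(ryr_xy, jph_xy, mask, bin_width, max_bin) {
  field <- mask_distance_field(mask, ryr_xy)
  dpix <- field[!is.na(field)]
  brk <- seq(0, max_bin, by = bin_width)
  area <- tabulate(pmin(findInterval(dpix, brk, rightmost.closed = FALSE),
                        length(brk) - 1L),
                   nbins = length(brk) - 1L) * mask$pixel_size^2
  if (nrow(jph_xy)) {
    dev <- min_cross_dist(jph_xy, ryr_xy)
    # only events inside the mask are counted
    col <- floor((jph_xy[, 1] - mask$origin[1]) / mask$pixel_size) + 1L
    row <- floor((jph_xy[, 2] - mask$origin[2]) / mask$pixel_size) + 1L
    inside <- row >= 1 & row <= nrow(mask$mask) & col >= 1 & col <= ncol(mask$mask)
    inside[inside] <- mask$mask[cbind(row[inside], col[inside])]
    dev <- dev[inside]
    cnt <- tabulate(pmin(findInterval(dev, brk), length(brk) - 1L),
                    nbins = length(brk) - 1L)
  } else {
    cnt <- rep(0L, length(brk) - 1L)
  }
  list(area = area, count = cnt, n_inside = sum(cnt))
}

# Uniform placement of n points over the mask (pixel centers jittered
# uniformly within the pixel).
sample_in_mask <- function(n, mask) {
  w <- which(mask$mask, arr.ind = TRUE)
  pick <- w[sample.int(nrow(w), n, replace = TRUE), , drop = FALSE]
  cbind(
    mask$origin[1] + (pick[, 2] - 1L) * mask$pixel_size +
      runif(n, 0, mask$pixel_size),
    mask$origin[2] + (pick[, 1] - 1L) * mask$pixel_size +
      runif(n, 0, mask$pixel_size)
  )
}

#' Radial density of one marker relative to RyR punctum centroids
#'
#' Computes the Euclidean distance field from the RyR centroids over the
#' junction mask, bins mask pixels by distance (bin areas come from the
#' discrete distance field, avoiding annulus-truncation bias at mask
#' borders), and reports the density of marker events per bin together with a
#' uniform-random control profile built by placing the same number of events
#' uniformly over the mask.
#'
#' @param ryr_puncta Tibble of RyR punctum centroids (`x_nm`, `y_nm`,
#'   optionally `cluster_id`).
#' @param jph_events Tibble of marker localizations or positions (`x_nm`,
#'   `y_nm`, optionally `cluster_id`).
#' @param masks A `raster_mask`, or a list of per-cluster `raster_mask`s
#'   named/indexed by cluster id (profiles are pooled: summed counts over
#'   summed areas).
#' @param bin_width Bin width in nm (default 10).
#' @param max_distance Largest distance binned (default 200 nm).
#' @param seed Optional seed for the uniform control.
#' @return A `radial_profile` tibble: `bin_lo`, `bin_hi`, `area_nm2`, `n`,
#'   `density`, `control_n`, `control_density`.
#' @export
radial_density <- function(ryr_puncta, jph_events, masks, bin_width = 10,
                           max_distance = 200, seed = NULL) {
  if (!nrow(ryr_puncta)) abort("Need at least one RyR punctum.")
  single <- inherits(masks, "raster_mask")
  if (single) {
    masks <- list(masks)
    ryr_list <- list(cbind(ryr_puncta$x_nm, ryr_puncta$y_nm))
    jph_list <- list(cbind(jph_events$x_nm, jph_events$y_nm))
  } else {
    ids <- names(masks) %||% as.character(seq_along(masks))
    ryr_list <- map(ids, function(id) {
      s <- ryr_puncta[as.character(ryr_puncta$cluster_id) == id, ]
      cbind(s$x_nm, s$y_nm)
    })
    jph_list <- map(ids, function(id) {
      s <- jph_events[as.character(jph_events$cluster_id) == id, ]
      cbind(s$x_nm, s$y_nm)
    })
  }
  with_seed_if(seed, {
    nb <- length(seq(0, max_distance, by = bin_width)) - 1L
    area <- n <- ctrl <- rep(0, nb)
    for (i in seq_along(masks)) {
      if (!nrow(ryr_list[[i]])) next
      ob <- radial_bins_one(ryr_list[[i]], jph_list[[i]], masks[[i]],
                            bin_width, max_distance)
      area <- area + ob$area
      n <- n + ob$count
      if (ob$n_inside > 0) {
        u <- sample_in_mask(ob$n_inside, masks[[i]])
        cb <- radial_bins_one(ryr_list[[i]], u, masks[[i]],
                              bin_width, max_distance)
        ctrl <- ctrl + cb$count
      }
    }
    brk <- seq(0, max_distance, by = bin_width)
    out <- tibble(
      bin_lo = brk[-length(brk)], bin_hi = brk[-1],
      area_nm2 = area, n = n,
      density = ifelse(area > 0, n / area, NA_real_),
      control_n = ctrl,
      control_density = ifelse(area > 0, ctrl / area, NA_real_)
    )
    class(out) <- c("radial_profile", class(out))
    out
  })
}

#' Fold enrichment of a radial profile near the RyRs
#'
#' Ratio of the mean density in bins at or below `cutoff` to the mean density
#' in bins beyond it (bins with zero area are ignored).
#'
#' @param profile A `radial_profile`.
#' @param cutoff Distance cutoff in nm (default 50).
#' @return The fold enrichment (single number).
#' @export
fold_enrichment <- function(profile, cutoff = 50) {
  near <- profile$density[profile$bin_hi <= cutoff & profile$area_nm2 > 0]
  far <- profile$density[profile$bin_lo >= cutoff & profile$area_nm2 > 0]
  mean(near, na.rm = TRUE) / mean(far, na.rm = TRUE)
}

#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("bin_lo", "density", "control_density")],
    c("density", "control_density"),
    names_to = "profile", values_to = "density"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_lo, .data$density,
                                   color = .data$profile)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance to nearest RyR centroid (nm)",
                  y = expression(density ~ (markers / nm^2)))
}

#' Per-cluster molecular ratios from exchange qPAINT
#'
#' Applies the RyR cluster masks to both exchange rounds, computes calibrated
#' qPAINT counts per channel (`N_R` RyR, `N_J` JPH2) and the per-cluster
#' molecular ratio `r_J_R = N_J / N_R` for clusters with more than
#' `min_ryr_count` RyRs.
#'
#' @param clusters A `cluster_set` segmented from the RyR channel.
#' @param ryr_events,jph_events Localization tibbles of the two rounds,
#'   registered to one coordinate frame.
#' @param ryr_unit,jph_unit Per-channel quantal calibration units (index per
#'   molecule), numbers or `qpaint_calibration` objects.
#' @param frame_time Seconds per frame.
#' @param min_ryr_count Only clusters with `N_R > min_ryr_count` are
#'   reported (default 15).
#' @param dilate_nm Radius (nm) by which each cluster mask is dilated before
#'   events are assigned, so that the analyzed region covers the junction
#'   around the RyR cluster (default 0: the bare RyR mask).
#' @param ... Passed to [qpaint_indices()].
#' @return Tibble: `cluster_id`, `n_r`, `n_j`, `r_j_r`.
#' @export
molecular_ratio <- function(clusters, ryr_events, jph_events,
                            ryr_unit, jph_unit, frame_time,
                            min_ryr_count = 15, dilate_nm = 0, ...) {
  if (inherits(ryr_unit, "qpaint_calibration")) ryr_unit <- ryr_unit$unit
  if (inherits(jph_unit, "qpaint_calibration")) jph_unit <- jph_unit$unit
  if (!is.numeric(ryr_unit) || !is.finite(ryr_unit) || ryr_unit <= 0) {
    abort("Missing or invalid RyR calibration unit.",
          class = "nanopaint_calibration_failure")
  }
  if (!is.numeric(jph_unit) || !is.finite(jph_unit) || jph_unit <= 0) {
    abort("Missing or invalid JPH2 calibration unit.",
          class = "nanopaint_calibration_failure")
  }
  labels <- clusters$labels
  if (dilate_nm > 0) {
    size <- 2L * round(dilate_nm / clusters$raster$pixel_size) + 1L
    labels <- matrix(
      as.integer(EBImage::dilate(labels, EBImage::makeBrush(size, "disc"))),
      nrow(labels), ncol(labels)
    )
  }
  assign_to_masks <- function(ev) {
    px <- events_to_pixels(ev, clusters$raster)
    lab <- rep(NA_integer_, nrow(ev))
    ok <- !is.na(px$row)
    lab[ok] <- labels[cbind(px$row[ok], px$col[ok])]
    lab[!is.na(lab) & lab == 0L] <- NA_integer_
    ev$cluster_id <- lab
    ev
  }
  idx_r <- qpaint_indices(assign_to_masks(ryr_events), frame_time, ...)
  idx_j <- qpaint_indices(assign_to_masks(jph_events), frame_time, ...)
  out <- idx_r %>%
    mutate(n_r = .data$qpaint_index / ryr_unit) %>%
    select("cluster_id", "n_r") %>%
    left_join(
      idx_j %>%
        mutate(n_j = .data$qpaint_index / jph_unit) %>%
        select("cluster_id", "n_j"),
      by = "cluster_id"
    ) %>%
    filter(is.finite(.data$n_r), .data$n_r > min_ryr_count) %>%
    mutate(
      n_j = ifelse(is.finite(.data$n_j), .data$n_j, 0),
      r_j_r = .data$n_j / .data$n_r
    )
  out
}
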