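# qPAINT molecular counting: binding-event reconstruction from localization
# streams, dark-time statistics, qPAINT index, quantal calibration and
# per-cluster molecule counts.

# Split one temporal run of localizations (frames already contiguous up to
# max_frame_gap) into spatially coherent sub-events: each localization joins
# the nearest open sub-event whose running centroid is within max_jump,
# otherwise starts a new sub-event.
split_run_spatial <- function(frame, x, y, max_jump) {
  n <- length(frame)
  ev <- integer(n)
  cx <- cy <- cn <- numeric(0)
  for (i in seq_len(n)) {
    if (length(cx)) {
      d2 <- (cx / cn - x[i])^2 + (cy / cn - y[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_jump^2) {
        ev[i] <- j
        cx[j] <- cx[j] + x[i]; cy[j] <- cy[j] + y[i]; cn[j] <- cn[j] + 1
        next
      }
    }
    cx <- c(cx, x[i]); cy <- c(cy, y[i]); cn <- c(cn, 1)
    ev[i] <- length(cx)
  }
  ev
}

#' Reconstruct binding events from a region's localization stream
#'
#' Merges localizations in consecutive frames (allowing up to
#' `max_frame_gap` missing frames) that stay within `max_jump` of the running
#' event position into single binding events, then computes the complete dark
#' times between consecutive events. Leading and trailing (censored) dark
#' intervals do not exist by construction; overlapping events (simultaneous
#' binding at distinct sites) contribute no dark time.
#'
#' @param events Localization tibble for one region (`x_nm`, `y_nm`,
#'   `frame`).
#' @param frame_time Seconds per frame.
#' @param max_frame_gap Missing frames tolerated inside one event
#'   (default 2).
#' @param max_jump Maximum distance (nm) between a localization and the
#'   running event position (default 20).
#' @return A `binding_trace`: `intervals` tibble (`event_id`, `start_frame`,
#'   `end_frame`, `n_loc`, `x_nm`, `y_nm`), `dark_times_s`, `frame_time`.
#' @export
merge_binding_events <- function(events, frame_time, max_frame_gap = 2,
                                 max_jump = 20) {
  assert_number(frame_time, "frame_time", strict_lower = TRUE, lower = 0)
  min_observable <- (max_frame_gap + 1) * frame_time
  if (!nrow(events)) {
    return(structure(list(
      intervals = tibble(event_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), n_loc = integer(0),
                         x_nm = numeric(0), y_nm = numeric(0)),
      dark_times_s = numeric(0), frame_time = frame_time,
      min_observable_s = min_observable
    ), class = "binding_trace"))
  }
  ord <- order(events$frame)
  fr <- events$frame[ord]; x <- events$x_nm[ord]; y <- events$y_nm[ord]
  n <- length(fr)
  # temporal runs: contiguous blocks separated by > max_frame_gap missing
  # frames (runs are contiguous in the frame-sorted order)
  newrun <- c(TRUE, diff(fr) > max_frame_gap + 1L)
  run <- cumsum(newrun)
  rs <- which(newrun)
  re <- c(rs[-1] - 1L, n)
  cnt <- re - rs + 1L
  nruns <- length(rs)
  mx <- as.vector(rowsum(x, run)) / cnt
  my <- as.vector(rowsum(y, run)) / cnt
  dev2 <- (x - mx[run])^2 + (y - my[run])^2
  multi <- which(cnt > 1L)
  loose <- multi[vapply(multi, function(i) max(dev2[rs[i]:re[i]]),
                        numeric(1)) > max_jump^2]
  sub_ids <- rep(1L, n)
  n_sub <- rep(1L, nruns)
  for (i in loose) {
    sel <- rs[i]:re[i]
    s <- split_run_spatial(fr[sel], x[sel], y[sel], max_jump)
    sub_ids[sel] <- s
    n_sub[i] <- max(s)
  }
  base <- cumsum(c(0L, n_sub[-nruns]))
  ev <- base[run] + sub_ids
  n_ev <- base[nruns] + n_sub[nruns]
  o2 <- order(ev, fr)
  e2 <- ev[o2]; f2 <- fr[o2]
  first <- !duplicated(e2)
  last <- !duplicated(e2, fromLast = TRUE)
  intervals <- tibble(
    start_frame = f2[first], end_frame = f2[last],
    n_loc = tabulate(ev, nbins = n_ev),
    x_nm = as.vector(rowsum(x, ev)) / tabulate(ev, nbins = n_ev),
    y_nm = as.vector(rowsum(y, ev)) / tabulate(ev, nbins = n_ev)
  ) %>%
    arrange(.data$start_frame, .data$end_frame) %>%
    mutate(event_id = row_number()) %>%
    select("event_id", "start_frame", "end_frame", "n_loc", "x_nm", "y_nm")
  gaps <- intervals$start_frame[-1] - intervals$end_frame[-nrow(intervals)]
  dark <- gaps[gaps > 0] * frame_time
  structure(list(intervals = intervals, dark_times_s = as.numeric(dark),
                 frame_time = frame_time, min_observable_s = min_observable),
            class = "binding_trace")
}

#' @export
print.binding_trace <- function(x, ...) {
  cat(sprintf("<binding_trace> %d binding events, %d complete dark times\n",
              nrow(x$intervals), length(x$dark_times_s)))
  invisible(x)
}

#' Estimate the mean dark time of a region
#'
#' Fits the exponential cumulative distribution to the empirical CDF of the
#' complete dark times by unweighted least squares (the cumulative-histogram
#' method) and returns the fitted `tau` together with the plain sample mean
#' as a cross-check.
#'
#' Dark times shorter than the frame-gap merging window can never be
#' observed, so when the input is a `binding_trace` the fit accounts for this
#' left truncation: by memorylessness the observable dark times are
#' `t0 + Exponential(tau)` with `t0 = (max_frame_gap + 1) * frame_time`, and
#' the fitted model is `1 - exp(-(t - t0) / tau)`. The correction is
#' negligible for sparse regions (`tau >> t0`) but removes a saturation bias
#' in dense regions. Pass `min_observable_s = 0` (the default for bare
#' numeric input) to disable it.
#'
#' @param x A `binding_trace` or a numeric vector of dark times in seconds.
#' @param min_dark_times Minimum number of complete dark times required
#'   (default 10).
#' @param min_observable_s Left-truncation point `t0` in seconds; defaults to
#'   the trace's merging window, or 0 for numeric input.
#' @return A `dark_time_fit`: `tau_d_s` (fitted), `sample_mean_s` (raw),
#'   `min_observable_s`, `n`.
#' @export
estimate_mean_dark_time <- function(x, min_dark_times = 10,
                                    min_observable_s = NULL) {
  if (inherits(x, "binding_trace")) {
    dark <- x$dark_times_s
    t0 <- min_observable_s %||% x$min_observable_s
  } else {
    dark <- as.numeric(x)
    t0 <- min_observable_s %||% 0
  }
  n <- length(dark)
  if (n < min_dark_times) {
    abort(
      sprintf("Insufficient dark times: %d observed, %d required.",
              n, min_dark_times),
      class = "nanopaint_insufficient_data", n_observed = n
    )
  }
  ts <- sort(dark)
  emp <- seq_len(n) / n
  if (max(ts) == min(ts)) {
    tau <- max(mean(ts) - t0, .Machine$double.eps)
  } else {
    ss <- function(log_tau) {
      tau <- exp(log_tau)
      model <- 1 - exp(-pmax(ts - t0, 0) / tau)
      sum((emp - model)^2)
    }
    m <- max(mean(ts) - t0, min(ts[ts > 0], na.rm = TRUE) / 10)
    opt <- optimize(ss, interval = log(c(m / 20, m * 20)))
    tau <- exp(opt$minimum)
  }
  structure(list(tau_d_s = tau, sample_mean_s = mean(dark),
                 min_observable_s = t0, n = n),
            class = "dark_time_fit")
}

#' @export
print.dark_time_fit <- function(x, ...) {
  cat(sprintf("<dark_time_fit> tau_d = %.4g s (sample mean %.4g s, n = %d)\n",
              x$tau_d_s, x$sample_mean_s, x$n))
  invisible(x)
}

#' Per-cluster qPAINT indices
#'
#' Runs binding-event reconstruction and dark-time estimation for every
#' cluster of a `cluster_set` (or every `cluster_id` group of a localization
#' tibble) and reports the qPAINT index, the inverse of the mean dark time,
#' which is directly proportional to the number of docking sites in the
#' region.
#'
#' @details
#' Two index estimators are available. `"cdf"` (the default) inverts the
#' dark-time CDF fit of [estimate_mean_dark_time()], matching the
#' cumulative-histogram description of the method. `"rate"` uses the
#' observed binding-event rate, `(n_events - 1)` divided by the time between
#' the first and last event starts; for sparse regions the two agree, while
#' at high event rates (many sites pooled in one region) the rate estimator
#' is exactly proportional to the number of sites even when sub-frame
#' bright intervals go undetected, so it is preferred for molecular
#' counting experiments.
#'
#' @param x A `cluster_set` or a localization tibble with a `cluster_id`
#'   column.
#' @param frame_time Seconds per frame.
#' @param max_frame_gap,max_jump See [merge_binding_events()].
#' @param min_dark_times Floor below which a cluster gets `NA` estimates.
#' @param estimator `"cdf"` (dark-time CDF fit) or `"rate"` (binding-event
#'   rate); see Details.
#' @return Tibble: `cluster_id`, `n_events`, `n_dark_times`, `tau_d_s`,
#'   `qpaint_index` (= `1 / tau_d_s`).
#' @export
qpaint_indices <- function(x, frame_time, max_frame_gap = 2, max_jump = 20,
                           min_dark_times = 10,
                           estimator = c("cdf", "rate")) {
  estimator <- arg_match(estimator)
  ev <- if (inherits(x, "cluster_set")) x$events else x
  ev <- ev %>% filter(!is.na(.data$cluster_id))
  ev %>%
    group_by(.data$cluster_id) %>%
    dplyr::group_map(function(df, key) {
      trace <- merge_binding_events(df, frame_time, max_frame_gap, max_jump)
      if (estimator == "cdf") {
        fit <- tryCatch(
          estimate_mean_dark_time(trace, min_dark_times),
          nanopaint_insufficient_data = function(e) NULL
        )
        tau <- if (is.null(fit)) NA_real_ else fit$tau_d_s
      } else {
        n_ev <- nrow(trace$intervals)
        tau <- if (n_ev >= min_dark_times + 1) {
          span <- (trace$intervals$start_frame[n_ev] -
                     trace$intervals$start_frame[1]) * frame_time
          span / (n_ev - 1)
        } else NA_real_
      }
      tibble(
        cluster_id = key$cluster_id,
        n_events = nrow(trace$intervals),
        n_dark_times = length(trace$dark_times_s),
        tau_d_s = tau,
        qpaint_index = 1 / tau
      )
    }) %>%
    bind_rows()
}

#' Calibrate the quantal qPAINT index unit
#'
#' Estimates the single-molecule index unit from the indices of small
#' calibration clusters: a Gaussian kernel density (Silverman's bandwidth) is
#' computed over the indices, and the first local maximum with prominence of
#' at least `prominence` times the density maximum is the quantal unit. As a
#' quality check, subsequent prominent modes must sit near integer multiples
#' of the unit (within `mode_tolerance` of `k * unit`); deviations attach a
#' calibration warning. The unit estimate is refined as the mean of the
#' indices within half a unit of the first mode.
#'
#' @param indices Numeric vector of qPAINT indices of calibration clusters.
#' @param min_clusters Minimum number of calibration clusters (default 20).
#' @param prominence Relative density floor for a mode (default 0.1).
#' @param mode_tolerance Allowed relative deviation of mode k from
#'   `k * unit` (default 0.25).
#' @param refine Refine the unit as the mean of first-peak indices
#'   (default `TRUE`).
#' @return A `qpaint_calibration`: `unit` (index units per molecule), `modes`
#'   tibble, `warnings` character vector, `n`.
#' @export
calibrate_quantal_unit <- function(indices, min_clusters = 20,
                                   prominence = 0.1, mode_tolerance = 0.25,
                                   refine = TRUE) {
  indices <- indices[is.finite(indices)]
  if (length(indices) < min_clusters) {
    abort(sprintf("Need >= %d calibration clusters, got %d.",
                  min_clusters, length(indices)),
          class = "nanopaint_insufficient_data")
  }
  if (sd(indices) < 1e-12 * max(abs(indices))) {
    # degenerate: all indices identical
    return(structure(list(
      unit = indices[1],
      modes = tibble(mode = indices[1], density = Inf, k = 1L, ok = TRUE),
      warnings = character(0), n = length(indices)
    ), class = "qpaint_calibration"))
  }
  den <- density(indices, bw = "nrd0", n = 1024, from = 0,
                 to = max(indices) * 1.1)
  y <- den$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= prominence * max(y)]
  if (!length(is_max)) {
    abort("No detectable mode in the calibration index density.",
          class = "nanopaint_calibration_failure")
  }
  modes <- den$x[is_max]
  unit <- modes[1]
  if (refine) {
    near <- indices[abs(indices - unit) <= unit / 2]
    if (length(near) >= 3) unit <- mean(near)
  }
  k <- pmax(1L, round(modes / unit))
  ok <- abs(modes - k * unit) <= mode_tolerance * unit
  warnings <- character(0)
  if (any(!ok)) {
    warnings <- sprintf(
      "Mode at %.4g is not within %g%% of %d x unit (%.4g).",
      modes[!ok], 100 * mode_tolerance, k[!ok], unit
    )
  }
  structure(list(
    unit = unit,
    modes = tibble(mode = modes, density = y[is_max], k = k, ok = ok),
    warnings = warnings, n = length(indices)
  ), class = "qpaint_calibration")
}

#' @export
print.qpaint_calibration <- function(x, ...) {
  cat(sprintf("<qpaint_calibration> unit = %.4g (n = %d, %d mode(s))\n",
              x$unit, x$n, nrow(x$modes)))
  if (length(x$warnings)) cat(" warnings:", x$warnings, sep = "\n  ")
  invisible(x)
}

#' Convert qPAINT indices to molecule counts
#'
#' `count = index / unit`, reported raw and rounded to the nearest integer.
#'
#' @param estimates Tibble with a `qpaint_index` column (e.g. from
#'   [qpaint_indices()]) or a numeric vector of indices.
#' @param unit Calibration unit (index units per molecule) or a
#'   `qpaint_calibration`.
#' @return The input with `count_raw` and `count` columns added (or a tibble
#'   of counts when `estimates` is a bare vector).
#' @export
count_molecules <- function(estimates, unit) {
  if (inherits(unit, "qpaint_calibration")) unit <- unit$unit
  assert_number(unit, "unit", strict_lower = TRUE, lower = 0)
  if (is.numeric(estimates)) {
    estimates <- tibble(qpaint_index = estimates)
  }
  estimates %>%
    mutate(
      count_raw = .data$qpaint_index / unit,
      count = round(.data$count_raw)
    )
}

#' Cluster area versus molecule count regression
#'
#' Ordinary least-squares regression of molecule count on cluster area. The
#' primary fit is through the origin (a zero-area cluster holds zero
#' molecules); a free-intercept fit is reported alongside. The through-origin
#' slope (molecules per nm^2) converts to a mean linear packing distance
#' `spacing = 1 / sqrt(slope)`.
#'
#' @param areas_nm2 Cluster areas in nm^2 (or a tibble with `area_nm2` and
#'   `count` columns).
#' @param counts Molecule counts (ignored when `areas_nm2` is a tibble).
#' @return A `density_fit` with [tidy()] and [glance()] methods.
#' @export
density_regression <- function(areas_nm2, counts = NULL) {
  if (is.data.frame(areas_nm2)) {
    counts <- areas_nm2$count
    areas_nm2 <- areas_nm2$area_nm2
  }
  keep <- is.finite(areas_nm2) & is.finite(counts) & areas_nm2 > 0
  a <- areas_nm2[keep]; cts <- counts[keep]
  if (length(a) < 1) abort("Need at least one cluster with positive area.")
  slope <- sum(a * cts) / sum(a * a) # closed-form through-origin OLS
  fit_free <- if (length(a) >= 2) lm(cts ~ a) else NULL
  ss_res <- sum((cts - slope * a)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  structure(list(
    slope = slope,
    spacing_nm = 1 / sqrt(slope),
    slope_free = if (!is.null(fit_free)) unname(coef(fit_free)[2]) else NA_real_,
    intercept_free = if (!is.null(fit_free)) unname(coef(fit_free)[1]) else NA_real_,
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(a),
    data = tibble(area_nm2 = a, count = cts)
  ), class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf(
    "<density_fit> slope %.3g molecules / 1,000 nm^2 -> spacing %.3g nm (n = %d)\n",
    1000 * x$slope, x$spacing_nm, x$n
  ))
  invisible(x)
}

#' @rdname density_regression
#' @param x A `density_fit`.
#' @param ... Unused.
#' @export
tidy.density_fit <- function(x, ...) {
  tibble(
    term = c("area_nm2 (through origin)", "area_nm2 (free)", "intercept (free)"),
    estimate = c(x$slope, x$slope_free, x$intercept_free)
  )
}

#' @rdname density_regression
#' @export
glance.density_fit <- function(x, ...) {
  tibble(
    slope_per_1000nm2 = 1000 * x$slope,
    spacing_nm = x$spacing_nm,
    r_squared = x$r_squared,
    n = x$n
  )
}

#' @export
autoplot.density_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$area_nm2, .data$count)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0,
                         color = "firebrick") +
    ggplot2::labs(x = expression(cluster ~ area ~ (nm^2)),
                  y = "qPAINT molecule count")
}

#' Mean linear spacing implied by a packing density
#'
#' Converts a packing density (molecules per nm^2, e.g. the slope of
#' [density_regression()]) into the mean linear distance between molecules,
#' `1 / sqrt(density)`.
#'
#' @param density_per_nm2 Molecules per nm^2.
#' @return Spacing in nm.
#' @export
spacing_from_density <- function(density_per_nm2) {
  assert_number(density_per_nm2, "density_per_nm2", strict_lower = TRUE,
                lower = 0)
  1 / sqrt(density_per_nm2)
}

#' Area per molecule of a crystalline lattice
#'
#' The 2D area occupied per molecule when molecules pack on a square lattice
#' with the given lattice constant: `lattice_constant^2`.
#'
#' @param lattice_constant_nm Lattice constant in nm.
#' @return Area in nm^2 per molecule.
#' @export
packing_area <- function(lattice_constant_nm) {
  assert_number(lattice_constant_nm, "lattice_constant_nm",
                strict_lower = TRUE, lower = 0)
  lattice_constant_nm^2
}

#' qPAINT parameter-recovery experiment
#'
#' Simulates clusters with known site counts under the binding-kinetics
#' model, runs the full qPAINT chain (event reconstruction, dark-time CDF
#' fit, quantal calibration from single-site regions, counting) and returns
#' everything needed to assess proportionality and counting accuracy. The
#' default acquisition is chosen so that the expected number of binding
#' events per docking site is about 500, giving a counting standard error of
#' `sqrt(N / 500)` molecules at site count `N`.
#'
#' @param site_counts True docking-site counts to simulate (default 1..48).
#' @param n_calibration Number of single-site calibration regions.
#' @param kinetics A [kinetics_params()] object; the default uses a per-site
#'   binding rate of 0.002 events/s and 2,500,000 frames of 0.1 s.
#' @param assembly An [assembly_params()] object for cluster geometry.
#' @param seed Optional integer seed.
#' @return A list: `regions` tibble (`n_sites`, `n_dark_times`, `tau_d_s`,
#'   `qpaint_index`, `count_raw`, `count`), `calibration`
#'   (`qpaint_calibration`), `unit_true` (the analytic single-site index,
#'   equal to the per-site binding rate).
#' @export
qpaint_recovery_experiment <- function(site_counts = 1:48,
                                       n_calibration = 60,
                                       kinetics = kinetics_params(
                                         site_binding_rate = 0.002,
                                         mean_bright_time = 1,
                                         frame_time = 0.1,
                                         n_frames = 3000000L
                                       ),
                                       assembly = assembly_params(),
                                       seed = NULL) {
  with_seed_if(seed, {
    grow_cluster <- function(n_sites) {
      for (attempt in 1:25) {
        cl <- tryCatch(simulate_cluster(n_sites, assembly),
                       nanopaint_infeasible_geometry = function(e) NULL)
        if (!is.null(cl)) return(cl)
      }
      abort(sprintf("Cluster of %d sites infeasible after 25 attempts.",
                    n_sites),
            class = "nanopaint_infeasible_geometry")
    }
    index_of_cluster <- function(n_sites) {
      cl <- grow_cluster(n_sites)
      ev <- simulate_paint_events(cl, kinetics)
      ev$cluster_id <- 1L
      est <- qpaint_indices(ev, kinetics$frame_time, estimator = "rate")
      tibble(n_sites = n_sites, n_dark_times = est$n_dark_times,
             tau_d_s = est$tau_d_s, qpaint_index = est$qpaint_index)
    }
    calib <- map(seq_len(n_calibration), function(i) index_of_cluster(1L)) %>%
      bind_rows()
    calibration <- calibrate_quantal_unit(calib$qpaint_index)
    regions <- map(site_counts, index_of_cluster) %>%
      bind_rows() %>%
      count_molecules(calibration)
    list(
      regions = regions,
      calibration = calibration,
      unit_true = kinetics$site_binding_rate
    )
  })
}
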