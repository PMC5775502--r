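# Binding-kinetics simulator: alternating renewal process per docking site,
# discretized to camera frames.

# Draw the alternating renewal process for one site over [0, t_total].
# Returns matrix with columns start_s, end_s of bright intervals.
site_intervals <- function(rate, mean_bright, t_total) {
  ints <- matrix(numeric(0), ncol = 2)
  t_now <- 0
  # draw in blocks until the acquisition is covered
  n_guess <- max(16L, ceiling(1.3 * t_total / (1 / rate + mean_bright)) + 8L)
  while (t_now < t_total) {
    dark <- rexp(n_guess, rate = rate)
    bright <- rexp(n_guess, rate = 1 / mean_bright)
    starts <- t_now + cumsum(dark + bright) - bright
    ends <- starts + bright
    ints <- rbind(ints, cbind(starts, ends))
    t_now <- ends[n_guess]
  }
  ints[ints[, 1] < t_total, , drop = FALSE]
}

# Frames (0-based) whose overlap with bright interval [a, b) is at least
# half a frame. Returns integer vector.
bright_frames <- function(a, b, frame_time, n_frames) {
  f0 <- floor(a / frame_time)
  f1 <- floor(b / frame_time)
  nf <- pmax(f1 - f0 + 1, 0)
  if (!length(f0) || sum(nf) == 0) return(integer(0))
  idx <- rep(seq_along(f0), nf)
  f <- sequence(nf, from = f0)
  lo <- pmax(a[idx], f * frame_time)
  hi <- pmin(b[idx], (f + 1) * frame_time)
  keep <- (hi - lo) >= 0.5 * frame_time & f >= 0 & f < n_frames
  structure(f[keep], interval = idx[keep])
}

#' Simulate DNA-PAINT localization events for a set of docking sites
#'
#' Each detected site emits an alternating renewal process: dark intervals
#' `Exponential(mean = 1 / site_binding_rate)`, bright intervals
#' `Exponential(mean_bright_time)`. Every frame overlapping a bright interval
#' by at least half a frame yields one localization at the site position plus
#' isotropic Gaussian noise (`loc_precision_sigma`), with a Poisson photon
#' count. Undetected sites emit nothing.
#'
#' @param sites Tibble of ground-truth sites (`x_nm`, `y_nm`, optional
#'   `detected`, `cluster_id`).
#' @param kinetics A [kinetics_params()] object.
#' @param seed Optional integer seed.
#' @param channel Channel label stored on every record.
#' @return A localization tibble with columns `x_nm`, `y_nm`, `frame`
#'   (0-based integer), `photons`, `sigma_nm`, `channel`. Ground-truth
#'   bookkeeping is attached as attribute `"binding_truth"`: a tibble with one
#'   row per bright interval (`site`, `start_s`, `end_s`, `n_frames_emitted`).
#' @export
simulate_paint_events <- function(sites, kinetics = kinetics_params(),
                                  seed = NULL, channel = "ryr") {
  stopifnot(inherits(kinetics, "kinetics_params"))
  empty <- tibble(
    x_nm = numeric(0), y_nm = numeric(0), frame = integer(0),
    photons = integer(0), sigma_nm = numeric(0), channel = character(0)
  )
  if (!nrow(sites)) {
    attr(empty, "binding_truth") <- tibble(
      site = integer(0), start_s = numeric(0), end_s = numeric(0),
      n_frames_emitted = integer(0)
    )
    return(empty)
  }
  det <- if ("detected" %in% names(sites)) which(sites$detected) else seq_len(nrow(sites))
  with_seed_if(seed, {
    t_total <- kinetics$n_frames * kinetics$frame_time
    loc_x <- vector("list", length(det))
    loc_y <- loc_frame <- loc_site <- loc_x
    truth <- vector("list", length(det))
    for (k in seq_along(det)) {
      i <- det[k]
      ints <- site_intervals(kinetics$site_binding_rate,
                             kinetics$mean_bright_time, t_total)
      if (!nrow(ints)) {
        truth[[k]] <- tibble(site = integer(0), start_s = numeric(0),
                             end_s = numeric(0), n_frames_emitted = integer(0))
        next
      }
      fr <- bright_frames(ints[, 1], ints[, 2], kinetics$frame_time,
                          kinetics$n_frames)
      per_int <- tabulate(attr(fr, "interval"), nbins = nrow(ints))
      truth[[k]] <- tibble(
        site = i, start_s = ints[, 1], end_s = ints[, 2],
        n_frames_emitted = per_int
      )
      nf <- length(fr)
      if (!nf) next
      loc_x[[k]] <- sites$x_nm[i] + rnorm(nf, 0, kinetics$loc_precision_sigma)
      loc_y[[k]] <- sites$y_nm[i] + rnorm(nf, 0, kinetics$loc_precision_sigma)
      loc_frame[[k]] <- as.integer(fr)
      loc_site[[k]] <- rep(i, nf)
    }
    x <- as.numeric(unlist(loc_x) %||% numeric(0))
    y <- as.numeric(unlist(loc_y) %||% numeric(0))
    fr <- as.integer(unlist(loc_frame) %||% integer(0))
    ord <- order(fr)
    out <- tibble(
      x_nm = x[ord], y_nm = y[ord], frame = fr[ord],
      photons = as.integer(rpois(length(x), kinetics$photons_mean)),
      sigma_nm = rep(kinetics$loc_precision_sigma, length(x)),
      channel = rep(channel, length(x))
    )
    attr(out, "binding_truth") <- bind_rows(truth)
    out
  })
}

#' Simulate a square lattice of docking sites and its event stream
#'
#' Convenience generator for resolvability checks: a `rows` x `cols` square
#' lattice with the given spacing, imaged with the supplied kinetics.
#'
#' @param spacing Lattice constant in nm.
#' @param rows,cols Lattice dimensions.
#' @param kinetics A [kinetics_params()] object.
#' @param seed Optional integer seed.
#' @param origin Position of the first lattice site (nm).
#' @return List with elements `sites` (ground-truth tibble) and `events`
#'   (localization tibble).
#' @export
simulate_grid <- function(spacing, rows, cols,
                          kinetics = kinetics_params(), seed = NULL,
                          origin = c(200, 200)) {
  assert_number(spacing, "spacing", strict_lower = TRUE, lower = 0)
  g <- expand.grid(ix = seq_len(cols) - 1L, iy = seq_len(rows) - 1L)
  sites <- tibble(
    x_nm = origin[1] + g$ix * spacing,
    y_nm = origin[2] + g$iy * spacing,
    cluster_id = 1L, protein = "RyR", detected = TRUE
  )
  events <- simulate_paint_events(sites, kinetics, seed = seed)
  list(sites = sites, events = events)
}
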