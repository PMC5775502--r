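#' Draw cluster sizes from the truncated exponential size law
#'
#' Cluster sizes follow an approximately exponential frequency distribution.
#' Draws are `ceiling(Exponential(mean = size_mean))`, resampled until the
#' value does not exceed `size_max`, so every cluster holds at least one site.
#'
#' @param n Number of sizes to draw.
#' @param params An [assembly_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `n`.
#' @export
sample_cluster_sizes <- function(n, params = assembly_params(), seed = NULL) {
  stopifnot(inherits(params, "assembly_params"))
  if (params$size_mean <= 0) abort("`size_mean` must be positive.")
  with_seed_if(seed, {
    out <- integer(n)
    need <- seq_len(n)
    while (length(need)) {
      draw <- as.integer(ceiling(rexp(length(need), rate = 1 / params$size_mean)))
      ok <- draw <= params$size_max
      out[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    out
  })
}

#' Simulate one RyR cluster by random-direction self-assembly
#'
#' Grows a cluster of `n_sites` docking sites. The first site sits at
#' `origin`; each subsequent site is placed at a distance
#' `Normal(step_mean, step_sigma)` in a uniformly random direction from the
#' anchor site, rejecting placements that violate the `min_separation`
#' hard-core exclusion (and, when `nearest_spacing` is set, placements for
#' which the anchor is not the nearest existing site). A placement is
#' resampled up to `max_placement_retries` times before the geometry is
#' declared infeasible.
#'
#' @param n_sites Number of sites (>= 1).
#' @param params An [assembly_params()] object.
#' @param seed Optional integer seed.
#' @param origin Length-2 numeric, nm position of the seed site.
#' @param cluster_id Label stored in the `cluster_id` column.
#' @return A tibble of ground-truth sites with columns `x_nm`, `y_nm`,
#'   `cluster_id`, `protein` (`"RyR"`), `detected` (all `TRUE`). The accepted
#'   anchor-to-site step distances are attached as attribute `"steps"`.
#' @export
simulate_cluster <- function(n_sites, params = assembly_params(), seed = NULL,
                             origin = c(0, 0), cluster_id = 1L) {
  stopifnot(inherits(params, "assembly_params"))
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1) {
    abort("`n_sites` must be a single integer >= 1.")
  }
  n_sites <- as.integer(n_sites)
  with_seed_if(seed, {
    xs <- numeric(n_sites); ys <- numeric(n_sites)
    xs[1] <- origin[1]; ys[1] <- origin[2]
    steps <- numeric(0)
    if (n_sites >= 2L) {
      for (i in 2:n_sites) {
        placed <- FALSE
        for (try in seq_len(params$max_placement_retries)) {
          p <- if (params$anchor == "uniform") sample.int(i - 1L, 1L) else i - 1L
          d <- rnorm(1, params$step_mean, params$step_sigma)
          if (d < params$min_separation) next
          th <- runif(1, 0, 2 * pi)
          x <- xs[p] + d * cos(th); y <- ys[p] + d * sin(th)
          dd <- sqrt((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2)
          if (min(dd) < params$min_separation) next
          if (params$nearest_spacing && min(dd) < d - 1e-9) next
          xs[i] <- x; ys[i] <- y
          steps <- c(steps, d)
          placed <- TRUE
          break
        }
        if (!placed) {
          abort(
            sprintf(
              "Placement retry budget exhausted at site %d of cluster %s.",
              i, format(cluster_id)
            ),
            class = "nanopaint_infeasible_geometry"
          )
        }
      }
    }
    out <- tibble(
      x_nm = xs, y_nm = ys, cluster_id = cluster_id,
      protein = "RyR", detected = TRUE
    )
    attr(out, "steps") <- steps
    out
  })
}

#' Simulate a field of RyR clusters
#'
#' Draws `n_clusters` sizes from the truncated exponential law and grows each
#' cluster by [simulate_cluster()], laying cluster origins on a square grid
#' with pitch `pitch_nm` so that clusters are well separated. A cluster whose
#' geometry turns out infeasible is regrown with fresh random draws (the size
#' is kept).
#'
#' @param n_clusters Number of clusters.
#' @param params An [assembly_params()] object.
#' @param seed Optional integer seed.
#' @param pitch_nm Center-to-center pitch of the cluster grid layout (nm).
#' @param margin_nm Offset of the first cluster origin from the field corner.
#' @return Tibble of ground-truth sites (columns as in [simulate_cluster()]),
#'   with the `detected` flags already drawn at `params$detection_fraction`.
#' @export
simulate_field <- function(n_clusters, params = assembly_params(), seed = NULL,
                           pitch_nm = 1500, margin_nm = 750) {
  with_seed_if(seed, {
    sizes <- sample_cluster_sizes(n_clusters, params)
    ncol_grid <- ceiling(sqrt(n_clusters))
    sites <- vector("list", n_clusters)
    for (k in seq_len(n_clusters)) {
      gx <- (k - 1L) %% ncol_grid
      gy <- (k - 1L) %/% ncol_grid
      org <- c(margin_nm + gx * pitch_nm, margin_nm + gy * pitch_nm)
      cl <- NULL
      for (attempt in 1:25) {
        cl <- tryCatch(
          simulate_cluster(sizes[k], params, origin = org, cluster_id = k),
          nanopaint_infeasible_geometry = function(e) NULL
        )
        if (!is.null(cl)) break
      }
      if (is.null(cl)) {
        abort(sprintf("Cluster %d infeasible after 25 regrow attempts.", k),
              class = "nanopaint_infeasible_geometry")
      }
      sites[[k]] <- cl
    }
    out <- bind_rows(sites)
    apply_detection_fraction(out, params$detection_fraction)
  })
}

#' Mark sites as detected with a given probability
#'
#' Models incomplete marker labeling: each site is independently flagged
#' `detected` with probability `fraction`; positions are unchanged.
#'
#' @param sites Tibble of ground-truth sites.
#' @param fraction Detection probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return `sites` with the `detected` column redrawn.
#' @export
apply_detection_fraction <- function(sites, fraction, seed = NULL) {
  assert_number(fraction, "fraction", lower = 0, upper = 1)
  with_seed_if(seed, {
    sites$detected <- runif(nrow(sites)) < fraction
    sites
  })
}

# Junction region polygon for one cluster: convex hull of the RyR sites
# scaled about its centroid to `scale` times the hull area. Degenerate
# clusters (< 3 sites, or collinear) fall back to a disc approximated by a
# 64-gon centered on the site centroid, sized to `scale` times a nominal
# per-site footprint of pi * step_mean^2 / 4.
junction_polygon <- function(ryr_xy, scale, step_mean = 40) {
  hull_ok <- FALSE
  if (nrow(ryr_xy) >= 3L) {
    h <- grDevices::chull(ryr_xy[, 1], ryr_xy[, 2])
    poly <- ryr_xy[h, , drop = FALSE]
    if (nrow(poly) >= 3L && polygon_area(poly) > 1e-6) hull_ok <- TRUE
  }
  if (hull_ok) {
    return(scale_polygon(poly, scale))
  }
  cx <- mean(ryr_xy[, 1]); cy <- mean(ryr_xy[, 2])
  r <- sqrt(scale * nrow(ryr_xy) * (step_mean^2) / 4)
  th <- seq(0, 2 * pi, length.out = 65L)[-65L]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

sample_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 16L)
    cx <- runif(m, xr[1], xr[2]); cy <- runif(m, yr[1], yr[2])
    keep <- point_in_polygon(cx, cy, poly)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Place JPH2 markers around simulated RyR clusters
#'
#' For each RyR cluster, the total JPH2 count is drawn as
#' `Poisson(ratio_mean * n_RyR)` so the per-cluster JPH2:RyR ratio has the
#' configured mean. A `bound_fraction` share (binomial draw) is placed
#' uniformly within `bound_radius` of uniformly chosen RyR sites; the rest is
#' placed uniformly over the junction region (scaled convex hull, see
#' [jph_params()]).
#'
#' @param ryr_sites Tibble of RyR ground-truth sites (needs `x_nm`, `y_nm`,
#'   `cluster_id`).
#' @param params A [jph_params()] object.
#' @param seed Optional integer seed.
#' @param step_mean Nominal RyR spacing used to size the junction fallback
#'   region for degenerate hulls (nm).
#' @return Tibble of JPH2 ground-truth sites (`protein = "JPH2"`), with a
#'   `pool` column (`"bound"` or `"sparse"`).
#' @export
place_jph2 <- function(ryr_sites, params = jph_params(), seed = NULL,
                       step_mean = 40) {
  stopifnot(inherits(params, "jph_params"))
  if (!nrow(ryr_sites)) abort("`ryr_sites` must contain at least one site.")
  with_seed_if(seed, {
    out <- ryr_sites %>%
      group_by(.data$cluster_id) %>%
      dplyr::group_map(function(df, key) {
        xy <- cbind(df$x_nm, df$y_nm)
        n_j <- rpois(1, params$ratio_mean * nrow(df))
        if (n_j == 0L) return(NULL)
        n_bound <- rbinom(1, n_j, params$bound_fraction)
        n_sparse <- n_j - n_bound
        pts <- matrix(numeric(0), ncol = 2)
        pool <- character(0)
        if (n_bound > 0L) {
          anchor <- xy[sample.int(nrow(xy), n_bound, replace = TRUE), , drop = FALSE]
          r <- params$bound_radius * sqrt(runif(n_bound))
          th <- runif(n_bound, 0, 2 * pi)
          pts <- rbind(pts, anchor + cbind(r * cos(th), r * sin(th)))
          pool <- c(pool, rep("bound", n_bound))
        }
        if (n_sparse > 0L) {
          poly <- junction_polygon(xy, params$sparse_region_scale, step_mean)
          pts <- rbind(pts, sample_in_polygon(n_sparse, poly))
          pool <- c(pool, rep("sparse", n_sparse))
        }
        tibble(
          x_nm = pts[, 1], y_nm = pts[, 2],
          cluster_id = key$cluster_id,
          protein = "JPH2", detected = TRUE, pool = pool
        )
      }) %>%
      bind_rows()
    out
  })
}
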