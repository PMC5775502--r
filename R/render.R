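# Density rendering: localization events -> grayscale raster with pixel
# intensity linearly proportional to local marker density.

new_density_raster <- function(pixels, pixel_size, origin) {
  structure(
    list(pixels = pixels, pixel_size = pixel_size, origin = origin),
    class = "density_raster"
  )
}

#' @export
print.density_raster <- function(x, ...) {
  cat(sprintf(
    "<density_raster> %d x %d px @ %g nm/px, origin (%g, %g) nm, total %.3f\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$origin[1], x$origin[2],
    sum(x$pixels)
  ))
  invisible(x)
}

# Pixel-grid-aligned extent: c(xmin, xmax, ymin, ymax).
default_extent <- function(events, pixel_size, pad) {
  c(
    floor((min(events$x_nm) - pad) / pixel_size) * pixel_size,
    ceiling((max(events$x_nm) + pad) / pixel_size) * pixel_size,
    floor((min(events$y_nm) - pad) / pixel_size) * pixel_size,
    ceiling((max(events$y_nm) + pad) / pixel_size) * pixel_size
  )
}

# 2D histogram of events on the raster grid. Rows index y, columns x.
bin_events <- function(x, y, extent, pixel_size) {
  ncols <- max(1L, round((extent[2] - extent[1]) / pixel_size))
  nrows <- max(1L, round((extent[4] - extent[3]) / pixel_size))
  cx <- floor((x - extent[1]) / pixel_size) + 1L
  cy <- floor((y - extent[3]) / pixel_size) + 1L
  keep <- cx >= 1L & cx <= ncols & cy >= 1L & cy <= nrows
  m <- matrix(0, nrows, ncols)
  if (any(keep)) {
    idx <- (cx[keep] - 1L) * nrows + cy[keep]
    tab <- tabulate(idx, nbins = nrows * ncols)
    m[] <- tab
  }
  m
}

gaussian_kernel_1d <- function(sigma_px, radius_px) {
  z <- (-radius_px):radius_px
  k <- exp(-z^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian convolution with zero padding; conserves mass exactly
# for kernels fully inside the padded raster.
smooth_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- gaussian_kernel_1d(sigma_px, r)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L * r, nc + 2L * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- m
  kern <- outer(k, k)
  out <- EBImage::filter2(pad, kern, boundary = 0)
  out[(r + 1):(r + nr), (r + 1):(r + nc)]
}

render_gaussian <- function(events, pixel_size, extent, sigma) {
  m <- matrix(0,
    max(1L, round((extent[4] - extent[3]) / pixel_size)),
    max(1L, round((extent[2] - extent[1]) / pixel_size))
  )
  if (!nrow(events)) return(m)
  sig <- if (!is.null(sigma)) rep(sigma, nrow(events)) else events$sigma_nm
  grp <- round(sig, 1)
  for (s in unique(grp)) {
    sel <- grp == s
    binned <- bin_events(events$x_nm[sel], events$y_nm[sel], extent, pixel_size)
    m <- m + smooth_matrix(binned, s / pixel_size)
  }
  m
}

# One jitter pass of the triangulation renderer: jitter events by their
# precision, Delaunay-triangulate, fill each triangle with intensity
# 1 / triangle area.
render_triangulation_pass <- function(x, y, extent, pixel_size, nr, nc) {
  dd <- deldir::deldir(x, y, rw = extent[c(1, 2, 3, 4)], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  m <- matrix(0, nr, nc)
  for (tr in tl) {
    px <- tr$x; py <- tr$y
    area <- polygon_area(cbind(px, py))
    if (area <= 0) next
    val <- 1 / area
    c0 <- max(1L, floor((min(px) - extent[1]) / pixel_size) + 1L)
    c1 <- min(nc, floor((max(px) - extent[1]) / pixel_size) + 1L)
    r0 <- max(1L, floor((min(py) - extent[3]) / pixel_size) + 1L)
    r1 <- min(nr, floor((max(py) - extent[3]) / pixel_size) + 1L)
    if (c1 < c0 || r1 < r0) next
    ccx <- extent[1] + (c0:c1 - 0.5) * pixel_size
    ccy <- extent[3] + (r0:r1 - 0.5) * pixel_size
    g <- expand.grid(yy = ccy, xx = ccx)
    inside <- point_in_polygon(g$xx, g$yy, cbind(px, py))
    sub <- matrix(inside, nrow = length(ccy))
    m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + sub * val
  }
  m
}

#' Render localization events into a density raster
#'
#' Converts an event table into a grayscale raster whose pixel intensity is
#' linearly proportional to the local density of localized markers. The
#' default `"gaussian"` method sums unit-mass isotropic Gaussian kernels (one
#' per event, sigma from the event's `sigma_nm` unless overridden), so the
#' total raster intensity equals the event count. The `"triangulation"`
#' method averages jittered Delaunay local-density maps (each pass jitters
#' events by their precision, triangulates, and fills triangles with
#' intensity inversely proportional to their area), normalized to the same
#' total mass.
#'
#' @param events Localization tibble (`x_nm`, `y_nm`, `sigma_nm`).
#' @param pixel_size Raster pixel size in nm (default 1).
#' @param method `"gaussian"` (default) or `"triangulation"`.
#' @param sigma Optional fixed kernel sigma in nm overriding per-event
#'   precision.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` in nm; defaults to the
#'   event bounding box padded by 4 times the largest sigma. Required when
#'   `events` is empty.
#' @param n_passes Number of jitter passes for the triangulation method.
#' @param seed Optional seed (used by the triangulation jitter).
#' @return A `density_raster` object: `pixels` matrix (rows = y, increasing
#'   downward), `pixel_size`, `origin` (nm of the corner of pixel `[1, 1]`).
#' @export
render_density <- function(events, pixel_size = 1,
                           method = c("gaussian", "triangulation"),
                           sigma = NULL, extent = NULL, n_passes = 10,
                           seed = NULL) {
  method <- arg_match(method)
  assert_number(pixel_size, "pixel_size", strict_lower = TRUE, lower = 0)
  if (!nrow(events)) {
    if (is.null(extent)) {
      abort("`extent` is required to render an empty event table.")
    }
    nr <- max(1L, round((extent[4] - extent[3]) / pixel_size))
    nc <- max(1L, round((extent[2] - extent[1]) / pixel_size))
    return(new_density_raster(matrix(0, nr, nc), pixel_size,
                              c(extent[1], extent[3])))
  }
  sig_all <- if (!is.null(sigma)) sigma else events$sigma_nm %||% 5
  if (is.null(extent)) {
    extent <- default_extent(events, pixel_size, pad = 4 * max(sig_all, 1))
  }
  if (method == "gaussian") {
    m <- render_gaussian(events, pixel_size, extent, sigma)
  } else {
    if (nrow(events) < 3L) {
      abort("Triangulation rendering needs at least 3 events.")
    }
    nr <- max(1L, round((extent[4] - extent[3]) / pixel_size))
    nc <- max(1L, round((extent[2] - extent[1]) / pixel_size))
    sig <- rep(sig_all, length.out = nrow(events))
    m <- with_seed_if(seed, {
      acc <- matrix(0, nr, nc)
      for (p in seq_len(n_passes)) {
        jx <- events$x_nm + rnorm(nrow(events), 0, sig)
        jy <- events$y_nm + rnorm(nrow(events), 0, sig)
        acc <- acc + render_triangulation_pass(jx, jy, extent, pixel_size, nr, nc)
      }
      acc / n_passes
    })
    if (sum(m) > 0) m <- m * nrow(events) / sum(m)
  }
  new_density_raster(m, pixel_size, c(extent[1], extent[3]))
}

#' Write a density raster as a 16-bit grayscale TIFF
#'
#' Intensities are linearly scaled so the raster maximum maps to 65535. The
#' scale factor, pixel size and origin are recorded in the TIFF description
#' tag and in a JSON sidecar (`<path>.json`) so that a round trip through
#' [read_raster()] reproduces relative intensities within quantization error.
#'
#' @param raster A `density_raster`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "density_raster"))
  if (!all(is.finite(raster$pixels))) abort("Raster contains non-finite values.")
  mx <- max(raster$pixels)
  scale <- if (mx > 0) 65535 / mx else 0
  img <- pmin(pmax(raster$pixels * scale / 65535, 0), 1) # writeTIFF wants [0, 1]
  meta <- list(
    pixel_size_nm = raster$pixel_size,
    origin_nm = raster$origin,
    intensity_scale = scale
  )
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a density raster written by [write_raster()]
#'
#' @param path TIFF file path (a `<path>.json` sidecar must exist).
#' @return A `density_raster` with intensities on the original scale.
#' @export
read_raster <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pixels <- img * 65535
  if (meta$intensity_scale > 0) pixels <- pixels / meta$intensity_scale
  new_density_raster(pixels, meta$pixel_size_nm, meta$origin_nm)
}

#' @export
autoplot.density_raster <- function(object, trans = "sqrt", ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$x_nm <- object$origin[1] + (df$col - 0.5) * object$pixel_size
  df$y_nm <- object$origin[2] + (df$row - 0.5) * object$pixel_size
  df$intensity <- object$pixels[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "density")
}
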