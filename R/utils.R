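# Internal geometry and RNG helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a fixed seed when one is supplied, leaving the caller's
# RNG stream untouched; otherwise use the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Euclidean distance from each row of `pts` (matrix n x 2) to each row of
# `ref` (m x 2); returns n x m matrix.
cross_dist <- function(pts, ref) {
  dx <- outer(pts[, 1], ref[, 1], "-")
  dy <- outer(pts[, 2], ref[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Minimum distance from each row of `pts` to any row of `ref`, computed in
# chunks to bound memory on large rasters.
min_cross_dist <- function(pts, ref, chunk = 200000L) {
  n <- nrow(pts)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j] <- do.call(pmin, c(
      lapply(seq_len(nrow(ref)), function(k) {
        sqrt((pts[i:j, 1] - ref[k, 1])^2 + (pts[i:j, 2] - ref[k, 2])^2)
      })
    ))
    i <- j + 1L
  }
  out
}

# Crossing-number point-in-polygon test, vectorised over points.
# `poly` is a matrix of vertices (closed implicitly).
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  nv <- length(px)
  inside <- logical(length(x))
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Scale a polygon about its centroid so that its area is multiplied by
# `area_factor`.
scale_polygon <- function(poly, area_factor) {
  cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
  f <- sqrt(area_factor)
  cbind(cx + f * (poly[, 1] - cx), cy + f * (poly[, 2] - cy))
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g].", name, lower, upper))
  }
  invisible(x)
}
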