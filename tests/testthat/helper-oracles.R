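# Independent brute-force oracles used across the suite. These deliberately
# use naive O(n^2)-style computations, not the package's code paths.

suppressMessages(library(dplyr))

brute_nnd <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    min(sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2))
  }, numeric(1))
}

brute_fournd <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2)
    mean(sort(d)[1:4])
  }, numeric(1))
}

# Exhaustive optimal assignment (min total distance, perfect matching of the
# smaller set) by dynamic programming over subsets; n <= 12.
brute_assignment <- function(ax, ay, bx, by) {
  na <- length(ax); nb <- length(bx)
  stopifnot(na <= nb, nb <= 12)
  d <- outer(seq_len(na), seq_len(nb),
             function(i, j) sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2))
  nstates <- bitwShiftL(1L, nb)
  inf <- 1e18
  dp <- rep(inf, nstates); dp[1] <- 0
  choice <- matrix(0L, na, nstates)
  for (i in seq_len(na)) {
    ndp <- rep(inf, nstates)
    for (s in 0:(nstates - 1L)) {
      if (dp[s + 1L] >= inf) next
      for (j in seq_len(nb)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) == 0L) {
          s2 <- bitwOr(s, bit)
          v <- dp[s + 1L] + d[i, j]
          if (v < ndp[s2 + 1L]) {
            ndp[s2 + 1L] <- v
            choice[i, s2 + 1L] <- j
          }
        }
      }
    }
    dp <- ndp
  }
  best <- which.min(dp)
  # backtrack
  pairs <- integer(na)
  s <- best - 1L
  for (i in rev(seq_len(na))) {
    j <- choice[i, s + 1L]
    pairs[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  pairs
}

# Truncated-exponential (ceiling-discretized) expectation by summation.
truncated_size_mean <- function(size_mean, size_max) {
  k <- seq_len(size_max)
  pk <- exp(-(k - 1) / size_mean) - exp(-k / size_mean)
  sum(k * pk) / sum(pk)
}

# Compact grid of simulated clusters with given sizes (used by tests that
# need a field under full control).
build_test_field <- function(sizes, params = assembly_params(),
                             pitch = 1200) {
  ncol_grid <- ceiling(sqrt(length(sizes)))
  out <- lapply(seq_along(sizes), function(k) {
    org <- c(600 + ((k - 1) %% ncol_grid) * pitch,
             600 + ((k - 1) %/% ncol_grid) * pitch)
    for (a in 1:25) {
      cl <- tryCatch(
        simulate_cluster(sizes[k], params, origin = org, cluster_id = k),
        nanopaint_infeasible_geometry = function(e) NULL
      )
      if (!is.null(cl)) return(cl)
    }
    stop("infeasible test cluster")
  })
  dplyr::bind_rows(out)
}

loc_tibble <- function(x, y, frame = 0L, sigma = 5) {
  tibble::tibble(
    x_nm = x, y_nm = y, frame = as.integer(frame),
    photons = 100L, sigma_nm = sigma, channel = "test"
  )
}
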