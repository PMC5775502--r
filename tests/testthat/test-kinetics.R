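test_that("no detected sites yields an empty event table, not an error", {
  kin <- kinetics_params()
  empty <- simulate_paint_events(tibble::tibble(x_nm = numeric(0),
                                                y_nm = numeric(0)), kin)
  expect_equal(nrow(empty), 0L)
  off <- simulate_paint_events(
    tibble::tibble(x_nm = 0, y_nm = 0, detected = FALSE), kin, seed = 1
  )
  expect_equal(nrow(off), 0L)
})

test_that("event tables are byte-identical under a fixed seed", {
  sites <- simulate_cluster(5, seed = 2)
  kin <- kinetics_params(n_frames = 20000L)
  a <- simulate_paint_events(sites, kin, seed = 7)
  b <- simulate_paint_events(sites, kin, seed = 7)
  expect_identical(a, b)
})

test_that("single-site dark gaps match the analytic exponential mean", {
  # rate 0.01 /s -> 100 s mean gap between binding events
  kin <- kinetics_params(site_binding_rate = 0.01, mean_bright_time = 2,
                         frame_time = 0.1, n_frames = 6000000L)
  ev <- simulate_paint_events(tibble::tibble(x_nm = 0, y_nm = 0,
                                             detected = TRUE), kin, seed = 12)
  truth <- attr(ev, "binding_truth")
  gaps <- diff(truth$start_s) # inter-arrival of binding events
  expect_lt(abs(mean(gaps) / (100 + 2) - 1), 0.05) # dark + bright renewal
  dark_gaps <- truth$start_s[-1] - truth$end_s[-nrow(truth)]
  expect_lt(abs(mean(dark_gaps) / 100 - 1), 0.05)
})

test_that("co-located sites superpose: pooled event rate scales with N", {
  kin <- kinetics_params(site_binding_rate = 0.01, mean_bright_time = 2,
                         frame_time = 0.1, n_frames = 600000L)
  one <- simulate_paint_events(tibble::tibble(x_nm = 0, y_nm = 0,
                                              detected = TRUE), kin, seed = 3)
  n1 <- nrow(attr(one, "binding_truth"))
  eight <- simulate_paint_events(
    tibble::tibble(x_nm = rep(0, 8), y_nm = rep(0, 8), detected = TRUE),
    kin, seed = 4
  )
  n8 <- nrow(attr(eight, "binding_truth"))
  expect_lt(abs(n8 / (8 * n1) - 1), 0.05)
})

test_that("every localization corresponds to one bright frame-overlap", {
  sites <- simulate_cluster(4, seed = 5)
  kin <- kinetics_params(site_binding_rate = 0.02, mean_bright_time = 0.5,
                         frame_time = 0.1, n_frames = 100000L)
  ev <- simulate_paint_events(sites, kin, seed = 6)
  truth <- attr(ev, "binding_truth")
  # conservation: emitted frame counts in the bookkeeping equal table rows
  expect_equal(sum(truth$n_frames_emitted), nrow(ev))
  # oracle: recount overlapping frames (>= half-frame rule) per interval
  recount <- sum(vapply(seq_len(nrow(truth)), function(i) {
    a <- truth$start_s[i]; b <- truth$end_s[i]
    f <- floor(a / 0.1):floor(b / 0.1)
    ov <- pmin(b, (f + 1) * 0.1) - pmax(a, f * 0.1)
    sum(ov >= 0.05 & f >= 0 & f < kin$n_frames)
  }, numeric(1)))
  expect_equal(recount, nrow(ev))
})

test_that("pooled dark time converges to 1/(N x rate) for region site counts", {
  kin <- kinetics_params(site_binding_rate = 0.005, mean_bright_time = 2,
                         frame_time = 0.05, n_frames = 4000000L)
  for (N in c(1L, 12L, 48L)) {
    sites <- tibble::tibble(
      x_nm = 100 * (seq_len(N) %% 8), y_nm = 100 * (seq_len(N) %/% 8),
      detected = TRUE
    )
    ev <- simulate_paint_events(sites, kin, seed = 100 + N)
    truth <- attr(ev, "binding_truth")
    ord <- order(truth$start_s)
    starts <- truth$start_s[ord]
    busy_end <- cummax(truth$end_s[ord]) # union of bright intervals
    gaps <- starts[-1] - busy_end[-length(busy_end)]
    gaps <- gaps[gaps > 0]
    expect_lt(abs(mean(gaps) / (1 / (N * 0.005)) - 1), 0.05)
  }
})

test_that("grid simulation produces the exact lattice geometry", {
  kin <- kinetics_params(n_frames = 1000L)
  g <- simulate_grid(30, 4, 4, kin, seed = 8)
  expect_equal(nrow(g$sites), 16L)
  nnd <- brute_nnd(g$sites$x_nm, g$sites$y_nm)
  expect_equal(nnd, rep(30, 16))
  g2 <- simulate_grid(40, 2, 2, kin, seed = 9)
  d <- sort(as.numeric(dist(cbind(g2$sites$x_nm, g2$sites$y_nm))))
  expect_equal(d, c(40, 40, 40, 40, sqrt(2) * 40, sqrt(2) * 40))
})
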