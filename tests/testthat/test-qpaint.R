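test_that("localizations merge into binding events by frame contiguity", {
  ev <- loc_tibble(rep(0, 3), rep(0, 3), frame = c(10L, 11L, 12L))
  tr <- merge_binding_events(ev, frame_time = 0.1)
  expect_equal(nrow(tr$intervals), 1L)
  expect_equal(tr$intervals$start_frame, 10L)
  expect_equal(tr$intervals$end_frame, 12L)
  expect_equal(length(tr$dark_times_s), 0L)

  # two events with a known gap: dark time is the frame gap times frame_time
  ev2 <- loc_tibble(c(0, 0), c(0, 0), frame = c(10L, 500L))
  tr2 <- merge_binding_events(ev2, frame_time = 0.1, max_frame_gap = 0)
  expect_equal(nrow(tr2$intervals), 2L)
  expect_equal(tr2$dark_times_s, 490 * 0.1)

  empty <- merge_binding_events(loc_tibble(numeric(0), numeric(0)),
                                frame_time = 0.1)
  expect_equal(nrow(empty$intervals), 0L)
})

test_that("simultaneous events at distinct positions are kept apart", {
  # two sites 60 nm apart bound in overlapping frame ranges
  ev <- dplyr::bind_rows(
    loc_tibble(rnorm(5, 0, 2), rnorm(5, 0, 2), frame = 10:14),
    loc_tibble(rnorm(5, 60, 2), rnorm(5, 0, 2), frame = 12:16)
  )
  tr <- merge_binding_events(ev, frame_time = 0.1, max_jump = 20)
  expect_equal(nrow(tr$intervals), 2L)
})

test_that("reconstructed event counts track the simulator's bookkeeping", {
  kin <- kinetics_params(site_binding_rate = 0.01, mean_bright_time = 1,
                         frame_time = 0.1, n_frames = 500000L)
  ev <- simulate_paint_events(tibble::tibble(x_nm = 0, y_nm = 0,
                                             detected = TRUE), kin, seed = 21)
  truth <- attr(ev, "binding_truth")
  visible <- sum(truth$n_frames_emitted > 0)
  tr <- merge_binding_events(ev, kin$frame_time)
  expect_lt(abs(nrow(tr$intervals) / visible - 1), 0.05)
})

test_that("the dark-time estimator recovers known means", {
  # degenerate: identical dark times
  fit0 <- estimate_mean_dark_time(rep(100, 20))
  expect_equal(fit0$tau_d_s, 100, tolerance = 1e-6)
  expect_equal(fit0$sample_mean_s, 100)
  # CDF fit on clean exponential draws
  d <- withr::with_seed(31, rexp(5000, 1 / 50))
  fit <- estimate_mean_dark_time(d)
  expect_lt(abs(fit$tau_d_s / 50 - 1), 0.05)
  # insufficient data signals with the observed count
  err <- tryCatch(estimate_mean_dark_time(rexp(4, 1)),
                  nanopaint_insufficient_data = function(e) e)
  expect_s3_class(err, "nanopaint_insufficient_data")
  expect_equal(err$n_observed, 4L)
})

test_that("a three-site region's dark time follows the superposition closed form", {
  sites <- simulate_cluster(3, seed = 41)
  kin <- kinetics_params(site_binding_rate = 0.01, mean_bright_time = 2,
                         frame_time = 0.05, n_frames = 4000000L)
  ev <- simulate_paint_events(sites, kin, seed = 42)
  tr <- merge_binding_events(ev, kin$frame_time)
  fit <- estimate_mean_dark_time(tr)
  expect_lt(abs(fit$tau_d_s / (1 / (3 * 0.01)) - 1), 0.10)
})

test_that("quantal calibration finds the unit and checks mode equidistance", {
  idx <- withr::with_seed(51, c(rnorm(120, 0.14, 0.008),
                                rnorm(60, 0.28, 0.010),
                                rnorm(30, 0.42, 0.012)))
  cal <- calibrate_quantal_unit(idx)
  expect_lt(abs(cal$unit / 0.14 - 1), 0.05)
  expect_true(all(cal$modes$ok))
  expect_length(cal$warnings, 0L)
  # all-identical indices: the unit is that index
  cal2 <- calibrate_quantal_unit(rep(0.2, 25))
  expect_equal(cal2$unit, 0.2)
  expect_error(calibrate_quantal_unit(rnorm(5, 1)),
               class = "nanopaint_insufficient_data")
})

test_that("counting is index over unit, raw and rounded", {
  out <- count_molecules(c(0.42, 0.14, 0.139), unit = 0.14)
  expect_equal(out$count_raw[1], 3)
  expect_equal(out$count, c(3, 1, 1))
  est <- tibble::tibble(qpaint_index = 0.14)
  expect_equal(count_molecules(est, 0.14)$count_raw, 1)
})

test_that("index and fitted dark time are exact inverses", {
  ev <- withr::with_seed(61, {
    sites <- simulate_cluster(4)
    kin <- kinetics_params(site_binding_rate = 0.02, n_frames = 100000L)
    simulate_paint_events(sites, kin)
  })
  ev$cluster_id <- 1L
  est <- qpaint_indices(ev, frame_time = 0.1)
  expect_equal(est$qpaint_index * est$tau_d_s, 1, tolerance = 1e-12)
})

test_that("through-origin regression matches its closed form and converts to spacing", {
  # exact proportionality: slope and spacing reproduce the construction
  areas <- c(10000, 25000, 60000, 120000)
  fit <- density_regression(areas, 0.00032 * areas)
  expect_equal(1000 * fit$slope, 0.32, tolerance = 1e-12)
  expect_equal(fit$spacing_nm, 1 / sqrt(0.00032), tolerance = 1e-12)
  expect_equal(round(fit$spacing_nm), 56)
  # random scatter: closed-form sum(a c)/sum(a^2)
  set.seed(71)
  a <- runif(50, 5000, 80000)
  cts <- 0.0003 * a + rnorm(50, 0, 2)
  fit2 <- density_regression(a, cts)
  expect_equal(fit2$slope, sum(a * cts) / sum(a * a), tolerance = 1e-12)
  # single cluster: slope = count/area exactly
  fit1 <- density_regression(30000, 9)
  expect_equal(fit1$slope, 9 / 30000)
  g <- glance(fit2)
  expect_true(all(c("slope_per_1000nm2", "spacing_nm") %in% names(g)))
})

test_that("desk conversions: lattice packing area and density-to-spacing", {
  expect_equal(packing_area(31.5), 992.25)
  expect_equal(spacing_from_density(0.32 / 1000), 55.90, tolerance = 1e-3)
})
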