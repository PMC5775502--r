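test_that("a single-site cluster sits at its origin", {
  cl <- simulate_cluster(1, seed = 7)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$x_nm, cl$y_nm), c(0, 0))
  expect_error(simulate_cluster(0), "n_sites")
})

test_that("assembly is deterministic under a fixed seed and respects the hard core", {
  p <- assembly_params(min_separation = 30)
  a <- simulate_cluster(12, p, seed = 101)
  b <- simulate_cluster(12, p, seed = 101)
  expect_identical(a, b)
  d <- dist(cbind(a$x_nm, a$y_nm))
  expect_true(min(d) >= 30)
  # two-site case: center distance at least the exclusion radius
  p2 <- assembly_params(min_separation = 30)
  two <- simulate_cluster(2, p2, seed = 5)
  d2 <- sqrt(diff(two$x_nm)^2 + diff(two$y_nm)^2)
  expect_gte(d2, 30)
  expect_equal(
    sqrt(diff(simulate_cluster(2, p2, seed = 5)$x_nm)^2 +
         diff(simulate_cluster(2, p2, seed = 5)$y_nm)^2),
    d2
  )
})

test_that("accepted step distances follow the configured normal law", {
  # an unconstrained configuration (tiny hard core, no nearest-spacing
  # rejection) accepts every draw, so the recorded steps are exactly
  # Normal(step_mean, step_sigma)
  p <- assembly_params(step_mean = 40, step_sigma = 7.4, min_separation = 1,
                       anchor = "uniform", nearest_spacing = FALSE)
  steps <- withr::with_seed(42, {
    unlist(lapply(1:100, function(i) attr(simulate_cluster(51, p), "steps")))
  })
  expect_equal(length(steps), 5000L)
  expect_lt(abs(mean(steps) - 40), 0.5)
  expect_lt(abs(sd(steps) - 7.4), 0.5)
})

test_that("placement retry exhaustion signals an infeasible-geometry error", {
  # an over-tight hard core relative to the step makes growth impossible
  p <- assembly_params(step_mean = 40, step_sigma = 0.1, min_separation = 39,
                       max_placement_retries = 5, nearest_spacing = TRUE)
  expect_error(
    simulate_cluster(40, p, seed = 1),
    class = "nanopaint_infeasible_geometry"
  )
})

test_that("cluster sizes follow the truncated exponential law", {
  p <- assembly_params(size_mean = 8.8, size_max = 40L)
  sizes <- sample_cluster_sizes(10000, p, seed = 11)
  expect_true(all(sizes >= 1 & sizes <= 40))
  expected <- truncated_size_mean(8.8, 40)
  expect_lt(abs(mean(sizes) / expected - 1), 0.03)
  # truncation at 1 forces the floor
  p1 <- assembly_params(size_mean = 8.8, size_max = 1L)
  expect_true(all(sample_cluster_sizes(200, p1, seed = 2) == 1L))
})

test_that("detection flags are independent Bernoulli draws leaving positions unchanged", {
  sites <- simulate_cluster(20, seed = 3)
  all_on <- apply_detection_fraction(sites, 1, seed = 1)
  expect_true(all(all_on$detected))
  none <- apply_detection_fraction(sites, 0, seed = 1)
  expect_false(any(none$detected))
  expect_equal(none$x_nm, sites$x_nm)
  big <- build_test_field(rep(25, 20), pitch = 1500)
  big <- do.call(rbind, replicate(20, big, simplify = FALSE))
  det <- apply_detection_fraction(big, 0.6, seed = 9)
  n <- nrow(big)
  bound <- 3 * sqrt(n * 0.6 * 0.4)
  expect_lt(abs(sum(det$detected) - 0.6 * n), bound)
})

test_that("JPH2 placement honors the bound pool and the target ratio", {
  ryr <- build_test_field(rep(10, 8), pitch = 1500)
  allbound <- place_jph2(ryr, jph_params(bound_fraction = 1, bound_radius = 20),
                         seed = 4)
  d <- nanopaint:::min_cross_dist(cbind(allbound$x_nm, allbound$y_nm),
                                  cbind(ryr$x_nm, ryr$y_nm))
  expect_true(all(d <= 20 + 1e-9))

  # ratio recovery over many clusters
  field <- simulate_field(500, assembly_params(), seed = 21)
  jph <- place_jph2(field, jph_params(ratio_mean = 1.38), seed = 22)
  per_ryr <- table(factor(field$cluster_id, levels = unique(field$cluster_id)))
  per_jph <- table(factor(jph$cluster_id, levels = unique(field$cluster_id)))
  ratios <- as.numeric(per_jph) / as.numeric(per_ryr)
  expect_lt(abs(mean(ratios) / 1.38 - 1), 0.05)
})

test_that("unbound JPH2 is uniform over the junction region", {
  ryr <- withr::with_seed(31, build_test_field(20))
  jp <- jph_params(bound_fraction = 0, sparse_region_scale = 3,
                   ratio_mean = 30) # many points for the two-sample test
  jph <- place_jph2(ryr, jp, seed = 32)
  # oracle: direct uniform rejection sampling over the same polygon
  poly <- nanopaint:::junction_polygon(cbind(ryr$x_nm, ryr$y_nm), 3)
  oracle <- withr::with_seed(33, nanopaint:::sample_in_polygon(2000, poly))
  d_obs <- nanopaint:::min_cross_dist(cbind(jph$x_nm, jph$y_nm),
                                      cbind(ryr$x_nm, ryr$y_nm))
  d_orc <- nanopaint:::min_cross_dist(oracle, cbind(ryr$x_nm, ryr$y_nm))
  expect_gt(suppressWarnings(stats::ks.test(d_obs, d_orc)$p.value), 0.01)
})
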