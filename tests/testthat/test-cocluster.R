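test_that("identical punctum sets match perfectly and symmetrically", {
  s <- withr::with_seed(1, tibble::tibble(x_nm = runif(25, 0, 800),
                                          y_nm = runif(25, 0, 800)))
  m <- match_puncta(s, s, cutoff = 20)
  expect_equal(nrow(m$pairs), 25L)
  expect_equal(m$median_displacement_nm, 0)
  expect_equal(unname(m$fraction_within["5nm"]), 1)
  # symmetry: match(A,B) and match(B,A) pair the same puncta
  s2 <- dplyr::mutate(s, x_nm = x_nm + rnorm(25, 0, 1))
  ab <- match_puncta(s, s2, cutoff = 20)
  ba <- match_puncta(s2, s, cutoff = 20)
  expect_equal(ab$pairs$idx_a[order(ab$pairs$idx_a)],
               ba$pairs$idx_b[order(ba$pairs$idx_b)])
  expect_equal(ab$median_displacement_nm, ba$median_displacement_nm)
  expect_error(match_puncta(s[0, ], s), class = "nanopaint_empty_input")
})

test_that("a rigid 3-nm shift reads out as a 3-nm median displacement", {
  s <- withr::with_seed(2, tibble::tibble(x_nm = runif(40, 0, 1500),
                                          y_nm = runif(40, 0, 1500)))
  shifted <- dplyr::mutate(s, x_nm = x_nm + 3)
  m <- match_puncta(s, shifted, cutoff = 20)
  expect_equal(m$median_displacement_nm, 3, tolerance = 1e-12)
  expect_equal(unname(m$fraction_within["5nm"]), 1)
  reg <- register_puncta(s, shifted)
  expect_equal(reg$shift, c(-3, 0), tolerance = 1e-9)
})

test_that("greedy matching agrees with exhaustive optimal assignment on small instances", {
  for (seed in 1:6) {
    n <- withr::with_seed(seed + 50, sample(4:12, 1))
    base <- withr::with_seed(seed, tibble::tibble(
      x_nm = runif(n, 0, 120 * n), y_nm = runif(n, 0, 120 * n)
    ))
    # enforce separation well above the jitter so the optimum is unambiguous
    keep <- brute_nnd(base$x_nm, base$y_nm) > 60
    base <- base[keep, , drop = FALSE]
    n <- nrow(base)
    if (n < 3) next
    perm <- withr::with_seed(seed + 100, sample(n))
    jit <- withr::with_seed(seed + 200, tibble::tibble(
      x_nm = base$x_nm[perm] + rnorm(n, 0, 2),
      y_nm = base$y_nm[perm] + rnorm(n, 0, 2)
    ))
    m <- match_puncta(base, jit, cutoff = 25)
    expect_equal(nrow(m$pairs), n)
    oracle <- brute_assignment(base$x_nm, base$y_nm, jit$x_nm, jit$y_nm)
    got <- m$pairs$idx_b[order(m$pairs$idx_a)]
    expect_equal(got, oracle)
    # and the optimal pairing recovers the planted permutation
    expect_equal(oracle, order(perm))
  }
})

test_that("uniform markers produce a flat radial profile matching the control", {
  ryr <- simulate_cluster(20, seed = 11)
  poly <- nanopaint:::junction_polygon(cbind(ryr$x_nm, ryr$y_nm), 3)
  mask <- polygon_mask(poly, pixel_size = 2)
  jph <- withr::with_seed(12, {
    xy <- nanopaint:::sample_in_polygon(1500, poly)
    tibble::tibble(x_nm = xy[, 1], y_nm = xy[, 2])
  })
  prof <- radial_density(ryr, jph, mask, bin_width = 10, seed = 13)
  # chi-square across bins with expectation proportional to bin area
  keep <- prof$area_nm2 > 0 & prof$n + prof$control_n > 0
  expected <- sum(prof$n[keep]) * prof$area_nm2[keep] / sum(prof$area_nm2[keep])
  chi <- sum((prof$n[keep] - expected)^2 / expected)
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  # no markers: all-zero densities
  prof0 <- radial_density(ryr, jph[0, ], mask, seed = 14)
  expect_true(all(prof0$n == 0))
  expect_true(all(prof0$density[prof0$area_nm2 > 0] == 0))
})

test_that("a bound JPH2 pool shows >5-fold density within 50 nm of RyRs", {
  sites <- simulate_field(60, seed = 21)
  jph <- place_jph2(sites, jph_params(bound_fraction = 0.8, bound_radius = 20,
                                      sparse_region_scale = 3), seed = 22)
  ids <- unique(sites$cluster_id)
  masks <- lapply(ids, function(id) {
    s <- sites[sites$cluster_id == id, ]
    polygon_mask(nanopaint:::junction_polygon(cbind(s$x_nm, s$y_nm), 3),
                 pixel_size = 2)
  })
  names(masks) <- as.character(ids)
  prof <- radial_density(sites, jph, masks, bin_width = 10, seed = 23)
  expect_gte(fold_enrichment(prof, 50), 5)
})

test_that("trivial molecular ratios follow N_J / N_R", {
  # ratio arithmetic on constructed counts
  expect_equal(27 / 20, 1.35)
  rr <- tibble::tibble(n_r = c(20, 16), n_j = c(27, 16))
  rr$r_j_r <- rr$n_j / rr$n_r
  expect_equal(rr$r_j_r, c(1.35, 1))
})

test_that("exchange qPAINT recovers generator co-clustering ratios monotonically", {
  run_ratio <- function(ratio_mean, seed) {
    withr::with_seed(seed, {
      asm <- assembly_params(size_mean = 25, size_max = 40)
      sizes <- pmax(sample_cluster_sizes(16, asm), 18)
      sites <- build_test_field(sizes, asm, pitch = 1100)
      jph <- place_jph2(sites, jph_params(ratio_mean = ratio_mean))
      kin <- kinetics_params(site_binding_rate = 0.002, mean_bright_time = 1,
                             frame_time = 0.1, n_frames = 200000L)
      rev_ <- simulate_paint_events(sites, kin, channel = "ryr")
      jev <- simulate_paint_events(jph, kin, channel = "jph2")
      r <- render_density(rev_, pixel_size = 2, sigma = 12)
      cs <- segment_clusters(r, rev_)
      unit <- 0.002 * (nrow(attr(rev_, "binding_truth") %>%
                              dplyr::filter(n_frames_emitted > 0)) /
                         nrow(attr(rev_, "binding_truth")))
      rr <- molecular_ratio(cs, rev_, jev, ryr_unit = unit, jph_unit = unit,
                            frame_time = kin$frame_time, dilate_nm = 80,
                            estimator = "rate")
      mean(rr$r_j_r)
    })
  }
  means <- vapply(c(0.5, 1.38, 2.0), run_ratio, numeric(1), seed = 31)
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[2] / 1.38 - 1), 0.10)
  expect_lt(abs(means[1] / 0.5 - 1), 0.15)
  expect_lt(abs(means[3] / 2.0 - 1), 0.10)
})
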