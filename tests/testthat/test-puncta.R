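test_that("a single labeled site yields one punctum at its position", {
  ev <- withr::with_seed(1, loc_tibble(rnorm(50, 200, 5), rnorm(50, 150, 5)))
  p <- detect_puncta(ev)
  expect_equal(nrow(p), 1L)
  # SEM of the centroid is sigma/sqrt(n) ~ 0.7 nm; 2 nm is a generous bound
  expect_lt(abs(p$x_nm - 200), 2)
  expect_lt(abs(p$y_nm - 150), 2)
  expect_equal(p$n_events, 50L)
  expect_equal(nrow(detect_puncta(loc_tibble(numeric(0), numeric(0)))), 0L)
})

test_that("a 30-nm grid is resolved into distinct puncta", {
  kin <- kinetics_params(site_binding_rate = 0.01, mean_bright_time = 0.5,
                         frame_time = 0.1, n_frames = 60000L,
                         loc_precision_sigma = 5)
  hits <- vapply(1:3, function(s) {
    g <- simulate_grid(30, 4, 4, kin, seed = s)
    p <- detect_puncta(g$events)
    if (!nrow(p)) return(0)
    d <- nanopaint:::cross_dist(cbind(g$sites$x_nm, g$sites$y_nm),
                                cbind(p$x_nm, p$y_nm))
    sum(apply(d, 1, min) <= 10)
  }, numeric(1))
  expect_true(all(hits >= 0.9 * 16))
})

test_that("NND and 4ND equal their brute-force oracles exactly", {
  pts <- withr::with_seed(5, tibble::tibble(
    cluster_id = 1L, x_nm = runif(20, 0, 400), y_nm = runif(20, 0, 400)
  ))
  nnd <- nearest_neighbor_distances(pts, min_cluster_size = 2)
  expect_equal(nnd$nnd_nm, brute_nnd(pts$x_nm, pts$y_nm))
  fnd <- four_neighbor_distances(pts)
  expect_equal(fnd$fournd_nm, brute_fournd(pts$x_nm, pts$y_nm))
  # 4ND dominates NND per punctum, always
  expect_true(all(fnd$fournd_nm >= nnd$nnd_nm))
})

test_that("lattice distances come out exactly", {
  g <- expand.grid(x = 0:3, y = 0:3)
  pts <- tibble::tibble(cluster_id = 1L, x_nm = 30 * g$x, y_nm = 30 * g$y)
  nnd <- nearest_neighbor_distances(pts)
  expect_true(all(nnd$nnd_nm == 30))
  fnd <- four_neighbor_distances(pts)
  # interior points have four equidistant neighbors
  interior <- pts$x_nm %in% c(30, 60) & pts$y_nm %in% c(30, 60)
  expect_true(all(fnd$fournd_nm[interior] == 30))
  # two puncta 40 nm apart: both NNDs are 40 (size floor of 2)
  two <- tibble::tibble(cluster_id = 1L, x_nm = c(0, 40), y_nm = 0)
  expect_equal(nearest_neighbor_distances(two, 2)$nnd_nm, c(40, 40))
  # fewer than the size floor: empty result
  expect_equal(nrow(nearest_neighbor_distances(two, 5)), 0L)
  expect_equal(nrow(four_neighbor_distances(two)), 0L)
})

test_that("distance fields equal brute-force evaluation", {
  mask <- polygon_mask(cbind(c(0, 200, 200, 0), c(0, 0, 150, 150)),
                       pixel_size = 2)
  one <- tibble::tibble(x_nm = 77, y_nm = 63)
  gm <- gap_map(one, mask, gap_threshold = 60)
  w <- which(mask$mask, arr.ind = TRUE)
  px <- mask$origin[1] + (w[, 2] - 0.5) * 2
  py <- mask$origin[2] + (w[, 1] - 0.5) * 2
  expect_equal(gm$distance_field$pixels[w],
               sqrt((px - 77)^2 + (py - 63)^2))
  # two puncta: pixel-wise minimum of the radial fields
  two <- tibble::tibble(x_nm = c(40, 160), y_nm = c(40, 100))
  gm2 <- gap_map(two, mask, gap_threshold = 60)
  brute <- pmin(sqrt((px - 40)^2 + (py - 40)^2),
                sqrt((px - 160)^2 + (py - 100)^2))
  expect_equal(gm2$distance_field$pixels[w], brute)
  expect_error(gap_map(two[0, ], mask), "punctum")
})

test_that("an engineered 150-nm void appears as one gap region", {
  p <- assembly_params()
  a <- simulate_cluster(12, p, seed = 1)
  b <- simulate_cluster(12, p, seed = 2)
  b$x_nm <- b$x_nm + max(a$x_nm) - min(b$x_nm) + 150
  both <- dplyr::bind_rows(a, dplyr::mutate(b, cluster_id = 1L))
  poly <- nanopaint:::junction_polygon(cbind(both$x_nm, both$y_nm), 1)
  gm <- gap_map(both, polygon_mask(poly, pixel_size = 2),
                gap_threshold = 100)
  expect_equal(nrow(gm$gap_regions), 1L)
  expect_gt(gm$gap_regions$max_distance_nm, 100)
})

test_that("detection-fraction sweep reproduces full-detection statistics at fraction 1", {
  sw <- detection_fraction_experiment(n_clusters = 150, seed = 40)
  full <- sw$summary[sw$summary$fraction == 1, ]
  sites <- sw$sites
  expect_equal(full$mean_nnd_nm,
               mean(nearest_neighbor_distances(sites)$nnd_nm))
  expect_equal(full$mean_fournd_nm,
               mean(four_neighbor_distances(sites)$fournd_nm))
  # mean 4ND is monotonically non-decreasing as the fraction decreases
  s <- sw$summary[order(-sw$summary$fraction), ]
  expect_true(all(diff(s$mean_fournd_nm) >= 0))
})

test_that("the NND histogram mode is stable under subsampling", {
  # missed detections add a long tail to the NND distribution but leave its
  # 40-nm mode in place (5-nm histogram bins over 0-200 nm)
  sw <- detection_fraction_experiment(n_clusters = 400, seed = 42)
  modes <- vapply(sw$values$nnd_nm, function(v) {
    h <- hist(v[v <= 200], breaks = seq(0, 200, 5), plot = FALSE)
    h$mids[which.max(h$counts)]
  }, numeric(1))
  expect_lte(max(modes) - min(modes), 5)
})
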