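# ROI splitting, endpoint classification, signal-detection statistics,
# and the medial-lateral endpoint histogram.

test_that("a slab ROI splits into two equal halves along the hint axis", {
  roi <- volume_grid(array(0, c(12L, 16L, 12L)))
  roi$data[6:7, 4:13, 6:7] <- 1               # 2 x 10 x 2 slab along y
  sp <- split_roi(roi, "y")
  expect_equal(sum(sp$anterior_mask$data), 20)
  expect_equal(sum(sp$posterior_mask$data), 20)
  expect_equal(sum(sp$anterior_mask$data * sp$posterior_mask$data), 0)
  expect_equal(sp$anterior_mask$data + sp$posterior_mask$data, roi$data)
  expect_equal(abs(sp$axis), c(0, 1, 0), tolerance = 1e-9)
  expect_gt(sum(sp$axis * c(0, 1, 0)), 0)     # sign-aligned with the hint
  # anterior half really is the high-y half
  ya <- voxel_centers(sp$anterior_mask)[, 2]
  yp <- voxel_centers(sp$posterior_mask)[, 2]
  expect_gt(min(ya), max(yp))
  expect_error(split_roi(volume_grid(array(0, c(8L, 8L, 8L)))), ">= 2")
})

test_that("degenerate ROIs fall back to the hint axis and stay balanced", {
  # ball: principal directions not unique
  roi <- volume_grid(array(0, c(15L, 15L, 15L)))
  idx <- which(array(TRUE, c(15L, 15L, 15L)), arr.ind = TRUE) - 1
  r2 <- rowSums(sweep(idx, 2, c(7, 7, 7))^2)
  roi$data[r2 <= 16] <- 1
  sp <- split_roi(roi, "y")
  n <- sum(roi$data)
  expect_lte(abs(sum(sp$anterior_mask$data) - sum(sp$posterior_mask$data)), 1)
  expect_equal(sum(sp$anterior_mask$data + sp$posterior_mask$data), n)
  expect_equal(sp$axis, c(0, 1, 0))
  # odd voxel count: the tie goes anterior
  roi2 <- volume_grid(array(0, c(9L, 9L, 9L)))
  roi2$data[5, 3:7, 5] <- 1
  sp2 <- split_roi(roi2, "y")
  expect_equal(sum(sp2$anterior_mask$data), 3)
  expect_equal(sum(sp2$posterior_mask$data), 2)
})

test_that("the phantom split separates the gradient map's extremes", {
  ph <- default_phantom()
  sp <- default_split()
  g <- ph$gradient_map$data
  mean_ant <- mean(g[sp$anterior_mask$data != 0])
  mean_pos <- mean(g[sp$posterior_mask$data != 0])
  expect_gt(mean_ant, mean_pos)   # gradient increases toward anterior
})

test_that("endpoint classification follows the distance rules", {
  roi <- volume_grid(array(0, c(12L, 16L, 12L)))
  roi$data[6:7, 4:13, 6:7] <- 1
  sp <- split_roi(roi, "y")
  at_anterior <- rbind(c(5, 0, 5), c(5, 12, 5))   # ends at an anterior center
  far <- rbind(c(5, 0, 5), c(0, 25, 0))           # > 2 mm from any voxel
  at_posterior <- rbind(c(5, 0, 5), c(5, 3, 5))
  cl <- classify_by_endpoint(tractogram(list(at_anterior, far, at_posterior)),
                             sp)
  expect_equal(as.character(cl$labels), c("PRO1", "UNASSIGNED", "PRO2"))
  expect_equal(sum(cl$proportions), 1)
  expect_equal(unname(cl$proportions), rep(1 / 3, 3))
  expect_error(classify_by_endpoint(tractogram(list()), sp), "empty")
})

test_that("endpoint classification recovers the phantom's labels", {
  ph <- default_phantom()
  cl <- classify_by_endpoint(ph$bundles, default_split())
  expect_gte(mean(as.character(cl$labels) == ph$labels), 0.95)
  expect_equal(sum(cl$proportions), 1)
})

test_that("d-prime reproduces the published worked examples", {
  # printed: d' = 1.90 at hits 90.1%, false alarms 26.9%
  expect_equal(detection_stats(0.901, 0.269)$d_prime, 1.90,
               tolerance = 0.005 / 1.90)
  # printed: d' = 2.24 at hits 88.5%, false alarms 14.7%; recomputation
  # from the rounded rates gives 2.2507, hence the wider band
  expect_equal(detection_stats(0.885, 0.147)$d_prime, 2.24,
               tolerance = 0.02 / 2.24)
  # z(0.97725) = 2, z(0.5) = 0
  expect_equal(detection_stats(0.97725, 0.5)$d_prime, 2.0, tolerance = 1e-4)
})

test_that("d-prime is antisymmetric, monotone, and clamped at the edges", {
  expect_equal(detection_stats(0.4, 0.4)$d_prime, 0)
  expect_equal(detection_stats(0.3, 0.8)$d_prime,
               -detection_stats(0.8, 0.3)$d_prime)
  hits <- seq(0.05, 0.95, by = 0.1)
  dps <- vapply(hits, function(h) detection_stats(h, 0.2)$d_prime, numeric(1))
  expect_true(all(diff(dps) > 0))
  # perfect rates need n and clamp to 1/(2N)
  expect_error(detection_stats(1, 0.2), "needs n")
  ds <- detection_stats(1, 0, n = 50)
  expect_equal(ds$d_prime,
               stats::qnorm(1 - 1 / 100) - stats::qnorm(1 / 100))
  expect_true(is.finite(ds$d_prime))
  expect_error(detection_stats(1.2, 0.5), "rates")
})

test_that("subcomponent detection counts the 2x2 table as declared", {
  membership <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  term <- c("anterior", "anterior", "posterior", "none",
            "posterior", "anterior")
  ds <- subcomponent_detection(membership, term, "anterior")
  # 3 assigned subcomponent fibers: 2 anterior, 1 posterior
  expect_equal(ds$hits, 2 / 3)
  expect_equal(ds$false_alarms, 1 / 3)
  expect_equal(ds$n, 3)
  expect_error(subcomponent_detection(rep(FALSE, 3),
                                      rep("anterior", 3), "anterior"),
               "zero fibers")
})

test_that("the endpoint histogram sorts voxels medially to laterally", {
  roi <- volume_grid(array(0, c(10L, 6L, 6L)))
  roi$data[c(2, 5, 8), 3, 3] <- 1             # centers at x = 1, 4, 7
  one_center <- rbind(c(1, 2, 2), c(20, 2, 2))
  h <- endpoint_histogram(tractogram(list(one_center)), roi)
  expect_equal(h$x_mm, c(1, 4, 7))
  expect_equal(h$count, c(1, 0, 0))
  # empty tractogram -> all-zero histogram
  h0 <- endpoint_histogram(tractogram(list()), roi)
  expect_equal(h0$count, c(0, 0, 0))
  expect_error(endpoint_histogram(tractogram(list()),
                                  volume_grid(array(0, c(4L, 4L, 4L)))),
               "empty")
  # a single endpoint within 2 mm of two voxel centers counts in both
  roi2 <- volume_grid(array(0, c(10L, 6L, 6L)))
  roi2$data[4:5, 3, 3] <- 1                   # centers x = 3 and 4
  h2 <- endpoint_histogram(tractogram(list(rbind(c(3.5, 2, 2),
                                                 c(30, 2, 2)))), roi2)
  expect_equal(h2$count, c(1, 1))
})

test_that("phantom seed endpoints are retinotopically ordered", {
  ph <- default_phantom()
  pro1 <- tractogram(ph$bundles$streamlines[ph$labels == "PRO1"],
                     validate = FALSE)
  pro2 <- tractogram(ph$bundles$streamlines[ph$labels == "PRO2"],
                     validate = FALSE)
  h1 <- endpoint_histogram(pro1, ph$seed_roi)
  h2 <- endpoint_histogram(pro2, ph$seed_roi)
  m1 <- sum(h1$x_mm * h1$count) / sum(h1$count)
  m2 <- sum(h2$x_mm * h2$count) / sum(h2$count)
  expect_lt(m1, m2)      # dorsal component enters medially
})
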