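# Geometry primitives: resampling, length, ROI distance criterion,
# exclusion planes, dilation.

test_that("resampling places nodes at exact equal spacing", {
  s <- rbind(c(0, 0, 0), c(0, 0, 9.9))
  r <- resample_streamline(s, 100)
  seg <- diff(r[, 3])
  expect_equal(seg, rep(0.1, 99), tolerance = 1e-12)
  expect_identical(r[1, ], s[1, ])
  expect_identical(r[100, ], s[2, ])
  # n = 2 returns the endpoints
  expect_equal(resample_streamline(quarter_circle(), 2),
               quarter_circle()[c(1, 200), ], ignore_attr = TRUE)
  expect_error(resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1)), 10),
               "zero-length")
  expect_error(resample_streamline(s, 1), ">= 2")
})

test_that("arc length is preserved through resampling", {
  qc <- quarter_circle(r = 10)
  r <- resample_streamline(qc, 100)
  expect_equal(streamline_length(r), 5 * pi, tolerance = 0.01 * 5 * pi)
  # resampling invariance property over a set of smooth fixtures
  set.seed(31)
  for (i in 1:5) {
    tt <- seq(0, 1, length.out = 300)
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    s <- cbind(10 * tt + sin(2 * pi * tt * a[1]),
               10 * tt * b[1] + cos(2 * pi * tt * a[2]),
               5 * sin(pi * tt * b[2]))
    l0 <- streamline_length(s)
    expect_lt(abs(streamline_length(resample_streamline(s, 100)) - l0) / l0,
              0.01)
  }
  # idempotence at fixed n: exact on equal-segment inputs, and a fixed
  # point of the map on smooth curves
  line <- resample_streamline(rbind(c(0, 0, 0), c(3, 4, 12)), 100)
  expect_lt(max(abs(line - resample_streamline(line, 100))), 1e-12)
  # on curved polylines the map converges quadratically to its fixed
  # point; successive applications shrink fast and settle below 1e-9
  r1 <- resample_streamline(qc, 100)
  r2 <- resample_streamline(r1, 100)
  r3 <- resample_streamline(r2, 100)
  r4 <- resample_streamline(r3, 100)
  expect_lt(max(abs(r2 - r3)), max(abs(r1 - r2)))
  expect_lt(max(abs(r3 - r4)), 1e-9)
})

test_that("streamline_length sums Euclidean segments", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(streamline_length(sq), 4)
})

test_that("ROI intersection uses an inclusive distance to voxel centers", {
  roi <- volume_grid(array(0, c(9L, 9L, 9L)))
  roi$data[5, 5, 5] <- 1                      # center at world (4, 4, 4)
  hit <- rbind(c(4, 4, 4), c(8, 8, 8))
  expect_true(intersects_roi(hit, roi))
  far <- rbind(c(4, 4, 9.001), c(4, 4, 12))   # nearest approach > 5 mm
  expect_false(intersects_roi(far, roi, max_dist = 2))
  # boundary exactly 2.0 mm: inclusive
  edge <- rbind(c(4, 4, 6), c(4, 4, 8))
  expect_true(intersects_roi(edge, roi, max_dist = 2))
  expect_false(intersects_roi(rbind(c(4, 4, 6 + 1e-6), c(4, 4, 8)),
                              roi, max_dist = 2))
  # monotone in max_dist and under dilation
  mid <- rbind(c(4, 4, 7), c(4, 4, 9))
  expect_false(intersects_roi(mid, roi, max_dist = 2))
  expect_true(intersects_roi(mid, roi, max_dist = 3))
  expect_true(intersects_roi(mid, dilate_mask(roi, 1), max_dist = 2))
  expect_error(intersects_roi(hit, volume_grid(array(0, c(4L, 4L, 4L)))),
               "empty")
})

test_that("exclusion planes drop the declared streamlines", {
  above <- rbind(c(0, 0, 5), c(1, 0, 6), c(2, 0, 7))
  below <- rbind(c(0, 0, -5), c(1, 0, -6))
  crossing <- rbind(c(0, 0, 8), c(0, 0, 12))
  t <- tractogram(list(above, below, crossing))
  keep_pos <- exclusion_plane(c(0, 0, 0), c(0, 0, 1), "keep_side_positive")
  expect_equal(attr(filter_by_planes(t, list(keep_pos)), "kept"),
               c(TRUE, FALSE, TRUE))
  keep_neg <- exclusion_plane(c(0, 0, 0), c(0, 0, 1), "keep_side_negative")
  expect_equal(attr(filter_by_planes(t, list(keep_neg)), "kept"),
               c(FALSE, TRUE, FALSE))
  cross10 <- exclusion_plane(c(0, 0, 10), c(0, 0, 1), "remove_crossing")
  expect_equal(attr(filter_by_planes(t, list(cross10)), "kept"),
               c(TRUE, TRUE, FALSE))
  # a point exactly on the plane counts as crossing
  touch <- tractogram(list(rbind(c(0, 0, 10), c(0, 0, 11))))
  expect_equal(n_streamlines(filter_by_planes(touch, list(cross10))), 0L)
  # conjunctive application, output subset of input, order-insensitive
  both <- filter_by_planes(t, list(keep_pos, cross10))
  expect_equal(attr(both, "kept"), c(TRUE, FALSE, FALSE))
  expect_lte(n_streamlines(both), n_streamlines(t))
  expect_equal(attr(filter_by_planes(t, list(cross10, keep_pos)), "kept"),
               attr(both, "kept"))
})

test_that("a mid-separation plane recovers the phantom's dorsal/ventral split", {
  ph <- default_phantom()
  ext <- (ph$spec$grid_shape - 1) * ph$spec$voxel_size
  zmid <- ext[3] / 2
  dz <- ph$spec$bundle_separation / 4
  dorsal <- attr(filter_by_planes(
    ph$bundles,
    list(exclusion_plane(c(0, 0, zmid - dz), c(0, 0, 1),
                         "keep_side_positive"))), "kept")
  agree <- mean((ph$labels == "PRO1") == dorsal)
  expect_gte(agree, 0.95)
})

test_that("6-connected dilation grows as the brute-force oracle says", {
  roi <- volume_grid(array(0, c(11L, 11L, 11L)))
  roi$data[6, 6, 6] <- 1
  expect_equal(sum(dilate_mask(roi, 1)$data), 7)
  expect_identical(dilate_mask(roi, 0)$data, roi$data)
  # oracle: explicit two-pass 6-neighbour growth
  grow <- function(m) {
    out <- m
    idx <- which(m != 0, arr.ind = TRUE)
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    for (r in seq_len(nrow(idx)))
      for (o in seq_len(6)) {
        p <- idx[r, ] + offs[o, ]
        if (all(p >= 1 & p <= dim(m))) out[p[1], p[2], p[3]] <- 1
      }
    out
  }
  oracle2 <- grow(grow(roi$data))
  d2 <- dilate_mask(roi, 2)
  expect_equal(sum(d2$data), sum(oracle2))
  expect_equal(sum(d2$data), 25)
  expect_identical(d2$data, oracle2)
})
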