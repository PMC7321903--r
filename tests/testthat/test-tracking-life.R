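# Deterministic ensemble tracking and NNLS streamline pruning.

test_that("bend limit follows the curvature geometry", {
  expect_equal(max_bend_angle(1, 1), 60)        # 2 asin(0.5)
  expect_equal(max_bend_angle(0.5, 4), 2 * asin(0.5 / 8) * 180 / pi)
  expect_equal(max_bend_angle(2, 0.5), 180)     # unconstrained
})

test_that("a straight tensor bridge yields monotone connecting streamlines", {
  w <- bridge_world()
  cfg <- tracking_config(max_fibers = 40L, max_trials = 400L, rng_seed = 9L,
                         min_length_mm = 5)
  tr <- track_single(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg,
                     radius = 1, w$roi_a, w$roi_b)
  expect_gt(n_streamlines(tr), 0)
  step <- 0.5
  theta_max <- max_bend_angle(step, 1)
  for (s in tr$streamlines) {
    expect_true(all(diff(s[, 1]) > 0) || all(diff(s[, 1]) < 0))
    d <- diff(s)
    d <- d / sqrt(rowSums(d^2))
    if (nrow(d) > 1) {
      ang <- acos(pmin(1, rowSums(d[-1, , drop = FALSE] *
                                  d[-nrow(d), , drop = FALSE]))) * 180 / pi
      expect_lt(max(ang), theta_max + 1e-6)
    }
    expect_true(intersects_roi(s, w$roi_a) && intersects_roi(s, w$roi_b))
  }
})

test_that("tracking is deterministic and respects its budgets", {
  w <- bridge_world()
  cfg <- tracking_config(max_fibers = 20L, max_trials = 300L, rng_seed = 17L,
                         min_length_mm = 5)
  t1 <- track_single(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg, 2,
                     w$roi_a, w$roi_b)
  t2 <- track_single(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg, 2,
                     w$roi_a, w$roi_b)
  expect_identical(t1$streamlines, t2$streamlines)
  expect_lte(n_streamlines(t1), 20L)
  # zero trial budget -> empty result
  cfg0 <- tracking_config(max_fibers = 0L, max_trials = 0L)
  expect_warning(
    t0 <- track_single(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg0, 1,
                       w$roi_a, w$roi_b),
    "no streamlines")
  expect_equal(n_streamlines(t0), 0L)
  # empty seed mask is a usage error
  empty <- volume_grid(array(0, dim(w$wm$data)))
  expect_error(track_single(w$tensors, w$wm, empty, cfg, 1,
                            w$roi_a, w$roi_b), "seed mask")
})

test_that("an isotropic field tracks nothing, with a warning", {
  n <- c(16L, 10L, 10L)
  coefficients <- array(0, c(n, 6))
  for (p in c(1, 3, 6)) coefficients[, , , p] <- 8e-4
  tens <- tensor_field(coefficients, array(1, n), volume_grid(array(1, n)))
  wm <- volume_grid(array(1, n))
  roi_a <- volume_grid(array(0, n)); roi_a$data[2, , ] <- 1
  roi_b <- volume_grid(array(0, n)); roi_b$data[15, , ] <- 1
  cfg <- tracking_config(max_fibers = 10L, max_trials = 100L, rng_seed = 3L)
  expect_warning(
    tr <- track_single(tens, wm, roi_union(roi_a, roi_b), cfg, 1,
                       roi_a, roi_b),
    "no streamlines")
  expect_equal(n_streamlines(tr), 0L)
})

test_that("the ensemble is the concatenation of per-radius runs", {
  w <- bridge_world()
  cfg <- tracking_config(curvature_radii = c(0.5, 1, 2),
                         max_fibers = 10L, max_trials = 200L, rng_seed = 5L,
                         min_length_mm = 5)
  ens <- ensemble_track(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg,
                        w$roi_a, w$roi_b)
  prov <- attr(ens, "provenance")
  expect_equal(nrow(prov), 3L)
  expect_equal(n_streamlines(ens), sum(prov$n_streamlines))
  # single-radius ensemble == track_single
  cfg1 <- tracking_config(curvature_radii = 1, max_fibers = 10L,
                          max_trials = 200L, rng_seed = 5L,
                          min_length_mm = 5)
  ens1 <- ensemble_track(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg1,
                         w$roi_a, w$roi_b)
  single <- track_single(w$tensors, w$wm, roi_union(w$roi_a, w$roi_b), cfg1,
                         1, w$roi_a, w$roi_b)
  expect_identical(ens1$streamlines, single$streamlines)
})

test_that("tracked phantom streamlines reach both target halves", {
  tr <- default_tracking()
  ph <- default_phantom()
  expect_gt(n_streamlines(tr), 0)
  cl <- classify_by_endpoint(tr, default_split())
  expect_gt(sum(cl$labels == "PRO1"), 0)
  expect_gt(sum(cl$labels == "PRO2"), 0)
})

# ---- LiFE pruning ---------------------------------------------------------

test_that("aligned candidates are kept, orthogonal ones zeroed", {
  w <- single_voxel_world(axis = c(1, 0, 0))
  aligned <- rbind(c(1, 2, 2), c(2, 2, 2), c(3, 2, 2))
  orthogonal <- rbind(c(2, 1, 2), c(2, 2, 2), c(2, 3, 2))
  cand <- tractogram(list(aligned, orthogonal))
  res <- life_prune(cand, w$dwi, w$gtab, w$mask)
  expect_gt(res$weights[1], 0)
  expect_equal(res$weights[2], 0, tolerance = 1e-10)
  expect_equal(res$kept_idx, 1L)
  expect_error(life_prune(tractogram(list()), w$dwi, w$gtab, w$mask),
               "no candidate")
})

test_that("NNLS weights match the exhaustive brute-force oracle", {
  # small dense instances solved against subset enumeration
  set.seed(41)
  for (trial in 1:10) {
    p <- sample(3:6, 1); m <- p + 4L
    A <- matrix(stats::rnorm(m * p), m, p)
    A[, 1] <- A[, 1] + 0.9 * A[, 2]           # induce collinearity
    y <- stats::rnorm(m)
    x_pkg <- nnls_fnnls(crossprod(A), drop(crossprod(A, y)))
    x_oracle <- nnls_bruteforce(A, y)
    expect_gte(min(x_pkg), 0)
    expect_lt(abs(sqrt(sum((y - A %*% x_pkg)^2)) -
                  sqrt(sum((y - A %*% x_oracle)^2))), 1e-6)
    expect_lt(max(abs(A %*% x_pkg - A %*% x_oracle)), 1e-5)
    # the pivoting solver agrees with the active-set solver
    x_bpp <- nnls_bpp(crossprod(A), drop(crossprod(A, y)))
    expect_lt(max(abs(A %*% x_bpp - A %*% x_oracle)), 1e-5)
  }
})

test_that("LiFE on a tiny instance matches the brute-force solution", {
  w <- single_voxel_world(axis = c(1, 1, 0))
  cands <- list(
    rbind(c(1, 1, 2), c(2, 2, 2), c(3, 3, 2)),      # aligned with (1,1,0)
    rbind(c(1, 3, 2), c(2, 2, 2), c(3, 1, 2)),      # orthogonal in-plane
    rbind(c(2, 2, 1), c(2, 2, 2), c(2, 2, 3)),      # along z
    rbind(c(1, 2, 2), c(2, 2, 2), c(3, 2, 2)))      # along x (oblique)
  cand <- tractogram(cands)
  res <- life_prune(cand, w$dwi, w$gtab, w$mask)
  # rebuild the same design densely and solve by enumeration
  pred <- life_predict(cand, w$dwi, w$gtab, w$mask,
                       weights = rep(1, 4))
  A <- vapply(1:4, function(j) {
    wts <- numeric(4); wts[j] <- 1
    life_predict(cand, w$dwi, w$gtab, w$mask, weights = wts)$prediction
  }, numeric(length(pred$prediction)))
  sel <- which(abs(w$gtab$bvals - 1000) < 1e-6)
  sig <- w$dwi$data[3, 3, 3, sel]
  y <- as.numeric(sig - mean(sig))
  x_oracle <- nnls_bruteforce(A, y)
  expect_lt(max(abs(A %*% res$weights - A %*% x_oracle)), 1e-6)
})

test_that("duplicating candidates redistributes weight, not prediction", {
  w <- single_voxel_world()
  aligned <- rbind(c(1, 2, 2), c(2, 2, 2), c(3, 2, 2))
  oblique <- rbind(c(1, 1.6, 2), c(2, 2, 2), c(3, 2.4, 2))
  base <- tractogram(list(aligned, oblique))
  doubled <- tractogram(rep(list(aligned, oblique), 2))
  r1 <- life_prune(base, w$dwi, w$gtab, w$mask)
  r2 <- life_prune(doubled, w$dwi, w$gtab, w$mask)
  p1 <- life_predict(base, w$dwi, w$gtab, w$mask, r1$weights)$prediction
  p2 <- life_predict(doubled, w$dwi, w$gtab, w$mask, r2$weights)$prediction
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("pruning invariants hold on the phantom run", {
  ph <- default_phantom()
  tr <- default_tracking()
  res <- life_prune(tr, ph$dwi, ph$gtab, ph$wm_mask)
  expect_true(all(res$weights >= 0))
  expect_lte(res$residual_norm, res$null_residual_norm)
  expect_equal(sort(res$kept_idx),
               which(res$weights > 1e-8 * max(res$weights)))
  # removing zero-weight streamlines leaves the prediction (and so the
  # residual on the surviving rows) unchanged
  pf <- life_predict(tr, ph$dwi, ph$gtab, ph$wm_mask, res$weights)
  keep <- res$weights > 0
  pk <- life_predict(tractogram(tr$streamlines[keep], validate = FALSE),
                     ph$dwi, ph$gtab, ph$wm_mask, res$weights[keep])
  nd <- sum(abs(ph$gtab$bvals - 1000) < 1e-6)
  vmatch <- match(pk$voxels, pf$voxels)
  expect_false(anyNA(vmatch))
  rows_full <- rep((vmatch - 1) * nd, each = nd) + seq_len(nd)
  expect_lt(max(abs(pf$prediction[rows_full] - pk$prediction)), 1e-10)
})
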