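# Density maps, Gaussian smoothing, consistency maps, tract profiles.

test_that("density map counts distinct streamlines and peaks at 1", {
  grid <- volume_grid(array(0, c(12L, 8L, 8L)))
  shared <- rbind(c(2, 4, 4), c(4, 4, 4))      # visits voxels x = 2..4
  alone <- rbind(c(2, 4, 4), c(9, 4, 4))       # continues to x = 9
  t3 <- tractogram(list(shared, shared + matrix(c(0, 0, 0.05), 2, 3,
                                                byrow = TRUE), alone))
  d <- density_map(t3, grid)
  expect_equal(max(d$data), 1)
  expect_equal(d$data[3 + 1, 5, 5], 1)          # all three pass x = 3
  expect_equal(d$data[8 + 1, 5, 5], 1 / 3)      # only `alone`
  # one streamline: every visited voxel at density 1
  d1 <- density_map(tractogram(list(alone)), grid)
  expect_true(all(d1$data %in% c(0, 1)))
  # a loop through one voxel counts once
  loop <- rbind(c(5, 4, 4), c(6, 4, 4), c(6, 5, 4), c(5, 4.1, 4),
                c(6, 4.05, 4))
  dl <- density_map(tractogram(list(loop, rbind(c(2, 2, 2), c(3, 2, 2)))),
                    grid)
  expect_lte(max(dl$data), 1)
  expect_equal(dl$data[6 + 1, 5, 5], 1)
  expect_error(density_map(tractogram(list()), grid), "empty")
})

test_that("Gaussian smoothing conserves mass and hits the analytic peak", {
  g <- volume_grid(array(0, c(31L, 31L, 31L)))
  g$data[16, 16, 16] <- 1
  expect_identical(smooth_volume(g, 0)$data, g$data)
  sm <- smooth_volume(g, 2)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  peak_analytic <- (2 * pi * sigma^2)^(-3 / 2)   # x 1 mm^3 voxel volume
  expect_equal(max(sm$data), peak_analytic, tolerance = 0.01)
  expect_equal(which(sm$data == max(sm$data)), which(g$data == 1))
  # linearity
  set.seed(51)
  v1 <- volume_grid(array(stats::rnorm(27e3), c(30L, 30L, 30L)))
  v2 <- volume_grid(array(stats::rnorm(27e3), c(30L, 30L, 30L)))
  lhs <- smooth_volume(volume_grid(2.5 * v1$data + v2$data,
                                   affine = v1$affine), 2)$data
  rhs <- 2.5 * smooth_volume(v1, 2)$data + smooth_volume(v2, 2)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  # anisotropic voxels are handled per axis (point source far from the
  # boundary: mass conserved)
  aniso <- volume_grid(array(0, c(21L, 21L, 41L)),
                       affine = diag(c(1, 2, 0.5, 1)))
  aniso$data[11, 11, 21] <- 3
  expect_equal(sum(smooth_volume(aniso, 2)$data), 3, tolerance = 1e-6)
  shear <- diag(4); shear[1, 2] <- 0.3
  expect_error(smooth_volume(volume_grid(array(1, c(8L, 8L, 8L)),
                                         affine = shear), 2),
               "unsupported geometry")
})

test_that("consistency map counts subjects and thresholds monotonically", {
  grid <- volume_grid(array(0, c(16L, 10L, 10L)))
  tr <- tractogram(list(rbind(c(3, 5, 5), c(12, 5, 5))))
  cm5 <- consistency_map(rep(list(tr), 5), grid)
  expect_equal(cm5$n_subjects, 5)
  expect_true(all(cm5$counts$data %in% c(0, 5)))
  expect_gt(sum(cm5$counts$data == 5), 0)
  # single subject: binary map
  cm1 <- consistency_map(list(tr), grid)
  expect_true(all(cm1$counts$data %in% c(0, 1)))
  # counts bounded by subject count, retained set shrinks with threshold
  shifted <- tractogram(list(rbind(c(3, 5, 8), c(12, 5, 8))))
  cm <- consistency_map(list(tr, tr, shifted), grid)
  expect_lte(max(cm$counts$data), 3)
  kept_k <- vapply(1:3, function(k)
    sum(consistency_map(list(tr, tr, shifted), grid,
                        threshold = k)$counts$data > 0), numeric(1))
  expect_true(all(diff(kept_k) <= 0))
  expect_error(consistency_map(list(), grid), ">= 1")
})

test_that("tract profiles sample the scalar field along the bundle", {
  n <- c(40L, 10L, 10L)
  grid <- volume_grid(array(1, n))
  # constant FA field -> flat profile
  mk_scalars <- function(fa_arr) {
    structure(list(fa = volume_grid(fa_arr, affine = grid$affine),
                   md = volume_grid(fa_arr * 1e-3, affine = grid$affine),
                   rd = volume_grid(fa_arr * 5e-4, affine = grid$affine)),
              class = "scalar_maps")
  }
  const <- mk_scalars(array(0.43, n))
  straight <- lapply(seq(4, 6, length.out = 7), function(y)
    rbind(c(3, y, 5), c(35, y, 5)))
  pr <- tract_profile(tractogram(straight), const, weighting = "uniform")
  expect_equal(length(pr$fa), 100)
  expect_equal(pr$fa, rep(0.43, 100), tolerance = 1e-12)
  # field linear along the bundle axis -> linear profile
  lin_arr <- array(rep(seq_len(n[1]) - 1, prod(n[2:3])) / n[1], n)
  lin <- mk_scalars(lin_arr)
  pr_lin <- tract_profile(tractogram(straight), lin, weighting = "uniform")
  expect_lt(max(abs(diff(diff(pr_lin$fa)))), 1e-9)   # no curvature
  expect_gt(pr_lin$fa[100], pr_lin$fa[1])
  # gaussian weighting changes nothing for a symmetric bundle here
  pr_g <- tract_profile(tractogram(straight), const)
  expect_equal(pr_g$fa, rep(0.43, 100), tolerance = 1e-12)
  expect_error(tract_profile(tractogram(list()), const), "empty")
})

test_that("a single-streamline profile equals the resampled samples", {
  n <- c(40L, 10L, 10L)
  set.seed(52)
  arr <- array(stats::runif(prod(n)), n)
  sc <- structure(list(fa = volume_grid(arr),
                       md = volume_grid(arr * 1e-3),
                       rd = volume_grid(arr * 5e-4)),
                  class = "scalar_maps")
  s <- rbind(c(2, 5, 5), c(15, 6, 5), c(30, 4, 6), c(37, 5, 5))
  pr <- tract_profile(tractogram(list(s)), sc)
  nodes <- resample_streamline(s, 100)
  oracle <- retinotract:::.trilinear_sample(sc$fa, nodes)
  expect_equal(pr$fa, oracle, tolerance = 1e-12)
  # reorientation: a flipped copy gives the same profile
  pr_f <- tract_profile(tractogram(list(s, s[nrow(s):1, ] +
                                          matrix(c(0, 0.2, 0), nrow(s), 3,
                                                 byrow = TRUE))), sc,
                        weighting = "uniform")
  pr_u <- tract_profile(tractogram(list(s, s +
                                          matrix(c(0, 0.2, 0), nrow(s), 3,
                                                 byrow = TRUE))), sc,
                        weighting = "uniform")
  expect_equal(pr_f$fa, pr_u$fa, tolerance = 1e-9)
})

test_that("phantom subcomponents show distinct apex-node profiles", {
  ph <- default_phantom()
  sc <- tensor_scalars(ph$tensors)
  pro1 <- tractogram(ph$bundles$streamlines[ph$labels == "PRO1"],
                     validate = FALSE)
  pro2 <- tractogram(ph$bundles$streamlines[ph$labels == "PRO2"],
                     validate = FALSE)
  p1 <- tract_profile(pro1, sc, tract_label = "PRO1")
  p2 <- tract_profile(pro2, sc, tract_label = "PRO2")
  # both corridors are anisotropic, the surrounding matter is not: the
  # two trajectories traverse distinct corridors, so mid-tract nodes
  # must disagree somewhere
  mid <- 30:70
  expect_gt(max(abs(p1$fa[mid] - p2$fa[mid])), 0.01)
  expect_true(all(p1$fa >= 0 & p1$fa <= 1))
})
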