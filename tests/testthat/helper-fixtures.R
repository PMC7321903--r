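# Shared fixtures, memoized so expensive objects are built once per
# test run. Everything is generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# The default phantom of the stated world: 400 labelled streamlines,
# seed 42.
default_phantom <- function() memo("phantom", function() {
  build_phantom(phantom_spec())
})

default_split <- function() memo("split", function() {
  split_roi(default_phantom()$target_roi, "y")
})

default_tensor_fit <- function() memo("tensor_fit", function() {
  ph <- default_phantom()
  fit_tensor(ph$dwi, ph$gtab, ph$wm_mask)
})

roi_union <- function(a, b) {
  volume_grid(array(as.numeric(a$data != 0 | b$data != 0), dim(a$data)),
              affine = a$affine, space_tag = a$space_tag)
}

default_tracking <- function() memo("tracking", function() {
  ph <- default_phantom()
  tf <- default_tensor_fit()
  cfg <- tracking_config(max_fibers = 200L, max_trials = 2000L,
                         rng_seed = 43L)
  ensemble_track(tf, ph$wm_mask, roi_union(ph$seed_roi, ph$target_roi),
                 cfg, ph$seed_roi, ph$target_roi)
})

default_pipeline_run <- function() memo("pipeline", function() {
  out <- file.path(tempdir(), "retinotract-pipeline-a")
  cfg <- default_run_config(out_dir = out)
  list(report = run_pipeline(cfg), out = out, cfg = cfg)
})

# A small uniform tensor field whose principal axis bridges two ROI
# boxes along world X; used for tracker unit tests.
bridge_world <- function(n = c(24L, 12L, 12L), lambdas = c(1.7e-3, 3e-4, 3e-4)) {
  grid <- volume_grid(array(1, n))
  coefficients <- array(0, c(n, 6))
  coefficients[, , , 1] <- lambdas[1]
  coefficients[, , , 3] <- lambdas[2]
  coefficients[, , , 6] <- lambdas[3]
  wm <- volume_grid(array(1, n))
  roi_a <- volume_grid(array(0, n)); roi_a$data[2:4, 4:9, 4:9] <- 1
  roi_b <- volume_grid(array(0, n)); roi_b$data[(n[1] - 3):(n[1] - 1), 4:9, 4:9] <- 1
  s0 <- array(1000, n)
  list(tensors = tensor_field(coefficients, s0, grid),
       wm = wm, roi_a = roi_a, roi_b = roi_b, grid = grid)
}

# Independent brute-force NNLS oracle: enumerate every support subset,
# solve the unconstrained LS on it with a pseudoinverse, and keep the
# best feasible (x >= 0) candidate. Exact for small p.
nnls_bruteforce <- function(A, y) {
  p <- ncol(A)
  best_x <- numeric(p)
  best_r <- sum(y^2)
  for (m in 0:(2^p - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
    if (length(idx) == 0) next
    Ai <- A[, idx, drop = FALSE]
    x_i <- tryCatch(qr.solve(Ai, y), error = function(e) NULL)
    if (is.null(x_i) || any(x_i < -1e-12)) next
    r <- sum((y - Ai %*% pmax(x_i, 0))^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best_x <- numeric(p)
      best_x[idx] <- pmax(x_i, 0)
    }
  }
  best_x
}

# One anisotropic voxel with a known orientation; candidates for LiFE
# tests are short straight streamlines through that voxel.
single_voxel_world <- function(axis = c(1, 0, 0)) {
  n <- c(5L, 5L, 5L)
  grid <- volume_grid(array(1, n))
  coefficients <- array(0, c(n, 6))
  D <- 3e-4 * diag(3) + (1.7e-3 - 3e-4) * tcrossprod(axis / sqrt(sum(axis^2)))
  lt <- c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
  for (p in 1:6) coefficients[3, 3, 3, p] <- lt[p]
  tens <- tensor_field(coefficients, array(1000, n), grid)
  gt <- make_scheme(1000, dirs_per_shell = 15, n_b0 = 2)
  dwi <- simulate_dwi(tens, gt, s0 = 1000, snr = Inf)
  mask <- volume_grid(array(0, n)); mask$data[3, 3, 3] <- 1
  list(dwi = dwi, gtab = gt, mask = mask)
}

# Quarter-circle polyline of radius r in the XY plane.
quarter_circle <- function(r = 10, n = 200) {
  th <- seq(0, pi / 2, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 + c^2 - b^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 + d^2 - b^2 - c^2),
         3, 3, byrow = TRUE)
}
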