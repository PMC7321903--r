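# Synthetic phantom: a small voxel grid holding two ground-truth
# labelled streamline bundles between a thalamic seed ROI (LGN stand-in)
# and an elongated cortical target ROI (prostriata stand-in) carrying an
# anterior-posterior scalar gradient, plus a matched tensor field and a
# noisy multi-shell diffusion series.
#
# Axis semantics (RAS, voxel size isotropic): first axis X runs
# medial -> lateral, second axis Y posterior -> anterior, third axis Z
# inferior -> superior. The dorsal bundle (label PRO1) arcs over a
# carved ventricle void and terminates anteriorly in the target and
# medially in the seed; the ventral bundle (PRO2) sweeps low and
# terminates posteriorly/laterally.

#' Specification of the synthetic phantom
#'
#' Defaults describe the stated world of the package's tests: a
#' 40 x 48 x 40 grid of 1 mm voxels, 200 streamlines per bundle (400
#' labelled streamlines total), an HCP-like 3-shell acquisition
#' (b = 1000/2000/3000 s/mm^2, 30 directions each, 6 b0 volumes) and
#' SNR 30 on the b0 signal.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 8).
#' @param voxel_size isotropic voxel edge, mm.
#' @param n_streamlines_per_bundle streamlines per bundle.
#' @param points_per_streamline points per generated streamline.
#' @param bundle_separation mm between the dorsal arc apex and the
#'   ventral path (control-point offset above/below the axial midplane).
#' @param roi_gradient_range c(low, high) of the anterior-posterior
#'   gradient over the target ROI (low = posterior).
#' @param snr b0 signal over noise sigma; `Inf` for noiseless.
#' @param shells diffusion-weighted b-values, s/mm^2.
#' @param dirs_per_shell directions per shell.
#' @param n_b0 number of b = 0 volumes.
#' @param rng_seed integer seed; identical specs give bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40L, 48L, 40L),
                         voxel_size = 1,
                         n_streamlines_per_bundle = 200L,
                         points_per_streamline = 60L,
                         bundle_separation = 12,
                         roi_gradient_range = c(0, 1),
                         snr = 30,
                         shells = c(1000, 2000, 3000),
                         dirs_per_shell = 30L,
                         n_b0 = 6L,
                         rng_seed = 42L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
               n_streamlines_per_bundle = as.integer(n_streamlines_per_bundle),
               points_per_streamline = as.integer(points_per_streamline),
               bundle_separation = bundle_separation,
               roi_gradient_range = roi_gradient_range, snr = snr,
               shells = shells, dirs_per_shell = as.integer(dirs_per_shell),
               n_b0 = as.integer(n_b0), rng_seed = as.integer(rng_seed))
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    usage_error("grid_shape components must be >= 8")
  if (spec$voxel_size <= 0) usage_error("voxel_size must be > 0")
  if (spec$snr <= 0) usage_error("snr must be > 0")
  if (any(spec$shells < 0)) usage_error("b-values must be >= 0")
  if (spec$n_streamlines_per_bundle < 1)
    usage_error("need >= 1 streamline per bundle")
  structure(spec, class = "phantom_spec")
}

# Cubic Bezier curve through 4 control points, n samples.
bezier_curve <- function(P, n) {
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  b %*% P
}

# Geometric layout of the phantom in world mm, derived from the spec.
phantom_layout <- function(spec) {
  ext <- (spec$grid_shape - 1) * spec$voxel_size   # world extent
  sx <- ext[1]; sy <- ext[2]; sz <- ext[3]
  zmid <- sz / 2
  sep <- spec$bundle_separation
  seed_center <- c(0.25 * sx, 0.25 * sy, zmid)
  target_x <- 0.70 * sx
  list(
    zmid = zmid,
    seed_center = seed_center,
    seed_half = c(3, 2, 2),
    target_x = target_x,
    target_half = c(2, 0.25 * sy, 2),
    target_center = c(target_x, 0.5 * sy, zmid),
    # dorsal bundle: medial seed -> anterior target, arcing up by `sep`
    ctrl_pro1 = rbind(
      c(seed_center[1] - 1.5, seed_center[2], zmid),
      c(0.35 * sx, 0.38 * sy, zmid + sep),
      c(0.55 * sx, 0.62 * sy, zmid + sep),
      c(target_x, 0.5 * sy + 0.17 * sy, zmid)),
    # ventral bundle: lateral seed -> posterior target, sweeping down
    ctrl_pro2 = rbind(
      c(seed_center[1] + 1.5, seed_center[2], zmid),
      c(0.35 * sx, 0.25 * sy, zmid - 0.8 * sep),
      c(0.55 * sx, 0.30 * sy, zmid - 0.8 * sep),
      c(target_x, 0.5 * sy - 0.17 * sy, zmid))
  )
}

box_mask <- function(grid, center, half) {
  shp <- vol_shape(grid)
  idx <- which(array(TRUE, shp), arr.ind = TRUE) - 1
  ctr <- apply_affine(grid$affine, idx)
  inside <- abs(ctr[, 1] - center[1]) <= half[1] &
            abs(ctr[, 2] - center[2]) <= half[2] &
            abs(ctr[, 3] - center[3]) <= half[3]
  vol_like(grid, array(as.numeric(inside), shp))
}

#' Build the synthetic phantom
#'
#' Deterministic given the spec (including its `rng_seed`). Generates
#' the grid and affine, seed/target ROIs, the anterior-posterior
#' gradient map over the target, two jittered Bezier bundles with
#' ground-truth labels, a tensor field aligned with the local mean
#' streamline tangent, a white-matter mask with a carved ventricle void
#' under the dorsal arc, and the noisy multi-shell diffusion series.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`: list with elements `dwi`,
#'   `gtab`, `wm_mask`, `seed_roi`, `target_roi`, `gradient_map`,
#'   `bundles` (tractogram), `labels` (per-streamline "PRO1"/"PRO2"),
#'   `tensors`, `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$grid_shape
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  grid <- volume_grid(array(0, shp), affine = affine, space_tag = "phantom")
  lay <- phantom_layout(spec)
  ext <- (shp - 1) * spec$voxel_size
  need <- lay$target_x + lay$target_half[1] + 3
  if (ext[1] < need)
    usage_error("grid too small along axis 1 (X): extent %.1f mm < %.1f mm needed",
                ext[1], need)
  if (ext[3] < lay$zmid + spec$bundle_separation + 4)
    usage_error("grid too small along axis 3 (Z): extent %.1f mm cannot hold the dorsal arc",
                ext[3])

  seed_roi <- box_mask(grid, lay$seed_center, lay$seed_half)
  target_roi <- box_mask(grid, lay$target_center, lay$target_half)

  # anterior-posterior gradient over the target ROI, strictly monotone in Y
  gr <- array(0, shp)
  tidx <- which(target_roi$data != 0, arr.ind = TRUE) - 1
  tctr <- apply_affine(affine, tidx)
  ylo <- min(tctr[, 2]); yhi <- max(tctr[, 2])
  val <- spec$roi_gradient_range[1] +
    (tctr[, 2] - ylo) / (yhi - ylo) * diff(spec$roi_gradient_range)
  gr[cbind(tidx[, 1] + 1, tidx[, 2] + 1, tidx[, 3] + 1)] <- val
  gradient_map <- vol_like(grid, gr)

  # bundles: jittered Bezier centerlines, constant per-streamline offset
  # in the plane normal to the local tangent
  n <- spec$n_streamlines_per_bundle
  npts <- spec$points_per_streamline
  gen_bundle <- function(ctrl) {
    cl <- bezier_curve(ctrl, npts)
    tangent <- rbind(cl[2, ] - cl[1, ],
                     cl[-1, ] - cl[-npts, ])
    tangent <- unit_rows(tangent)
    lapply(seq_len(n), function(i) {
      off <- stats::rnorm(2, sd = 0.6)
      # orthonormal frame per node
      ref <- c(0, 0, 1)
      e1 <- unit_rows(matrix(c(tangent[, 2] * ref[3] - tangent[, 3] * ref[2],
                               tangent[, 3] * ref[1] - tangent[, 1] * ref[3],
                               tangent[, 1] * ref[2] - tangent[, 2] * ref[1]),
                             ncol = 3))
      e2 <- matrix(c(tangent[, 2] * e1[, 3] - tangent[, 3] * e1[, 2],
                     tangent[, 3] * e1[, 1] - tangent[, 1] * e1[, 3],
                     tangent[, 1] * e1[, 2] - tangent[, 2] * e1[, 1]),
                   ncol = 3)
      cl + off[1] * e1 + off[2] * e2
    })
  }
  bundles_list <- with_seed(spec$rng_seed, {
    c(gen_bundle(lay$ctrl_pro1), gen_bundle(lay$ctrl_pro2))
  })
  labels <- rep(c("PRO1", "PRO2"), each = n)
  bundles <- tractogram(bundles_list, space_tag = "phantom")

  # tensor field: mean tangent per visited voxel, stick eigenvalues.
  # The dorsal corridor is more anisotropic than the ventral one (same
  # MD), giving the two subcomponents distinct FA profiles; the dorsal
  # bundle overwrites the ventral where the corridors overlap near the
  # ROIs.
  pro1_t <- tractogram(bundles_list[seq_len(n)], validate = FALSE)
  pro2_t <- tractogram(bundles_list[n + seq_len(n)], validate = FALSE)
  lam1 <- c(1.7e-3, 0.3e-3, 0.3e-3)
  lam2 <- c(1.4e-3, 0.45e-3, 0.45e-3)
  coefficients <- array(0, c(shp, 6))
  nxyz <- prod(shp)
  paint <- function(visited, lam) {
    for (r in seq_len(nrow(visited$tangents))) {
      v <- visited$tangents[r, ]
      D <- lam[2] * diag(3) + (lam[1] - lam[2]) * tcrossprod(v)
      coefficients[visited$vox[r] + (0:5) * nxyz] <<- matrix_to_lt(D)
    }
  }
  vis2 <- .splat_tangents(pro2_t, grid, spacing = spec$voxel_size / 2)
  vis1 <- .splat_tangents(pro1_t, grid, spacing = spec$voxel_size / 2)
  paint(vis2, lam2)
  paint(vis1, lam1)
  vv <- sort(unique(c(vis1$vox, vis2$vox)))

  # white matter: corridor + dilated ROIs, minus a ventricle void kept
  # clear of the corridor
  corridor <- array(0, shp); corridor[vv] <- 1
  corridor_v <- vol_like(grid, corridor)
  wm <- dilate_mask(corridor_v, 1)$data +
    dilate_mask(seed_roi, 1)$data + dilate_mask(target_roi, 1)$data
  wm <- array(as.numeric(wm > 0), shp)
  void <- box_mask(grid, c(0.48 * ext[1], 0.47 * ext[2], lay$zmid),
                   c(0.12 * ext[1], 0.16 * ext[2], 0.10 * ext[3]))$data
  guard <- dilate_mask(corridor_v, 2)$data
  wm[void > 0 & guard == 0] <- 0
  wm_mask <- vol_like(grid, wm)

  # isotropic deep matter in the remaining white-matter voxels
  iso_vox <- which(wm > 0 & corridor == 0)
  d_iso <- 0.8e-3
  coefficients[iso_vox + 0 * nxyz] <- d_iso
  coefficients[iso_vox + 2 * nxyz] <- d_iso
  coefficients[iso_vox + 5 * nxyz] <- d_iso

  s0 <- array(0, shp); s0[wm > 0] <- 1000
  tensors <- tensor_field(coefficients, s0, grid)

  gtab <- make_scheme(spec$shells, spec$dirs_per_shell, spec$n_b0)
  dwi <- simulate_dwi(tensors, gtab, s0 = 1000, snr = spec$snr,
                      rng_seed = spec$rng_seed + 1L)

  structure(list(dwi = dwi, gtab = gtab, wm_mask = wm_mask,
                 seed_roi = seed_roi, target_roi = target_roi,
                 gradient_map = gradient_map, bundles = bundles,
                 labels = labels, tensors = tensors, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", paste(x$spec$grid_shape, collapse = " x "), "voxels,",
      n_streamlines(x$bundles), "labelled streamlines,",
      length(x$gtab$bvals), "dwi volumes\n")
  invisible(x)
}

# Sample all streamlines at fixed spacing, accumulate per-voxel mean
# tangents (sign-aligned within each voxel).
.splat_tangents <- function(t, grid, spacing) {
  shp <- vol_shape(grid)
  nxyz <- prod(shp)
  sums <- matrix(0, nxyz, 3)
  hit <- logical(nxyz)
  inv <- solve(grid$affine)
  for (s in t$streamlines) {
    len <- streamline_length(s)
    nn <- max(2L, ceiling(len / spacing) + 1L)
    rs <- resample_streamline(s, nn)
    tg <- unit_rows(rbind(rs[2, ] - rs[1, ], rs[-1, ] - rs[-nn, ]))
    ijk <- round(apply_affine(inv, rs))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
          ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
          ijk[, 3] >= 0 & ijk[, 3] < shp[3]
    lin <- ijk[ok, 1] + shp[1] * (ijk[ok, 2] + shp[2] * ijk[ok, 3]) + 1
    tgo <- tg[ok, , drop = FALSE]
    # sign-align against the running sum (or the first tangent seen)
    for (r in seq_along(lin)) {
      v <- lin[r]
      cur <- sums[v, ]
      tt <- tgo[r, ]
      if (hit[v] && sum(cur * tt) < 0) tt <- -tt
      sums[v, ] <- cur + tt
      hit[v] <- TRUE
    }
  }
  vox <- which(hit)
  tangents <- unit_rows(sums[vox, , drop = FALSE])
  list(vox = vox, tangents = tangents)
}

#' Simulate a diffusion-weighted series from a tensor field
#'
#' Forward model `S(b, g) = s0 exp(-b g' D g)` per gradient-table row,
#' with optional Rician (default) or Gaussian noise of
#' `sigma = s0 / snr`; `snr = Inf` returns the exact noiseless model.
#'
#' @param tensors a [tensor_field()]; tensors must be positive
#'   semi-definite.
#' @param gtab a [gradient_table()].
#' @param s0 non-diffusion-weighted signal level.
#' @param snr b0 signal over noise sigma (`Inf` = noiseless).
#' @param rng_seed integer seed for the noise.
#' @param noise one of `"rician"`, `"gaussian"`.
#' @return a 4-D [volume_grid()].
#' @export
simulate_dwi <- function(tensors, gtab, s0 = 1000, snr = Inf,
                         rng_seed = 1L, noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  if (s0 <= 0) usage_error("s0 must be > 0")
  co <- tensors$coefficients
  shp <- dim(co)[1:3]; nxyz <- prod(shp)
  ev <- tensor_eigenvalues(tensors)
  bad <- which(ev[, 3] < -1e-12)
  if (length(bad))
    model_error("tensor not positive semi-definite at voxel(s) %s",
                paste(utils::head(bad, 5), collapse = ", "))
  cm <- matrix(co, nrow = nxyz)
  nvol <- length(gtab$bvals)
  out <- array(0, c(shp, nvol))
  for (i in seq_len(nvol)) {
    b <- gtab$bvals[i]; g <- gtab$bvecs[i, ]
    quad <- g[1]^2 * cm[, 1] + g[2]^2 * cm[, 3] + g[3]^2 * cm[, 6] +
      2 * (g[1] * g[2] * cm[, 2] + g[1] * g[3] * cm[, 4] +
           g[2] * g[3] * cm[, 5])
    out[, , , i] <- array(s0 * exp(-b * quad), shp)
  }
  if (is.finite(snr)) {
    sigma <- s0 / snr
    out <- with_seed(rng_seed, {
      if (noise == "gaussian") {
        out + array(stats::rnorm(length(out), sd = sigma), dim(out))
      } else {
        n1 <- array(stats::rnorm(length(out), sd = sigma), dim(out))
        n2 <- array(stats::rnorm(length(out), sd = sigma), dim(out))
        sqrt((out + n1)^2 + n2^2)
      }
    })
  }
  volume_grid(out, affine = tensors$affine, space_tag = tensors$space_tag)
}
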