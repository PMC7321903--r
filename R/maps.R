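# Voxel maps and tract profiles: normalized fiber density, Gaussian
# smoothing in mm, cross-subject consistency maps, and 100-node
# FA/MD/RD profiles along a bundle.

#' Normalized fiber density map
#'
#' Counts, per voxel, the number of distinct streamlines with at least
#' one sampled point in the voxel (each streamline is resampled at
#' <= half-voxel spacing first, and counts once per voxel no matter how
#' often it revisits), then divides by the maximum count so the map
#' peaks at exactly 1.
#'
#' @param t a non-empty [tractogram()].
#' @param grid a [volume_grid()] defining the lattice and affine.
#' @return a [volume_grid()] with values in \[0, 1\].
#' @export
density_map <- function(t, grid) {
  if (n_streamlines(t) == 0) usage_error("empty tractogram")
  shp <- vol_shape(grid)
  inv <- solve(grid$affine)
  spacing <- min(voxel_sizes(grid)) / 2
  counts <- array(0, shp)
  for (s in t$streamlines) {
    len <- streamline_length(s)
    nn <- max(2L, ceiling(len / spacing) + 1L)
    rs <- resample_streamline(s, nn)
    ijk <- round(apply_affine(inv, rs))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
          ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
          ijk[, 3] >= 0 & ijk[, 3] < shp[3]
    lin <- unique(ijk[ok, 1] + shp[1] * (ijk[ok, 2] + shp[2] * ijk[ok, 3]) + 1)
    counts[lin] <- counts[lin] + 1
  }
  mx <- max(counts)
  if (mx == 0) usage_error("no streamline point falls inside the grid")
  vol_like(grid, counts / mx)
}

#' Isotropic Gaussian smoothing of a volume, FWHM in mm
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` mm,
#' converted to voxel units per axis via the affine; `fwhm = 0` is the
#' identity. The kernel is normalized to unit sum, so total intensity
#' is conserved away from the boundary (zero padding). Anisotropic
#' voxels are handled per axis; a sheared affine is rejected.
#'
#' @param v 3-D [volume_grid()].
#' @param fwhm full width at half maximum, mm (>= 0).
#' @return the smoothed [volume_grid()].
#' @export
smooth_volume <- function(v, fwhm) {
  if (fwhm < 0) usage_error("fwhm must be >= 0")
  if (fwhm == 0) return(v)
  A <- v$affine[1:3, 1:3]
  vsz <- sqrt(colSums(A^2))
  ortho <- crossprod(A / rep(vsz, each = 3))
  if (max(abs(ortho - diag(3))) > 1e-6)
    usage_error("sheared affine: unsupported geometry for smoothing")
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  x <- v$data
  for (ax in 1:3) {
    sigma_vox <- sigma_mm / vsz[ax]
    r <- max(1L, ceiling(4 * sigma_vox))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
    k <- k / sum(k)
    x <- .conv_axis(x, k, ax)
  }
  vol_like(v, x)
}

# Zero-padded convolution of a 3-D array along one axis with an odd
# symmetric kernel, implemented as a sum of shifted copies.
.conv_axis <- function(x, k, ax) {
  shp <- dim(x)
  r <- (length(k) - 1L) / 2L
  out <- array(0, shp)
  n <- shp[ax]
  for (o in -r:r) {
    w <- k[o + r + 1L]
    src_lo <- max(1L, 1L - o); src_hi <- min(n, n - o)
    if (src_lo > src_hi) next
    dst <- (src_lo + o):(src_hi + o)
    src <- src_lo:src_hi
    if (ax == 1) out[dst, , ] <- out[dst, , ] + w * x[src, , ]
    else if (ax == 2) out[, dst, ] <- out[, dst, ] + w * x[, src, ]
    else out[, , dst] <- out[, , dst] + w * x[, , src]
  }
  out
}

#' Cross-subject tract consistency map
#'
#' For each subject's tractogram (all in one common space): density map,
#' Gaussian smoothing at `fwhm` mm, binarization at `> binarize_eps`.
#' The consistency counts are the voxelwise sum of the binary maps
#' (0..N subjects); an optional threshold `k` zeroes voxels present in
#' fewer than `k` subjects.
#'
#' @param per_subject_tracts list of [tractogram()] (>= 1).
#' @param grid common-space [volume_grid()].
#' @param fwhm smoothing FWHM, mm (default 2).
#' @param binarize_eps presence threshold applied after smoothing.
#' @param threshold optional minimum subject count to retain.
#' @return an object of class `consistency_map`: list with `counts`
#'   ([volume_grid()]), `n_subjects`, `threshold`.
#' @export
consistency_map <- function(per_subject_tracts, grid, fwhm = 2,
                            binarize_eps = 1e-6, threshold = NULL) {
  if (length(per_subject_tracts) < 1) usage_error("need >= 1 subject")
  shp <- vol_shape(grid)
  counts <- array(0, shp)
  for (t in per_subject_tracts) {
    d <- density_map(t, grid)
    sm <- smooth_volume(d, fwhm)
    counts <- counts + (sm$data > binarize_eps)
  }
  if (!is.null(threshold)) counts[counts < threshold] <- 0
  structure(list(counts = vol_like(grid, counts),
                 n_subjects = length(per_subject_tracts),
                 threshold = threshold),
            class = "consistency_map")
}

#' @export
print.consistency_map <- function(x, ...) {
  cat("<consistency_map>", x$n_subjects, "subjects; max count",
      max(x$counts$data), "\n")
  invisible(x)
}

#' Tract profile: a scalar map sampled at equidistant nodes along a bundle
#'
#' Streamlines are reoriented to a common direction by nearest-endpoint
#' matching against the first streamline, resampled to `n_nodes`
#' equal-arc-length nodes, and the scalar maps are sampled tri-linearly
#' at every streamline's nodes. The per-node value is the mean over
#' streamlines, either uniform or Gaussian-weighted by each node's
#' distance to the core fiber (the per-node coordinate mean), with
#' sigma equal to the per-node coordinate standard deviation.
#'
#' @param t a non-empty [tractogram()].
#' @param scalars a [tensor_scalars()] result (fields `fa`, `md`, `rd`).
#' @param n_nodes number of profile nodes (default 100).
#' @param weighting `"gaussian"` (default) or `"uniform"`.
#' @param tract_label label stored with the profile.
#' @return an object of class `tract_profile`: data frame-like list
#'   with `node` (arc-length fraction), `fa`, `md`, `rd`, `spacing_mm`
#'   (mean inter-node distance), `n_streamlines`, `tract_label`.
#' @export
tract_profile <- function(t, scalars, n_nodes = 100,
                          weighting = c("gaussian", "uniform"),
                          tract_label = "FULL") {
  weighting <- match.arg(weighting)
  nf <- n_streamlines(t)
  if (nf == 0) usage_error("empty tractogram")
  ref <- t$streamlines[[1]]
  ref_start <- ref[1, ]
  nodes <- array(0, c(nf, n_nodes, 3))
  for (i in seq_len(nf)) {
    s <- t$streamlines[[i]]
    d_start <- sum((s[1, ] - ref_start)^2)
    d_end <- sum((s[nrow(s), ] - ref_start)^2)
    if (d_end < d_start) s <- s[nrow(s):1, , drop = FALSE]
    nodes[i, , ] <- resample_streamline(s, n_nodes)
  }
  core <- apply(nodes, c(2, 3), mean)
  if (weighting == "gaussian" && nf > 1) {
    dev <- sweep(nodes, c(2, 3), core)
    dist2 <- apply(dev^2, c(1, 2), sum)            # nf x n_nodes
    sigma2 <- colMeans(dist2)                       # per-node variance
    sigma2[sigma2 == 0] <- 1
    w <- exp(-dist2 / (2 * rep(sigma2, each = nf)))
    w <- sweep(w, 2, colSums(w), "/")
  } else {
    w <- matrix(1 / nf, nf, n_nodes)
  }
  sample_map <- function(vol) {
    out <- matrix(0, nf, n_nodes)
    for (i in seq_len(nf))
      out[i, ] <- .trilinear_sample(vol, nodes[i, , ])
    colSums(out * w)
  }
  spacing <- rowMeans(vapply(seq_len(nf), function(i) {
    seg <- sqrt(rowSums((nodes[i, -1, ] - nodes[i, -n_nodes, ])^2))
    c(seg, seg[n_nodes - 1])
  }, numeric(n_nodes)))
  structure(list(node = seq(0, 1, length.out = n_nodes),
                 fa = sample_map(scalars$fa),
                 md = sample_map(scalars$md),
                 rd = sample_map(scalars$rd),
                 spacing_mm = spacing,
                 n_streamlines = nf,
                 tract_label = tract_label),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat("<tract_profile>", x$tract_label, "over", length(x$node), "nodes,",
      x$n_streamlines, "streamlines; mean FA",
      signif(mean(x$fa), 3), "\n")
  invisible(x)
}

# Tri-linear interpolation of a 3-D volume at world-mm points; points
# outside the grid clamp to the boundary.
.trilinear_sample <- function(vol, pts) {
  shp <- vol_shape(vol)
  xyz <- world_to_voxel(vol, pts)
  xyz[, 1] <- pmin(pmax(xyz[, 1], 0), shp[1] - 1)
  xyz[, 2] <- pmin(pmax(xyz[, 2], 0), shp[2] - 1)
  xyz[, 3] <- pmin(pmax(xyz[, 3], 0), shp[3] - 1)
  x0 <- pmin(floor(xyz[, 1]), shp[1] - 2); fx <- xyz[, 1] - x0
  y0 <- pmin(floor(xyz[, 2]), shp[2] - 2); fy <- xyz[, 2] - y0
  z0 <- pmin(floor(xyz[, 3]), shp[3] - 2); fz <- xyz[, 3] - z0
  out <- numeric(nrow(pts))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
           (if (dz) fz else 1 - fz)
    lin <- (x0 + dx) + shp[1] * ((y0 + dy) + shp[2] * (z0 + dz)) + 1
    out <- out + wgt * vol$data[lin]
  }
  out
}

#' Profile data as a data frame (node, fa, md, rd, spacing_mm)
#' @param x a [tract_profile()].
#' @param ... unused.
#' @return a data frame with one row per node.
#' @export
as.data.frame.tract_profile <- function(x, ...) {
  data.frame(node = x$node, fa = x$fa, md = x$md, rd = x$rd,
             spacing_mm = x$spacing_mm)
}
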