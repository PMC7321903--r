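# Core streamline geometry: arc-length resampling, length, ROI
# intersection at a millimetre criterion, exclusion-plane filtering, and
# binary mask dilation.

#' Resample a streamline to equally spaced arc-length nodes
#'
#' Nodes are placed at equal arc-length spacing along the original
#' polyline, by linear interpolation between input points; the first and
#' last input points are preserved exactly.
#'
#' @param s numeric n x 3 matrix of points (mm).
#' @param n_nodes number of output nodes (>= 2).
#' @return an `n_nodes` x 3 matrix.
#' @export
resample_streamline <- function(s, n_nodes) {
  s <- matrix(as.numeric(s), ncol = 3)
  if (n_nodes < 2) usage_error("n_nodes must be >= 2")
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  total <- sum(seg)
  if (total == 0) geometry_error("cannot resample a zero-length streamline")
  cum <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n_nodes)
  out <- matrix(0, n_nodes, 3)
  out[1, ] <- s[1, ]
  out[n_nodes, ] <- s[nrow(s), ]
  if (n_nodes > 2) {
    ti <- target[2:(n_nodes - 1)]
    j <- findInterval(ti, cum, rightmost.closed = TRUE)
    j[j >= nrow(s)] <- nrow(s) - 1L
    frac <- (ti - cum[j]) / seg[j]
    out[2:(n_nodes - 1), ] <- s[j, , drop = FALSE] +
      (s[j + 1L, , drop = FALSE] - s[j, , drop = FALSE]) * frac
  }
  out
}

#' Total length of a streamline in mm
#'
#' Sum of Euclidean segment lengths of the polyline.
#'
#' @param s numeric n x 3 matrix of points.
#' @return length in mm.
#' @export
streamline_length <- function(s) {
  s <- matrix(as.numeric(s), ncol = 3)
  sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

#' Does a streamline intersect an ROI within a distance criterion?
#'
#' True iff the minimum Euclidean distance between any streamline point
#' and any nonzero ROI voxel center is `<= max_dist` (inclusive).
#'
#' @param s numeric n x 3 matrix of world-mm points.
#' @param roi binary [volume_grid()].
#' @param max_dist distance criterion in mm (default 2).
#' @return logical scalar.
#' @export
intersects_roi <- function(s, roi, max_dist = 2) {
  centers <- voxel_centers(roi)
  if (nrow(centers) == 0) usage_error("ROI is empty")
  min_dist_pointsets(matrix(s, ncol = 3), centers) <= max_dist
}

# Minimum distance between two point sets (blocked to bound memory).
min_dist_pointsets <- function(a, b) {
  best <- Inf
  bs <- 2048L
  b2 <- rowSums(b^2)
  for (start in seq(1, nrow(a), by = bs)) {
    blk <- a[start:min(start + bs - 1L, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), b2, "+") - 2 * blk %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' An exclusion plane for manual-style bundle extraction
#'
#' @param point a point on the plane, world mm.
#' @param normal plane normal (normalized internally; must be non-zero).
#' @param mode `"remove_crossing"` drops streamlines crossing the plane;
#'   `"keep_side_positive"` / `"keep_side_negative"` drop streamlines
#'   having any point on the forbidden side (the positive side is the
#'   side the normal points into).
#' @return an object of class `exclusion_plane`.
#' @export
exclusion_plane <- function(point, normal,
                            mode = c("remove_crossing", "keep_side_positive",
                                     "keep_side_negative")) {
  mode <- match.arg(mode)
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) usage_error("plane normal must be non-zero")
  structure(list(point = as.numeric(point), normal = normal / nn, mode = mode),
            class = "exclusion_plane")
}

#' Filter a tractogram with exclusion planes
#'
#' Planes are applied conjunctively, in order. A point exactly on a
#' plane belongs to both sides: it triggers `remove_crossing` when a
#' neighbouring point sits strictly on either side, and it never by
#' itself violates a `keep_side` constraint.
#'
#' @param t a [tractogram()].
#' @param planes list of [exclusion_plane()] objects.
#' @return the filtered [tractogram()]; an attribute `"kept"` carries the
#'   logical keep mask over the input streamlines.
#' @export
filter_by_planes <- function(t, planes) {
  keep <- rep(TRUE, n_streamlines(t))
  for (pl in planes) {
    stopifnot(inherits(pl, "exclusion_plane"))
    for (i in which(keep)) {
      s <- t$streamlines[[i]]
      side <- drop(sweep(s, 2, pl$point) %*% pl$normal)
      keep[i] <- switch(pl$mode,
        remove_crossing = all(side > 0) || all(side < 0),
        keep_side_positive = all(side >= 0),
        keep_side_negative = all(side <= 0))
    }
  }
  out <- tractogram(t$streamlines[keep], space_tag = t$space_tag,
                    validate = FALSE)
  attr(out, "kept") <- keep
  out
}

#' Binary dilation of a mask with 6-connectivity
#'
#' `npass` iterations of one-voxel dilation along the face-connected
#' (6-neighbour) structuring element; `npass = 0` returns the input.
#'
#' @param roi binary [volume_grid()].
#' @param npass number of dilation passes (>= 0).
#' @return the dilated [volume_grid()].
#' @export
dilate_mask <- function(roi, npass) {
  if (npass < 0) usage_error("npass must be >= 0")
  m <- roi$data != 0
  shp <- dim(m)
  for (p in seq_len(npass)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-shp[1], , ]
    out[-shp[1], , ] <- out[-shp[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -shp[2], ]
    out[, -shp[2], ] <- out[, -shp[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -shp[3]]
    out[, , -shp[3]] <- out[, , -shp[3]] | m[, , -1]
    m <- out
  }
  vol_like(roi, array(as.numeric(m), dim = shp))
}

#' Voxels within a Euclidean distance of a mask's voxel centers
#'
#' Marks every voxel whose center lies within `dist_mm` of the center of
#' some nonzero voxel of `roi`; used to turn the "within 2 mm of an ROI"
#' criterion into a lookup mask.
#' @keywords internal
reach_mask <- function(roi, dist_mm) {
  vsz <- voxel_sizes(roi)
  r <- floor(dist_mm / vsz)
  offs <- expand.grid(i = -r[1]:r[1], j = -r[2]:r[2], k = -r[3]:r[3])
  d <- sqrt((offs$i * vsz[1])^2 + (offs$j * vsz[2])^2 + (offs$k * vsz[3])^2)
  offs <- offs[d <= dist_mm, , drop = FALSE]
  shp <- dim(roi$data)
  src <- which(roi$data != 0, arr.ind = TRUE)
  out <- array(FALSE, shp)
  for (r_ in seq_len(nrow(offs))) {
    i <- src[, 1] + offs$i[r_]
    j <- src[, 2] + offs$j[r_]
    k <- src[, 3] + offs$k[r_]
    ok <- i >= 1 & i <= shp[1] & j >= 1 & j <= shp[2] & k >= 1 & k <= shp[3]
    out[cbind(i[ok], j[ok], k[ok])] <- TRUE
  }
  vol_like(roi, array(as.numeric(out), shp))
}
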