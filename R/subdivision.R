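# Endpoint-based subdivision of a tract against a gradient-bearing ROI:
# split the ROI 50/50 along its major axis, classify each streamline by
# the half its termination falls in, quantify a candidate subdivision
# with signal-detection statistics (hits, false alarms, d-prime), and
# histogram seed-side endpoints along the medial-lateral axis.

.axis_vec <- function(hint) {
  switch(hint,
         x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         usage_error("orientation_hint must be one of 'x', 'y', 'z'"))
}

#' Split a binary ROI into two equal halves along its major axis
#'
#' The major axis is the first principal direction of the ROI voxel
#' world coordinates, sign-aligned with the orientation hint so that
#' "anterior" is the positive end. Voxels are ordered by their
#' projection on the axis (ties broken by voxel linear index, so the
#' split is deterministic and enumeration-order invariant); the upper
#' half (ties going anterior) forms the anterior mask. For a degenerate
#' ROI whose principal directions are not unique (e.g. a sphere), the
#' hint axis itself is used.
#'
#' @param roi binary [volume_grid()] with >= 2 nonzero voxels.
#' @param orientation_hint `"x"`, `"y"` or `"z"`: the world axis the
#'   anterior direction points along (default `"y"`).
#' @return an object of class `roi_split`: list with `anterior_mask`,
#'   `posterior_mask` ([volume_grid()]), `axis` (unit 3-vector), and
#'   `split_value` (median projection).
#' @export
split_roi <- function(roi, orientation_hint = "y") {
  hint <- .axis_vec(orientation_hint)
  lin <- which(roi$data != 0)
  if (length(lin) < 2) usage_error("ROI must have >= 2 voxels")
  idx <- which(roi$data != 0, arr.ind = TRUE) - 1
  # canonical voxel order for determinism
  ord0 <- order(lin)
  lin <- lin[ord0]; idx <- idx[ord0, , drop = FALSE]
  ctr <- apply_affine(roi$affine, idx)
  cen <- sweep(ctr, 2, colMeans(ctr))
  sv <- svd(cen, nu = 0, nv = 3)
  axis <- sv$v[, 1]
  degenerate <- length(sv$d) > 1 &&
    (sv$d[1] == 0 || (sv$d[1] - sv$d[2]) / sv$d[1] < 1e-6)
  if (degenerate) axis <- hint
  if (sum(axis * hint) < 0) axis <- -axis
  proj <- drop(cen %*% axis)
  ord <- order(proj, lin)            # stable: ties by voxel index
  n <- length(lin)
  n_ant <- ceiling(n / 2)
  ant_lin <- lin[ord][(n - n_ant + 1):n]
  pos_lin <- lin[ord][seq_len(n - n_ant)]
  shp <- vol_shape(roi)
  am <- array(0, shp); am[ant_lin] <- 1
  pm <- array(0, shp); pm[pos_lin] <- 1
  structure(list(anterior_mask = vol_like(roi, am),
                 posterior_mask = vol_like(roi, pm),
                 axis = axis,
                 split_value = stats::median(proj)),
            class = "roi_split")
}

#' @export
print.roi_split <- function(x, ...) {
  cat("<roi_split>", sum(x$anterior_mask$data), "anterior /",
      sum(x$posterior_mask$data), "posterior voxels; axis",
      paste(signif(x$axis, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Classify streamlines by their termination zone in a split ROI
#'
#' For each streamline, the endpoint nearer the ROI is tested: within
#' `max_dist` mm of an anterior voxel center only -> `PRO1`; of a
#' posterior voxel center only -> `PRO2`; within reach of both -> the
#' nearer half (ties anterior); of neither -> `UNASSIGNED`.
#'
#' @param t a non-empty [tractogram()].
#' @param split a [split_roi()] result.
#' @param max_dist endpoint distance criterion, mm (default 2).
#' @return an object of class `classification_result`: list with
#'   `labels` (factor PRO1/PRO2/UNASSIGNED) and `proportions` (named,
#'   sums to 1).
#' @export
classify_by_endpoint <- function(t, split, max_dist = 2) {
  if (n_streamlines(t) == 0) usage_error("empty tractogram")
  ca <- voxel_centers(split$anterior_mask)
  cp <- voxel_centers(split$posterior_mask)
  labels <- character(n_streamlines(t))
  for (i in seq_len(n_streamlines(t))) {
    s <- t$streamlines[[i]]
    ends <- s[c(1, nrow(s)), , drop = FALSE]
    dA <- c(min_dist_pointsets(ends[1, , drop = FALSE], ca),
            min_dist_pointsets(ends[2, , drop = FALSE], ca))
    dP <- c(min_dist_pointsets(ends[1, , drop = FALSE], cp),
            min_dist_pointsets(ends[2, , drop = FALSE], cp))
    droi <- pmin(dA, dP)
    e <- which.min(droi)             # endpoint nearer the ROI
    inA <- dA[e] <= max_dist
    inP <- dP[e] <= max_dist
    labels[i] <- if (inA && (!inP || dA[e] <= dP[e])) "PRO1"
                 else if (inP) "PRO2"
                 else "UNASSIGNED"
  }
  labels <- factor(labels, levels = c("PRO1", "PRO2", "UNASSIGNED"))
  props <- as.numeric(table(labels)) / length(labels)
  names(props) <- levels(labels)
  structure(list(labels = labels, proportions = props),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result>",
      paste(sprintf("%s: %.1f%%", names(x$proportions),
                    100 * x$proportions), collapse = "  "), "\n")
  invisible(x)
}

#' Signal-detection statistics for a tract subdivision
#'
#' `d' = z(hits) - z(false alarms)` with `z` the standard-normal
#' quantile. Rates of exactly 0 or 1 are clamped to `1/(2N)` and
#' `1 - 1/(2N)` (the standard correction keeping d' finite), which
#' requires `n`.
#'
#' @param hits hit rate in \[0, 1\], or counts via `n`.
#' @param false_alarms false-alarm rate in \[0, 1\].
#' @param n number of fibers behind each rate (needed only for
#'   clamping perfect rates).
#' @return an object of class `detection_stats`: list with `hits`,
#'   `false_alarms`, `d_prime`, `n`.
#' @export
detection_stats <- function(hits, false_alarms, n = NULL) {
  if (hits < 0 || hits > 1 || false_alarms < 0 || false_alarms > 1)
    usage_error("rates must lie in [0, 1]")
  clamp <- function(r) {
    if (r %in% c(0, 1)) {
      if (is.null(n))
        usage_error("rate of exactly %g needs n for the 1/(2N) correction", r)
      r <- max(1 / (2 * n), min(1 - 1 / (2 * n), r))
    }
    r
  }
  h <- clamp(hits); f <- clamp(false_alarms)
  structure(list(hits = hits, false_alarms = false_alarms,
                 d_prime = stats::qnorm(h) - stats::qnorm(f),
                 n = n),
            class = "detection_stats")
}

#' @export
print.detection_stats <- function(x, ...) {
  cat(sprintf("<detection_stats> hits %.1f%%, false alarms %.1f%%, d' = %.2f\n",
              100 * x$hits, 100 * x$false_alarms, x$d_prime))
  invisible(x)
}

#' Detection statistics of a subcomponent against a split ROI
#'
#' Given which fibers of the whole tract belong to an
#' anatomically-extracted subcomponent and which ROI half each fiber
#' terminates in, computes hits (fraction of the subcomponent's fibers
#' terminating in its reference half), false alarms (fraction
#' terminating in the opposite half), and d'. Fibers terminating in
#' neither half are excluded from the rates.
#'
#' @param membership logical: is each fiber in the subcomponent?
#' @param term_half factor/character per fiber: `"anterior"`,
#'   `"posterior"`, or `"none"`.
#' @param reference_half `"anterior"` or `"posterior"`: the half the
#'   subcomponent is expected to reach.
#' @return a [detection_stats()] object.
#' @export
subcomponent_detection <- function(membership, term_half,
                                   reference_half = c("anterior",
                                                      "posterior")) {
  reference_half <- match.arg(reference_half)
  opposite <- setdiff(c("anterior", "posterior"), reference_half)
  sub <- membership & term_half %in% c("anterior", "posterior")
  nsub <- sum(sub)
  if (nsub == 0) usage_error("subcomponent has zero fibers")
  hits <- sum(term_half[sub] == reference_half) / nsub
  fas <- sum(term_half[sub] == opposite) / nsub
  detection_stats(hits, fas, n = nsub)
}

#' Medial-to-lateral histogram of seed-side endpoints
#'
#' Sorts the nonzero voxels of the seed ROI by ascending world X
#' (medial to lateral) and counts, for each voxel, the streamlines whose
#' seed-side endpoint (the endpoint nearer the seed ROI) lies within
#' `max_dist` mm of that voxel center. A streamline may contribute to
#' several voxels.
#'
#' @param t a [tractogram()] (may be empty).
#' @param seed_roi binary non-empty [volume_grid()].
#' @param max_dist distance criterion, mm.
#' @return data frame with columns `x_mm` (voxel center X, ascending)
#'   and `count`.
#' @export
endpoint_histogram <- function(t, seed_roi, max_dist = 2) {
  centers <- voxel_centers(seed_roi)
  if (nrow(centers) == 0) usage_error("seed ROI is empty")
  ord <- order(centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  counts <- integer(nrow(centers))
  for (s in t$streamlines) {
    ends <- s[c(1, nrow(s)), , drop = FALSE]
    d1 <- sqrt(colSums((t(centers) - ends[1, ])^2))
    d2 <- sqrt(colSums((t(centers) - ends[2, ])^2))
    ep <- if (min(d1) <= min(d2)) d1 else d2
    counts <- counts + (ep <= max_dist)
  }
  data.frame(x_mm = centers[, 1], count = counts)
}
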