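#' Volume grid: a 3-D or 4-D scalar lattice with a voxel-to-world affine
#'
#' The basic spatial container of the package, mirroring what a NIfTI-1
#' image carries: a data array, a 4x4 affine mapping 0-based voxel
#' indices (i, j, k) to world coordinates in mm (RAS), and a free-text
#' label of the common space the volume lives in.
#'
#' Voxel centers sit at integer indices: the center of voxel (i, j, k)
#' is `affine %*% c(i, j, k, 1)`.
#'
#' @param data numeric or logical array, 3-D or 4-D.
#' @param affine 4x4 numeric matrix, invertible; last row c(0, 0, 0, 1).
#' @param space_tag character label of the coordinate space.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, affine = diag(4), space_tag = "phantom") {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    usage_error("volume data must be 3-D or 4-D, got %d dimensions", nd)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    usage_error("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    usage_error("affine is singular")
  structure(list(data = data, affine = affine, space_tag = space_tag),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> dims:", paste(dim(x$data), collapse = " x "),
      " space:", x$space_tag, "\n")
  cat("  voxel size (mm):",
      paste(signif(voxel_sizes(x), 4), collapse = " x "), "\n")
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")

#' Spatial dimensions (first three) of a volume
#' @keywords internal
vol_shape <- function(v) dim(v$data)[1:3]

#' Per-axis voxel edge lengths in mm (column norms of the affine)
#' @param v a `volume_grid`.
#' @return numeric length 3.
#' @export
voxel_sizes <- function(v) {
  sqrt(colSums(v$affine[1:3, 1:3]^2))
}

#' World coordinates of voxel centers
#'
#' @param v a `volume_grid`.
#' @param idx n x 3 matrix of 0-based voxel indices; if `NULL`, the
#'   centers of all voxels where the (3-D) data are nonzero.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_centers <- function(v, idx = NULL) {
  if (is.null(idx)) {
    w <- which(v$data != 0, arr.ind = TRUE)
    if (length(w) == 0) return(matrix(numeric(0), ncol = 3))
    idx <- w[, 1:3, drop = FALSE] - 1
  }
  apply_affine(v$affine, idx)
}

#' Map world coordinates to continuous 0-based voxel coordinates
#' @keywords internal
world_to_voxel <- function(v, pts) {
  apply_affine(solve(v$affine), pts)
}

#' Test world points for membership in a binary mask
#'
#' A point belongs to the voxel whose center is nearest to it
#' (rounding of its continuous voxel coordinate).
#' @keywords internal
points_in_mask <- function(v, pts) {
  ijk <- round(world_to_voxel(v, pts))
  shp <- vol_shape(v)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
        ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
        ijk[, 3] >= 0 & ijk[, 3] < shp[3]
  inside <- logical(nrow(pts))
  if (any(ok)) {
    lin <- ijk[ok, 1] + shp[1] * (ijk[ok, 2] + shp[2] * ijk[ok, 3]) + 1
    inside[ok] <- v$data[lin] != 0
  }
  inside
}

#' Construct a like-shaped volume with new data
#' @keywords internal
vol_like <- function(v, data) {
  volume_grid(data, affine = v$affine, space_tag = v$space_tag)
}
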