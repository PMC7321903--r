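# Diffusion-tensor model: per-voxel log-linear least-squares fit of
# S(b, g) = S0 exp(-b g' D g), and the rotation-invariant scalar maps
# (FA, MD, RD) derived from the tensor eigenvalues.
#
# Tensor coefficients are stored throughout in lower-triangular order
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), mm^2/s.

.LT_ORDER <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

#' Tensor field: per-voxel symmetric diffusion tensor
#'
#' @param coefficients 4-D array (X, Y, Z, 6), lower-triangular order
#'   Dxx, Dxy, Dyy, Dxz, Dyz, Dzz, in mm^2/s.
#' @param s0_map 3-D array of non-diffusion-weighted signal.
#' @param grid a [volume_grid()] supplying the affine (data ignored).
#' @param flagged integer vector of linear voxel indices whose fit was
#'   degenerate (all-zero signal).
#' @return an object of class `tensor_field`.
#' @export
tensor_field <- function(coefficients, s0_map, grid, flagged = integer(0)) {
  stopifnot(length(dim(coefficients)) == 4, dim(coefficients)[4] == 6)
  structure(list(coefficients = coefficients, s0_map = s0_map,
                 affine = grid$affine, space_tag = grid$space_tag,
                 flagged = flagged),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> grid:", paste(dim(x$coefficients)[1:3], collapse = " x "),
      "voxels;", length(x$flagged), "flagged\n")
  invisible(x)
}

# Expand the 6 lower-triangular coefficients of one voxel to 3x3.
lt_to_matrix <- function(ltc) {
  matrix(c(ltc[1], ltc[2], ltc[4],
           ltc[2], ltc[3], ltc[5],
           ltc[4], ltc[5], ltc[6]), 3, 3)
}

matrix_to_lt <- function(D) {
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}

#' Fit the diffusion-tensor model by ordinary least squares on log-signal
#'
#' Per masked voxel, solves `log S = log S0 - b g' D g` in the least
#' squares sense over all volumes of the series (all shells). Weighted
#' least squares (weights S_i^2, one reweighting pass from the OLS
#' estimate) is available behind `method = "wls"`. Signals <= 0 are
#' floored to machine epsilon before the log. Voxels outside the mask
#' are zero-filled; masked voxels whose signal is identically zero are
#' recorded in the `flagged` field and left zero.
#'
#' @param dwi 4-D [volume_grid()], one volume per gradient-table row.
#' @param gtab a [gradient_table()].
#' @param mask binary 3-D [volume_grid()].
#' @param method `"ols"` (default) or `"wls"`.
#' @return a [tensor_field()].
#' @export
fit_tensor <- function(dwi, gtab, mask, method = c("ols", "wls")) {
  method <- match.arg(method)
  shp <- vol_shape(dwi)
  nvol <- dim(dwi$data)[4]
  if (nvol != length(gtab$bvals))
    usage_error("dwi has %d volumes but gradient table %d rows",
                nvol, length(gtab$bvals))
  if (nvol < 7 || sum(gtab$bvals == 0) < 1)
    model_error("tensor fit needs >= 7 volumes including >= 1 b = 0 (got %d volumes, %d b0)",
                nvol, sum(gtab$bvals == 0))
  if (!all(vol_shape(mask) == shp))
    usage_error("mask shape does not match dwi grid")

  g <- gtab$bvecs; b <- gtab$bvals
  # design: log S = X beta, beta = (log S0, Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
  X <- cbind(1,
             -b * g[, 1]^2,
             -2 * b * g[, 1] * g[, 2],
             -b * g[, 2]^2,
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3],
             -b * g[, 3]^2)
  vox <- which(mask$data != 0)
  nvox <- length(vox)
  S <- matrix(aperm(dwi$data, c(4, 1, 2, 3)), nrow = nvol)[, vox, drop = FALSE]
  flagged <- vox[colSums(S != 0) == 0]
  usable <- colSums(S != 0) > 0
  S[S <= 0] <- .Machine$double.eps
  beta <- qr.coef(qr(X), log(S))
  if (method == "wls") {
    # one reweighting pass with weights = predicted squared signal
    pred <- X %*% beta
    for (j in which(usable)) {
      w <- exp(2 * pred[, j])
      Xw <- X * w
      beta[, j] <- solve(crossprod(X, Xw), crossprod(Xw, log(S[, j])))
    }
  }
  beta[, !usable] <- 0
  coefficients <- array(0, c(shp, 6))
  s0 <- array(0, shp)
  nxyz <- prod(shp)
  for (p in 1:6) coefficients[vox + (p - 1) * nxyz] <- beta[p + 1, ]
  s0[vox] <- ifelse(usable, exp(beta[1, ]), 0)
  tensor_field(coefficients, s0, dwi, flagged = flagged)
}

#' Eigenvalues of every voxel's tensor, closed form, vectorized
#'
#' Analytic eigenvalues of the symmetric 3x3 tensors (trigonometric
#' method), returned in descending order. Raw (possibly negative)
#' values; callers clamp as needed.
#'
#' @param t a [tensor_field()].
#' @return n_voxel x 3 matrix (lambda1 >= lambda2 >= lambda3) over all
#'   voxels in array order.
#' @export
tensor_eigenvalues <- function(t) {
  co <- t$coefficients
  shp <- dim(co)[1:3]; n <- prod(shp)
  cm <- matrix(co, nrow = n)          # columns: Dxx Dxy Dyy Dxz Dyz Dzz
  dxx <- cm[, 1]; dxy <- cm[, 2]; dyy <- cm[, 3]
  dxz <- cm[, 4]; dyz <- cm[, 5]; dzz <- cm[, 6]
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 +
    2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q
  # diagonal tensors are solved exactly (keeps FA of a pure stick at 1)
  diag_only <- (dxy == 0 & dxz == 0 & dyz == 0)
  if (any(diag_only)) {
    dd <- cbind(dxx, dyy, dzz)[diag_only, , drop = FALSE]
    dd <- t(apply(dd, 1, sort, decreasing = TRUE))
    l1[diag_only] <- dd[, 1]
    l2[diag_only] <- dd[, 2]
    l3[diag_only] <- dd[, 3]
  }
  nz <- p > 0 & !diag_only
  if (any(nz)) {
    bxx <- (dxx - q) / p; byy <- (dyy - q) / p; bzz <- (dzz - q) / p
    bxy <- dxy / p; bxz <- dxz / p; byz <- dyz / p
    detB <- bxx * (byy * bzz - byz^2) -
            bxy * (bxy * bzz - byz * bxz) +
            bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3)
}

#' Scalar maps (FA, MD, RD) from a tensor field
#'
#' Eigenvalues are sorted descending and clamped to zero before the
#' scalar formulas: MD = (l1+l2+l3)/3, RD = (l2+l3)/2,
#' FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2)). The FA of
#' an all-zero tensor is defined as 0.
#'
#' @param t a [tensor_field()].
#' @return a list of class `scalar_maps` with [volume_grid()] elements
#'   `fa`, `md`, `rd`.
#' @export
tensor_scalars <- function(t) {
  ev <- pmax(tensor_eigenvalues(t), 0)
  md <- rowMeans(ev)
  rd <- (ev[, 2] + ev[, 3]) / 2
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- rowSums(ev^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  shp <- dim(t$coefficients)[1:3]
  grid <- volume_grid(array(0, shp), affine = t$affine,
                      space_tag = t$space_tag)
  structure(list(fa = vol_like(grid, array(fa, shp)),
                 md = vol_like(grid, array(md, shp)),
                 rd = vol_like(grid, array(rd, shp))),
            class = "scalar_maps")
}

#' @export
print.scalar_maps <- function(x, ...) {
  cat("<scalar_maps> fa/md/rd over",
      paste(dim(x$fa$data), collapse = " x "), "voxels\n")
  invisible(x)
}

#' Write a tensor field as a 6-volume NIfTI (lower-triangular order)
#' @param t a [tensor_field()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_tensor <- function(t, path) {
  shp <- dim(t$coefficients)[1:3]
  grid <- volume_grid(t$coefficients,
                      affine = t$affine, space_tag = t$space_tag)
  write_volume(grid, path, datatype = "float64")
}
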