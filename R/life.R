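# Streamline pruning in the spirit of linear fascicle evaluation (LiFE):
# predict the diffusion-weighted signal from the orientation of each
# candidate streamline in every voxel it traverses, solve a non-negative
# least-squares problem against the measured (demeaned) signal, and
# discard zero-weight streamlines.
#
# This is a deliberate reduction of the published kernel: a single-stick
# forward model exp(-b (g.t)^2 d_axial) on the demeaned
# diffusion-weighted signal of one shell, without isotropic
# compartments.

#' Fast non-negative least squares (Bro & de Jong FNNLS)
#'
#' Solves `min ||A x - y||` subject to `x >= 0`, given the normal
#' matrices `AtA = A'A` and `Aty = A'y`. Active-set method; exact for
#' non-degenerate problems.
#'
#' @param AtA p x p cross-product matrix.
#' @param Aty length-p vector.
#' @param tol KKT tolerance; default scales with the problem.
#' @return non-negative solution vector of length p.
#' @export
nnls_fnnls <- function(AtA, Aty, tol = NULL) {
  p <- length(Aty)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(AtA)) * p
  x <- numeric(p)
  P <- logical(p)
  # solve AtA[idx, idx] s = Aty[idx], Cholesky first, pseudoinverse on
  # rank deficiency
  psolve <- function(idx) {
    M <- AtA[idx, idx, drop = FALSE]
    tryCatch({
      R <- chol(M)
      backsolve(R, forwardsolve(t(R), Aty[idx]))
    }, error = function(e)
      drop(MASS_ginv(M) %*% Aty[idx]))
  }
  grad <- function() {
    idx <- which(P)
    if (length(idx) == 0) return(Aty)
    Aty - AtA[, idx, drop = FALSE] %*% x[idx]
  }
  w <- grad()
  iter <- 0L
  max_iter <- 30L * p
  while (any(!P & w > tol) && iter < max_iter) {
    j <- which.max(ifelse(P, -Inf, w))
    P[j] <- TRUE
    repeat {
      s <- numeric(p)
      idx <- which(P)
      s[idx] <- psolve(idx)
      if (all(s[idx] > tol)) { x <- s; break }
      neg <- idx[s[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[x <= tol] <- FALSE
      x[!P] <- 0
      iter <- iter + 1L
      if (iter >= max_iter) break
    }
    w <- grad()
    iter <- iter + 1L
  }
  as.numeric(x)
}

#' Non-negative least squares by block principal pivoting
#'
#' The Portugal-Judice-Vicente block principal pivoting method with the
#' standard backup rule that guarantees finite termination on
#' degenerate problems. Exchanges whole blocks of variables between the
#' active and passive sets, which avoids the one-at-a-time cycling that
#' cripples classical active-set methods when many candidate columns
#' are nearly collinear.
#'
#' @inheritParams nnls_fnnls
#' @return non-negative solution vector of length p.
#' @export
nnls_bpp <- function(AtA, Aty, tol = NULL) {
  p <- length(Aty)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(AtA), 1) * p
  psolve <- function(idx) {
    M <- AtA[idx, idx, drop = FALSE]
    tryCatch({
      R <- chol(M)
      backsolve(R, forwardsolve(t(R), Aty[idx]))
    }, error = function(e) drop(MASS_ginv(M) %*% Aty[idx]))
  }
  FSet <- logical(p)
  x <- numeric(p)
  w <- Aty
  alpha <- 3L
  beta <- p + 1L
  for (it in seq_len(30L * p)) {
    H1 <- which(FSet & x < -tol)
    H2 <- which(!FSet & w > tol)
    ninf <- length(H1) + length(H2)
    if (ninf == 0) break
    if (ninf < beta) {
      beta <- ninf; alpha <- 3L
      exch <- c(H1, H2)
    } else if (alpha > 0L) {
      alpha <- alpha - 1L
      exch <- c(H1, H2)
    } else {
      exch <- max(c(H1, H2))      # backup rule: single largest index
    }
    FSet[exch] <- !FSet[exch]
    x <- numeric(p)
    idx <- which(FSet)
    if (length(idx)) x[idx] <- psolve(idx)
    w <- if (length(idx)) Aty - AtA[, idx, drop = FALSE] %*% x[idx] else Aty
  }
  x[x < 0] <- 0
  as.numeric(x)
}

#' Non-negative least squares, sized to the problem
#'
#' Small problems (p <= 64) go through the classical active-set solver
#' [nnls_fnnls()]; larger ones use block principal pivoting
#' ([nnls_bpp()]), which reaches the same optimum without cycling on
#' near-collinear streamline columns.
#'
#' @inheritParams nnls_fnnls
#' @return non-negative solution vector.
#' @export
nnls_solve <- function(AtA, Aty, tol = NULL) {
  if (length(Aty) <= 64) nnls_fnnls(AtA, Aty, tol)
  else nnls_bpp(AtA, Aty, tol)
}

# Moore-Penrose pseudoinverse (small systems only).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Per-voxel mean tangent of each streamline: returns a data frame of
# (streamline, voxel linear index, tx, ty, tz).
.streamline_voxel_tangents <- function(t, grid, spacing) {
  shp <- vol_shape(grid)
  inv <- solve(grid$affine)
  rows <- vector("list", n_streamlines(t))
  for (f in seq_len(n_streamlines(t))) {
    s <- t$streamlines[[f]]
    len <- streamline_length(s)
    nn <- max(2L, ceiling(len / spacing) + 1L)
    rs <- resample_streamline(s, nn)
    tg <- unit_rows(rbind(rs[2, ] - rs[1, ], rs[-1, ] - rs[-nn, ]))
    ijk <- round(apply_affine(inv, rs))
    ok <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
          ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
          ijk[, 3] >= 0 & ijk[, 3] < shp[3]
    if (!any(ok)) next
    lin <- ijk[ok, 1] + shp[1] * (ijk[ok, 2] + shp[2] * ijk[ok, 3]) + 1
    tgo <- tg[ok, , drop = FALSE]
    # mean tangent per visited voxel, sign-aligned to the first sample
    spl <- split(seq_along(lin), lin)
    vt <- t(vapply(spl, function(ii) {
      tt <- tgo[ii, , drop = FALSE]
      ref <- tt[1, ]
      flip <- (tt %*% ref) < 0
      tt[flip, ] <- -tt[flip, , drop = FALSE]
      v <- colMeans(tt)
      n <- sqrt(sum(v^2))
      if (n == 0) c(1, 0, 0) else v / n
    }, numeric(3)))
    rows[[f]] <- cbind(f, as.integer(names(spl)), vt)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("fiber", "voxel", "tx", "ty", "tz")
  out
}

#' Prune candidate streamlines by non-negative signal prediction
#'
#' Builds a sparse design matrix whose column for streamline `f`
#' accumulates, over each voxel `v` the streamline traverses, the
#' demeaned stick-model signal `exp(-b (g't)^2 d_axial)` for the local
#' mean tangent `t`, scaled by the voxel's mean b0 signal; solves
#' non-negative least squares against the equally demeaned measured
#' diffusion-weighted signal of one shell; and keeps streamlines whose
#' weight exceeds `1e-8 x max(weight)`.
#'
#' @param candidates a non-empty [tractogram()].
#' @param dwi 4-D [volume_grid()].
#' @param gtab a [gradient_table()].
#' @param mask binary [volume_grid()]; only voxels inside it enter the
#'   fit.
#' @param shell b-value of the shell used (default: smallest b > 0).
#' @param d_axial stick axial diffusivity, mm^2/s.
#' @return an object of class `life_result`: list with `weights`
#'   (per-candidate), `kept` ([tractogram()]), `kept_idx`, `error_map`
#'   ([volume_grid()] of per-voxel residual norms), `residual_norm`,
#'   `null_residual_norm`.
#' @export
life_prune <- function(candidates, dwi, gtab, mask, shell = NULL,
                       d_axial = 1.7e-3) {
  if (n_streamlines(candidates) == 0)
    usage_error("no candidate streamlines to prune")
  bpos <- gtab$bvals[gtab$bvals > 0]
  if (is.null(shell)) shell <- min(bpos)
  sel <- which(abs(gtab$bvals - shell) < 1e-6)
  if (length(sel) < 6)
    usage_error("shell b=%g has only %d directions", shell, length(sel))
  g <- gtab$bvecs[sel, , drop = FALSE]
  nd <- length(sel)
  shp <- vol_shape(dwi)
  vsz <- voxel_sizes(dwi)

  tv <- .streamline_voxel_tangents(candidates, dwi, spacing = min(vsz) / 2)
  inmask <- mask$data[tv[, "voxel"]] != 0
  tv <- tv[inmask, , drop = FALSE]
  vox <- sort(unique(tv[, "voxel"]))
  nv <- length(vox)
  if (nv == 0) usage_error("no candidate traverses the mask")
  vrow <- match(tv[, "voxel"], vox)

  # measured signal: per kept voxel, demeaned shell signal
  nxyz <- prod(shp)
  sig <- matrix(0, nv, nd)
  for (k in seq_len(nd))
    sig[, k] <- dwi$data[vox + (sel[k] - 1) * nxyz]
  b0_idx <- which(gtab$bvals == 0)
  s0 <- if (length(b0_idx)) {
    rowMeans(matrix(dwi$data[rep(vox, length(b0_idx)) +
                             rep(b0_idx - 1, each = nv) * nxyz], nv))
  } else rep(1, nv)
  y <- as.numeric(t(sig - rowMeans(sig)))   # voxel-major blocks of nd

  # design: demeaned stick prediction per (voxel, fiber) pair
  gt <- tv[, c("tx", "ty", "tz"), drop = FALSE] %*% t(g)  # pairs x nd
  pred <- exp(-shell * gt^2 * d_axial) * s0[vrow]
  pred <- pred - rowMeans(pred)
  nf <- n_streamlines(candidates)
  A <- Matrix::sparseMatrix(
    i = as.integer(rep((vrow - 1) * nd, each = nd) + rep(seq_len(nd), nrow(tv))),
    j = as.integer(rep(tv[, "fiber"], each = nd)),
    x = as.numeric(t(pred)),
    dims = c(nv * nd, nf))

  zero_cols <- Matrix::colSums(A != 0) == 0
  if (any(zero_cols))
    warning(sum(zero_cols), " candidate(s) contribute no signal and get weight 0",
            call. = FALSE)
  AtA <- as.matrix(Matrix::crossprod(A))
  Aty <- as.numeric(Matrix::crossprod(A, y))
  weights <- nnls_solve(AtA, Aty)
  weights[zero_cols] <- 0

  keep <- weights > 1e-8 * max(weights, 0)
  resid <- y - as.numeric(A %*% weights)
  rm_mat <- matrix(resid, nd, nv)            # nd x nv (voxel-major)
  err <- array(0, shp)
  err[vox] <- sqrt(colSums(rm_mat^2))
  structure(list(
    weights = weights,
    kept = tractogram(candidates$streamlines[keep],
                      space_tag = candidates$space_tag, validate = FALSE),
    kept_idx = which(keep),
    error_map = volume_grid(err, affine = dwi$affine,
                            space_tag = dwi$space_tag),
    residual_norm = sqrt(sum(resid^2)),
    null_residual_norm = sqrt(sum(y^2))),
    class = "life_result")
}

#' @export
print.life_result <- function(x, ...) {
  cat("<life_result>", length(x$weights), "candidates ->",
      n_streamlines(x$kept), "kept; residual",
      signif(x$residual_norm, 4), "(null", signif(x$null_residual_norm, 4),
      ")\n")
  invisible(x)
}

#' Predicted demeaned signal of a weighted streamline set
#'
#' Exposed for equivalence testing (e.g. duplicating every candidate
#' redistributes weights but leaves the prediction unchanged).
#'
#' @inheritParams life_prune
#' @param weights per-candidate weights.
#' @return numeric vector, the model prediction on the fitted rows.
#' @export
life_predict <- function(candidates, dwi, gtab, mask, weights,
                         shell = NULL, d_axial = 1.7e-3) {
  bpos <- gtab$bvals[gtab$bvals > 0]
  if (is.null(shell)) shell <- min(bpos)
  sel <- which(abs(gtab$bvals - shell) < 1e-6)
  g <- gtab$bvecs[sel, , drop = FALSE]
  nd <- length(sel)
  shp <- vol_shape(dwi)
  vsz <- voxel_sizes(dwi)
  tv <- .streamline_voxel_tangents(candidates, dwi, spacing = min(vsz) / 2)
  inmask <- mask$data[tv[, "voxel"]] != 0
  tv <- tv[inmask, , drop = FALSE]
  vox <- sort(unique(tv[, "voxel"]))
  nv <- length(vox)
  vrow <- match(tv[, "voxel"], vox)
  nxyz <- prod(shp)
  b0_idx <- which(gtab$bvals == 0)
  s0 <- if (length(b0_idx)) {
    rowMeans(matrix(dwi$data[rep(vox, length(b0_idx)) +
                             rep(b0_idx - 1, each = nv) * nxyz], nv))
  } else rep(1, nv)
  gt <- tv[, c("tx", "ty", "tz"), drop = FALSE] %*% t(g)
  pred <- exp(-shell * gt^2 * d_axial) * s0[vrow]
  pred <- pred - rowMeans(pred)
  A <- Matrix::sparseMatrix(
    i = as.integer(rep((vrow - 1) * nd, each = nd) + rep(seq_len(nd), nrow(tv))),
    j = as.integer(rep(tv[, "fiber"], each = nd)),
    x = as.numeric(t(pred)),
    dims = c(nv * nd, n_streamlines(candidates)))
  list(prediction = as.numeric(A %*% weights), voxels = vox)
}
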