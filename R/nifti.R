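# NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the standard the pipeline needs: 3-D/4-D volumes,
# datatypes uint8 / int16 / int32 / float32 / float64 / uint16, sform or
# qform (or pixdim fallback) affines, scl_slope/scl_inter scaling.
# Little-endian on write; either endianness on read.

.nifti_dtypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L, 512L),
  what   = c("integer", "integer", "integer", "double", "double", "integer"),
  size   = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param space_tag label attached to the returned volume.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, space_tag = "file") {
  if (!file.exists(path)) usage_error("no such file: %s", path)
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348)
  if (length(hdr_raw) < 348)
    format_error("not a NIfTI-1 file (header truncated at byte %d): %s",
                 length(hdr_raw), path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) format_error("not a NIfTI-1 file (sizeof_hdr=%d): %s", sz, path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    format_error("bad NIfTI magic '%s': %s", magic, path)
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n, 4, endian = endian)
  dim0 <- rd_i16(40, 8)
  ndim <- dim0[1]
  if (!ndim %in% c(3L, 4L))
    format_error("unsupported NIfTI dimensionality %d: %s", ndim, path)
  shp <- dim0[2:(1 + ndim)]
  datatype <- rd_i16(70, 1)
  row <- .nifti_dtypes[.nifti_dtypes$code == datatype, ]
  if (nrow(row) == 0)
    format_error("unsupported NIfTI datatype code %d: %s", datatype, path)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)

  affine <- NULL
  if (sform_code > 0) {
    srow <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    q <- rd_f32(256, 3)          # quatern_b, c, d
    qoff <- rd_f32(268, 3)
    b <- q[1]; c_ <- q[2]; d <- q[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2),
      3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    affine <- rbind(cbind(R %*% S, qoff), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }

  n <- prod(shp)
  # skip any extension bytes between header and data
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, row$what, n, row$size, signed = row$signed,
                  endian = endian)
  if (length(vals) < n)
    format_error("NIfTI body truncated (%d of %d values) at byte offset %d: %s",
                 length(vals), n, vox_offset + length(vals) * row$size, path)
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  volume_grid(array(vals, dim = shp), affine = affine, space_tag = space_tag)
}

#' Write a volume as NIfTI-1
#'
#' The affine is stored in the sform (code 1); data are written
#' little-endian with no scaling. Masks and other integral volumes go
#' out as uint8/int32, everything else as float64.
#'
#' @param v a [volume_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of `"auto"`, `"uint8"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = "auto") {
  stopifnot(is_volume_grid(v))
  d <- v$data
  if (datatype == "auto") {
    datatype <- if (is.logical(d)) "uint8"
                else if (all(d == round(d)) && max(abs(d)) <= 255 && min(d) >= 0) "uint8"
                else if (all(d == round(d)) && max(abs(d)) < 2^31) "int32"
                else "float64"
  }
  code <- switch(datatype, uint8 = 2L, int32 = 8L, float32 = 16L,
                 float64 = 64L,
                 usage_error("unknown datatype '%s'", datatype))
  size <- switch(datatype, uint8 = 1L, int32 = 4L, float32 = 4L, float64 = 8L)
  shp <- dim(d)
  ndim <- length(shp)
  dim0 <- integer(8); dim0[1] <- ndim; dim0[2:(1 + ndim)] <- shp
  dim0[(2 + ndim):8] <- 1L
  vsz <- voxel_sizes(v)
  pixdim <- c(1, vsz, rep(1, 4))

  hdr <- raw(348)
  put <- function(bytes, off) {
    hdr[(off + 1):(off + length(bytes))] <<- bytes
  }
  w_i32 <- function(x, off) put(writeBin(as.integer(x), raw(), 4, endian = "little"), off)
  w_i16 <- function(x, off) put(writeBin(as.integer(x), raw(), 2, endian = "little"), off)
  w_f32 <- function(x, off) put(writeBin(as.numeric(x), raw(), 4, endian = "little"), off)
  w_i32(348L, 0)
  put(charToRaw("r"), 39)                       # dim_info unused
  w_i16(dim0, 40)
  w_i16(code, 70)
  w_i16(8L * size, 72)                          # bitpix
  w_f32(pixdim, 76)
  w_f32(352, 108)                               # vox_offset
  w_f32(1, 112); w_f32(0, 116)                  # scl_slope / inter
  put(as.raw(10L), 123)                         # xyzt_units: mm
  w_i16(0L, 252)                                # qform_code
  w_i16(1L, 254)                                # sform_code
  w_f32(v$affine[1, ], 280)
  w_f32(v$affine[2, ], 296)
  w_f32(v$affine[3, ], 312)
  put(c(charToRaw("n+1"), as.raw(0L)), 344)

  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                         # extension flag = 0
  vals <- as.vector(d)
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(vals)), con)
  } else if (datatype == "int32") {
    writeBin(as.integer(vals), con, size = size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = size, endian = "little")
  }
  invisible(path)
}
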