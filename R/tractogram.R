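#' Tractogram: an ordered collection of streamlines in world mm
#'
#' Each streamline is an n x 3 matrix of RAS world coordinates (mm) with
#' at least two points and no coincident consecutive points.
#'
#' @param streamlines list of numeric n x 3 matrices.
#' @param space_tag character label of the coordinate space.
#' @param validate check streamline invariants (set `FALSE` on hot paths).
#' @return an object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), space_tag = "phantom",
                       validate = TRUE) {
  streamlines <- lapply(streamlines, function(s) {
    s <- matrix(as.numeric(s), ncol = 3)
    dimnames(s) <- NULL
    s
  })
  if (validate && length(streamlines)) {
    for (i in seq_along(streamlines)) {
      s <- streamlines[[i]]
      if (nrow(s) < 2)
        usage_error("streamline %d has fewer than 2 points", i)
      if (anyNA(s))
        usage_error("streamline %d contains NaN/NA coordinates", i)
      seg <- sqrt(rowSums((s[-1, , drop = FALSE] -
                           s[-nrow(s), , drop = FALSE])^2))
      if (any(seg == 0))
        usage_error("streamline %d has zero-length segment", i)
    }
  }
  structure(list(streamlines = streamlines, space_tag = space_tag),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat("<tractogram>", n, "streamlines; space:", x$space_tag, "\n")
  if (n) {
    npts <- vapply(x$streamlines, nrow, 1L)
    cat("  points per streamline:", min(npts), "-", max(npts), "\n")
  }
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Number of streamlines in a tractogram
#' @param t a [tractogram()].
#' @export
n_streamlines <- function(t) length(t$streamlines)

#' Read a tractogram from TCK (MRtrix) or TRK (TrackVis) format
#'
#' TCK coordinates are already world mm and are passed through. TRK
#' stores coordinates in "voxel-mm" with the origin at the corner of the
#' first voxel; they are converted to world RAS via the header's
#' vox_to_ras matrix, so the returned streamlines are always world mm.
#'
#' @param path input file.
#' @param format `"tck"`, `"trk"`, or `"auto"` (from the extension).
#' @return a [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tck", "trk"))
      usage_error("cannot infer tractogram format from '%s'", path)
  }
  if (!file.exists(path)) usage_error("no such file: %s", path)
  switch(format, tck = .read_tck(path), trk = .read_trk(path))
}

#' Write a tractogram to TCK or TRK
#'
#' @param t a [tractogram()].
#' @param path output file.
#' @param format `"tck"`, `"trk"`, or `"auto"` (from the extension).
#' @param trk_affine voxel-to-world affine stored in the TRK header
#'   (TRK only); world coordinates are converted to the TRK voxel-mm
#'   dialect through its inverse.
#' @param trk_dim grid dimensions for the TRK header (TRK only).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(t, path, format = c("auto", "tck", "trk"),
                             trk_affine = diag(4), trk_dim = c(64L, 64L, 64L)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tck", "trk"))
      usage_error("cannot infer tractogram format from '%s'", path)
  }
  switch(format,
         tck = .write_tck(t, path),
         trk = .write_trk(t, path, trk_affine, trk_dim))
  invisible(path)
}

# ---- TCK ------------------------------------------------------------------

.read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, 1, warn = FALSE)
  if (!identical(first, "mrtrix tracks"))
    format_error("not a TCK file (bad signature) at byte 0: %s", path)
  offset <- NA_real_
  dtype <- "Float32LE"
  count <- NA_integer_
  repeat {
    line <- readLines(con, 1, warn = FALSE)
    if (length(line) == 0)
      format_error("TCK header missing END: %s", path)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(":", line), invert = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "file") {
      offset <- as.numeric(sub("^\\.\\s+", "", val))
    } else if (key == "datatype") {
      dtype <- val
    } else if (key == "count") {
      count <- as.integer(val)
    }
  }
  if (is.na(offset)) format_error("TCK header lacks 'file' field: %s", path)
  size <- if (grepl("64", dtype)) 8L else 4L
  endian <- if (grepl("BE$", dtype)) "big" else "little"
  seek(con, offset)
  body_bytes <- file.size(path) - offset
  vals <- readBin(con, "double", n = body_bytes %/% size, size = size,
                  endian = endian)
  if (length(vals) %% 3 != 0)
    format_error("TCK body length not a multiple of 3 at byte offset %.0f: %s",
                 offset + length(vals) * size, path)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  terminated <- FALSE
  for (r in seq_len(nrow(m))) {
    if (all(is.nan(m[r, ]))) {
      if (r > start)
        streamlines[[length(streamlines) + 1L]] <- m[start:(r - 1L), , drop = FALSE]
      start <- r + 1L
    } else if (all(is.infinite(m[r, ]))) {
      terminated <- TRUE
      break
    }
  }
  if (!terminated)
    format_error("TCK body missing Inf terminator (truncated) at byte offset %.0f: %s",
                 offset + nrow(m) * 3 * size, path)
  if (!is.na(count) && count != length(streamlines))
    format_error("TCK declared count %d but body holds %d streamlines: %s",
                 count, length(streamlines), path)
  tractogram(streamlines, space_tag = "world")
}

.write_tck <- function(t, path) {
  n <- n_streamlines(t)
  fixed <- paste0(paste(c("mrtrix tracks",
                          "datatype: Float32LE",
                          sprintf("count: %d", n),
                          "timestamp: 0"), collapse = "\n"), "\n")
  # the offset names the byte where the binary section starts, which
  # depends on its own printed width: iterate to the fixed point
  off <- 0L
  repeat {
    hdr_txt <- paste0(fixed, sprintf("file: . %d", off), "\nEND\n")
    total <- nchar(hdr_txt, type = "bytes")
    if (total == off) break
    off <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr_txt, con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- TRK ------------------------------------------------------------------

.read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1000)
  if (length(hdr) < 1000)
    format_error("TRK header truncated at byte %d: %s", length(hdr), path)
  if (rawToChar(hdr[1:5]) != "TRACK")
    format_error("not a TRK file (bad id string) at byte 0: %s", path)
  rd_i16 <- function(off, n, e) readBin(hdr[(off + 1):(off + 2 * n)],
                                        "integer", n, 2, endian = e)
  rd_i32 <- function(off, n, e) readBin(hdr[(off + 1):(off + 4 * n)],
                                        "integer", n, 4, endian = e)
  rd_f32 <- function(off, n, e) readBin(hdr[(off + 1):(off + 4 * n)],
                                        "double", n, 4, endian = e)
  endian <- "little"
  if (rd_i32(996, 1, endian) != 1000L) {
    endian <- "big"
    if (rd_i32(996, 1, endian) != 1000L)
      format_error("TRK hdr_size field invalid: %s", path)
  }
  voxel_size <- rd_f32(12, 3, endian)
  n_scalars <- rd_i16(36, 1, endian)
  n_properties <- rd_i16(238, 1, endian)
  M <- matrix(rd_f32(440, 16, endian), 4, 4, byrow = TRUE)
  if (all(M == 0)) M <- diag(4)            # pre-v2 files: assume identity
  n_count <- rd_i32(988, 1, endian)
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1, 4, endian = endian)
    if (length(npts) == 0) break
    vals <- readBin(con, "double", npts * (3 + n_scalars), 4, endian = endian)
    if (length(vals) < npts * (3 + n_scalars))
      format_error("TRK body truncated inside streamline %d: %s",
                   length(streamlines) + 1L, path)
    if (n_properties > 0) readBin(con, "double", n_properties, 4, endian = endian)
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # voxel-mm, corner origin -> 0-based voxel index -> world
    idx <- sweep(pm, 2, voxel_size, "/") - 0.5
    streamlines[[length(streamlines) + 1L]] <- apply_affine(M, idx)
  }
  if (n_count > 0 && n_count != length(streamlines))
    format_error("TRK declared n_count %d but body holds %d streamlines: %s",
                 n_count, length(streamlines), path)
  tractogram(streamlines, space_tag = "world")
}

.write_trk <- function(t, path, affine, dim3) {
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  inv <- solve(affine)
  hdr <- raw(1000)
  put <- function(bytes, off) hdr[(off + 1):(off + length(bytes))] <<- bytes
  w_i16 <- function(x, off) put(writeBin(as.integer(x), raw(), 2, endian = "little"), off)
  w_i32 <- function(x, off) put(writeBin(as.integer(x), raw(), 4, endian = "little"), off)
  w_f32 <- function(x, off) put(writeBin(as.numeric(x), raw(), 4, endian = "little"), off)
  put(c(charToRaw("TRACK"), as.raw(0L)), 0)
  w_i16(dim3, 6)
  w_f32(voxel_size, 12)
  w_f32(c(0, 0, 0), 24)
  w_i16(0L, 36)                                  # n_scalars
  w_i16(0L, 238)                                 # n_properties
  w_f32(as.numeric(t(affine)), 440)              # vox_to_ras
  put(charToRaw("RAS"), 948)                     # voxel_order
  w_i32(n_streamlines(t), 988)
  w_i32(2L, 992)                                 # version
  w_i32(1000L, 996)                              # hdr_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (s in t$streamlines) {
    idx <- apply_affine(inv, s)
    pm <- sweep(idx + 0.5, 2, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(pm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
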