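#' Gradient table: per-volume b-value and unit direction
#'
#' @param bvals numeric vector, s/mm^2, one per diffusion volume.
#' @param bvecs n x 3 matrix of gradient directions; rows with b > 0 must
#'   be unit length (tolerance 1e-6), rows with b = 0 may be zero.
#' @return an object of class `gradient_table`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  if (length(bvals) != nrow(bvecs))
    usage_error("bvals (%d) and bvecs (%d rows) disagree in length",
                length(bvals), nrow(bvecs))
  if (any(bvals < 0)) usage_error("negative b-value")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    usage_error("non-unit gradient direction at volume(s) %s",
                paste(which(bad), collapse = ", "))
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table>", length(x$bvals), "volumes; shells:",
      paste(sort(unique(round(x$bvals))), collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' Evenly spread unit directions by electrostatic repulsion
#'
#' Starts from a deterministic Fibonacci-sphere arrangement and runs a
#' fixed number of projected-gradient steps minimizing the antipodally
#' symmetric Coulomb energy sum(1/|xi - xj| + 1/|xi + xj|), the standard
#' construction for diffusion sampling schemes. Fully deterministic.
#'
#' @param n number of directions.
#' @param n_iter repulsion iterations.
#' @return n x 3 matrix of unit vectors.
#' @export
repulsion_directions <- function(n, n_iter = 200) {
  if (n < 1) usage_error("need at least one direction")
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  x <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (j in seq_len(n)) {
      d1 <- sweep(x, 2, x[j, ])              # xi - xj
      d2 <- sweep(x, 2, -x[j, ])             # xi + xj
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-9)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-9)
      r1[j] <- Inf
      force <- force + d1 / r1^3 + d2 / r2^3
    }
    x <- x + step * force / n
    x <- unit_rows(x)
  }
  x
}

#' Build a multi-shell acquisition scheme
#'
#' @param shells b-values of the diffusion-weighted shells, s/mm^2.
#' @param dirs_per_shell directions per shell.
#' @param n_b0 number of b = 0 volumes (placed first).
#' @return a [gradient_table()].
#' @export
make_scheme <- function(shells = c(1000, 2000, 3000), dirs_per_shell = 30,
                        n_b0 = 6) {
  dirs <- repulsion_directions(dirs_per_shell)
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, n_b0, 3)
  for (k in seq_along(shells)) {
    # small deterministic rotation per shell so shells interleave
    ang <- (k - 1) * pi / 7
    Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    bvals <- c(bvals, rep(shells[k], dirs_per_shell))
    bvecs <- rbind(bvecs, dirs %*% t(Rz))
  }
  gradient_table(bvals, bvecs)
}

#' Read / write FSL-style bval and bvec text files
#'
#' `bvals` is one whitespace-separated row; `bvecs` is three rows
#' (x, y, z components), one column per volume.
#'
#' @param bval_path,bvec_path file paths.
#' @return for the reader, a [gradient_table()]; the writer returns the
#'   paths invisibly.
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3)
    format_error("bvec file must have 3 rows, got %d", nrow(bv))
  gradient_table(bvals, t(bv))
}

#' @rdname read_scheme
#' @param gtab a [gradient_table()].
#' @export
write_scheme <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  m <- t(gtab$bvecs)
  writeLines(apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
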