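#' @useDynLib retinotract, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator with `seed`,
#' evaluates `expr`, and restores the previous RNG state on exit. All
#' stochastic operations in the package funnel their randomness through
#' this helper so that a fixed seed yields bit-identical output.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ..., class = "retinotract_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

usage_error <- function(fmt, ...) stopf(fmt, ..., class = "retinotract_usage_error")
format_error <- function(fmt, ...) stopf(fmt, ..., class = "retinotract_format_error")
model_error <- function(fmt, ...) stopf(fmt, ..., class = "retinotract_model_error")
geometry_error <- function(fmt, ...) stopf(fmt, ..., class = "retinotract_geometry_error")

#' Normalize rows of a matrix to unit length
#' @keywords internal
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Apply a 4x4 affine to an n x 3 coordinate matrix.
apply_affine <- function(affine, pts) {
  pts <- matrix(pts, ncol = 3)
  out <- cbind(pts, 1) %*% t(affine)
  out[, 1:3, drop = FALSE]
}
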