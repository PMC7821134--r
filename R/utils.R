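#' Wrap angles into (-pi, pi]
#'
#' The wrap operator \eqn{\Omega} maps any angle to its representative in
#' the half-open interval \eqn{(-\pi, \pi]}, i.e. the value congruent to
#' the input modulo \eqn{2\pi} with the smallest magnitude (ties resolved
#' towards \eqn{+\pi}). NaN/NA propagate.
#'
#' @param x numeric vector or array of angles in radians.
#' @return object of the same shape with all finite values in
#'   \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_to_pi(c(0, 2 * pi, 3.5 * pi))   # 0, 0, -pi/2
#' @export
wrap_to_pi <- function(x) {
  x - (2 * pi) * ceiling((x - pi) / (2 * pi))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# dims of a 3D/4D array, tolerating plain vectors for 1-voxel edge cases
dim3 <- function(a) {
  d <- dim(a)
  if (is.null(d)) stop("expected an array, got a dimensionless vector")
  d
}

# extract volume t of a 4D array as 3D without dropping singleton axes
vol_at <- function(a, t) {
  v <- a[, , , t, drop = FALSE]
  dim(v) <- dim(v)[1:3]
  v
}

stopifnot_shape <- function(a, b, what = "arrays") {
  if (!identical(dim3(a), dim3(b))) {
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim3(a), collapse = "x"),
                 paste(dim3(b), collapse = "x")))
  }
}
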