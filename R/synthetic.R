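#' Generate a smooth synthetic B0 field topography
#'
#' The field is a reproducible stand-in for the complex field-inhomogeneity
#' topographies used to benchmark unwrappers: a random mixture of broad 3D
#' Gaussian sources blended with a random linear gradient, recentred and
#' scaled so that the peak deviation is exactly `amplitude_hz` in both
#' directions (peak-to-peak range `2 * amplitude_hz`). The construction is
#' infinitely differentiable and, with the default source widths, keeps
#' the phase difference between 6-neighbours below \eqn{\pi} at the echo
#' times of the default phantom, so exact recovery by a spatial unwrapper
#' is well-posed. Fully deterministic given `rng_seed`.
#'
#' @param shape integer triple, at least `(8, 8, 8)`.
#' @param n_sources number of Gaussian sources (>= 1; use
#'   `gradient_frac = 1` for a purely planar field).
#' @param amplitude_hz target peak `|delta B0|` in Hz.
#' @param gradient_frac blend fraction (0..1) of the linear-gradient
#'   component.
#' @param rng_seed integer seed.
#' @return 3D array: the `delta B0` field in Hz.
#' @export
make_topography <- function(shape, n_sources = 8, amplitude_hz = 1250,
                            gradient_frac = 0.4, rng_seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("shape must be a triple with every extent >= 8")
  }
  if (n_sources < 1) stop("n_sources must be >= 1")
  with_seed(rng_seed, {
    # normalized coordinates in [0, 1] per axis
    u <- lapply(shape, function(n) seq(0, 1, length.out = n))
    mix <- array(0, dim = shape)
    for (k in seq_len(n_sources)) {
      centre <- runif(3, 0.15, 0.85)
      sigma <- runif(1, 0.28, 0.45)
      amp <- runif(1, -1, 1)
      gx <- exp(-((u[[1]] - centre[1])^2) / (2 * sigma^2))
      gy <- exp(-((u[[2]] - centre[2])^2) / (2 * sigma^2))
      gz <- exp(-((u[[3]] - centre[3])^2) / (2 * sigma^2))
      mix <- mix + amp * (gx %o% gy %o% gz)
    }
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    plane <- ((u[[1]] - 0.5) * dir[1]) %o% rep(1, shape[2]) %o% rep(1, shape[3]) +
      rep(1, shape[1]) %o% ((u[[2]] - 0.5) * dir[2]) %o% rep(1, shape[3]) +
      rep(1, shape[1]) %o% rep(1, shape[2]) %o% ((u[[3]] - 0.5) * dir[3])
    rng <- function(a) {
      s <- max(a) - min(a)
      if (s == 0) a else a / s
    }
    field <- (1 - gradient_frac) * rng(mix) + gradient_frac * rng(plane)
    if (amplitude_hz == 0) return(array(0, dim = shape))
    mx <- max(field); mn <- min(field)
    if (mx == mn) stop("degenerate (constant) topography; change the seed")
    (field - (mx + mn) / 2) * (2 * amplitude_hz / (mx - mn))
  })
}

# smooth magnitude object in [0.3, 1] with optional deep low-SNR pockets
# and a thin zero-signal line segment whose end lies inside the object
# (the classic open-ended fringe-line failure locus)
make_magnitude <- function(shape, snr_pockets = 2, fringe_line = TRUE) {
  u <- lapply(shape, function(n) seq(0, 1, length.out = n))
  mix <- array(0, dim = shape)
  for (k in 1:3) {
    centre <- runif(3, 0.2, 0.8)
    sigma <- runif(1, 0.25, 0.4)
    amp <- runif(1, -1, 1)
    gx <- exp(-((u[[1]] - centre[1])^2) / (2 * sigma^2))
    gy <- exp(-((u[[2]] - centre[2])^2) / (2 * sigma^2))
    gz <- exp(-((u[[3]] - centre[3])^2) / (2 * sigma^2))
    mix <- mix + amp * (gx %o% gy %o% gz)
  }
  s <- (mix - min(mix)) / max(max(mix) - min(mix), .Machine$double.eps)
  m <- 0.3 + 0.7 * s
  if (snr_pockets > 0) {
    idx <- lapply(shape, seq_len)
    for (k in seq_len(snr_pockets)) {
      centre <- vapply(shape, function(n) runif(1, 0.25 * n, 0.75 * n), 0)
      sigma <- runif(1, 2.5, 4.5) # voxels
      gx <- exp(-((idx[[1]] - centre[1])^2) / (2 * sigma^2))
      gy <- exp(-((idx[[2]] - centre[2])^2) / (2 * sigma^2))
      gz <- exp(-((idx[[3]] - centre[3])^2) / (2 * sigma^2))
      m <- m * (1 - 0.97 * (gx %o% gy %o% gz))
    }
  }
  if (fringe_line) {
    len <- max(2L, shape[1] %/% 4L)
    x0 <- shape[1] %/% 3L
    m[x0:(x0 + len - 1L), shape[2] %/% 2L, shape[3] %/% 2L] <- 0
  }
  m
}

#' Simulate a multi-echo wrapped-phase phantom with exact ground truth
#'
#' The true phase at each echo is exactly \eqn{\theta_t = 2\pi\,TE_t\,
#' \Delta B_0} (TE in seconds). Noise is added per voxel and echo under
#' one of two models:
#' \describe{
#'   \item{`"complex"` (default)}{independent Gaussian noise on the real
#'     and imaginary channels of \eqn{M e^{i\theta}}, with SD
#'     `noise_fraction * max(magnitude)`; `noise_fraction = 0.1` thus
#'     corresponds to SNR 10 in full-signal voxels, with phase noise
#'     growing as the local signal falls and becoming uniform where the
#'     signal is zero. The reported magnitude is the noisy modulus.}
#'   \item{`"phase"`}{additive Gaussian phase noise with per-voxel SD
#'     `noise_fraction * |theta_true|`, a literal "percentage of the
#'     phase" reading; magnitude is noise-free.}
#' }
#' In both cases the stored `theta_noisy` is the exact pre-wrap phase
#' (truth plus realized noise), the target an unwrapper can at best
#' recover: `phase_wrapped` is its wrapped representative and unwrapping
#' errors against `theta_noisy` are exact multiples of \eqn{2\pi}.
#'
#' @param field 3D `delta B0` array in Hz (see [make_topography()]).
#' @param echo_times echo times in ms; default `c(4, 8, 10)`.
#' @param noise_fraction noise level (>= 0); 0 disables noise entirely.
#' @param noise_model `"complex"` or `"phase"`.
#' @param magnitude optional 3D magnitude object; by default a smooth
#'   object in `[0.3, 1]` with `snr_pockets` deep low-SNR pockets and
#'   (optionally) a thin zero-signal segment that seeds an open-ended
#'   fringe line under noise.
#' @param snr_pockets,fringe_line controls for the default magnitude
#'   object.
#' @param rng_seed integer seed; fully determines the phantom.
#' @return an object of class `phantom`: list with `delta_b0`,
#'   `theta_true`, `theta_noisy`, `phase_wrapped`, `magnitude` (all
#'   4D except `delta_b0`), `echo_times`, `noise_fraction`,
#'   `noise_model`, `rng_seed`.
#' @export
simulate_echoes <- function(field, echo_times = c(4, 8, 10),
                            noise_fraction = 0,
                            noise_model = c("complex", "phase"),
                            magnitude = NULL, snr_pockets = 2,
                            fringe_line = TRUE, rng_seed = 1) {
  noise_model <- match.arg(noise_model)
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  shape <- dim3(field)
  nt <- length(echo_times)
  with_seed(rng_seed, {
    if (is.null(magnitude)) {
      magnitude <- make_magnitude(shape, snr_pockets, fringe_line)
    } else {
      if (!identical(dim3(magnitude), shape)) {
        stop("magnitude shape does not match the field")
      }
    }
    theta_true <- array(0, dim = c(shape, nt))
    for (t in seq_len(nt)) {
      theta_true[, , , t] <- 2 * pi * (echo_times[t] / 1000) * field
    }
    mag4 <- array(rep(magnitude, nt), dim = c(shape, nt))
    if (noise_fraction == 0) {
      theta_noisy <- theta_true
      phase_wrapped <- wrap_to_pi(theta_true)
    } else if (noise_model == "complex") {
      sdn <- noise_fraction * max(magnitude)
      nvol <- prod(shape)
      theta_noisy <- theta_true
      phase_wrapped <- theta_true
      for (t in seq_len(nt)) {
        th <- vol_at(theta_true, t)
        zr <- magnitude * cos(th) + rnorm(nvol, sd = sdn)
        zi <- magnitude * sin(th) + rnorm(nvol, sd = sdn)
        phi <- wrap_to_pi(atan2(zi, zr))
        delta <- wrap_to_pi(phi - wrap_to_pi(th))
        theta_noisy[, , , t] <- th + delta
        phase_wrapped[, , , t] <- phi
        mag4[, , , t] <- sqrt(zr^2 + zi^2)
      }
    } else {
      noise <- array(rnorm(length(theta_true)), dim = dim(theta_true)) *
        (noise_fraction * abs(theta_true))
      theta_noisy <- theta_true + noise
      phase_wrapped <- wrap_to_pi(theta_noisy)
    }
    structure(list(delta_b0 = field, theta_true = theta_true,
                   theta_noisy = theta_noisy, phase_wrapped = phase_wrapped,
                   magnitude = mag4, echo_times = echo_times,
                   noise_fraction = noise_fraction, noise_model = noise_model,
                   rng_seed = rng_seed),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom: grid %s, TE %s ms, noise %.3g (%s), %d wraps at last echo>\n",
    paste(dim(x$delta_b0), collapse = "x"),
    paste(format(x$echo_times, trim = TRUE), collapse = ", "),
    x$noise_fraction, x$noise_model, wrap_count(x)))
  invisible(x)
}

#' Convert a phantom to an echo series
#'
#' @param phantom a `phantom` from [simulate_echoes()].
#' @return an `echo_series` holding the phantom's wrapped phase and noisy
#'   magnitude.
#' @export
as_echo_series <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  echo_series(phantom$phase_wrapped, magnitude = phantom$magnitude,
              echo_times = phantom$echo_times)
}

#' Count phase wraps spanned by a volume
#'
#' The number of full \eqn{2\pi} cycles between the smallest and largest
#' true phase in a volume - a simple difficulty measure of the wrap
#' topography.
#'
#' @param x a `phantom` (last echo used by default) or a 3D array of
#'   unwrapped phase in radians.
#' @param echo 1-based echo index when `x` is a phantom.
#' @return integer wrap count.
#' @export
wrap_count <- function(x, echo = NULL) {
  th <- if (inherits(x, "phantom")) {
    if (is.null(echo)) echo <- length(x$echo_times)
    vol_at(x$theta_true, echo)
  } else x
  as.integer(floor((max(th) - min(th)) / (2 * pi)))
}
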