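#' Count 2-pi-multiple unwrapping errors against a reference
#'
#' Unwrapping never changes a voxel's phase modulo \eqn{2\pi}, so the
#' difference between an unwrapped estimate and a congruent reference is a
#' per-voxel integer number of cycles `n`. Voxels with `n != 0` are
#' erroneous. Because a spatial unwrapper anchors each connected
#' component only up to one global cycle offset, the modal `n` is removed
#' first by default (set `remove_global = FALSE` for raw counting; the
#' removed offset is reported as `global_k`). Differences that are not
#' close to a multiple of \eqn{2\pi} (possible when the reference is
#' itself noisy) are binned to the nearest `n`; a warning is emitted when
#' more than 1% of voxels have residuals above 0.5 rad.
#'
#' @param theta_est,theta_ref 3D unwrapped phase arrays (radians).
#' @param mask optional 3D logical evaluation mask.
#' @param remove_global remove the modal cycle offset before counting.
#' @return a `wrap_error_report`: list with `counts_by_n` (named integer
#'   vector over observed `n`), `n_errors`, `percent_errors`, `global_k`,
#'   `n_evaluated`.
#' @export
wrap_error_report <- function(theta_est, theta_ref, mask = NULL,
                              remove_global = TRUE) {
  stopifnot_shape(theta_est, theta_ref, "estimate and reference")
  keep <- is.finite(theta_est) & is.finite(theta_ref)
  if (!is.null(mask)) {
    stopifnot_shape(mask, theta_est, "mask and estimate")
    keep <- keep & mask
  }
  if (!any(keep)) stop("empty evaluation region")
  diff <- (theta_est[keep] - theta_ref[keep]) / (2 * pi)
  n <- round(diff)
  resid <- abs(diff - n) * 2 * pi
  if (mean(resid > 0.5) > 0.01) {
    warning(sprintf(
      "%.1f%% of voxels deviate from a 2*pi multiple by > 0.5 rad; ",
      100 * mean(resid > 0.5)),
      "estimate and reference may not be congruent")
  }
  global_k <- 0L
  if (remove_global) {
    tab <- table(n)
    global_k <- as.integer(names(tab)[which.max(tab)])
    n <- n - global_k
  }
  counts <- table(n)
  counts_by_n <- as.integer(counts)
  names(counts_by_n) <- names(counts)
  n_eval <- length(n)
  n_err <- n_eval - sum(n == 0)
  structure(list(counts_by_n = counts_by_n,
                 n_errors = n_err,
                 percent_errors = 100 * n_err / n_eval,
                 global_k = global_k,
                 n_evaluated = n_eval),
            class = "wrap_error_report")
}

#' @export
print.wrap_error_report <- function(x, ...) {
  cat(sprintf(
    "<wrap_error_report: %d/%d voxels erroneous (%.4g%%), global offset %d cycle(s)>\n",
    x$n_errors, x$n_evaluated, x$percent_errors, x$global_k))
  if (length(x$counts_by_n) > 1L) {
    cat("  cycles-off histogram:\n")
    print(x$counts_by_n)
  }
  invisible(x)
}

#' Build a temporal reference across echoes from one unwrapped volume
#'
#' Given an unwrapped (trusted) first-echo phase, the reference for each
#' later echo assumes linear phase evolution in time. When the wrapped
#' phase of the later echoes is supplied, each volume is obtained with
#' [template_propagate()] (the measured phase snapped to the TE-scaled
#' prediction); without it, the reference is the pure scaling
#' `theta_first * TE_t / TE_1`.
#'
#' @param theta_first 3D unwrapped phase at the first echo.
#' @param echo_times echo times in ms (first entry corresponds to
#'   `theta_first`).
#' @param phase optional 4D wrapped phase for all echoes.
#' @return 4D reference phase.
#' @export
temporal_reference <- function(theta_first, echo_times, phase = NULL) {
  nt <- length(echo_times)
  shape <- dim3(theta_first)
  out <- array(0, dim = c(shape, nt))
  for (t in seq_len(nt)) {
    out[, , , t] <- if (is.null(phase)) {
      theta_first * echo_times[t] / echo_times[1]
    } else {
      template_propagate(theta_first, vol_at(phase, t),
                         echo_times[1], echo_times[t])
    }
  }
  out
}

#' Per-voxel standard deviation of the field map over echoes
#'
#' Each echo yields its own field-map estimate; if the phase was
#' unwrapped consistently, these agree and the per-voxel SD over echoes
#' is near zero. Residual echo-dependent unwrapping errors appear as
#' localized high-SD voxels.
#'
#' @param theta 4D unwrapped phase (>= 2 echoes), radians.
#' @param echo_times echo times in ms.
#' @param units passed to [compute_fieldmap()].
#' @return 3D SD map (Hz by default).
#' @export
fieldmap_sd <- function(theta, echo_times, units = c("hz", "rad_s")) {
  d <- dim3(theta)
  if (length(d) != 4L || d[4] < 2L) stop("need a 4D array with >= 2 echoes")
  fm <- compute_fieldmap(theta, echo_times, units = units)
  apply(fm, 1:3, sd)
}

#' Count global cycle jumps between consecutive volumes
#'
#' A whole-volume \eqn{2\pi n} jump between consecutive time points is a
#' typical failure of volume-by-volume unwrapping of time series. A pair
#' of consecutive volumes counts as a jump when the median (within the
#' mask) of their phase difference rounds to a nonzero number of cycles.
#'
#' @param theta 4D unwrapped phase (>= 2 volumes).
#' @param mask optional 3D logical mask.
#' @return integer number of jumps.
#' @export
count_global_jumps <- function(theta, mask = NULL) {
  d <- dim3(theta)
  if (length(d) != 4L || d[4] < 2L) stop("need a 4D array with >= 2 volumes")
  jumps <- 0L
  for (t in seq_len(d[4] - 1L)) {
    dv <- vol_at(theta, t + 1L) - vol_at(theta, t)
    if (!is.null(mask)) dv <- dv[mask] else dv <- dv[is.finite(dv)]
    if (round(median(dv) / (2 * pi)) != 0) jumps <- jumps + 1L
  }
  jumps
}

#' Error histogram figure (log-scaled counts per cycle offset)
#'
#' @param report a `wrap_error_report`.
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_error_histogram <- function(report) {
  stopifnot(inherits(report, "wrap_error_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(n = as.integer(names(report$counts_by_n)),
                   count = as.numeric(report$counts_by_n))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n), y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cycles off (n)", y = "voxels (log scale)") +
    ggplot2::theme_minimal()
}
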