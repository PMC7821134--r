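#' Normalize phase values into (-pi, pi]
#'
#' Scanner phase exports are frequently stored as scaled integers (e.g.
#' 0..4095) rather than radians. `normalize_phase` autodetects the scale:
#' data whose magnitude never exceeds \eqn{\pi} (up to a 0.1% slack) are
#' taken to be radians already and pass through unchanged apart from
#' mapping \eqn{-\pi} onto its \eqn{+\pi} representative; anything else is
#' linearly rescaled from its observed range onto one full phase cycle.
#' For integer-valued input the full cycle is `max - min + 1` levels wide
#' (so 0..4095 maps 0 to \eqn{-\pi} and the virtual level 4096 to
#' \eqn{+\pi}); otherwise the observed `[min, max]` spans the cycle. NaN
#' values are preserved.
#'
#' @param raw numeric array (3D or 4D) of phase values.
#' @return array of the same shape with all finite values in
#'   \eqn{(-\pi, \pi]}.
#' @export
normalize_phase <- function(raw) {
  fin <- is.finite(raw)
  if (!any(fin)) stop("phase volume contains no finite values")
  v <- raw[fin]
  if (max(abs(v)) <= pi * (1 + 1e-3)) {
    # already radians; unify the wrap-boundary representative
    out <- raw
    out[fin & raw <= -pi] <- pi
    return(out)
  }
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    stop("constant-valued phase volume outside [-pi, pi]: rescale undefined")
  }
  width <- if (all(v == round(v))) hi - lo + 1 else hi - lo
  out <- (raw - lo) / width * (2 * pi) - pi
  wrap_to_pi(out)
}

#' Read a 3D/4D phase (and magnitude) series from NIfTI files
#'
#' Accepts either one 4D file or an ordered list of 3D files per contrast.
#' Phase is normalized to radians in \eqn{(-\pi, \pi]} via
#' [normalize_phase()]; the first file's NIfTI header is retained for
#' writing results back on the same grid. No reorientation is performed:
#' unwrapping is agnostic to the anatomical meaning of the axes.
#'
#' @param phase_paths character vector of NIfTI paths holding the wrapped
#'   phase (one 4D file, or one 3D file per echo/time point).
#' @param magnitude_paths optional character vector of matching magnitude
#'   volumes (same convention and grid).
#' @param echo_times numeric vector of echo times in ms, one per volume;
#'   must be strictly increasing (multi-echo) or all equal (a constant-TE
#'   time series).
#' @return an object of class `echo_series`: list with `phase` (4D array,
#'   radians), `magnitude` (4D array or `NULL`), `echo_times`,
#'   `grid_dim` and `reference` (an `RNifti` image for header reuse).
#' @export
read_series <- function(phase_paths, magnitude_paths = NULL, echo_times) {
  vols <- read_volumes(phase_paths)
  reference <- vols$reference
  phase <- vols$data
  mag <- NULL
  if (!is.null(magnitude_paths)) {
    mvols <- read_volumes(magnitude_paths)
    stopifnot_shape(mvols$data, phase, "magnitude and phase")
    mag <- mvols$data
  }
  echo_series(phase, magnitude = mag, echo_times = echo_times,
              reference = reference)
}

#' Assemble an echo series from in-memory arrays
#'
#' @param phase 3D or 4D array of wrapped phase (any scaling accepted; see
#'   [normalize_phase()]).
#' @param magnitude optional matching magnitude array (values >= 0).
#' @param echo_times echo times in ms (see [read_series()]).
#' @param reference optional `RNifti` image whose header is reused when
#'   writing results.
#' @return an `echo_series` object.
#' @export
echo_series <- function(phase, magnitude = NULL, echo_times,
                        reference = NULL) {
  if (length(dim(phase)) == 3L) dim(phase) <- c(dim(phase), 1L)
  if (length(dim(phase)) != 4L) stop("phase must be a 3D or 4D array")
  nt <- dim(phase)[4]
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) != nt) {
    stop(sprintf("echo_times has length %d but the series has %d volumes",
                 length(echo_times), nt))
  }
  if (any(echo_times <= 0)) stop("echo times must be positive")
  d <- diff(echo_times)
  if (length(d) && !(all(d > 0) || all(d == 0))) {
    stop("echo times must be strictly increasing, or all equal for a time series")
  }
  if (!is.null(magnitude)) {
    if (length(dim(magnitude)) == 3L) dim(magnitude) <- c(dim(magnitude), 1L)
    stopifnot_shape(magnitude, phase, "magnitude and phase")
    if (any(magnitude[is.finite(magnitude)] < 0)) {
      stop("magnitude must be non-negative")
    }
  }
  structure(list(phase = normalize_phase(phase), magnitude = magnitude,
                 echo_times = echo_times,
                 grid_dim = dim(phase)[1:3], reference = reference),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("<echo_series: grid %s, %d volume(s), TE %s ms%s>\n",
              paste(x$grid_dim, collapse = "x"), length(x$echo_times),
              paste(format(x$echo_times, trim = TRUE), collapse = ", "),
              if (is.null(x$magnitude)) "" else ", with magnitude"))
  invisible(x)
}

# read one 4D file or several 3D files into a single 4D array
read_volumes <- function(paths) {
  paths <- as.character(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("file not found: ", paste(missing, collapse = ", "))
  }
  imgs <- lapply(paths, RNifti::readNifti)
  arrs <- lapply(imgs, function(im) {
    a <- as.array(im)
    if (!length(dim(a)) %in% c(3L, 4L)) {
      stop("volumes must be 3D or 4D, got ", length(dim(a)), "D")
    }
    a
  })
  if (length(arrs) == 1L) {
    data <- arrs[[1L]]
    if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  } else {
    if (any(vapply(arrs, function(a) length(dim(a)), 1L) != 3L)) {
      stop("when several files are given, each must be a 3D volume")
    }
    g <- dim(arrs[[1L]])
    for (a in arrs) {
      if (!identical(dim(a), g)) {
        stop("shape mismatch between volumes: ",
             paste(g, collapse = "x"), " vs ",
             paste(dim(a), collapse = "x"))
      }
    }
    data <- array(unlist(arrs, use.names = FALSE), dim = c(g, length(arrs)))
  }
  list(data = data, reference = imgs[[1L]])
}

#' Write an array as NIfTI, reusing a reference header
#'
#' @param array 3D or 4D numeric array to write.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference optional `RNifti` image (or an `echo_series`) whose
#'   header/affine is copied; its grid must match `array`.
#' @param datatype storage type, default single-precision float.
#' @return the path, invisibly.
#' @export
write_volume <- function(array, path, reference = NULL,
                         datatype = "float") {
  if (inherits(reference, "echo_series")) reference <- reference$reference
  if (!is.null(reference)) {
    rd <- dim(as.array(reference))
    if (!identical(as.integer(dim3(array)[1:3]), as.integer(rd[1:3]))) {
      stop("array grid does not match the reference header")
    }
  }
  img <- RNifti::asNifti(array, reference = reference)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary inclusion mask
#'
#' Nonzero voxels are included. The mask must match the series grid and
#' select at least one voxel.
#'
#' @param path NIfTI file with nonzero = included.
#' @param grid_dim integer triple the mask must match.
#' @return 3D logical array.
#' @export
read_mask <- function(path, grid_dim = NULL) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L) stop("mask must be a single 3D volume")
  m <- is.finite(a) & a != 0
  if (!is.null(grid_dim) && !identical(dim(m), as.integer(grid_dim))) {
    stop("mask shape does not match the series grid")
  }
  if (!any(m)) stop("mask selects no voxels")
  m
}
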