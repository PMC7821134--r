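#' Spatial phase coherence weight
#'
#' For each 6-neighbour edge along one axis,
#' \deqn{W = 1 - |\Omega(\phi_i - \phi_j)| / \pi,}
#' where \eqn{\Omega} wraps into \eqn{(-\pi, \pi]}. Identical neighbouring
#' phases give weight 1; a wrapped difference of \eqn{\pi} gives 0.
#'
#' @param phase 3D array of wrapped phase in radians.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return array of edge weights in `[0, 1]` (shape reduced by one along
#'   `axis`).
#' @export
spatial_phase_coherence <- function(phase, axis) {
  ep <- edge_endpoints(phase, axis)
  1 - abs(wrap_to_pi(ep$i - ep$j)) / pi
}

#' Temporal phase coherence weight
#'
#' Compares the wrapped spatial phase difference at two echoes: with
#' linear-in-TE phase evolution the later echo's difference, scaled by the
#' echo-time ratio, predicts the earlier one, so
#' \deqn{W = \max\{0,\; 1 - |\Omega(\Delta\phi_{t-1}) -
#'   \Omega(\Delta\phi_t)\, TE_{t-1}/TE_t|\}.}
#' Deviations of one radian or more clamp to 0.
#'
#' @param phase_tm1,phase_t 3D wrapped phase at the earlier/later echo.
#' @param te_tm1,te_t echo times in ms, `0 < te_tm1 < te_t`.
#' @param axis 1, 2 or 3.
#' @return array of edge weights in `[0, 1]`.
#' @export
temporal_phase_coherence <- function(phase_tm1, phase_t, te_tm1, te_t, axis) {
  if (!(te_tm1 > 0 && te_t > te_tm1)) {
    stop("echo times must satisfy 0 < te_tm1 < te_t")
  }
  d1 <- edge_endpoints(phase_tm1, axis)
  d2 <- edge_endpoints(phase_t, axis)
  dev <- abs(wrap_to_pi(d1$i - d1$j) - wrap_to_pi(d2$i - d2$j) * te_tm1 / te_t)
  pmax(1 - dev, 0) # first argument keeps the array shape
}

#' Magnitude coherence weight
#'
#' \deqn{W = (\min(M_i, M_j) / \max(M_i, M_j))^2.}
#' Similar neighbouring magnitudes give weight near 1; an edge into a
#' much weaker voxel is down-weighted. A pair of exact zeros (0/0 in the
#' formula) is defined as 0: zero-signal voxels carry no phase
#' information.
#'
#' @param mag 3D array of magnitudes (>= 0).
#' @param axis 1, 2 or 3.
#' @return array of edge weights in `[0, 1]`.
#' @export
magnitude_coherence <- function(mag, axis) {
  if (any(mag[is.finite(mag)] < 0)) stop("magnitude must be non-negative")
  ep <- edge_endpoints(mag, axis)
  w <- (pmin(ep$i, ep$j) / pmax(ep$i, ep$j))^2
  w[ep$i == 0 & ep$j == 0] <- 0
  w
}

#' Combine weight components into a per-direction quality map
#'
#' The final quality of an edge is the product of the selected weights
#' (any nonempty subset of spatial, temporal and magnitude coherence).
#' Edges touching a masked-out voxel, or a voxel whose phase/magnitude is
#' not finite, are flagged as disconnected: they receive cost 0 under
#' [quantize_costs()], which stops the unwrapping path there (the same
#' semantics as the border of a mask).
#'
#' @param components list of one or more `edge_field` objects of kind
#'   `"quality"` on the same grid.
#' @param mask optional 3D logical array; `FALSE` voxels are excluded.
#' @return an `edge_field` of kind `"quality"` with attribute `blocked`
#'   (per-axis logical edge arrays).
#' @export
combine_quality <- function(components, mask = NULL) {
  if (length(components) == 0L) stop("at least one weight component required")
  g <- grid_dim(components[[1L]])
  prods <- list(x = NULL, y = NULL, z = NULL)
  for (comp in components) {
    if (!inherits(comp, "edge_field") || comp$kind != "quality") {
      stop("components must be quality edge_field objects")
    }
    if (!identical(grid_dim(comp), g)) stop("components differ in grid shape")
    for (ax in c("x", "y", "z")) {
      prods[[ax]] <- if (is.null(prods[[ax]])) comp[[ax]]
                     else prods[[ax]] * comp[[ax]]
    }
  }
  blocked <- lapply(prods, function(p) !is.finite(p))
  if (!is.null(mask)) {
    mb <- mask_blocked_edges(mask, g)
    blocked <- Map(`|`, blocked, mb)
  }
  for (ax in c("x", "y", "z")) prods[[ax]][blocked[[ax]]] <- 0
  out <- edge_field(prods$x, prods$y, prods$z, kind = "quality")
  attr(out, "blocked") <- blocked
  out
}

#' Quantize a quality map to integer edge costs
#'
#' Real-valued quality in `[0, 1]` is converted to 8-bit integer costs by
#' `cost = max(round(255 * (1 - quality)), 1)`: quality 1 maps to cost 1
#' (best connection), quality 0 to cost 255 (worst). Rounding is R's
#' round-half-to-even. Edges flagged as disconnected get the special cost
#' 0 and are never entered into the priority queue.
#'
#' @param quality an `edge_field` of kind `"quality"` (optionally carrying
#'   a `blocked` attribute from [combine_quality()]), or a bare numeric
#'   vector/array of quality values for scalar use.
#' @return an `edge_field` of kind `"cost"` (or an integer array for bare
#'   numeric input).
#' @export
quantize_costs <- function(quality) {
  q1 <- function(q, blocked = NULL) {
    bad <- is.finite(q) & (q < 0 | q > 1)
    if (any(bad)) stop("quality values must lie in [0, 1]")
    cost <- pmax(as.integer(round(255 * (1 - q))), 1L)
    cost[!is.finite(q)] <- 0L
    if (!is.null(blocked)) cost[blocked] <- 0L
    if (!is.null(dim(q))) dim(cost) <- dim(q)
    cost
  }
  if (!inherits(quality, "edge_field")) return(q1(quality))
  if (quality$kind != "quality") stop("expected a quality edge_field")
  blocked <- attr(quality, "blocked")
  edge_field(q1(quality$x, blocked$x),
             q1(quality$y, blocked$y),
             q1(quality$z, blocked$z), kind = "cost")
}

#' Compute the quality map for an echo series
#'
#' Builds the per-direction quality maps that guide unwrapping. Spatial
#' and magnitude coherence are computed on one chosen echo (by default the
#' template echo); temporal coherence compares two echoes (by default the
#' first and second) and requires a genuinely multi-echo series. Weights
#' that the data cannot support (temporal with one volume, magnitude
#' without magnitude data) are dropped from the product rather than being
#' replaced by constants.
#'
#' @param series an `echo_series`.
#' @param use character subset of `c("spatial", "temporal", "magnitude")`.
#' @param weight_echo echo index used for the spatial and magnitude
#'   weights (default: the template echo, i.e. 2 when available).
#' @param temporal_echoes integer pair of echo indices for the temporal
#'   weight (default `c(1, 2)`).
#' @param mask optional 3D logical inclusion mask.
#' @return an `edge_field` of kind `"quality"` (with `blocked` attribute).
#' @export
compute_weights <- function(series,
                            use = c("spatial", "temporal", "magnitude"),
                            weight_echo = NULL,
                            temporal_echoes = c(1L, 2L),
                            mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  use <- match.arg(use, several.ok = TRUE)
  nt <- length(series$echo_times)
  if (is.null(weight_echo)) weight_echo <- min(2L, nt)
  if (weight_echo < 1L || weight_echo > nt) stop("invalid weight_echo")
  te <- series$echo_times

  multi_echo <- nt >= 2L && te[temporal_echoes[2L]] > te[temporal_echoes[1L]]
  comps <- list()
  per_axis <- function(fun) {
    edge_field(fun(1L), fun(2L), fun(3L), kind = "quality")
  }
  if ("spatial" %in% use) {
    p <- vol_at(series$phase, weight_echo)
    comps <- c(comps, list(per_axis(function(ax)
      spatial_phase_coherence(p, ax))))
  }
  if ("temporal" %in% use && multi_echo) {
    p1 <- vol_at(series$phase, temporal_echoes[1L])
    p2 <- vol_at(series$phase, temporal_echoes[2L])
    comps <- c(comps, list(per_axis(function(ax)
      temporal_phase_coherence(p1, p2, te[temporal_echoes[1L]],
                               te[temporal_echoes[2L]], ax))))
  }
  if ("magnitude" %in% use && !is.null(series$magnitude)) {
    m <- vol_at(series$magnitude, weight_echo)
    comps <- c(comps, list(per_axis(function(ax)
      magnitude_coherence(m, ax))))
  }
  if (length(comps) == 0L) {
    stop("no usable weight component for this series (need at least one of: ",
         "spatial; temporal with >= 2 distinct echoes; magnitude with data)")
  }
  # phase non-finiteness must block edges even when only magnitude weights
  # are in use; fold it in through the mask pathway
  pfin <- is.finite(vol_at(series$phase, weight_echo))
  mask_eff <- if (is.null(mask)) pfin else (mask & pfin)
  combine_quality(comps, mask = mask_eff)
}
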