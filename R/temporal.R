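#' Unwrap one volume against an unwrapped template via TE scaling
#'
#' Under linear phase evolution in time, the template's unwrapped phase
#' scaled by the echo-time ratio predicts the target volume's phase; the
#' wrapped measurement is then snapped to the nearest congruent value:
#' \deqn{\theta = \phi - 2\pi\,\mathrm{round}\{(\phi -
#'   \theta_t\,TE/TE_t)/(2\pi)\}.}
#' For constant-TE time series the ratio is 1 and this reduces to
#' nearest-cycle matching against the template.
#'
#' @param theta_template 3D unwrapped template phase (radians).
#' @param phi_other 3D wrapped phase of the volume to unwrap.
#' @param te_template,te_other echo times in ms (both > 0).
#' @return 3D unwrapped phase, congruent to `phi_other` mod \eqn{2\pi}.
#' @export
template_propagate <- function(theta_template, phi_other,
                               te_template, te_other) {
  if (te_template <= 0 || te_other <= 0) stop("echo times must be positive")
  stopifnot_shape(theta_template, phi_other, "template and target")
  pred <- theta_template * (te_other / te_template)
  phi_other - (2 * pi) * round((phi_other - pred) / (2 * pi))
}

#' Unwrap a 4D multi-echo or time series
#'
#' In `"template"` mode (the default and the fast path) the quality map is
#' computed once, a single template volume (echo 2 by default; echo 1
#' tends to be more affected by flow and pre-steady-state signal) is
#' unwrapped spatially, and every other volume is unwrapped directly
#' against the template with [template_propagate()]. This couples all
#' volumes to one spatial solution, which both avoids introducing
#' whole-volume 2\eqn{\pi} jumps between echoes/time points and skips
#' recomputing weights per volume. `"individual"` mode instead computes
#' weights and runs the spatial unwrapper for every volume independently
#' (useful when phase evolution is not linear in time, e.g. large
#' inter-volume motion).
#'
#' @param series an `echo_series`.
#' @param costs optional precomputed `edge_field` of kind `"cost"`; when
#'   absent, [compute_weights()] + [quantize_costs()] are used with the
#'   given `use` set.
#' @param template_index 1-based index of the template volume; default
#'   `min(2, n_volumes)`.
#' @param mode `"template"` or `"individual"`.
#' @param use weight components, as in [compute_weights()].
#' @param mask optional 3D logical inclusion mask.
#' @param chain if `TRUE` (template mode), propagate volume-to-volume
#'   outward from the template instead of always from the template
#'   directly; can help long time series with slow drift.
#' @param anchor if `TRUE` (template mode), re-anchor the spatially
#'   unwrapped template before propagating. The spatial unwrapper fixes
#'   each component only up to a global number of cycles `K` (the seed
#'   keeps its wrapped value); scaling by a non-integer echo-time ratio
#'   turns a nonzero `K` into a fractional global offset at other echoes,
#'   which corrupts the cycle choice of [template_propagate()] volume-wide.
#'   The anchor step estimates `K` from the wrapped phase of the other
#'   volumes (linear-in-TE self-consistency) and removes it; `K` remains
#'   determined only up to offsets that scale to whole cycles at every
#'   echo, which are harmless. Skipped automatically for constant-TE
#'   series, where the ratio is 1.
#' @return a `series_unwrap_result`: list with `theta` (4D), `visited`,
#'   `template_index`, `mode`, `seed` and `components` (template mode).
#' @export
unwrap_series <- function(series, costs = NULL, template_index = NULL,
                          mode = c("template", "individual"),
                          use = c("spatial", "temporal", "magnitude"),
                          mask = NULL, chain = FALSE, anchor = TRUE) {
  stopifnot(inherits(series, "echo_series"))
  mode <- match.arg(mode)
  nt <- length(series$echo_times)
  if (is.null(template_index)) template_index <- min(2L, nt)
  if (template_index < 1L || template_index > nt) {
    stop(sprintf("template_index %d outside 1..%d", template_index, nt))
  }
  te <- series$echo_times
  theta <- series$phase

  if (mode == "template") {
    if (is.null(costs)) {
      costs <- quantize_costs(compute_weights(series, use = use,
                                              weight_echo = template_index,
                                              mask = mask))
    }
    tmpl <- unwrap_spatial(vol_at(series$phase, template_index), costs)
    theta_t <- tmpl$theta
    if (anchor) {
      k <- anchor_offset(theta_t, series, template_index, tmpl$visited)
      theta_t <- theta_t - 2 * pi * k
    }
    theta[, , , template_index] <- theta_t
    for (t in order(abs(seq_len(nt) - template_index))) {
      if (t == template_index) next
      src <- if (chain) t - sign(t - template_index) else template_index
      theta[, , , t] <- template_propagate(vol_at(theta, src),
                                           vol_at(series$phase, t),
                                           te[src], te[t])
    }
    structure(list(theta = theta, visited = tmpl$visited,
                   template_index = template_index, mode = mode,
                   seed = tmpl$seed, components = tmpl$components),
              class = "series_unwrap_result")
  } else {
    visited <- NULL
    comps <- vector("list", nt)
    seed <- NULL
    for (t in seq_len(nt)) {
      costs_t <- costs
      if (is.null(costs_t)) {
        costs_t <- quantize_costs(compute_weights(series, use = use,
                                                  weight_echo = t,
                                                  mask = mask))
      }
      r <- unwrap_spatial(vol_at(series$phase, t), costs_t)
      theta[, , , t] <- r$theta
      comps[[t]] <- r$components
      if (t == template_index) {
        visited <- r$visited
        seed <- r$seed
      }
    }
    structure(list(theta = theta, visited = visited,
                   template_index = template_index, mode = mode,
                   seed = seed, components = comps),
              class = "series_unwrap_result")
  }
}

# Estimate the template's global cycle offset K from the other volumes.
#
# If the unwrapped template is theta2 = theta_true + 2*pi*K and phase
# evolves linearly in TE, then for every other echo t with ratio
# r_t = TE_t / TE_template the wrapped measurement satisfies
#   phi_t - theta2 * r_t  ==  -2*pi*K*r_t   (mod 2*pi)
# volume-wide. The left side's circular mean over visited voxels gives a
# robust estimate of the right side for each echo; a search over integer
# K picks the value consistent with all echoes at once. K is only
# identifiable modulo offsets for which every K*r_t is an integer, but
# those scale to whole cycles per volume and leave field maps and error
# counts untouched; ties are broken towards the smallest |K|.
anchor_offset <- function(theta_template, series, template_index, visited) {
  te <- series$echo_times
  nt <- length(te)
  others <- setdiff(seq_len(nt), template_index)
  ratios <- te[others] / te[template_index]
  keep <- abs(ratios - round(ratios)) > 1e-9 # integer ratios carry no signal
  others <- others[keep]
  ratios <- ratios[keep]
  if (length(others) == 0L) return(0L)
  sel <- which(visited)
  if (length(sel) == 0L) return(0L)
  if (length(sel) > 200000L) { # strided subsample, deterministic
    sel <- sel[seq(1L, length(sel), length.out = 200000L)]
  }
  th <- theta_template[sel]
  rho <- vapply(seq_along(others), function(i) {
    d <- series$phase[, , , others[i]][sel] - th * ratios[i]
    Arg(sum(complex(argument = d)))
  }, 0)
  span <- range(theta_template[sel]) / (2 * pi)
  kcand <- seq(floor(span[1]) - 2L, ceiling(span[2]) + 2L)
  cost <- vapply(kcand, function(k) {
    sum(abs(wrap_to_pi(rho + 2 * pi * k * ratios)))
  }, 0)
  best <- cost <= min(cost) + 1e-9
  kbest <- kcand[best]
  kbest[order(abs(kbest), kbest)][1L]
}

#' @export
print.series_unwrap_result <- function(x, ...) {
  cat(sprintf("<series_unwrap_result: %s, %d volume(s), template %d, grid %s>\n",
              x$mode, dim(x$theta)[4], x$template_index,
              paste(dim(x$theta)[1:3], collapse = "x")))
  invisible(x)
}

#' Convert unwrapped phase to a B0 field map
#'
#' GRE phase grows approximately linearly with echo time,
#' \eqn{\theta \approx 2\pi\, TE\, \Delta B_0}, so each echo yields
#' \eqn{\Delta B_0 = \theta / (2\pi\, TE)} in Hz (`units = "hz"`, the
#' default). `units = "rad_s"` omits the \eqn{2\pi} factor and returns
#' \eqn{\theta / TE} in rad/s.
#'
#' @param theta 3D unwrapped phase (with scalar `echo_times`) or 4D
#'   (one echo time per volume), radians.
#' @param echo_times echo time(s) in ms.
#' @param units `"hz"` or `"rad_s"`.
#' @return field map with the same shape as `theta`.
#' @export
compute_fieldmap <- function(theta, echo_times, units = c("hz", "rad_s")) {
  units <- match.arg(units)
  if (any(echo_times <= 0)) stop("echo times must be positive")
  te_s <- echo_times / 1000
  denom <- if (units == "hz") 2 * pi * te_s else te_s
  d <- dim3(theta)
  if (length(d) == 3L) {
    if (length(te_s) != 1L) stop("3D theta needs a single echo time")
    theta / denom
  } else {
    if (length(te_s) != d[4]) stop("need one echo time per volume")
    out <- theta
    for (t in seq_len(d[4])) out[, , , t] <- out[, , , t] / denom[t]
    out
  }
}
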