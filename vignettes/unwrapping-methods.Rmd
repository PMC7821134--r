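---
title: "Quality-guided spanning-tree phase unwrapping: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-guided spanning-tree phase unwrapping: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MRI measures phase only modulo $2\pi$: the scanner reports
$\varphi = \Omega(\theta)$, where $\theta$ is the physical phase accrued by
spins and $\Omega$ wraps any angle into $(-\pi, \pi]$. For gradient-echo
acquisitions $\theta \approx 2\pi\,TE\,\Delta B_0$, so at high field, long
echo times or near strong susceptibility gradients the true phase spans
tens of cycles and the wrapped image is covered in fringe lines.
Downstream applications — B0 field mapping, quantitative susceptibility
mapping, phase-based distortion correction, flow and temperature mapping —
need the integer cycle count per voxel restored *exactly*: smoothing-based
(Laplacian) unwrapping is not sufficient for these uses because it changes
values by non-integer amounts.

phasetree implements an exact, path-following unwrapper. It restores, at
every voxel it can reach, a value congruent to the measurement modulo
$2\pi$, choosing the cycle count by walking a minimum spanning tree from
reliable to unreliable voxel connections.

## Edge weights and the quality map

The 3D volume is a 6-connected grid graph. Each edge $(i, j)$ receives up
to three reliability weights in $[0, 1]$:

* **Spatial phase coherence** $W^{\mathrm{Spat}}_{ij} = 1 -
  |\Omega(\varphi_i - \varphi_j)| / \pi$. Neighbouring voxels on a smooth
  field differ little in wrapped phase; a difference of $\pi$ (weight 0)
  is maximally ambiguous.
* **Temporal phase coherence** (multi-echo data)
  $W^{\mathrm{Temp}}_{ij} = \max\{0,\, 1 - |\Omega(\Delta\varphi_{t-1}) -
  \Omega(\Delta\varphi_{t})\,TE_{t-1}/TE_{t}|\}$, with echoes 1 and 2 by
  default. If phase truly evolves linearly with TE, the later echo's
  spatial difference predicts the earlier one; deviation of a radian or
  more clamps to 0.
* **Magnitude coherence**
  $W^{M}_{ij} = (\min(M_i, M_j)/\max(M_i, M_j))^2$. A connection into a
  much weaker voxel is unreliable. The $0/0$ case (two zero-signal
  voxels) is defined as 0, since such voxels carry no phase information.

The per-direction quality map is the product of the selected weights.
Components the data cannot support (temporal with a single volume,
magnitude without magnitude images) are dropped from the product, never
replaced by constants. Which echo feeds the spatial/magnitude weights is
selectable (`weight_echo`); the default is the template echo.

For speed and memory the quality $q$ is quantized to 8-bit integer costs,
$\mathrm{cost} = \max(\mathrm{round}(255\,(1-q)),\, 1)$: cost 1 is the
best possible connection, 255 the worst. Cost 0 is reserved as "no
connection": edges that touch a masked-out voxel or a non-finite
phase/magnitude value get cost 0 and are never entered in the queue, so
the unwrapping path simply stops there, exactly like at a mask border.

## Spanning-tree growth with a bucket queue

Unwrapping starts from a seed: the first endpoint of a minimum-cost edge
(ties broken by deterministic scan order). The seed keeps its measured
wrapped value. Edges leaving the visited region live in a bucket priority
queue — one FIFO list per integer cost 1..255 — so the cheapest frontier
edge pops in $O(1)$ amortized time and runtime scales linearly with the
number of edge insertions (Prim–Jarník). When an edge pops whose
endpoints are both already visited it is discarded (lazy deletion rather
than decrease-key). Otherwise the unvisited endpoint is unwrapped against
its visited neighbour,
$\theta_2 = \varphi_2 - 2\pi\,\mathrm{round}\{(\varphi_2 -
\theta_1)/(2\pi)\}$, marked visited, and its own positive-cost edges join
the queue. When the queue empties while cost-connected voxels remain
(regions separated by cost-0 edges), each remaining component is
re-seeded by the same seed rule restricted to it and unwrapped
independently; voxels with no positive-cost edge at all keep their
wrapped value and are flagged unvisited.

Determinism: FIFO buckets, the fixed seed rule, and one canonical
identifier per undirected edge (axis + lower-corner voxel) make repeated
runs bit-identical.

## 4D data: template unwrapping

For multi-echo or time-series data, weights are computed once, a single
*template* volume (echo 2 by default — the first echo is more affected by
flow and pre-steady-state signal) is unwrapped spatially, and every other
volume is obtained per voxel from
$\theta_{t} = \varphi_{t} - 2\pi\,\mathrm{round}\{(\varphi_{t} -
\hat\theta\,TE_{t}/TE_{\mathrm{tmpl}})/(2\pi)\}$. For constant-TE time
series the ratio is 1 and this becomes nearest-cycle matching against the
template, which by construction cannot introduce whole-volume cycle jumps
between time points. `mode = "individual"` falls back to per-volume
weights + spatial unwrapping for data violating the linear-evolution
assumption (e.g. large motion).

**Template anchoring.** A spatial unwrapper fixes each component only up
to a global cycle count $K$ (the seed keeps its wrapped value). That is
harmless within one volume, but the TE-scaling above multiplies
$2\pi K$ by a generally non-integer ratio: with $K \ne 0$ the prediction
for another echo is off by a *fractional* number of cycles volume-wide,
and the rounding step then splits the volume between two adjacent cycle
choices. `unwrap_series(anchor = TRUE)` therefore estimates $K$ before
propagating, using the data's own linearity: for each other echo,
$\Omega(\varphi_t - \hat\theta\,r_t)$ concentrates around
$\Omega(-2\pi K r_t)$, so circular means over visited voxels followed by
a small integer search recover $K$. $K$ remains identifiable only modulo
offsets for which every $K r_t$ is an integer; the residual ambiguity
shifts each volume by whole cycles in a TE-proportional way, which leaves
field maps (a constant offset) and per-volume error counts (a global
offset) untouched. Anchoring is skipped when all ratios are integers
(e.g. constant-TE series), where it is unnecessary.

## Field maps and evaluation metrics

* `compute_fieldmap`: $\Delta B_0 = \theta/(2\pi\,TE)$ in Hz by default;
  `units = "rad_s"` returns $\theta/TE$ without the $2\pi$. Both
  conventions circulate in the field-mapping literature, so the unit is
  explicit.
* `wrap_error_report`: because unwrapping preserves phase modulo $2\pi$,
  estimate minus congruent reference is an integer cycle count $n$ per
  voxel; voxels with $n \ne 0$ are erroneous. The modal $n$ (the
  arbitrary global anchor) is removed first by default and reported as
  `global_k`. Non-congruent inputs are binned to the nearest $n$, with a
  warning when more than 1% of voxels sit further than 0.5 rad from the
  lattice.
* `temporal_reference`: extends a trusted first-echo volume across
  echoes under linear evolution, the standard surrogate for ground truth
  in vivo.
* `fieldmap_sd`: per-voxel SD of the per-echo field maps; echo-dependent
  unwrapping mistakes light up as high-SD voxels.
* `count_global_jumps`: counts consecutive-volume pairs whose median
  phase difference rounds to a nonzero cycle count — the signature
  failure of volume-by-volume unwrapping of time series.

## The synthetic phantom

`make_topography` builds a smooth $\Delta B_0$ field: a mixture of broad
random 3D Gaussian sources (default 8, widths 0.28–0.45 of the grid in
normalized units) blended with a random linear gradient (fraction 0.4),
recentred and scaled so the peak deviation is `amplitude_hz` both ways.
The defaults — $128^3$ voxels, 1250 Hz, echoes 4/8/10 ms — give 25 full
cycles peak-to-peak at the last echo while keeping every 6-neighbour step
of the true phase below $\pi$ (about 2.7 rad at worst over probe seeds),
so exact recovery is well-posed: difficulty comes from wrap density and
noise, not from undersampling the field. The source widths were chosen
once, at design time, to guarantee that margin; narrower sources at the
same amplitude violate it.

`simulate_echoes` derives the exact per-echo truth
$\theta_t = 2\pi\,TE_t\,\Delta B_0$ and adds noise under one of two
models:

* `noise_model = "complex"` (default): independent Gaussian noise on the
  real and imaginary channels of $M e^{i\theta}$ with SD equal to
  `noise_fraction` times the peak magnitude — `0.10` means SNR 10 in
  full-signal voxels. Phase noise then grows where signal falls and is
  uniform where signal vanishes, as in a real acquisition; the reported
  magnitude is the noisy modulus. We default to this model because a
  phase-error rate in the per-mille range is only a meaningful target
  when noise is bounded in high-signal tissue; a noise SD proportional
  to the *unwrapped* phase itself (tens of radians at long TE) would by
  itself push most voxels more than $\pi$ from the truth, making every
  unwrapper fail by construction.
* `noise_model = "phase"`: additive Gaussian phase noise with per-voxel
  SD `noise_fraction * |theta_true|`, the literal "percentage of the
  phase" reading, kept for completeness behind the flag.

In both cases the phantom stores `theta_noisy`, the exact pre-wrap phase
(truth plus realized noise). That is the reference for error counting:
an unwrapper restores cycle counts but cannot remove noise, so
differences from `theta_noisy` are exact $2\pi$ multiples and "erroneous
voxel" is unambiguous.

The default magnitude object is smooth in $[0.3, 1]$ with two deep
low-SNR pockets and a thin zero-signal line segment ending inside the
object; under noise the segment produces an open-ended fringe line, the
classic failure locus of path-following unwrappers near ear canals and
sinuses. What the phantom does **not** emulate: anatomy-shaped air/tissue
interfaces, phase offsets at $TE = 0$ (coil phase), $T_2^*$ decay of the
magnitude over echoes, motion between volumes, EPI distortion, or
multi-channel coil combination. Passing the phantom suite therefore
demonstrates correct cycle restoration under dense wraps, varying SNR and
signal voids — not robustness to offset or motion artefacts.

## Numerical choices

* Rounding of cycle counts and of the cost quantization is
  round-half-to-even (R's `round`, `nearbyint` in the compiled core), so
  the exact half-cycle tie — measure zero in real data — is resolved
  deterministically and identically in both code paths.
* Phase storage is autodetected by `normalize_phase`: values within
  $\pi(1+10^{-3})$ pass through; integer-scaled exports are mapped onto
  one full cycle using `max - min + 1` levels for integer data (so
  0..4095 puts level 2048 exactly at 0). The wrap boundary uses the
  $(-\pi, \pi]$ convention everywhere; the $-\pi$ representative maps to
  $+\pi$.
* NaN phase or magnitude disconnects the voxel's edges (cost 0) rather
  than erroring: zero-filled corners and air behave like masked regions.
* Degenerate inputs: all-cost-0 volumes refuse to select a seed;
  constant out-of-range phase refuses to rescale; empty masks and empty
  evaluation regions are errors rather than silent no-ops.

## Problem sizes

The bundled tests run the full pipeline at $128^3$ (the default phantom,
noise-free and at 10% noise with three seeds) and exercise properties on
grids between $8^3$ and $48^3$; oracle-equivalence checks compare the
compiled path against a sequential 1D rewrap and an exhaustive-sort MST
on 110 random instances of up to 1000 voxels. The acceptance script
regenerates three $128^3$ noisy phantoms from scratch. These sizes are
the package's chosen benchmark conditions; a $256^3$ volume unwraps the
same way, linearly slower.

## Known limitations

* No phase-offset (coil) removal: template unwrapping assumes
  $\theta \approx 0$ at $TE = 0$. Data with large offsets need offset
  removal upstream or `mode = "individual"`.
* 6-connectivity only; no diagonal edges (by design, matching the
  per-direction quality maps).
* No reorientation or DICOM reading; NIfTI voxel order is used as-is.
* The anchor estimate assumes most visited voxels follow the linear
  evolution; a template dominated by non-linear phase (massive motion)
  should use `anchor = FALSE` with `mode = "individual"`.
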