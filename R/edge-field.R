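#' Per-direction edge fields
#'
#' An `edge_field` stores one value per 6-neighbour edge of a regular 3D
#' grid, split by axis: component `x` has shape `(nx-1, ny, nz)` and holds
#' the value of the edge between voxel `(i,j,k)` and `(i+1,j,k)`, and
#' analogously for `y` and `z`. Two kinds exist: `"quality"` (real values
#' in `[0, 1]`, larger = better connection) and `"cost"` (integers in
#' `{0} U [1, 255]`, where 1 is the best connection, 255 the worst and 0
#' means no connection at all).
#'
#' @param x,y,z per-axis arrays of edge values.
#' @param kind `"quality"` or `"cost"`.
#' @return an object of class `edge_field`: a list with elements `x`, `y`,
#'   `z`, `kind` and attribute `grid_dim`.
#' @export
edge_field <- function(x, y, z, kind = c("quality", "cost")) {
  kind <- match.arg(kind)
  dx <- dim3(x); dy <- dim3(y); dz <- dim3(z)
  grid <- c(dx[1] + 1L, dx[2], dx[3])
  if (!identical(dy, c(grid[1], grid[2] - 1L, grid[3])) ||
      !identical(dz, c(grid[1], grid[2], grid[3] - 1L))) {
    stop("edge arrays are not consistent with a single grid shape")
  }
  fin_ok <- function(a) {
    v <- a[is.finite(a)]
    if (kind == "quality") all(v >= 0 & v <= 1)
    else all(v == round(v) & v >= 0 & v <= 255)
  }
  if (!fin_ok(x) || !fin_ok(y) || !fin_ok(z)) {
    stop(sprintf("edge values out of range for kind '%s'", kind))
  }
  structure(list(x = x, y = y, z = z, kind = kind),
            grid_dim = as.integer(grid), class = "edge_field")
}

#' @export
print.edge_field <- function(x, ...) {
  g <- attr(x, "grid_dim")
  cat(sprintf("<edge_field: %s, grid %s, %d edges>\n", x$kind,
              paste(g, collapse = "x"),
              length(x$x) + length(x$y) + length(x$z)))
  invisible(x)
}

grid_dim <- function(ef) attr(ef, "grid_dim")

# slabs of the two endpoints of every edge along `axis` (1, 2 or 3);
# a singleton axis has no edges and yields empty slabs
edge_endpoints <- function(a, axis) {
  d <- dim3(a)
  n <- d[axis]
  idx_lo <- idx_hi <- rep(list(quote(expr = )), 3L)
  idx_lo[[axis]] <- seq_len(max(n - 1L, 0L))
  idx_hi[[axis]] <- seq_len(max(n - 1L, 0L)) + 1L
  list(i = do.call(`[`, c(list(a), idx_lo, list(drop = FALSE))),
       j = do.call(`[`, c(list(a), idx_hi, list(drop = FALSE))))
}

# logical per-axis edge arrays marking edges with at least one excluded
# endpoint (mask FALSE). `mask` is a 3D logical array.
mask_blocked_edges <- function(mask, grid) {
  if (!identical(dim3(mask), as.integer(grid))) {
    stop("mask shape does not match the grid")
  }
  blocked_axis <- function(axis) {
    ep <- edge_endpoints(mask, axis)
    !(ep$i & ep$j)
  }
  list(x = blocked_axis(1L), y = blocked_axis(2L), z = blocked_axis(3L))
}
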