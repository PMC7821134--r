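#' Rewrap a voxel's phase against an unwrapped reference
#'
#' The elementary unwrapping step: the integer number of cycles
#' `n = round((phi2 - theta1) / (2 pi))` is removed so that the result is
#' congruent to `phi2` modulo \eqn{2\pi} and within \eqn{\pi} of the
#' reference `theta1`. Rounding is half-to-even (R's `round`), so the
#' exact half-cycle tie is resolved deterministically.
#'
#' @param phi2 wrapped phase of the voxel being unwrapped (radians).
#' @param theta1 unwrapped phase of its already-visited neighbour.
#' @return unwrapped phase, vectorized over both arguments.
#' @export
rewrap_voxel <- function(phi2, theta1) {
  phi2 - (2 * pi) * round((phi2 - theta1) / (2 * pi))
}

#' Select the unwrapping seed voxel
#'
#' The seed is the first endpoint (lowest linear index) of a minimum-cost
#' edge, with ties broken by scan order (voxels in linear order; +x, +y,
#' +z edges per voxel). It is the voxel with the best available
#' connection, where unwrapping is most reliable.
#'
#' @param costs an `edge_field` of kind `"cost"`.
#' @return 1-based linear voxel index with attribute `coords` (the
#'   `(i, j, k)` triple).
#' @export
select_seed <- function(costs) {
  stopifnot(inherits(costs, "edge_field"), costs$kind == "cost")
  g <- grid_dim(costs)
  v0 <- .select_seed_cpp(g, as.integer(costs$x), as.integer(costs$y),
                         as.integer(costs$z))
  if (v0 < 0) stop("all edges have cost 0: no seed can be selected")
  linear_to_voxel(v0 + 1, g)
}

linear_to_voxel <- function(lin, grid) {
  lin <- as.integer(lin)
  i <- (lin - 1L) %% grid[1] + 1L
  j <- ((lin - 1L) %/% grid[1]) %% grid[2] + 1L
  k <- (lin - 1L) %/% (grid[1] * grid[2]) + 1L
  structure(lin, coords = c(i, j, k))
}

voxel_to_linear <- function(v, grid) {
  if (length(v) == 3L) {
    as.integer(v[1] + grid[1] * (v[2] - 1L) + grid[1] * grid[2] * (v[3] - 1L))
  } else {
    as.integer(v)
  }
}

#' Spatially unwrap a 3D phase volume along a minimum spanning tree
#'
#' Grows a minimum spanning tree over the cost field with the Prim–Jarník
#' algorithm on a bucket priority queue: starting from the seed (which
#' keeps its measured value), the lowest-cost edge leaving the visited
#' region is popped (FIFO within equal costs, lazy deletion of stale
#' edges) and its unvisited endpoint is unwrapped against the visited one
#' via [rewrap_voxel()]. Cost-0 edges are never crossed, so masked-out
#' borders stop the path. When the queue empties while cost-connected
#' voxels remain (several components separated by cost-0 edges), each
#' remaining component is re-seeded by the seed rule restricted to it.
#' Voxels with no positive-cost edge at all keep their wrapped value and
#' stay unvisited.
#'
#' @param phase 3D array of wrapped phase in radians.
#' @param costs matching `edge_field` of kind `"cost"`.
#' @param seed optional seed voxel (1-based linear index or `(i,j,k)`
#'   triple); default: automatic via [select_seed()].
#' @param track_order if `TRUE`, also return the visiting rank per voxel.
#' @return an `unwrap_result`: list with `theta` (unwrapped phase),
#'   `visited` (3D logical), `seed`, `components` (data.frame of each
#'   component's seed and voxel count) and optionally `order`.
#' @export
unwrap_spatial <- function(phase, costs, seed = NULL, track_order = FALSE) {
  stopifnot(inherits(costs, "edge_field"), costs$kind == "cost")
  g <- grid_dim(costs)
  if (!identical(as.integer(dim3(phase)), g)) {
    stop("phase shape does not match the cost field grid")
  }
  seed0 <- if (is.null(seed)) -1 else voxel_to_linear(seed, g) - 1
  res <- .unwrap_spatial_cpp(as.double(phase), g,
                             as.integer(costs$x), as.integer(costs$y),
                             as.integer(costs$z), seed0, track_order)
  theta <- res$theta; dim(theta) <- g
  visited <- res$visited; dim(visited) <- g
  out <- list(
    theta = theta,
    visited = visited,
    seed = linear_to_voxel(res$seed + 1, g),
    components = data.frame(
      seed = as.integer(res$component_seeds + 1),
      size = as.integer(res$component_sizes))
  )
  if (track_order) {
    ord <- res$order; dim(ord) <- g
    out$order <- ord
  }
  structure(out, class = "unwrap_result")
}

#' @export
print.unwrap_result <- function(x, ...) {
  cat(sprintf(
    "<unwrap_result: grid %s, seed (%s), %d component(s), %d/%d visited>\n",
    paste(dim(x$theta), collapse = "x"),
    paste(attr(x$seed, "coords"), collapse = ","),
    nrow(x$components), sum(x$visited), length(x$visited)))
  invisible(x)
}

# ---- bucket priority queue (reference implementation) ----------------------

#' Bucket priority queue over integer costs
#'
#' A queue with one FIFO bucket per integer cost 1..255. `queue_pop`
#' always returns an entry from the lowest non-empty bucket in O(1)
#' amortized time; entries of equal cost come out in insertion order.
#' Cost-0 entries (no connection) are rejected. This is the queue
#' discipline used by the compiled unwrapping core; the R-level object
#' exists for inspection and testing.
#'
#' @return an empty `bucket_queue` object.
#' @export
bucket_queue <- function() {
  structure(new.env(parent = emptyenv()), class = "bucket_queue") -> q
  q$buckets <- vector("list", 255L)
  q$heads <- rep(1L, 255L)
  q$n <- 0L
  q
}

#' @rdname bucket_queue
#' @param q a `bucket_queue`.
#' @param cost integer cost 1..255.
#' @param id entry identifier (any scalar).
#' @export
queue_push <- function(q, cost, id) {
  cost <- as.integer(cost)
  if (cost < 1L || cost > 255L) {
    stop("only costs 1..255 may be enqueued (cost 0 means no connection)")
  }
  q$buckets[[cost]] <- c(q$buckets[[cost]], list(id))
  q$n <- q$n + 1L
  invisible(q)
}

#' @rdname bucket_queue
#' @export
queue_pop <- function(q) {
  if (q$n == 0L) stop("queue is empty")
  for (cost in 1:255) {
    if (q$heads[cost] <= length(q$buckets[[cost]])) {
      id <- q$buckets[[cost]][[q$heads[cost]]]
      q$heads[cost] <- q$heads[cost] + 1L
      q$n <- q$n - 1L
      return(list(cost = cost, id = id))
    }
  }
}

#' @rdname bucket_queue
#' @export
queue_size <- function(q) q$n

#' Initial queue state around a seed voxel
#'
#' Builds the bucket queue as it stands when unwrapping starts: it holds
#' the cost values of the seed's incident edges in the six directions
#' (-x, +x, -y, +y, -z, +z), skipping cost-0 (disconnected) edges and
#' directions that leave the grid. An interior seed with all-positive
#' costs therefore yields exactly six entries.
#'
#' @param costs an `edge_field` of kind `"cost"`.
#' @param seed seed voxel (1-based linear index or `(i,j,k)` triple).
#' @return a `bucket_queue` whose entries are `list(axis, lower)` edge
#'   identifiers (axis in 1..3, lower = 1-based `(i,j,k)` of the edge's
#'   lower corner).
#' @export
queue_initial_state <- function(costs, seed) {
  stopifnot(inherits(costs, "edge_field"), costs$kind == "cost")
  g <- grid_dim(costs)
  v <- attr(linear_to_voxel(voxel_to_linear(seed, g), g), "coords")
  q <- bucket_queue()
  axes <- list(costs$x, costs$y, costs$z)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      lower <- v
      if (dir < 0L) lower[axis] <- lower[axis] - 1L
      if (lower[axis] < 1L || lower[axis] > g[axis] - 1L) next
      cost <- axes[[axis]][lower[1], lower[2], lower[3]]
      if (cost > 0L) queue_push(q, cost, list(axis = axis, lower = lower))
    }
  }
  q
}
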