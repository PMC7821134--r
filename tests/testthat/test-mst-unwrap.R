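test_that("rewrap_voxel removes whole cycles towards the reference", {
  expect_equal(rewrap_voxel(0.2, 0.2), 0.2)             # n = 0
  expect_equal(rewrap_voxel(-3.0, 3.0), -3.0 + 2 * pi)  # n = -1
  expect_equal(rewrap_voxel(0.1, 10 * pi), 0.1 + 10 * pi)
  phi <- runif(500, -pi, pi)
  th1 <- runif(500, -40, 40)
  th2 <- rewrap_voxel(phi, th1)
  expect_lt(max(abs(th2 - th1)), pi + 1e-12)            # lands within pi
  d <- (th2 - phi) / (2 * pi)
  expect_lt(max(abs(d - round(d))), 1e-12)              # congruent
})

test_that("seed selection picks the first endpoint of a minimum-cost edge", {
  costs <- uniform_costs(c(4, 4, 4), 200L)
  costs$y[2, 3, 4] <- 7L   # unique minimum: edge (2,3,4)-(2,4,4)
  s <- select_seed(costs)
  expect_equal(attr(s, "coords"), c(2L, 3L, 4L))
  # uniform costs: tie broken by scan order -> voxel (1,1,1)
  expect_equal(attr(select_seed(uniform_costs(c(3, 3, 3))), "coords"),
               c(1L, 1L, 1L))
  expect_error(select_seed(uniform_costs(c(3, 3, 3), 0L)), "cost 0")
})

test_that("the initial queue holds the seed's positive-cost edges", {
  costs <- uniform_costs(c(5, 5, 5), 10L)
  expect_equal(queue_size(queue_initial_state(costs, c(3, 3, 3))), 6L)
  expect_equal(queue_size(queue_initial_state(costs, c(1, 1, 1))), 3L)
  costs$x[2, 3, 3] <- 0L  # disconnect the -x edge of the interior seed
  expect_equal(queue_size(queue_initial_state(costs, c(3, 3, 3))), 5L)
})

test_that("the bucket queue pops minimum cost first, FIFO within a bucket", {
  q <- bucket_queue()
  queue_push(q, 17, "a"); queue_push(q, 3, "b")
  queue_push(q, 17, "c"); queue_push(q, 3, "d")
  queue_push(q, 255, "e")
  expect_error(queue_push(q, 0, "zero"), "cost 0")
  got <- replicate(5, queue_pop(q), simplify = FALSE)
  expect_equal(vapply(got, `[[`, 0, "cost"), c(3, 3, 17, 17, 255))
  expect_equal(vapply(got, `[[`, "", "id"), c("b", "d", "a", "c", "e"))
  # interleaved: a later push of lower cost is served before older higher
  queue_push(q, 9, "x"); queue_push(q, 2, "y")
  expect_equal(queue_pop(q)$id, "y")
})

test_that("unwrap_spatial recovers 1D ramps exactly (cumulative oracle)", {
  truth <- seq(0, 4 * pi, length.out = 9)
  phi <- array(wrap_to_pi(truth), dim = c(9, 1, 1))
  res <- unwrap_spatial(phi, uniform_costs(c(9, 1, 1)))
  expect_equal(as.vector(res$theta), truth)
  expect_equal(as.vector(res$theta), cumulative_unwrap_1d(as.vector(phi)))
  expect_true(all(res$visited))
  # trivially wrap-free input passes through
  phi2 <- array(c(0.1, 0.2), dim = c(2, 1, 1))
  expect_equal(as.vector(unwrap_spatial(phi2, uniform_costs(c(2, 1, 1)))$theta),
               c(0.1, 0.2))
})

test_that("random 1D/2D instances match the independent oracles", {
  set.seed(42)
  for (rep in 1:30) {
    if (rep %% 2 == 0) {
      n <- sample(8:40, 1)
      truth <- cumsum(runif(n, -2.5, 2.5))
      g <- c(n, 1L, 1L)
    } else {
      nx <- sample(5:14, 1); ny <- sample(5:14, 1)
      truth <- smooth_truth(c(nx, ny, 1), cycles = runif(1, 0.5, 3))
      g <- c(nx, ny, 1L)
    }
    phi <- array(wrap_to_pi(truth), dim = g)
    quality <- compute_weights(echo_series(array(phi, dim = c(g, 1L)),
                                           echo_times = 10))
    costs <- quantize_costs(quality)
    res <- unwrap_spatial(phi, costs)
    expect_equal_mod_2pi(res$theta, array(truth, dim = g))
    oracle <- exhaustive_mst_unwrap(phi, costs, seed = as.integer(res$seed))
    expect_equal(res$theta, oracle)
  }
})

test_that("cost-0 planes split the volume into separately anchored parts", {
  g <- c(6, 3, 3)
  # linear-index ramp; gentle enough that every grid neighbour step < pi
  truth <- array(seq(0, 2.5 * pi, length.out = prod(g)), dim = g)
  phi <- wrap_to_pi(truth)
  costs <- uniform_costs(g)
  costs$x[3, , ] <- 0L   # sever between x = 3 and x = 4
  res <- unwrap_spatial(phi, costs)
  expect_equal(nrow(res$components), 2L)
  expect_true(all(res$visited))
  # each block is internally correct up to its own global offset
  expect_equal_mod_2pi(res$theta[1:3, , ], truth[1:3, , ])
  expect_equal_mod_2pi(res$theta[4:6, , ], truth[4:6, , ])
  # fully isolated voxels keep their wrapped value, unvisited
  costs2 <- uniform_costs(g)
  costs2$x[c(1, 2), 1, 1] <- 0L
  costs2$y[1:2, 1, 1] <- 0L
  costs2$z[1:2, 1, 1] <- 0L
  res2 <- unwrap_spatial(phi, costs2)
  expect_false(res2$visited[2, 1, 1])
  expect_equal(res2$theta[2, 1, 1], phi[2, 1, 1])
})

test_that("unwrapping is congruent, deterministic and mask-stable", {
  ph <- tiny_phantom(c(12, 12, 12), amplitude_hz = 75)
  ser <- as_echo_series(ph)
  costs <- quantize_costs(compute_weights(ser))
  phi <- ph$phase_wrapped[, , , 2]
  r1 <- unwrap_spatial(phi, costs)
  expect_lt(congruence_residual(r1$theta, phi), 1e-9)
  r2 <- unwrap_spatial(phi, costs)
  expect_identical(r1$theta, r2$theta)    # bit-identical rerun

  # benign single-component phantom: exact up to one global offset
  expect_equal_mod_2pi(r1$theta, ph$theta_true[, , , 2])

  # connected mask: inside agreement up to a global offset
  mask <- array(FALSE, dim = dim(phi))
  mask[3:10, 3:10, 3:10] <- TRUE
  costs_m <- quantize_costs(compute_weights(ser, mask = mask))
  rm_ <- unwrap_spatial(phi, costs_m)
  expect_equal_mod_2pi(rm_$theta, r1$theta, mask = mask)
})

test_that("the visiting order is a valid growth sequence", {
  ph <- tiny_phantom(c(8, 8, 8))
  phi <- ph$phase_wrapped[, , , 2]
  costs <- quantize_costs(compute_weights(as_echo_series(ph)))
  res <- unwrap_spatial(phi, costs, track_order = TRUE)
  expect_equal(sort(as.vector(res$order[res$visited])), seq_len(sum(res$visited)))
  expect_equal(res$order[attr(res$seed, "coords")[1],
                         attr(res$seed, "coords")[2],
                         attr(res$seed, "coords")[3]], 1L)
})
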