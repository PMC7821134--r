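test_that("wrap_to_pi maps angles onto (-pi, pi] congruently", {
  expect_equal(wrap_to_pi(0), 0)
  expect_equal(wrap_to_pi(2 * pi), 0)
  expect_equal(wrap_to_pi(3.5 * pi), -0.5 * pi)   # 3.5*pi - 4*pi
  expect_equal(wrap_to_pi(pi), pi)
  expect_equal(wrap_to_pi(-pi), pi)               # boundary representative
  x <- runif(1000, -50, 50)
  w <- wrap_to_pi(x)
  expect_true(all(w > -pi & w <= pi))
  expect_lt(max(abs((x - w) / (2 * pi) - round((x - w) / (2 * pi)))), 1e-12)
  expect_true(is.na(wrap_to_pi(NaN)))
})

test_that("spatial phase coherence spans [0, 1] with the expected anchors", {
  ph <- array(0, dim = c(3, 1, 1))
  ph[2, 1, 1] <- pi / 2   # edge 1: diff pi/2 -> 0.5 ; edge 2: back to 0
  w <- spatial_phase_coherence(ph, 1)
  expect_equal(as.vector(w), c(0.5, 0.5))
  ph[2, 1, 1] <- 0
  expect_equal(as.vector(spatial_phase_coherence(ph, 1)), c(1, 1))
  ph[2, 1, 1] <- pi       # maximal wrapped difference
  expect_equal(spatial_phase_coherence(ph, 1)[1], 0)
  # symmetry under endpoint swap: reversing the volume reverses the edges
  p2 <- array(runif(60, -pi, pi), dim = c(5, 4, 3))
  w2 <- spatial_phase_coherence(p2, 1)
  w2r <- spatial_phase_coherence(p2[5:1, , ], 1)
  expect_equal(w2, w2r[4:1, , ])
  expect_true(all(w2 >= 0 & w2 <= 1))
})

test_that("temporal phase coherence rewards TE-linear evolution", {
  # any phase series exactly proportional to TE scores 1 everywhere
  base <- smooth_truth(c(6, 5, 4), cycles = 1) / 20  # sub-pi differences
                                                     # even at the later TE
  te <- c(5, 12.5)
  p1 <- wrap_to_pi(base * te[1])
  p2 <- wrap_to_pi(base * te[2])
  for (ax in 1:3) {
    expect_equal(temporal_phase_coherence(p1, p2, te[1], te[2], ax),
                 array(1, dim(temporal_phase_coherence(p1, p2, te[1], te[2], ax))),
                 tolerance = 1e-12)
  }
  # direct evaluation: diffs 0.6 and 0.4 rad, TE ratio 0.5 -> 1-|0.6-0.2|
  q1 <- array(c(0, 0.6), dim = c(2, 1, 1))
  q2 <- array(c(0, 0.4), dim = c(2, 1, 1))
  expect_equal(temporal_phase_coherence(q1, q2, 10, 20, 1)[1], 0.6)
  # deviations of >= 1 rad clamp to zero
  q3 <- array(c(0, 2.0), dim = c(2, 1, 1))
  q4 <- array(c(0, -2.0), dim = c(2, 1, 1))
  expect_equal(temporal_phase_coherence(q3, q4, 10, 20, 1)[1], 0)
  expect_error(temporal_phase_coherence(q1, q2, 20, 10, 1), "echo times")
})

test_that("magnitude coherence is a squared ratio, scale-free, 0 at zeros", {
  m <- array(c(1, 2, 2, 0, 0, 0, 3, 3), dim = c(8, 1, 1))
  w <- magnitude_coherence(m, 1)
  expect_equal(as.vector(w), c(0.25, 1, 0, 0, 0, 0, 1))
  # invariant to global rescaling
  expect_equal(magnitude_coherence(7.3 * m, 1), w)
  expect_error(magnitude_coherence(-m, 1), "non-negative")
})

test_that("quality maps multiply and absorb zeros; blocked edges flagged", {
  g <- c(4, 3, 3)
  ones <- function() array(1, dim = g)
  ef <- function(val) {
    edge_field(array(val, dim = c(g[1] - 1, g[2], g[3])),
               array(val, dim = c(g[1], g[2] - 1, g[3])),
               array(val, dim = c(g[1], g[2], g[3] - 1)), kind = "quality")
  }
  one <- ef(1); quarter <- ef(0.25); zero <- ef(0)
  expect_equal(combine_quality(list(quarter))$x, quarter$x)  # identity
  expect_equal(combine_quality(list(one, quarter))$y, quarter$y)
  expect_equal(max(combine_quality(list(quarter, zero))$z), 0) # absorbing
  expect_error(combine_quality(list()), "at least one")

  mask <- array(TRUE, dim = g); mask[1, , ] <- FALSE
  q <- combine_quality(list(one), mask = mask)
  blocked <- attr(q, "blocked")
  expect_true(all(blocked$x[1, , ]))     # edges leaving the masked slab
  expect_false(any(blocked$x[3, , ]))
  expect_true(all(blocked$y[1, , ]))     # in-slab edges blocked too
  costs <- quantize_costs(q)
  expect_true(all(costs$x[1, , ] == 0L)) # mask border -> no connection
  expect_true(all(costs$x[3, , ] == 1L))
})

test_that("cost quantization hits the documented endpoints exactly", {
  expect_identical(quantize_costs(1), 1L)     # best connection
  expect_identical(quantize_costs(0), 255L)   # worst connection
  expect_identical(quantize_costs(0.5), 128L) # round(127.5) half-to-even
  q <- seq(0, 1, length.out = 1001)
  cost <- quantize_costs(q)
  expect_true(all(cost %in% 1:255))
  expect_true(all(diff(cost) <= 0L))          # non-increasing in quality
  expect_error(quantize_costs(1.2), "\\[0, 1\\]")
  expect_identical(quantize_costs(NaN), 0L)   # non-finite -> disconnected
})

test_that("compute_weights drops unavailable components, never fakes them", {
  ph <- tiny_phantom(c(10, 9, 8))
  ser <- as_echo_series(ph)
  q_all <- compute_weights(ser)
  expect_s3_class(q_all, "edge_field")
  expect_true(all(q_all$x >= 0 & q_all$x <= 1))

  # single-echo, no magnitude: spatial only; identical to the explicit call
  one <- echo_series(ph$phase_wrapped[, , , 2, drop = FALSE], echo_times = 8)
  q_sp <- compute_weights(one)
  expect_equal(q_sp$x,
               spatial_phase_coherence(ph$phase_wrapped[, , , 2], 1))
  # asking only for what the data cannot support errors out
  expect_error(compute_weights(one, use = "magnitude"), "no usable")
})

test_that("non-finite phase voxels disconnect their edges", {
  ph <- tiny_phantom(c(8, 8, 8))
  pw <- ph$phase_wrapped
  pw[4, 4, 4, 2] <- NaN
  ser <- echo_series(pw, magnitude = ph$magnitude,
                     echo_times = ph$echo_times)
  costs <- quantize_costs(compute_weights(ser))
  expect_identical(costs$x[3, 4, 4], 0L)
  expect_identical(costs$x[4, 4, 4], 0L)
  expect_identical(costs$y[4, 3, 4], 0L)
  expect_identical(costs$z[4, 4, 4], 0L)
})
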