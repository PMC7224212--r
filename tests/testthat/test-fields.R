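test_that("phase decoding follows the encoding arithmetic", {
  enc <- phase_encoding_spec(gyromagnetic_ratio = 2.675e8,
                             encoding_duration = 1e-3,
                             encoding_gradient = 0.01)
  ph0 <- phase_field(matrix(0, 5, 4), spacing = 0.1)
  expect_equal(unname(decode_displacement(ph0, enc, 1L)), matrix(0, 5, 4))

  # gamma * t_enc * dG = 2.675e8 * 1e-3 * 0.01 = 2.675e3 rad/m,
  # so 2.675 rad corresponds to exactly 1 mm
  ph1 <- phase_field(matrix(2.675, 3, 3), spacing = 0.1)
  expect_equal(unname(decode_displacement(ph1, enc, 1L)),
               matrix(1, 3, 3), tolerance = 1e-12)

  # linearity: doubling the phase doubles the displacement
  ph2 <- phase_field(matrix(2 * 2.675, 3, 3), spacing = 0.1)
  expect_equal(decode_displacement(ph2, enc, 1L),
               2 * decode_displacement(ph1, enc, 1L))

  # zero gradient difference is an invalid encoding
  enc0 <- phase_encoding_spec(encoding_duration = 1e-3,
                              encoding_gradient = 0.01,
                              reference_gradient = 0.01)
  expect_error(decode_displacement(ph1, enc0, 1L), "invalid encoding")
})

test_that("encode/decode round-trips displacements to 1e-12 relative", {
  set.seed(11)
  enc <- phase_encoding_spec(encoding_duration = 2e-3,
                             encoding_gradient = c(0.02, 0.015))
  dx <- matrix(rnorm(30, sd = 0.3), 6, 5)
  for (axis in 1:2) {
    ph <- phase_field(encode_phase(dx, enc, axis), spacing = 0.2)
    back <- decode_displacement(ph, enc, axis)
    expect_equal(unname(back), unname(dx), tolerance = 1e-12)
  }
})

test_that("phase unwrapping recovers wrapped ramps up to a 2*pi multiple", {
  # no wraps present: returned unchanged
  ramp <- outer(seq(0, 0.9, length.out = 10), rep(1, 8))
  ph <- phase_field(ramp, spacing = 1)
  expect_equal(unwrap_phase(ph)$phase, ramp, tolerance = 1e-12)

  # constant field stays constant
  cst <- phase_field(matrix(1.2, 6, 6), spacing = 1)
  expect_equal(unwrap_phase(cst)$phase, matrix(1.2, 6, 6))

  # a 4*pi ramp wrapped into (-pi, pi]: smooth ramp recovered up to 2*pi*k,
  # and output - input is everywhere an integer multiple of 2*pi
  true <- outer(seq(0, 4 * pi, length.out = 24), rep(1, 10))
  wrapped <- true - 2 * pi * round(true / (2 * pi))
  ph <- phase_field(wrapped, spacing = 1)
  un <- unwrap_phase(ph)$phase
  offset <- (un - true) / (2 * pi)
  expect_equal(max(offset) - min(offset), 0, tolerance = 1e-9)
  expect_equal(offset[1, 1], round(offset[1, 1]), tolerance = 1e-9)
  k <- (un - wrapped) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("disconnected masks are unwrapped per component with a warning", {
  mask <- matrix(TRUE, 9, 4)
  mask[5, ] <- FALSE
  ph <- phase_field(matrix(0.3, 9, 4), spacing = 1, mask = mask)
  expect_warning(unwrap_phase(ph), "disconnected")
})

test_that("robust LOWESS reproduces linear fields and rejects spikes", {
  fld <- affine_field()
  sm <- smooth_lowess(fld, window_pixels = 30)
  for (a in 1:2)
    expect_equal(sm$components[[a]], fld$components[[a]], tolerance = 1e-8)

  # constant field with one +1 mm spike: robust fit stays near the constant
  comp <- matrix(0.2, 15, 15)
  comp[8, 8] <- comp[8, 8] + 1
  spiky <- displacement_field(list(comp, comp), spacing = 0.2)
  sm <- smooth_lowess(spiky, window_pixels = 40, robust = TRUE)
  expect_lt(abs(sm$components[[1]][8, 8] - 0.2), 0.05)

  # oversized window shrinks with a warning
  small <- displacement_field(list(matrix(0.1, 4, 4), matrix(0, 4, 4)),
                              spacing = 1)
  expect_warning(smooth_lowess(small, window_pixels = 150), "shrinking")
})

test_that("both smoothers are mask-local", {
  set.seed(7)
  mask <- matrix(TRUE, 12, 12)
  mask[, 7:12] <- FALSE
  mk <- function(outside) {
    inside <- matrix(rnorm(144), 12, 12)
    inside[!mask] <- outside
    displacement_field(list(inside, inside * 0.5), spacing = 1, mask = mask)
  }
  set.seed(8); f1 <- mk(0)
  set.seed(8); f2 <- mk(99)
  l1 <- smooth_lowess(f1, 20); l2 <- smooth_lowess(f2, 20)
  expect_equal(l1$components[[1]][mask], l2$components[[1]][mask])
  g1 <- smooth_gaussian(f1, 1.5); g2 <- smooth_gaussian(f2, 1.5)
  expect_equal(g1$components[[1]][mask], g2$components[[1]][mask])
})

test_that("mask-normalized Gaussian smoothing preserves constants but biases edges", {
  cst <- displacement_field(list(matrix(0.7, 10, 10), matrix(-0.1, 10, 10)),
                            spacing = 1)
  sm <- smooth_gaussian(cst, 2)
  expect_equal(sm$components[[1]], matrix(0.7, 10, 10), tolerance = 1e-12)

  # a linear ramp far from any edge is preserved (kernel symmetry) ...
  fld <- affine_field(nx = 21, ny = 21, a = c(0.05, 0), b = c(0, 0),
                      c0 = c(0, 0))
  sm <- smooth_gaussian(fld, 1.5)
  interior <- sm$components[[1]][9:13, 9:13]
  expect_equal(interior, fld$components[[1]][9:13, 9:13], tolerance = 1e-6)

  # ... but the gradient at a mask edge is flattened (one-sided average),
  # which robust LOWESS avoids: compare edge-column gradients
  edge_grad <- function(f) f$components[[1]][2, 11] - f$components[[1]][1, 11]
  g0 <- edge_grad(fld)
  expect_lt(edge_grad(smooth_gaussian(fld, 1.5)) / g0, 0.9)
  expect_gt(edge_grad(smooth_lowess(fld, 30)) / g0, 0.99)
})

test_that("noise injection matches its spec and is bit-reproducible", {
  fld <- affine_field(nx = 100, ny = 100)
  expect_identical(add_noise(fld, noise_spec(sigma = 0)), fld)

  ns <- noise_spec(sigma = 0.1, seed = 42L)
  noisy <- add_noise(fld, ns)
  d <- noisy$components[[1]] - fld$components[[1]]
  # chi-square bounds on the sample SD at n = 1e4, alpha ~ 1e-3
  expect_gt(sd(d), 0.097)
  expect_lt(sd(d), 0.103)
  expect_identical(noisy, add_noise(fld, ns))

  # boundary exclusion leaves the mask rim untouched
  ns2 <- noise_spec(sigma = 0.1, seed = 1L, apply_to_boundary = FALSE)
  quiet <- add_noise(fld, ns2)
  expect_equal(quiet$components[[1]][1, ], fld$components[[1]][1, ])
  expect_false(isTRUE(all.equal(quiet$components[[1]][50, 50],
                                fld$components[[1]][50, 50])))
})

test_that("outlier down-weighting flags only the corrupted pixels", {
  fld <- affine_field(nx = 15, ny = 15)
  comp <- fld$components
  comp[[1]][4, 9] <- comp[[1]][4, 9] + 2
  bad <- displacement_field(comp, spacing = fld$spacing)
  w <- weight_outliers(bad, smoothed = fld)$weights
  expect_equal(w[4, 9], 0.5)
  expect_equal(sum(w == 0.5), 1L)
})
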