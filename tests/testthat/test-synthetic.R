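test_that("Kelvin-Voigt response matches closed forms", {
  times <- seq(0, 0.02, by = 1e-5)
  step <- function(t) ifelse(t >= 0, 100, 0)
  eps <- kelvin_voigt_response(step, E = 1000, eta = 1, times) # tau = 1 ms
  expect_equal(eps[1], 0)                                      # causal start
  expect_equal(eps[length(eps)], 0.1, tolerance = 1e-6)        # sigma / E
  at_tau <- eps[which.min(abs(times - 1e-3))]
  expect_equal(at_tau, 0.1 * (1 - exp(-1)), tolerance = 1e-6)
  # exact at every sample, not just asymptotically
  expect_equal(eps, 0.1 * (1 - exp(-times / 1e-3)), tolerance = 1e-9)
})

test_that("Kelvin-Voigt response is linear in the stress", {
  times <- seq(0, 0.01, by = 2e-5)
  s1 <- function(t) ifelse(t >= 0, 50, 0)
  s2 <- function(t) 30 * exp(-((t - 0.004) / 0.001)^2)
  both <- function(t) s1(t) + s2(t)
  e1 <- kelvin_voigt_response(s1, 800, 2, times)
  e2 <- kelvin_voigt_response(s2, 800, 2, times)
  e12 <- kelvin_voigt_response(both, 800, 2, times)
  expect_equal(e12, e1 + e2, tolerance = 1e-10)
})

test_that("parameter validation rejects non-physical inputs", {
  expect_error(kelvin_voigt_response(function(t) 1, E = 0, eta = 1, 0:1),
               "positive")
  expect_error(kelvin_voigt_response(function(t) 1, E = 1, eta = -1, 0:1),
               "positive")
  expect_error(synthetic_cell_spec(E_true = -5))
  expect_error(synthetic_cell_spec(noise_sd = -1))
})

test_that("make_contour synthesizes shapes that re-analyse to their input", {
  # only a0: circle of radius a0/2
  circ <- make_contour(c(20), n_points = 360)
  pc <- polar_transform(circ)
  expect_equal(pc$r, rep(10, pc$n_points), tolerance = 1e-9)

  # a0 + a2: fore-aft symmetric; odd coefficients of the re-analysis vanish
  sp <- contour_spectrum(make_contour(c(20, 0, 1)), k_interp = 0)
  expect_equal(unname(sp$a["a2"]), 1, tolerance = 1e-3)
  expect_lt(max(abs(sp$a[c("a1", "a3", "a5", "a7", "a9")])), 1e-6 * 20)

  # a0 + a1: bullet-like asymmetry; odd deformation strictly positive
  spb <- contour_spectrum(make_contour(c(20, 1)), k_interp = 0)
  expect_gt(reconstruct_contour(spb, "odd")$d, 0)

  # radius must stay positive
  expect_error(make_contour(c(2, 1.5)), "invalid shape")
})

test_that("simulated traces are reproducible and carry valid ground truth", {
  spec <- synthetic_cell_spec(noise_sd = 0.18, seed = 11L)
  gt1 <- simulate_trace(spec)
  gt2 <- simulate_trace(spec)
  expect_identical(gt1$contours, gt2$contours)
  gt3 <- simulate_trace(synthetic_cell_spec(noise_sd = 0.18, seed = 12L))
  expect_false(identical(gt1$contours, gt3$contours))

  expect_gte(length(gt1$times), 14)           # at least 14 points per trace
  expect_false(is.unsorted(gt1$times, strictly = TRUE))
  expect_equal(gt1$tau_true, spec$eta_true / spec$E_true)
  expect_true(all(gt1$d_odd_true >= 0))
  expect_true(all(diff(gt1$d_odd_true) >= -1e-12)) # monotone creep
  expect_true(all(gt1$d_even_true >= 0))
  # even response peaks at the inlet (z = 0)
  expect_lt(abs(gt1$z_um[which.max(gt1$d_even_true)]), 10)
})

test_that("noiseless contour pipeline recovers tau within 1%", {
  gt <- simulate_trace(synthetic_cell_spec())
  dtr <- decompose_trace(list(contours = gt$contours, z_um = gt$z_um,
                              t_s = gt$times, cell_id = 1L))
  inch <- dtr$z_um >= 0 & dtr$z_um <= 300
  fit <- fit_exponential(dtr$t_s[inch], dtr$d_odd[inch], "channel")
  expect_true(fit$accepted)
  expect_lt(abs(fit$tau - gt$tau_true) / gt$tau_true, 0.01)
})

test_that("rendering rasterizes areas correctly and is deterministic", {
  circ <- circle_contour(R = 10, n = 720, center = c(30, 13.6))
  fs <- render_frames(list(circ, circ), pixel_size_um = 0.34,
                      frame_shape = c(80, 1280), fps = 2000)
  expect_identical(fs$frames[[1]], fs$frames[[2]])
  area_px <- sum(fs$frames[[1]])
  expect_lt(abs(area_px - pi * (10 / 0.34)^2) / (pi * (10 / 0.34)^2), 0.02)

  # empty contour list: empty stack with valid metadata
  fs0 <- render_frames(list(), pixel_size_um = 0.34, fps = 2000)
  expect_s3_class(fs0, "frame_stream")
  expect_length(fs0$frames, 0)
  expect_equal(fs0$pixel_size_um, 0.34)

  # contour outside the frame is a render error
  off <- circle_contour(R = 10, n = 90, center = c(-5, 13.6))
  expect_error(render_frames(list(off), 0.34), "exceeds frame bounds")
})
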