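test_that("interpolation inserts k points per edge and preserves geometry", {
  sq <- contour_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
  dense <- interpolate_contour(sq, k_interp = 49)
  expect_equal(length(dense$x), 4 * 50)
  expect_identical(interpolate_contour(sq, 0), sq)
  # original vertices preserved, perimeter unchanged (collinear insertions)
  expect_true(all(sq$x %in% dense$x))
  expect_equal(measure_geometry(dense)$P, 4)
  expect_equal(measure_geometry(dense)$A, 1)
})

test_that("polar transform yields correct radii and angular weights", {
  pc <- polar_transform(circle_contour(R = 7, n = 500, center = c(3, -2)))
  expect_equal(pc$r, rep(7, pc$n_points), tolerance = 1e-6)
  expect_equal(sum(pc$dphi), 2 * pi, tolerance = 1e-9)
  expect_false(is.unsorted(pc$phi, strictly = TRUE))

  # unit square with edge midpoints: corners at sqrt(2)/2, midpoints at 1/2
  sq8 <- interpolate_contour(contour_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  pc <- polar_transform(sq8)
  expect_equal(sort(unique(round(pc$r, 10))), c(0.5, sqrt(2) / 2))
  expect_equal(sum(pc$dphi), 2 * pi, tolerance = 1e-9)
})

test_that("non-star-shaped input is rejected", {
  # C-shaped polygon (annulus segment): the angular sweep about the centroid
  # folds back along the inner arc
  th <- seq(-2.4, 2.4, length.out = 60)
  bad <- structure(list(x = c(10 * cos(th), 6 * cos(rev(th))),
                        y = c(10 * sin(th), 6 * sin(rev(th))),
                        frame_index = NA, timestamp = NA),
                   class = "contour_polygon")
  expect_error(polar_transform(bad), "star-shaped")
})

test_that("Fourier coefficients match analytic integrals", {
  # constant radius: a0 = 2R, everything else at numerical zero
  sp <- fourier_coefficients(polar_transform(circle_contour(R = 5, n = 1200)))
  expect_equal(unname(sp$a["a0"]), 10, tolerance = 1e-6)
  expect_lt(max(abs(c(sp$a[-1], sp$b))), 1e-6 * 5)

  # r(phi) = 1 + 0.1 cos(2 phi): a2 = 0.1, a0 = 2 (quadrature oracle)
  cp <- make_contour(c(2, 0, 0.1), n_points = 3000)
  sp <- contour_spectrum(cp, k_interp = 0)
  expect_equal(unname(sp$a["a0"]), 2, tolerance = 1e-4)
  expect_equal(unname(sp$a["a2"]), 0.1, tolerance = 1e-4)
  others <- c(sp$a[c("a1", "a3", "a4", "a5")], sp$b)
  expect_lt(max(abs(others)), 1e-4)

  # normalization divides by a0
  spn <- contour_spectrum(cp, k_interp = 0, normalize = TRUE)
  expect_equal(unname(spn$a["a0"]), 1)
  expect_equal(unname(spn$a["a2"]), unname(sp$a["a2"] / sp$a["a0"]))
})

test_that("implementation agrees with the naive-loop oracle to 1e-9", {
  set.seed(42)
  for (i in 1:20) { # full 100-contour sweep lives in the acceptance suite
    pc <- polar_transform(random_star_contour())
    sp <- fourier_coefficients(pc)
    or <- naive_fourier_oracle(pc)
    expect_lt(max(abs(unname(sp$a) - or$a)) / max(abs(or$a)), 1e-9)
    expect_lt(max(abs(unname(sp$b) - or$b)) / max(abs(or$a)), 1e-9)
  }
})

test_that("coefficients converge to analytic values as sampling is refined", {
  # coarse polygons on an analytic curve, densified by the interpolation
  # step: the chord discretization error must at least halve when the
  # vertex count doubles
  a2_true <- 0.4
  err <- sapply(c(24, 48, 96), function(n) {
    sp <- contour_spectrum(make_contour(c(8, 0, a2_true), n_points = n),
                           k_interp = 49)
    abs(unname(sp$a["a2"]) - a2_true)
  })
  expect_lt(err[2] / err[1], 0.6)
  expect_lt(err[3] / err[2], 0.6)
})

test_that("parity identities hold", {
  # fore-aft symmetric contour: odd a_k vanish
  sp <- contour_spectrum(ellipse_contour(a = 12, b = 9))
  expect_lt(max(abs(sp$a[c("a1", "a3", "a5", "a7", "a9")])), 1e-6 * sp$a["a0"])
  # axis-symmetric (mirror in y): b_k vanish
  expect_lt(max(abs(sp$b)), 1e-6 * sp$a["a0"])
  # bullet-like asymmetry puts power into the odd reconstruction
  spb <- contour_spectrum(egg_contour(R = 10, alpha = 0.4))
  expect_gt(reconstruct_contour(spb, "odd")$d, 0.005)
  # a resting (symmetric) ellipse has no odd deformation
  expect_lt(reconstruct_contour(sp, "odd")$d, 0.01)
})

test_that("reconstruction returns the original circle and full shapes", {
  sp <- contour_spectrum(circle_contour(R = 10, n = 720))
  for (p in c("even", "odd", "full")) {
    rc <- reconstruct_contour(sp, p)
    expect_lt(rc$d, 1e-4)
    expect_equal(mean(rc$r_rec), 10, tolerance = 1e-3)
  }
  # full reconstruction tracks the raw deformation of a bullet shape
  cp <- egg_contour(R = 10, alpha = 0.5)
  rc <- reconstruct_contour(contour_spectrum(cp), "full")
  expect_lt(abs(rc$d - deformation(cp)) / deformation(cp), 0.01)
})

test_that("reconstruction errors on non-positive radius", {
  sp <- structure(list(a = c(a0 = 2, a1 = 0, a2 = 1.5, a3 = 0, a4 = 0,
                             a5 = 0, a6 = 0, a7 = 0, a8 = 0, a9 = 0),
                       b = c(b1 = 0, b2 = 0, b3 = 0, b4 = 0, b5 = 0, b6 = 0,
                             b7 = 0, b8 = 0, b9 = 0), normalized = FALSE),
                  class = "shape_spectrum")
  expect_error(reconstruct_contour(sp, "even"), "non-positive radius")
})

test_that("decompose_trace assembles parity traces with expected structure", {
  spec <- synthetic_cell_spec(fps = 2000)
  gt <- simulate_trace(spec)
  dtr <- decompose_trace(list(contours = gt$contours, z_um = gt$z_um,
                              t_s = gt$times, cell_id = 7L))
  expect_s3_class(dtr, "deformation_trace")
  expect_true(all(c("d_raw", "d_even", "d_odd", "a0_um", "a5", "b9")
                  %in% names(dtr)))
  expect_true(all(dtr$d_odd >= 0))
  # odd deformation starts at ~zero and is maximal at the outlet
  expect_lt(dtr$d_odd[1], 1e-3)
  expect_gt(which.max(dtr$d_odd), 0.8 * nrow(dtr))
  # even deformation peaks near the inlet (z = 0) then relaxes
  zpk <- dtr$z_um[which.max(dtr$d_even)]
  expect_lt(abs(zpk), 30)
  expect_lt(dtr$d_even[nrow(dtr)], 0.3 * max(dtr$d_even))

  # a static circle decomposes to zero deformation everywhere
  still <- decompose_trace(static_track(circle_contour(R = 9, n = 240)))
  expect_lt(max(still$d_raw, still$d_even, still$d_odd), 2e-4)
})

test_that("short or broken tracks are rejected with informative errors", {
  tr <- static_track(circle_contour(R = 9), n_frames = 10)
  expect_error(decompose_trace(tr), "at least 14")
})
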