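test_that("shoelace geometry reproduces closed forms", {
  sq <- contour_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
  g <- measure_geometry(sq, pixel_size_um = 1)
  expect_equal(g$A, 1)
  expect_equal(g$P, 4)
  expect_equal(g$com, c(0.5, 0.5))

  tri <- contour_polygon(c(0, 2, 0), c(0, 0, 2))
  g <- measure_geometry(tri)
  expect_equal(g$A, 2)
  expect_equal(g$com, c(2 / 3, 2 / 3))

  # pixel scaling is quadratic in area, linear in perimeter
  g2 <- measure_geometry(sq, pixel_size_um = 0.34)
  expect_equal(g2$A, 0.34^2)
  expect_equal(g2$P, 4 * 0.34)

  # regular 360-gon approaches the disk
  g <- measure_geometry(circle_contour(R = 10, n = 360))
  expect_lt(abs(g$A - pi * 100) / (pi * 100), 0.001)
})

test_that("deformation follows 1 - 2*sqrt(pi*A)/P with closed-form cases", {
  expect_lt(deformation(circle_contour(R = 10, n = 360)), 1e-3)
  sq <- contour_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(deformation(sq), 1 - sqrt(pi) / 2)
  # 2:1 ellipse: perimeter from a fine polygonal approximation
  ell <- ellipse_contour(a = 2, b = 1, n = 20000)
  g <- measure_geometry(ell)
  d_expected <- 1 - 2 * sqrt(pi * g$A) / g$P
  expect_equal(deformation(ell), d_expected)
  expect_lt(abs(deformation(ell) - 0.083), 1e-3)
})

test_that("degenerate polygons raise geometry errors", {
  expect_error(contour_polygon(c(0, 1), c(0, 0)), "at least 3")
  line <- structure(list(x = c(0, 1, 2), y = c(0, 0, 0)),
                    class = "contour_polygon")
  expect_error(measure_geometry(line), "degenerate")
})

test_that("contours are stored counterclockwise and hulled correctly", {
  cw <- contour_polygon(c(0, 0, 1, 1), c(0, 1, 1, 0)) # given clockwise
  expect_gt(dcrheo:::.signed_area(cw$x, cw$y), 0)
  # hull removes a concave dent without changing the hull vertices
  dent <- contour_polygon(c(0, 2, 2, 1, 0), c(0, 0, 2, 0.5, 2))
  h <- convex_hull(dent)
  expect_equal(length(h$x), 4)
  expect_equal(measure_geometry(h)$A, 4)
})
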