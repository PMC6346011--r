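## Radial Fourier shape-mode analysis.
##
## A convex cell contour is interpreted as an angle-dependent radius function
## r(phi) about its center-of-mass and decomposed by a discrete Fourier
## transform with trapezoid-type angular weights. Even cosine modes (a2, a4,
## ...) capture fore-aft symmetric elongation, odd modes (a1, a3, ...) the
## bullet-like asymmetry; a0 is twice the mean radius. Reconstructing the
## two parity subsets separately (each with a0) disentangles the cell's
## response to the inlet stress peak from its response to the constant
## channel stress.

#' Densify a contour by piecewise linear interpolation
#'
#' Inserts `k_interp` equidistant points between each pair of neighbouring
#' vertices (including the closing edge), so an N-vertex polygon becomes an
#' `N * (k_interp + 1)`-vertex polygon. Original vertices are preserved and
#' the perimeter is unchanged.
#'
#' @param contour A [contour_polygon].
#' @param k_interp Number of interpolated points per edge (default 49).
#' @return A denser [contour_polygon].
#' @export
interpolate_contour <- function(contour, k_interp = 49) {
  stopifnot(k_interp >= 0, k_interp == round(k_interp))
  if (k_interp == 0) return(contour)
  x <- contour$x; y <- contour$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  frac <- seq(0, k_interp) / (k_interp + 1)          # 0 keeps the vertex itself
  ix <- as.vector(t(outer(x, 1 - frac) + outer(xn, frac)))
  iy <- as.vector(t(outer(y, 1 - frac) + outer(yn, frac)))
  contour_polygon(ix, iy, frame_index = contour$frame_index,
                  timestamp = contour$timestamp)
}

#' Polar representation of a contour about its center-of-mass
#'
#' Transforms a (dense) contour into polar coordinates \eqn{(r_n, \varphi_n)}
#' about the shoelace centroid, with \eqn{\varphi_n} measured from the flow
#' axis by the two-argument arctangent. Vertices are kept in traversal order,
#' rotated to start at the vertex nearest \eqn{\varphi = -\pi}; the angular
#' weights are \eqn{\Delta\varphi_n = \tfrac12(\varphi_{n+1} -
#' \varphi_{n-1})} with cyclic indexing and \eqn{2\pi} unwrapping, so they
#' telescope to \eqn{2\pi} exactly.
#'
#' @param contour A [contour_polygon], star-shaped about its centroid
#'   (guaranteed for convex contours).
#' @return An object of class `polar_contour` with fields `r`, `phi`, `dphi`,
#'   `com`, `n_points`.
#' @export
polar_transform <- function(contour) {
  g <- .polygon_geometry(contour$x, contour$y)
  xr <- contour$x - g$com[1]
  yr <- contour$y - g$com[2]
  r <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  if (any(r <= 0)) stop("contour passes through its own centroid")
  ## drop consecutive duplicate angles (can arise from interpolation of
  ## collinear pixel runs)
  keep <- c(TRUE, diff(phi) != 0)
  r <- r[keep]; phi <- phi[keep]
  if (length(phi) > 3 && phi[length(phi)] == phi[1]) {
    r <- r[-length(r)]; phi <- phi[-length(phi)]
  }
  n <- length(phi)
  ## star-shapedness: along the (ccw) traversal phi must advance monotonically
  ## modulo 2*pi
  step <- diff(phi[c(seq_len(n), 1)]) %% (2 * pi)
  if (any(step <= 0) || any(step >= pi))
    stop("contour is not star-shaped about its centroid")
  start <- which.min(phi)                     # vertex nearest phi = -pi
  idx <- c(start:n, seq_len(start - 1))[seq_len(n)]
  r <- r[idx]; phi <- phi[idx]
  dphi <- (step[idx] + step[c(idx[n], idx[-n])]) / 2
  structure(list(r = r, phi = phi, dphi = dphi, com = g$com, n_points = n),
            class = "polar_contour")
}

#' Radial Fourier coefficients of a polar contour
#'
#' Computes the shape-mode coefficients
#' \deqn{a_k = \frac{1}{\pi}\sum_n r_n \cos(k\varphi_n)\,\Delta\varphi_n,\quad
#'       b_k = \frac{1}{\pi}\sum_n r_n \sin(k\varphi_n)\,\Delta\varphi_n.}
#' For a circle of radius R, `a0 = 2R` and all higher coefficients vanish.
#' The `b_k` encode angular orientation / off-center displacement and have
#' expectation zero for cells aligned with the flow axis.
#'
#' @param pc A `polar_contour` from [polar_transform()].
#' @param k_max Highest mode order (default 9, i.e. the first ten `a_k`).
#' @param normalize If `TRUE`, divide all coefficients by `a0` for a
#'   size-invariant representation (used for reporting, not reconstruction).
#' @return An object of class `shape_spectrum`: fields `a` (named `a0`..),
#'   `b` (named `b1`..), `normalized`.
#' @export
fourier_coefficients <- function(pc, k_max = 9, normalize = FALSE) {
  stopifnot(inherits(pc, "polar_contour"), k_max >= 1)
  w <- pc$r * pc$dphi / pi
  kphi <- outer(pc$phi, 0:k_max)
  a <- as.vector(crossprod(cos(kphi), w))
  b <- as.vector(crossprod(sin(kphi[, -1, drop = FALSE]), w))
  names(a) <- paste0("a", 0:k_max)
  names(b) <- paste0("b", seq_len(k_max))
  if (a[1] <= 0) stop("invalid spectrum: a0 must be positive")
  if (normalize) {
    b <- b / a[1]
    a <- a / a[1]
  }
  structure(list(a = a, b = b, normalized = normalize), class = "shape_spectrum")
}

#' @export
print.shape_spectrum <- function(x, ...) {
  cat(sprintf("shape_spectrum (%s): a0 = %.4g\n",
              if (x$normalized) "normalized" else "µm", x$a[1]))
  print(signif(c(x$a[-1], x$b), 4))
  invisible(x)
}

#' Shape spectrum of a contour polygon
#'
#' Convenience chain: [interpolate_contour()] then [polar_transform()] then
#' [fourier_coefficients()].
#'
#' @inheritParams interpolate_contour
#' @inheritParams fourier_coefficients
#' @export
contour_spectrum <- function(contour, k_interp = 49, k_max = 9, normalize = FALSE) {
  fourier_coefficients(polar_transform(interpolate_contour(contour, k_interp)),
                       k_max = k_max, normalize = normalize)
}

#' Reconstruct a contour from a parity subset of its shape modes
#'
#' Synthesizes the radius function on a uniform angular grid from either the
#' even modes (`a0` plus `a2, a4, a6, a8` and matching `b`), the odd modes
#' (`a0` plus `a1, a3, a5, a7, a9` and matching `b`), or all ten `a_k`:
#' \deqn{r_{rec}(\varphi) = \frac{a_0}{2} +
#'   \sum_k \left[a_k \cos(k\varphi) + b_k \sin(k\varphi)\right].}
#' Area, perimeter and deformation of the reconstruction are computed on the
#' sampled polygon.
#'
#' @param spec A `shape_spectrum` in length units (not normalized).
#' @param parity One of `"even"`, `"odd"`, `"full"`.
#' @param n_angles Number of uniform angles to sample (default 1000).
#' @param use_b Include the `b_k` (sine) terms; default `TRUE`. They matter
#'   for cells slightly displaced from the channel center.
#' @return An object of class `reconstructed_contour` with fields `parity`,
#'   `phi_rec`, `r_rec`, `A`, `P`, `d`.
#' @export
reconstruct_contour <- function(spec, parity = c("full", "even", "odd"),
                                n_angles = 1000, use_b = TRUE) {
  parity <- match.arg(parity)
  stopifnot(inherits(spec, "shape_spectrum"), n_angles >= 64)
  if (isTRUE(spec$normalized))
    stop("reconstruction needs coefficients in length units, not normalized")
  ks <- switch(parity,
               even = c(2L, 4L, 6L, 8L),
               odd  = c(1L, 3L, 5L, 7L, 9L),
               full = 1:9)
  phi <- seq(-pi, pi, length.out = n_angles + 1)[-1]
  r <- rep(spec$a[["a0"]] / 2, n_angles)
  for (k in ks) {
    r <- r + spec$a[[paste0("a", k)]] * cos(k * phi)
    if (use_b) r <- r + spec$b[[paste0("b", k)]] * sin(k * phi)
  }
  if (any(r <= 0))
    stop("reconstruction error: non-positive radius (parity = ", parity, ")")
  g <- .polygon_geometry(r * cos(phi), r * sin(phi))
  structure(list(parity = parity, phi_rec = phi, r_rec = r,
                 A = g$A, P = g$P, d = .deformation_from_AP(g$A, g$P)),
            class = "reconstructed_contour")
}

#' @export
print.reconstructed_contour <- function(x, ...) {
  cat(sprintf("reconstructed_contour (%s parity): d = %.4g\n", x$parity, x$d))
  invisible(x)
}

#' Decompose a tracked cell into parity deformation traces
#'
#' Runs the full shape-mode chain per frame (interpolate, polar transform,
#' Fourier decomposition, even and odd reconstruction) and assembles the
#' per-frame deformations into a tidy trace: `d_raw` from the original
#' contour, `d_even` (alias `d_inlet`) from the even reconstruction and
#' `d_odd` (alias `d_channel`) from the odd reconstruction, together with
#' times, axial positions and all coefficients.
#'
#' @param track A [tracked_cell], or a list of [contour_polygon] plus
#'   `z_um`/`t_s` vectors.
#' @param pixel_size_um Pixel pitch used to scale contours to µm.
#' @param k_interp,n_angles,use_b See [interpolate_contour()] and
#'   [reconstruct_contour()].
#' @param hull Apply the convex-hull step before analysis (default `TRUE`).
#' @param min_points Minimum number of valid observations (default 14).
#' @param max_fail_frac Reject the trace if more than this fraction of frames
#'   fails reconstruction (default 0.2).
#' @return A `deformation_trace`: a data frame with one row per frame and
#'   columns `cell_id`, `frame`, `t_s`, `z_um`, `A_um2`, `d_raw`, `d_even`,
#'   `d_odd`, `a0_um`, `a0`..`a9`, `b1`..`b9`.
#' @export
decompose_trace <- function(track, pixel_size_um = 1, k_interp = 49,
                            n_angles = 1000, use_b = TRUE, hull = TRUE,
                            min_points = 14, max_fail_frac = 0.2) {
  if (inherits(track, "tracked_cell")) {
    contours <- track$contours
    z <- track$z_um
    t_s <- track$t_s
    id <- track$cell_id
    pixel_size_um <- track$pixel_size_um %||% pixel_size_um
  } else {
    contours <- track$contours
    z <- track$z_um
    t_s <- track$t_s
    id <- track$cell_id %||% 1L
  }
  n <- length(contours)
  if (n < min_points)
    stop("trace rejected: ", n, " contours, need at least ", min_points)
  rows <- vector("list", n)
  nfail <- 0
  for (i in seq_len(n)) {
    res <- tryCatch({
      cp <- contours[[i]]
      cp_um <- contour_polygon(cp$x * pixel_size_um, cp$y * pixel_size_um,
                               frame_index = cp$frame_index,
                               timestamp = cp$timestamp)
      if (hull) cp_um <- convex_hull(cp_um)
      sp <- contour_spectrum(cp_um, k_interp = k_interp)
      list(A = measure_geometry(cp_um)$A,
           d_raw = deformation(cp_um),
           d_even = reconstruct_contour(sp, "even", n_angles, use_b)$d,
           d_odd = reconstruct_contour(sp, "odd", n_angles, use_b)$d,
           a = sp$a, b = sp$b)
    }, error = function(e) NULL)
    if (is.null(res)) {
      nfail <- nfail + 1
      next
    }
    rows[[i]] <- data.frame(cell_id = id, frame = i - 1L, t_s = t_s[i],
                            z_um = z[i], A_um2 = res$A, d_raw = res$d_raw,
                            d_even = res$d_even, d_odd = res$d_odd,
                            a0_um = unname(res$a[1]),
                            as.list(res$a), as.list(res$b))
  }
  if (nfail / n > max_fail_frac)
    stop(sprintf("trace rejected: %d/%d frames failed reconstruction", nfail, n))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) < min_points)
    stop("trace rejected: fewer than ", min_points, " valid observations")
  class(out) <- c("deformation_trace", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
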