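## Ground-truth simulator.
##
## A synthetic cell is a convex contour whose even-parity deformation follows
## the Kelvin-Voigt response to a half-Gaussian stress peak at the channel
## inlet, and whose odd-parity deformation follows the Kelvin-Voigt creep
## response to the constant channel stress. The generator prescribes the two
## parity deformation traces directly (deformation is the observable the
## creep model is fitted to) and numerically inverts a mode-amplitude ->
## deformation map so that the rendered contours reproduce those traces.
## That map is computed by generator-local geometry code (shoelace sums and a
## trapezoid-weighted DFT written independently of the analysis module), so
## recovery tests compare two separate code paths.
##
## Shape families: an area-preserving ellipse carries the even response (it
## has no odd harmonic content by symmetry); an egg curve
## (x = a cos u, y = b sin u (1 + alpha cos u)) carries the odd, bullet-like
## response and stays convex up to alpha ~ 0.7.

#' Specification of one synthetic cell
#'
#' @param radius_um Undeformed cell radius (µm).
#' @param E_true Apparent Young's modulus (Pa).
#' @param eta_true Apparent viscosity (Pa·s).
#' @param inlet_peak_amp Peak even-parity deformation at the inlet
#'   (dimensionless).
#' @param channel_step_stress Constant channel stress \eqn{\sigma_{channel}}
#'   (Pa).
#' @param velocity_um_s Translocation speed (µm/s).
#' @param noise_sd Radial contour noise per vertex (µm, i.i.d. Gaussian,
#'   applied before any convex-hull step downstream).
#' @param seed RNG seed; the whole simulation is reproducible for a fixed
#'   seed.
#' @param fps Frame rate of the emulated acquisition (frames/s).
#' @param pixel_size_um Pixel pitch for rendering (µm/px).
#' @param channel_length_um Channel length (µm), inlet at z = 0.
#' @param approach_um Length of the pre-channel approach covered by the
#'   simulation (µm).
#' @param y_offset_um Lateral offset of the cell from the channel axis (µm).
#' @param pulse_width_um Width of the half-Gaussian inlet stress peak (µm).
#'   The functional form of the inlet transient is not constrained by
#'   hydrodynamic theory here; the half-Gaussian is a documented stand-in.
#' @param n_points Vertices per synthetic contour (default 360, well above
#'   the 10-coefficient bandwidth).
#' @param calibration A [calibration_table] linking channel deformation and
#'   modulus; default is `toy_calibration_table("saturating",
#'   sigma_pa = channel_step_stress)`.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(radius_um = 9, E_true = 400, eta_true = 3.43,
                                inlet_peak_amp = 0.04,
                                channel_step_stress = 142,
                                velocity_um_s = 7000, noise_sd = 0, seed = 1L,
                                fps = 2000, pixel_size_um = 0.34,
                                channel_length_um = 300, approach_um = 35,
                                y_offset_um = 0, pulse_width_um = 15,
                                n_points = 360, calibration = NULL) {
  stopifnot(radius_um > 0, E_true > 0, eta_true > 0, noise_sd >= 0,
            inlet_peak_amp >= 0, channel_step_stress > 0, velocity_um_s > 0,
            fps > 0, pixel_size_um > 0, channel_length_um > 0,
            approach_um > radius_um, pulse_width_um > 0, n_points >= 32)
  if (is.null(calibration))
    calibration <- toy_calibration_table("saturating",
                                         sigma_pa = channel_step_stress)
  structure(list(radius_um = radius_um, E_true = E_true, eta_true = eta_true,
                 inlet_peak_amp = inlet_peak_amp,
                 channel_step_stress = channel_step_stress,
                 velocity_um_s = velocity_um_s, noise_sd = noise_sd,
                 seed = as.integer(seed), fps = fps,
                 pixel_size_um = pixel_size_um,
                 channel_length_um = channel_length_um,
                 approach_um = approach_um, y_offset_um = y_offset_um,
                 pulse_width_um = pulse_width_um,
                 n_points = n_points, calibration = calibration),
            class = "synthetic_cell_spec")
}

#' Kelvin-Voigt strain response to an arbitrary stress history
#'
#' Integrates \eqn{\eta\,\dot\varepsilon + E\,\varepsilon = \sigma(t)} with
#' \eqn{\varepsilon(0) = 0} using the exact exponential update for piecewise
#' constant stress (midpoint rule). For a step stress \eqn{\sigma} applied at
#' t = 0 this returns \eqn{\varepsilon(t) = (\sigma/E)(1 - e^{-t/\tau})} with
#' \eqn{\tau = \eta/E}, exactly at the sample points.
#'
#' @param stress_profile Function of time (s) returning stress (Pa);
#'   vectorized or scalar.
#' @param E Young's modulus (Pa), > 0.
#' @param eta Viscosity (Pa·s), > 0.
#' @param times Increasing sample times (s), starting at the causal origin.
#' @return Strain series (dimensionless), same length as `times`, first
#'   element 0.
#' @export
kelvin_voigt_response <- function(stress_profile, E, eta, times) {
  if (!is.numeric(E) || E <= 0 || !is.numeric(eta) || eta <= 0)
    stop("E and eta must be positive")
  stopifnot(is.function(stress_profile), !is.unsorted(times, strictly = TRUE))
  tau <- eta / E
  n <- length(times)
  eps <- numeric(n)
  if (n == 1) return(eps)
  dt <- diff(times)
  mid <- times[-n] + dt / 2
  sig <- vapply(mid, function(t) as.numeric(stress_profile(t)[1]), numeric(1))
  decay <- exp(-dt / tau)
  for (i in seq_len(n - 1))
    eps[i + 1] <- eps[i] * decay[i] + (sig[i] / E) * (1 - decay[i])
  eps
}

#' Synthesize a contour polygon from radial Fourier coefficients
#'
#' Inverse of the shape-mode decomposition: samples
#' \eqn{r(\varphi) = a_0/2 + \sum_k a_k\cos(k\varphi) + b_k\sin(k\varphi)}
#' at `n_points` uniform angles. Feeding the result back through the analysis
#' recovers the coefficients up to discretization and centroid re-centering.
#'
#' @param mode_amplitudes Numeric vector `c(a0, a1, ..., )` in length units;
#'   `a0 > 0`.
#' @param b_amplitudes Optional `c(b1, b2, ...)` sine coefficients.
#' @param n_points Number of uniformly spaced vertices (default 360).
#' @return A [contour_polygon] centred on the origin of the radius expansion.
#' @export
make_contour <- function(mode_amplitudes, b_amplitudes = NULL, n_points = 360) {
  a <- as.numeric(mode_amplitudes)
  if (length(a) < 1 || a[1] <= 0) stop("a0 must be positive")
  b <- if (is.null(b_amplitudes)) numeric(length(a) - 1) else as.numeric(b_amplitudes)
  phi <- seq(-pi, pi, length.out = n_points + 1)[-1]
  r <- rep(a[1] / 2, n_points)
  for (k in seq_along(a)[-1])
    r <- r + a[k] * cos((k - 1) * phi)
  for (k in seq_along(b))
    r <- r + b[k] * sin(k * phi)
  if (any(r <= 0))
    stop("invalid shape: radius function non-positive at some angle")
  contour_polygon(r * cos(phi), r * sin(phi))
}

## ---- generator-local geometry (independent of the analysis code path) ----

.gt_geom <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  list(A = abs(A),
       P = sum(sqrt((xn - x)^2 + (yn - y)^2)),
       cx = sum((x + xn) * cr) / (6 * A),
       cy = sum((y + yn) * cr) / (6 * A))
}

## both parity deformations of a polygon, measured about its centroid with a
## trapezoid-weighted DFT truncated at k = 9
.gt_parity_d <- function(x, y, modes = FALSE) {
  g <- .gt_geom(x, y)
  xr <- x - g$cx; yr <- y - g$cy
  r <- sqrt(xr^2 + yr^2)
  phi <- atan2(yr, xr)
  o <- order(phi)
  r <- r[o]; phi <- phi[o]
  n <- length(phi)
  dphi <- ((phi[c(2:n, 1)] - phi[c(n, 1:(n - 1))]) %% (2 * pi)) / 2
  a <- vapply(0:9, function(k) sum(r * cos(k * phi) * dphi) / pi, numeric(1))
  b <- vapply(1:9, function(k) sum(r * sin(k * phi) * dphi) / pi, numeric(1))
  ph <- seq(-pi, pi, length.out = 1441)[-1]
  pard <- function(ks) {
    rr <- rep(a[1] / 2, length(ph))
    for (k in ks) rr <- rr + a[k + 1] * cos(k * ph) + b[k] * sin(k * ph)
    g2 <- .gt_geom(rr * cos(ph), rr * sin(ph))
    max(0, 1 - 2 * sqrt(pi * g2$A) / g2$P)
  }
  out <- list(d_even = pard(seq(2, 8, 2)), d_odd = pard(seq(1, 9, 2)))
  if (modes) c(out, list(a = a, b = b)) else out
}

## parametric cell outline: ellipse elongation delta + egg asymmetry alpha
.sim_outline <- function(R, delta, alpha, n_points, center = c(0, 0)) {
  u <- seq(-pi, pi, length.out = n_points + 1)[-1]
  a <- R * (1 + delta); b <- R / (1 + delta)
  list(x = center[1] + a * cos(u),
       y = center[2] + b * sin(u) * (1 + alpha * cos(u)))
}

.sim_map_cache <- new.env(parent = emptyenv())

## joint map (delta, alpha) -> (d_even, d_odd) on a grid; elongation and
## asymmetry couple, so both parities are tabulated over both parameters
.sim_amplitude_map <- function(R, n_points = 720) {
  key <- sprintf("%.9g_%d", R, n_points)
  if (!is.null(.sim_map_cache[[key]])) return(.sim_map_cache[[key]])
  delta <- seq(0, 0.60, length.out = 16)
  alpha <- seq(0, 0.70, length.out = 18)
  De <- Do <- matrix(NA_real_, length(delta), length(alpha))
  for (i in seq_along(delta)) for (j in seq_along(alpha)) {
    o <- .sim_outline(R, delta[i], alpha[j], n_points)
    d <- .gt_parity_d(o$x, o$y)
    De[i, j] <- d$d_even
    Do[i, j] <- d$d_odd
  }
  map <- list(delta = delta, alpha = alpha, De = De, Do = Do,
              d_even_max = De[length(delta), 1], d_odd_max = Do[1, length(alpha)],
              n_points = n_points, R = R)
  .sim_map_cache[[key]] <- map
  map
}

## invert the joint map: find (delta, alpha) whose measured parity
## deformations equal the targets. Alternating 1-D inversions (each axis is
## monotone and the cross-coupling is mild), then correction passes against
## the exact generator-local measurement. delta clamps at 0 when the even
## target falls below the asymmetry-induced even leakage.
.sim_invert_amplitudes <- function(map, d_even_t, d_odd_t) {
  ## 1-D slice of a grid matrix at fixed delta (rows) or alpha (cols)
  slice_a <- function(M, de) { # vector over alpha at elongation de
    i <- findInterval(de, map$delta, all.inside = TRUE)
    w <- (de - map$delta[i]) / (map$delta[i + 1] - map$delta[i])
    (1 - w) * M[i, ] + w * M[i + 1, ]
  }
  slice_d <- function(M, al) { # vector over delta at asymmetry al
    j <- findInterval(al, map$alpha, all.inside = TRUE)
    w <- (al - map$alpha[j]) / (map$alpha[j + 1] - map$alpha[j])
    (1 - w) * M[, j] + w * M[, j + 1]
  }
  inv1 <- function(vals, grid, target) { # monotone 1-D inverse with clamping
    if (target <= vals[1]) return(grid[1])
    if (target >= vals[length(vals)]) return(grid[length(grid)])
    stats::approx(vals, grid, xout = target, ties = "ordered")$y
  }
  de <- 0; al <- 0
  for (it in 1:6) {
    al_new <- inv1(slice_a(map$Do, de), map$alpha, d_odd_t)
    de_new <- inv1(slice_d(map$De, al_new), map$delta, d_even_t)
    conv <- abs(al_new - al) < 1e-9 && abs(de_new - de) < 1e-9
    al <- al_new; de <- de_new
    if (conv) break
  }
  ## exact correction: adjust by the residual of the true measurement using
  ## local grid slopes; the last evaluation (contour measurement including
  ## mode amplitudes) is returned so callers need not re-measure
  d <- NULL
  for (it in 1:4) {
    o <- .sim_outline(map$R, de, al, map$n_points)
    d <- .gt_parity_d(o$x, o$y, modes = TRUE)
    r_o <- d$d_odd - d_odd_t
    r_e <- d$d_even - d_even_t
    tol <- 1e-6 + 1e-4 * (d_odd_t + d_even_t)
    if ((abs(r_o) < tol && abs(r_e) < tol) || it == 4) break
    vo <- slice_a(map$Do, de)
    so <- stats::approx(map$alpha[-1] - diff(map$alpha) / 2,
                        diff(vo) / diff(map$alpha), xout = al, rule = 2)$y
    if (is.finite(so) && so > 0) al <- min(max(al - r_o / so, 0), max(map$alpha))
    ve <- slice_d(map$De, al)
    se <- stats::approx(map$delta[-1] - diff(map$delta) / 2,
                        diff(ve) / diff(map$delta), xout = de, rule = 2)$y
    if (de > 0 || r_e < 0)
      if (is.finite(se) && se > 0) de <- min(max(de - r_e / se, 0), max(map$delta))
  }
  list(delta = de, alpha = al, modes = d)
}

## run expr with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (has) assign(".Random.seed", old, envir = .GlobalEnv) else
            rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate one cell transit with ground truth
#'
#' Generates the cell's trajectory through approach and channel, the
#' ground-truth even/odd deformation traces (Kelvin-Voigt responses to the
#' half-Gaussian inlet peak and to the channel step stress, respectively),
#' and one contour per frame, positioned in the lab frame (µm; x = 0 at the
#' left edge of the field of view, the channel inlet sits at
#' `x = approach_um`).
#'
#' @param spec A [synthetic_cell_spec].
#' @return An object of class `ground_truth_trace`: `times` (s), `z_um`
#'   (axial position relative to the inlet), `contours` (list of
#'   [contour_polygon] in µm), `d_even_true`, `d_odd_true`, `tau_true` (s),
#'   `d_hat_inlet_true`, `d_hat_channel_true`, `mode_amplitudes` (n x 10
#'   matrix of the a-coefficients measured on the noiseless contours),
#'   and the input `spec`.
#' @export
simulate_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  R <- spec$radius_um
  tau <- spec$eta_true / spec$E_true
  v <- spec$velocity_um_s
  z_start <- -(spec$approach_um - R - 2)
  if (z_start >= 0) stop("approach region too short for this cell radius")
  n <- floor((spec$channel_length_um - z_start) / v * spec$fps) + 1
  times <- (seq_len(n) - 1) / spec$fps
  z <- z_start + v * times
  t_in <- -z_start / v

  ## even (inlet) response: Kelvin-Voigt response to the half-Gaussian peak,
  ## normalized to the prescribed peak amplitude
  w_t <- spec$pulse_width_um / v
  pulse <- function(t) {
    zz <- z_start + v * t
    ifelse(zz < 0, exp(-zz^2 / (2 * w_t^2 * v^2)), 0)
  }
  d_even <- if (spec$inlet_peak_amp > 0) {
    tfine <- seq(0, times[n], by = min(1 / spec$fps, tau, w_t) / 25)
    eps <- kelvin_voigt_response(pulse, spec$E_true, spec$eta_true, tfine)
    if (max(eps) <= 0) rep(0, n)
    else spec$inlet_peak_amp *
      stats::approx(tfine, eps / max(eps), xout = times, rule = 2)$y
  } else rep(0, n)

  ## odd (channel) response: creep to the step stress, amplitude set by the
  ## calibration map so that analysis inversion is a closed loop
  d_hat_ch <- calibration_deformation(spec$E_true, 2 * R, spec$calibration)
  d_odd <- ifelse(z < 0, 0, d_hat_ch * (1 - exp(-(times - t_in) / tau)))

  map <- .sim_amplitude_map(R)
  if (max(d_even) > map$d_even_max || max(d_odd) > map$d_odd_max)
    stop(sprintf(paste0("requested deformation exceeds the convex shape range",
                        " (even max %.3f, odd max %.3f)"),
                 map$d_even_max, map$d_odd_max))
  # channel axis height in the 80 px field at 0.34 µm/px, plus lateral offset
  y_c <- 13.6 + spec$y_offset_um
  contours <- vector("list", n)
  amps <- matrix(NA_real_, n, 10, dimnames = list(NULL, paste0("a", 0:9)))
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed,
               matrix(stats::rnorm(n * spec$n_points, sd = spec$noise_sd), n))
  else NULL
  for (i in seq_len(n)) {
    sol <- .sim_invert_amplitudes(map, max(d_even[i], 0), max(d_odd[i], 0))
    amps[i, ] <- sol$modes$a
    o <- .sim_outline(R, sol$delta, sol$alpha, spec$n_points,
                      center = c(z[i] + spec$approach_um, y_c))
    if (!is.null(noise)) {
      cx <- z[i] + spec$approach_um
      rr <- sqrt((o$x - cx)^2 + (o$y - y_c)^2)
      f <- (rr + noise[i, ]) / rr
      o$x <- cx + (o$x - cx) * f
      o$y <- y_c + (o$y - y_c) * f
    }
    contours[[i]] <- contour_polygon(o$x, o$y, frame_index = i - 1L,
                                     timestamp = times[i])
  }
  structure(list(spec = spec, times = times, z_um = z, contours = contours,
                 d_even_true = d_even, d_odd_true = d_odd, tau_true = tau,
                 d_hat_inlet_true = max(d_even), d_hat_channel_true = d_hat_ch,
                 mode_amplitudes = amps, t_inlet = t_in),
            class = "ground_truth_trace")
}

#' @export
print.ground_truth_trace <- function(x, ...) {
  cat(sprintf(paste0("ground_truth_trace: %d frames, tau = %.3g ms, ",
                     "d_hat_inlet = %.3g, d_hat_channel = %.3g\n"),
              length(x$times), 1000 * x$tau_true, x$d_hat_inlet_true,
              x$d_hat_channel_true))
  invisible(x)
}

#' Rasterize contours into a binary frame stack
#'
#' Renders each contour as a filled shape on a pixel grid (pixel centers at
#' integer multiples of `pixel_size_um`), using supersampled area coverage
#' with a 50% threshold. Rendering is deterministic.
#'
#' @param contours List of [contour_polygon] in µm (lab frame), or a
#'   `ground_truth_trace`.
#' @param pixel_size_um Pixel pitch (µm/px), default 0.34.
#' @param frame_shape `c(ny, nx)` in pixels, default `c(80, 1280)`.
#' @param fps Frame rate stored in the resulting stream metadata.
#' @param supersample Subpixel sampling factor per axis (default 3).
#' @return A [frame_stream] of binary frames (values 0/1); for a
#'   `ground_truth_trace` input the truth is attached as attribute
#'   `"ground_truth"`.
#' @export
render_frames <- function(contours, pixel_size_um = 0.34,
                          frame_shape = c(80, 1280), fps = NULL,
                          supersample = 3) {
  truth <- NULL
  if (inherits(contours, "ground_truth_trace")) {
    truth <- contours
    pixel_size_um <- truth$spec$pixel_size_um
    fps <- fps %||% truth$spec$fps
    contours <- truth$contours
  }
  fps <- fps %||% NA_real_
  ny <- frame_shape[1]; nx <- frame_shape[2]
  frames <- vector("list", length(contours))
  for (i in seq_along(contours)) {
    cp <- contours[[i]]
    if (min(cp$x) < 0 || max(cp$x) > (nx - 1) * pixel_size_um ||
        min(cp$y) < 0 || max(cp$y) > (ny - 1) * pixel_size_um)
      stop(sprintf("render error: contour %d exceeds frame bounds", i))
    frames[[i]] <- .rasterize_star(cp, pixel_size_um, ny, nx, supersample)
  }
  fs <- frame_stream(frames, fps = fps, pixel_size_um = pixel_size_um)
  if (!is.null(truth)) attr(fs, "ground_truth") <- truth
  fs
}

## fill a star-shaped polygon by radius-function lookup about its centroid
.rasterize_star <- function(cp, px, ny, nx, ss) {
  g <- .gt_geom(cp$x, cp$y)
  r <- sqrt((cp$x - g$cx)^2 + (cp$y - g$cy)^2)
  th <- atan2(cp$y - g$cy, cp$x - g$cx)
  o <- order(th)
  rfun <- stats::approxfun(c(th[o], th[o][1] + 2 * pi), c(r[o], r[o][1]))
  rmax <- max(r)
  js <- max(0, floor((g$cx - rmax) / px - 1)):min(nx - 1, ceiling((g$cx + rmax) / px + 1))
  is <- max(0, floor((g$cy - rmax) / px - 1)):min(ny - 1, ceiling((g$cy + rmax) / px + 1))
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * px
  cov <- matrix(0, length(is), length(js))
  for (dx in sub) for (dy in sub) {
    gx <- outer(rep(1, length(is)), js * px + dx - g$cx)
    gy <- outer(is * px + dy - g$cy, rep(1, length(js)))
    rr <- sqrt(gx^2 + gy^2)
    tt <- atan2(gy, gx)
    tt[tt < min(th)] <- tt[tt < min(th)] + 2 * pi
    cov <- cov + (rr <= rfun(pmin(pmax(tt, min(th)), min(th) + 2 * pi)))
  }
  frame <- matrix(0, ny, nx)
  frame[is + 1, js + 1] <- (cov >= ss^2 / 2) * 1
  frame
}

#' Simulate a cell and render its frames in one call
#'
#' @inheritParams simulate_trace
#' @inheritParams render_frames
#' @return A [frame_stream] with the `ground_truth_trace` attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_frames <- function(spec, frame_shape = c(80, 1280), supersample = 3) {
  render_frames(simulate_trace(spec), frame_shape = frame_shape,
                supersample = supersample)
}
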