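# Shared fixtures: shape generators and the naive-loop Fourier oracle.

# dense regular polygon approximating a circle
circle_contour <- function(R = 10, n = 360, center = c(0, 0)) {
  th <- seq(-pi, pi, length.out = n + 1)[-1]
  contour_polygon(center[1] + R * cos(th), center[2] + R * sin(th))
}

# ellipse with semi-axes a (flow axis) and b
ellipse_contour <- function(a = 2, b = 1, n = 720, center = c(0, 0)) {
  th <- seq(-pi, pi, length.out = n + 1)[-1]
  contour_polygon(center[1] + a * cos(th), center[2] + b * sin(th))
}

# egg-shaped (bullet-like, fore-aft asymmetric) convex contour
egg_contour <- function(R = 10, alpha = 0.4, n = 720, center = c(0, 0)) {
  th <- seq(-pi, pi, length.out = n + 1)[-1]
  contour_polygon(center[1] + R * cos(th),
                  center[2] + R * sin(th) * (1 + alpha * cos(th)))
}

# random smooth star-shaped (near-convex) contour: low-order random harmonics
random_star_contour <- function(R = 10, n = 400, k_max = 6, amp = 0.04) {
  th <- seq(-pi, pi, length.out = n + 1)[-1]
  r <- rep(R, n)
  for (k in seq_len(k_max))
    r <- r + R * amp * (stats::runif(1, -1, 1) * cos(k * th) +
                          stats::runif(1, -1, 1) * sin(k * th)) / k
  contour_polygon(r * cos(th), r * sin(th))
}

# independent naive-loop evaluation of the shape-mode sums on a polar contour
naive_fourier_oracle <- function(pc, k_max = 9) {
  a <- numeric(k_max + 1)
  b <- numeric(k_max)
  for (k in 0:k_max) {
    s <- 0
    for (n in seq_along(pc$r))
      s <- s + pc$r[n] * cos(k * pc$phi[n]) * pc$dphi[n]
    a[k + 1] <- s / pi
  }
  for (k in seq_len(k_max)) {
    s <- 0
    for (n in seq_along(pc$r))
      s <- s + pc$r[n] * sin(k * pc$phi[n]) * pc$dphi[n]
    b[k] <- s / pi
  }
  list(a = a, b = b)
}

# a minimal synthetic track: list interface accepted by decompose_trace()
static_track <- function(contour, n_frames = 15, fps = 2000, v_um_s = 7000,
                         z0 = -20) {
  contours <- lapply(seq_len(n_frames) - 1L, function(i) {
    contour_polygon(contour$x, contour$y, frame_index = i,
                    timestamp = i / fps)
  })
  list(contours = contours, z_um = z0 + v_um_s * (seq_len(n_frames) - 1) / fps,
       t_s = (seq_len(n_frames) - 1) / fps, cell_id = 1L)
}
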