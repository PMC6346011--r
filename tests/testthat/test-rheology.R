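test_that("exponential creep fit recovers exact parameters in-class", {
  t <- seq(0, 0.01, length.out = 50)
  d <- 0.02 + 0.05 * exp(-t / 0.002)
  fit <- fit_exponential(t, d, "inlet")
  expect_true(fit$accepted)
  expect_equal(fit$d0, 0.02, tolerance = 1e-6)
  expect_equal(fit$d_hat, 0.05, tolerance = 1e-6)   # + sign on the inlet
  expect_equal(fit$tau, 0.002, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  dch <- 0.02 - 0.05 * exp(-t / 0.002)
  fitc <- fit_exponential(t, dch, "channel")
  expect_equal(fitc$d_hat, -0.05, tolerance = 1e-6) # - sign in the channel
  expect_equal(fitc$tau, 0.002, tolerance = 1e-6)
})

test_that("creep fit is robust to noise and unbiased across tau", {
  # noisy replicates: median tau within 5% of 2 ms
  t <- seq(0, 0.01, length.out = 50)
  d0 <- 0.02 + 0.05 * exp(-t / 0.002)
  set.seed(7)
  taus <- replicate(200, {
    fit <- fit_exponential(t, d0 + rnorm(50, sd = 0.002), "inlet",
                           r2_cutoff = 0)
    fit$tau
  })
  expect_lt(abs(median(taus) - 0.002) / 0.002, 0.05)

  # noiseless recovery over tau in [0.1 ms, 50 ms], 14+ points over >= 3 tau
  for (tau in c(1e-4, 1e-3, 1e-2, 5e-2)) {
    tt <- seq(0, 3.5 * tau, length.out = 20)
    fit <- fit_exponential(tt, 0.01 - 0.03 * exp(-tt / tau), "channel")
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
  }
})

test_that("the r2 gate rejects pure noise", {
  set.seed(99)
  t <- seq(0, 0.01, length.out = 60)
  fit <- fit_exponential(t, rnorm(60, sd = 0.01), "channel")
  expect_false(fit$accepted)
  expect_match(fit$reason, "below cutoff|converge")
})

test_that("extract_peaks reads both stress responses off a trace", {
  gt <- simulate_trace(synthetic_cell_spec())
  dtr <- decompose_trace(list(contours = gt$contours, z_um = gt$z_um,
                              t_s = gt$times, cell_id = 1L))
  pk <- extract_peaks(dtr, channel_length_um = 300)
  expect_lt(abs(pk$d_hat_inlet - gt$d_hat_inlet_true) / gt$d_hat_inlet_true,
            0.02)
  expect_lt(abs(pk$d_hat_channel - gt$d_hat_channel_true) /
              gt$d_hat_channel_true, 0.02)

  # constant-shape track: both peaks are zero
  still <- decompose_trace(static_track(circle_contour(R = 9, n = 240),
                                        n_frames = 40))
  pk0 <- extract_peaks(still, channel_length_um = 300)
  expect_equal(pk0$d_hat_inlet, 0)
  expect_equal(pk0$d_hat_channel, 0)

  # trace cut off before the plateau: value from fit d0, flagged
  cut <- dtr[dtr$t_s <= dtr$t_s[match(TRUE, dtr$z_um >= 0)] +
               1.2 * gt$tau_true, ]
  class(cut) <- class(dtr)
  pkc <- extract_peaks(cut, channel_length_um = 300)
  expect_true("no_plateau" %in% pkc$flags)
  expect_true(is.finite(pkc$d_hat_channel))
})

test_that("young_modulus interpolates the calibration table", {
  # toy linear-elastic table: E = sigma * g / d_hat with g = 0.1
  tab <- toy_calibration_table("linear", sigma_pa = 142, gain = 0.1)
  expect_equal(young_modulus(0.05, 15, tab), 142 * 0.1 / 0.05,
               tolerance = 1e-3)
  # exact at a grid node
  dnode <- tab$deformations[40]
  expect_equal(young_modulus(dnode, tab$diameters_um[3], tab),
               tab$E_pa[3, 40])
  # monotone: larger deformation at fixed size -> smaller E
  ds <- seq(0.01, 0.2, by = 0.01)
  Es <- vapply(ds, young_modulus, numeric(1), diameter_um = 15, table = tab)
  expect_true(all(diff(Es) < 0))
  # out-of-hull queries fail loudly, listing the hull
  expect_error(young_modulus(0.5, 15, tab), "outside calibration hull")
  expect_error(young_modulus(0.05, 100, tab), "outside calibration hull")
  # forward map is consistent with the inverse
  dfwd <- calibration_deformation(568, 15, tab)
  expect_equal(young_modulus(dfwd, 15, tab), 568, tolerance = 1e-3)
})

test_that("apparent viscosity follows the Kelvin-Voigt relation", {
  expect_equal(apparent_viscosity(1, 1), 1)
  expect_equal(apparent_viscosity(8.575e-3, 400), 3.43)
  expect_equal(apparent_viscosity(0.005, 800),
               2 * apparent_viscosity(0.005, 400))
  expect_error(apparent_viscosity(-1, 400), "positive")
  # closure: eta / E equals tau to machine precision
  tau <- 0.0123
  expect_equal(apparent_viscosity(tau, 567) / 567, tau, tolerance = 1e-12)
})

test_that("buffer viscosity reproduces the power-law rheometry", {
  m1 <- buffer_viscosity_model("mc06")
  m2 <- buffer_viscosity_model("mc10")
  expect_identical(buffer_viscosity(1, m1), 0.16)
  expect_identical(buffer_viscosity(1, m2), 0.60)
  # in-channel shear rates give viscosities of tens of mPa s
  eta_chan <- buffer_viscosity(5100, m2)
  expect_equal(eta_chan, 0.60 * 5100^(0.64 - 1))
  expect_true(eta_chan > 0.005 && eta_chan < 0.1)
  # log-log slope equals n - 1
  g <- c(10, 1000)
  slope <- diff(log(buffer_viscosity(g, m1))) / diff(log(g))
  expect_equal(slope, m1$n - 1, tolerance = 1e-9)
  # strictly shear-thinning for n < 1
  expect_true(all(diff(buffer_viscosity(c(1, 10, 100, 1000), m2)) < 0))
  expect_error(buffer_viscosity(0, m1), "positive")
})

test_that("power-law creep fit recovers exact parameters in-class", {
  t <- exp(seq(log(1e-3), log(1e-1), length.out = 40))
  sigma <- 142
  J <- (1 / 500) * t^0.3
  d <- J * sigma # strain_scale chosen so the mapping is the identity
  fit <- powerlaw_fit(t, d, sigma_channel = sigma,
                      strain_scale = max(d))
  expect_equal(fit$E_pl, 500, tolerance = 1e-4)
  expect_equal(fit$beta, 0.3, tolerance = 1e-4)

  # beta = 0: elastic limit, J constant at 1/E
  dflat <- rep(sigma / 800, 40)
  fit0 <- powerlaw_fit(t, dflat, sigma, strain_scale = max(dflat))
  expect_equal(fit0$beta, 0, tolerance = 1e-6)
  expect_equal(fit0$E_pl, 800, tolerance = 1e-4)

  expect_error(powerlaw_fit(t, rep(0, 40), sigma), "all-zero")
})

test_that("log-normal population fit excludes 3-sigma outliers", {
  set.seed(123)
  x <- rlnorm(1000, meanlog = 0, sdlog = 0.5)
  ps <- population_fit(x)
  expect_lt(abs(ps$log_mu - 0), 0.05)
  expect_lt(abs(ps$log_sigma - 0.5), 0.05)

  # five 100x outliers are all excluded
  xo <- c(rlnorm(200, 0, 0.3), rlnorm(5, 0, 0.3) * 100)
  pso <- population_fit(xo)
  expect_equal(pso$n_outliers, 5)
  expect_true(all(!pso$kept[201:205]))

  expect_error(population_fit(rep(2, 50)), "degenerate")
  expect_error(population_fit(c(-1, rlnorm(30))), "positive")
  expect_error(population_fit(rlnorm(10)), "at least 20")
})
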