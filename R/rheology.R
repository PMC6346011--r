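## Creep fitting and material parameters.
##
## Both parity deformation traces are fitted with a single-exponential creep
## law d(t) = d0 + d_hat * exp(-t/tau) (sign convention: +d_hat for the
## relaxing inlet trace, -d_hat for the saturating channel trace), gated by
## the coefficient of correlation r^2 >= 0.6. The channel time constant is
## interpreted through a Kelvin-Voigt model, tau_channel = eta / E, where E
## comes from a pluggable deformation -> modulus calibration table.

#' Exponential creep fit of a trace segment
#'
#' Bounded nonlinear least squares of
#' \eqn{d(t) = d_0 + \hat d\, e^{-t/\tau}} (inlet segment) or
#' \eqn{d(t) = d_0 - \hat d\, e^{-t/\tau}} (channel segment), with
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}} as fit-quality gate. Times are measured
#' from the start of the segment. Initial guesses: `d0` = last value,
#' `d_hat` = |first - last|, `tau` = a third of the segment span; `tau` is
#' bounded to `[dt/10, 100 * span]`.
#'
#' @param t Time points (s), increasing, at least 5.
#' @param d Deformation values, same length.
#' @param segment `"inlet"` or `"channel"` (sets the sign of `d_hat`).
#' @param r2_cutoff Acceptance threshold on \eqn{r^2} (default 0.6).
#' @return An object of class `creep_fit`: `d0`, `d_hat` (signed: positive
#'   for inlet, negative for channel), `tau` (s), `r2`, `segment`,
#'   `accepted`, `reason` (when rejected), `tau_at_bound`, `fitted`.
#' @export
fit_exponential <- function(t, d, segment = c("inlet", "channel"),
                            r2_cutoff = 0.6) {
  segment <- match.arg(segment)
  stopifnot(length(t) == length(d), length(t) >= 5,
            !is.unsorted(t, strictly = TRUE))
  s <- if (segment == "inlet") 1 else -1
  tt <- t - t[1]
  span <- tt[length(tt)]
  dt <- stats::median(diff(tt))
  lo_tau <- dt / 10
  hi_tau <- 100 * span
  start <- list(d0 = d[length(d)], dh = abs(d[1] - d[length(d)]),
                tau = span / 3)
  if (start$dh == 0) start$dh <- max(stats::sd(d), 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ d0 + s * dh * exp(-tt / tau),
                      data = list(d = d, tt = tt, s = s),
                      start = start,
                      lower = c(d0 = -Inf, dh = 0, tau = lo_tau),
                      upper = c(d0 = Inf, dh = Inf, tau = hi_tau),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(segment = segment, accepted = FALSE,
                          reason = paste("fit did not converge:",
                                         conditionMessage(fit)),
                          d0 = NA_real_, d_hat = NA_real_, tau = NA_real_,
                          r2 = NA_real_, tau_at_bound = NA),
                     class = "creep_fit"))
  cf <- stats::coef(fit)
  f <- stats::fitted(fit)
  ss_res <- sum((d - f)^2)
  ss_tot <- sum((d - mean(d))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  at_bound <- cf[["tau"]] <= lo_tau * (1 + 1e-8) ||
    cf[["tau"]] >= hi_tau * (1 - 1e-8)
  accepted <- is.finite(r2) && r2 >= r2_cutoff
  structure(list(segment = segment, accepted = accepted,
                 reason = if (accepted) NA_character_
                          else if (!is.finite(r2)) "zero variance in segment"
                          else sprintf("r2 = %.3f below cutoff %.2f", r2,
                                       r2_cutoff),
                 d0 = unname(cf["d0"]), d_hat = s * unname(cf["dh"]),
                 tau = unname(cf["tau"]), r2 = r2, tau_at_bound = at_bound,
                 fitted = f, t = t, d = d),
            class = "creep_fit")
}

#' @export
print.creep_fit <- function(x, ...) {
  cat(sprintf("creep_fit (%s): %s\n", x$segment,
              if (x$accepted) sprintf(
                "d0 = %.4g, d_hat = %+.4g, tau = %.4g ms, r2 = %.3f",
                x$d0, x$d_hat, 1000 * x$tau, x$r2)
              else paste("rejected -", x$reason)))
  invisible(x)
}

#' Peak deformations of a decomposed trace
#'
#' `d_hat_inlet` is the local maximum of the even-parity trace near the
#' inlet. `d_hat_channel` is the steady-state plateau of the odd-parity
#' trace — the `d0` parameter of the channel creep fit — relative to the
#' pre-channel baseline of `d_odd` (so initially non-circular cells start
#' from zero). If the trace ends before a plateau is reached the fit `d0`
#' is still used, flagged `"no_plateau"`.
#'
#' @param trace A `deformation_trace` from [decompose_trace()].
#' @param channel_length_um Channel length (µm); inlet at z = 0.
#' @param inlet_window_frac Fraction of the channel length after the inlet
#'   within which the even-parity maximum is searched (default 0.3).
#' @param r2_cutoff Passed to the channel [fit_exponential()].
#' @return List with `d_hat_inlet`, `d_hat_channel`, `baseline_odd`,
#'   `channel_fit` (a `creep_fit`), `flags` (character vector).
#' @export
extract_peaks <- function(trace, channel_length_um = 300,
                          inlet_window_frac = 0.3, r2_cutoff = 0.6) {
  stopifnot(is.data.frame(trace), all(c("z_um", "t_s", "d_even", "d_odd")
                                      %in% names(trace)))
  flags <- character(0)
  if (stats::sd(trace$d_even) == 0 && stats::sd(trace$d_odd) == 0)
    return(list(d_hat_inlet = 0, d_hat_channel = 0, baseline_odd =
                  trace$d_odd[1], channel_fit = NULL,
                flags = "constant_shape"))
  win <- trace$z_um <= inlet_window_frac * channel_length_um
  if (!any(win)) stop("trace rejected: no samples near the inlet")
  de <- trace$d_even[win]
  imax <- which.max(de)
  interior_max <- imax > 1 && imax < length(de) || # allow peak at entry frame
    (imax == 1 && de[1] > de[length(de)])
  if (!interior_max && stats::sd(de) > 0)
    stop("trace rejected: no local maximum of d_even near the inlet")
  d_hat_inlet <- de[imax]
  pre <- which(trace$z_um < 0)
  baseline <- if (length(pre))
    stats::median(trace$d_odd[utils::tail(pre, 5)]) else trace$d_odd[1]
  inch <- which(trace$z_um >= 0 & trace$z_um <= channel_length_um)
  if (length(inch) < 5) stop("trace rejected: too few in-channel samples")
  fit <- fit_exponential(trace$t_s[inch], trace$d_odd[inch],
                         segment = "channel", r2_cutoff = r2_cutoff)
  if (!is.na(fit$tau) &&
      diff(range(trace$t_s[inch])) < 2 * fit$tau)
    flags <- c(flags, "no_plateau")
  d_hat_channel <- if (is.na(fit$d0)) NA_real_ else fit$d0 - baseline
  list(d_hat_inlet = d_hat_inlet, d_hat_channel = d_hat_channel,
       baseline_odd = baseline, channel_fit = fit, flags = flags)
}

#' Apparent viscosity from the Kelvin-Voigt relation
#'
#' \eqn{\tau_{channel} = \eta / E}, hence \eqn{\eta = E\,\tau_{channel}}.
#'
#' @param tau_channel Channel relaxation time (s), > 0.
#' @param E Apparent Young's modulus (Pa), > 0.
#' @return Apparent viscosity (Pa·s).
#' @export
apparent_viscosity <- function(tau_channel, E) {
  if (!is.finite(tau_channel) || tau_channel <= 0 || !is.finite(E) || E <= 0)
    stop("tau_channel and E must be positive")
  E * tau_channel
}

#' Shear-thinning buffer viscosity model
#'
#' Power-law viscosity \eqn{\eta(\dot\gamma) = K(\dot\gamma/\dot\gamma_0)
#' ^{n-1}} of the methylcellulose measurement buffers. Presets:
#' `buffer_viscosity_model("mc06")` for PBS with 0.6% (w/v) methylcellulose
#' (K = 0.16 Pa·s, n = 0.74) and `"mc10"` for 1% (K = 0.60 Pa·s, n = 0.64),
#' both with reference shear rate 1/s.
#'
#' @param K Consistency coefficient (Pa·s), or a preset name.
#' @param n Flow behavior index, 0 < n <= 1.
#' @param gamma_dot_0 Reference shear rate (1/s), default 1.
#' @return An object of class `buffer_viscosity_model`.
#' @export
buffer_viscosity_model <- function(K, n = NULL, gamma_dot_0 = 1) {
  if (is.character(K)) {
    preset <- match.arg(K, c("mc06", "mc10"))
    K <- c(mc06 = 0.16, mc10 = 0.60)[[preset]]
    n <- c(mc06 = 0.74, mc10 = 0.64)[[preset]]
  }
  stopifnot(K > 0, n > 0, n <= 1, gamma_dot_0 > 0)
  structure(list(K = K, n = n, gamma_dot_0 = gamma_dot_0),
            class = "buffer_viscosity_model")
}

#' Buffer viscosity at a given shear rate
#'
#' @param gamma_dot Shear rate (1/s), > 0.
#' @param model A [buffer_viscosity_model].
#' @return Viscosity (Pa·s); strictly decreasing in `gamma_dot` for n < 1.
#' @examples
#' buffer_viscosity(1, buffer_viscosity_model("mc06")) # 0.16 Pa s
#' @export
buffer_viscosity <- function(gamma_dot, model) {
  stopifnot(inherits(model, "buffer_viscosity_model"))
  if (any(gamma_dot <= 0)) stop("gamma_dot must be positive")
  model$K * (gamma_dot / model$gamma_dot_0)^(model$n - 1)
}

#' Power-law (soft glassy) creep fit of the channel trace
#'
#' Fits the creep compliance \eqn{J(t) = \frac{1}{E}(t/t_0)^\beta} to the
#' channel deformation trace. The cellular strain is approximated by scaling
#' the normalized deformation to the estimated 10% peak surface displacement
#' (`strain_scale`), and \eqn{J(t) = \varepsilon(t)/\sigma_{channel}}. The
#' RMSE (in compliance and in deformation units) allows model comparison
#' against the exponential Kelvin-Voigt fit on the same segment.
#'
#' @param t Times (s) from the start of the channel segment; the first
#'   sample may be 0 and is dropped from the fit.
#' @param d Channel deformation trace, same length; not all zero.
#' @param sigma_channel Channel stress (Pa).
#' @param strain_scale Peak strain estimate mapping deformation to strain
#'   (default 0.1).
#' @param t0 Reference time (s), default 1.
#' @return An object of class `power_law_result`: `E_pl` (Pa), `beta`,
#'   `t0`, `rmse` (compliance units), `rmse_d` (deformation units),
#'   `sigma_channel`, `strain_scale`, `fitted_d`.
#' @export
powerlaw_fit <- function(t, d, sigma_channel, strain_scale = 0.1, t0 = 1) {
  stopifnot(length(t) == length(d), sigma_channel > 0, strain_scale > 0,
            t0 > 0)
  if (all(d == 0)) stop("fit error: all-zero deformation trace")
  scale <- strain_scale / max(d)
  eps <- d * scale
  J <- eps / sigma_channel
  use <- t > 0
  if (sum(use & J > 0) < 3) stop("fit error: too few positive samples")
  lmfit <- stats::lm(log(J[use & J > 0]) ~ log(t[use & J > 0] / t0))
  start <- list(logE = -unname(stats::coef(lmfit)[1]),
                beta = unname(stats::coef(lmfit)[2]))
  ## a numerically zero start stalls the finite-difference gradient in beta
  if (abs(start$beta) < 1e-4) start$beta <- 1e-2
  fit <- minpack.lm::nlsLM(J ~ exp(-logE) * (tt / t0)^beta,
                           data = list(J = J[use], tt = t[use], t0 = t0),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  E_pl <- exp(unname(stats::coef(fit)["logE"]))
  beta <- unname(stats::coef(fit)["beta"])
  Jfit <- rep(0, length(t))
  Jfit[use] <- stats::fitted(fit)
  rmse <- sqrt(mean((J - Jfit)^2))
  structure(list(E_pl = E_pl, beta = beta, t0 = t0, rmse = rmse,
                 rmse_d = rmse * sigma_channel / scale,
                 sigma_channel = sigma_channel, strain_scale = strain_scale,
                 fitted_d = Jfit * sigma_channel / scale),
            class = "power_law_result")
}

#' @export
print.power_law_result <- function(x, ...) {
  cat(sprintf("power_law_result: E = %.4g Pa, beta = %.3f, rmse(J) = %.3g\n",
              x$E_pl, x$beta, x$rmse))
  invisible(x)
}

#' Log-normal population fit with 3-sigma outlier exclusion
#'
#' Fits a log-normal distribution to a positive-valued population
#' observable: log-transform, estimate (mu, sigma), exclude points outside
#' mu ± `ci_sigma`·sigma in log space, and refit once on the retained
#' points.
#'
#' @param values Positive observations, at least 20.
#' @param ci_sigma Outlier window in units of sigma (default 3).
#' @return An object of class `population_stats`: `log_mu`, `log_sigma`,
#'   `n_total`, `n_outliers`, `ci_sigma`, `kept` (logical vector).
#' @export
population_fit <- function(values, ci_sigma = 3) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("population_fit needs finite positive values")
  if (length(values) < 20) stop("population_fit needs at least 20 values")
  lx <- log(values)
  mu <- mean(lx); sig <- stats::sd(lx)
  if (sig == 0) stop("degenerate population: all values identical")
  kept <- abs(lx - mu) <= ci_sigma * sig
  mu2 <- mean(lx[kept]); sig2 <- stats::sd(lx[kept])
  if (!is.finite(sig2) || sig2 == 0)
    stop("degenerate population after outlier exclusion")
  structure(list(log_mu = mu2, log_sigma = sig2, n_total = length(values),
                 n_outliers = sum(!kept), ci_sigma = ci_sigma, kept = kept),
            class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(paste0("population_stats: log-normal mu = %.4g, sigma = %.4g ",
                     "(%d/%d kept, %d outliers beyond %g sigma)\n"),
              x$log_mu, x$log_sigma, x$n_total - x$n_outliers, x$n_total,
              x$n_outliers, x$ci_sigma))
  invisible(x)
}
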