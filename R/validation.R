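## Ground-truth parameter recovery studies.
##
## The simulator knows (E, eta, tau); the study runs the full analysis on
## simulated cells and compares. Because a single binarized transit carries
## irreducible sub-pixel contour noise, the study follows the instrument's
## own logic and reports population medians over several cells; velocity and
## entry phase are jittered slightly, as in a real cohort, which also
## decorrelates the sub-pixel sampling patterns across cells.
## Sampling design (fixed a priori): the transit spans ~6 relaxation times
## (velocity capped at the 24 cm/s a cell can reach) so the creep plateau is
## well constrained, and the frame rate is 8 frames per relaxation time,
## clamped to [2000, 20000] fps.

#' Parameter recovery study for one (E, eta) condition
#'
#' Simulates `n_cells` cells with the given ground-truth Kelvin-Voigt
#' parameters, runs the analysis chain (optionally through rendered binary
#' frames and the tracking stage) and summarizes recovered apparent Young's
#' modulus, viscosity and channel relaxation time as population medians.
#'
#' @param E_pa,eta_pas Ground-truth modulus (Pa) and viscosity (Pa·s).
#' @param seed Base RNG seed; cell i uses `seed + i`.
#' @param n_cells Number of cells; default balances the total frame count
#'   across conditions (`frames_budget`), at least 2, at most 24.
#' @param noise_sd Radial contour noise in µm (see [synthetic_cell_spec()]).
#' @param render If `TRUE` (default) analyse rendered binary frames through
#'   tracking and contour extraction; if `FALSE` analyse the simulated
#'   contours directly.
#' @param frames_budget Approximate total frames per condition used to pick
#'   `n_cells` (default 600).
#' @param transit_tau Channel transit length in units of the relaxation
#'   time (default 6).
#' @param ... Further arguments to [synthetic_cell_spec()].
#' @return An object of class `recovery_study`: `cells` (per-cell results),
#'   `truth`, and `summary` with median recovered values and relative
#'   errors.
#' @export
recovery_study <- function(E_pa, eta_pas, seed = 1L, n_cells = NULL,
                           noise_sd = 0, render = TRUE, frames_budget = 600,
                           transit_tau = 6, ...) {
  stopifnot(E_pa > 0, eta_pas > 0)
  tau <- eta_pas / E_pa
  v <- min(300 / (transit_tau * tau), 240000)
  fps <- min(max(8 / tau, 2000), 20000)
  npc <- ceiling(335 / v * fps)
  if (is.null(n_cells))
    n_cells <- max(2, min(24, ceiling(frames_budget / npc)))
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    jit <- .with_seed(1000L * as.integer(seed) + i, list(
      v = stats::runif(1, -0.02, 0.02), phase = stats::runif(1, 0, 0.34)))
    spec <- synthetic_cell_spec(E_true = E_pa, eta_true = eta_pas,
                                velocity_um_s = v * (1 + jit$v), fps = fps,
                                approach_um = 35 + jit$phase,
                                noise_sd = noise_sd,
                                seed = as.integer(seed) + i, ...)
    cfg <- channel_config(fps = spec$fps,
                          inlet_x_px = spec$approach_um / spec$pixel_size_um,
                          calibration_table = spec$calibration,
                          channel_length_um = spec$channel_length_um)
    gt <- simulate_trace(spec)
    res <- if (render) {
      analyze_stream(render_frames(gt), cfg)
    } else {
      dtr <- decompose_trace(list(contours = gt$contours, z_um = gt$z_um,
                                  t_s = gt$times, cell_id = i))
      analyze_trace(dtr, cfg)
    }
    if (nrow(res) == 1) {
      res$cell_id <- i
      rows[[i]] <- res
    }
  }
  cells <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ok <- !is.na(cells$E_pa)
  med <- function(x) stats::median(x, na.rm = TRUE)
  summary <- list(
    n_cells = n_cells, n_recovered = sum(ok),
    E_median_pa = med(cells$E_pa),
    eta_median_pas = med(cells$eta_pas),
    tau_median_s = med(cells$tau_channel_ms) / 1000,
    E_rel_err = med(cells$E_pa) / E_pa - 1,
    eta_rel_err = med(cells$eta_pas) / eta_pas - 1,
    tau_rel_err = med(cells$tau_channel_ms) / 1000 / tau - 1)
  structure(list(cells = cells, summary = summary,
                 truth = list(E_pa = E_pa, eta_pas = eta_pas, tau_s = tau),
                 render = render, noise_sd = noise_sd),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("recovery_study (%s, noise %.3g µm): %d/%d cells\n",
                     "  E   %.4g Pa (true %.4g, %+.2f%%)\n",
                     "  eta %.4g Pa s (true %.4g, %+.2f%%)\n",
                     "  tau %.4g ms (true %.4g, %+.2f%%)\n"),
              if (x$render) "rendered frames" else "contour path",
              x$noise_sd, s$n_recovered, s$n_cells,
              s$E_median_pa, x$truth$E_pa, 100 * s$E_rel_err,
              s$eta_median_pas, x$truth$eta_pas, 100 * s$eta_rel_err,
              1000 * s$tau_median_s, 1000 * x$truth$tau_s,
              100 * s$tau_rel_err))
  invisible(x)
}
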