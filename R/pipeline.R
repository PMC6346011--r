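## End-to-end analysis: frames -> tracks -> parity traces -> per-cell
## viscoelastic parameters.

#' Viscoelastic analysis of one decomposed trace
#'
#' Fits the inlet relaxation (even parity, from the peak to
#' `inlet_fit_frac` of the channel length) and the channel creep (odd
#' parity, from channel entry to the outlet), extracts the peak
#' deformations, converts the channel plateau into an apparent Young's
#' modulus through the calibration table and the channel time constant into
#' an apparent viscosity via the Kelvin-Voigt relation \eqn{\eta = E\,\tau}.
#' Cells failing the \eqn{r^2} gate keep their trace values but get `NA`
#' material parameters and an explanatory flag.
#'
#' @param trace A `deformation_trace` from [decompose_trace()].
#' @param cfg A [channel_config].
#' @return One-row data frame: `cell_id`, `n_frames`, `A_um2`, `a0_um`,
#'   `d_hat_inlet`, `d_hat_channel`, `tau_inlet_ms`, `tau_channel_ms`,
#'   `r2_inlet`, `r2_channel`, `E_pa`, `eta_pas`, `flags`
#'   (semicolon-separated).
#' @export
analyze_trace <- function(trace, cfg = channel_config()) {
  stopifnot(inherits(cfg, "channel_config"))
  L <- cfg$channel_length_um
  flags <- character(0)

  peaks <- extract_peaks(trace, channel_length_um = L,
                         inlet_window_frac = cfg$inlet_window_frac,
                         r2_cutoff = cfg$r2_cutoff)
  flags <- c(flags, peaks$flags)
  chfit <- peaks$channel_fit

  ## inlet relaxation: from the even-parity maximum to inlet_fit_frac * L
  win <- which(trace$z_um <= cfg$inlet_window_frac * L)
  ipk <- win[which.max(trace$d_even[win])]
  iend <- max(which(trace$z_um <= cfg$inlet_fit_frac * L))
  infit <- if (iend - ipk + 1 >= 5)
    fit_exponential(trace$t_s[ipk:iend], trace$d_even[ipk:iend],
                    segment = "inlet", r2_cutoff = cfg$r2_cutoff)
  else NULL
  if (is.null(infit)) flags <- c(flags, "inlet_segment_too_short")
  else if (!infit$accepted) flags <- c(flags, "r2_inlet_gate")
  if (!is.null(infit) && isTRUE(infit$tau_at_bound))
    flags <- c(flags, "tau_inlet_at_bound")

  inch <- trace$z_um >= 0 & trace$z_um <= L
  a0 <- mean(trace$a0_um[inch])
  A <- mean(trace$A_um2[inch])

  E <- eta <- NA_real_
  if (is.null(chfit) || !isTRUE(chfit$accepted)) {
    flags <- c(flags, if (is.null(chfit)) "constant_shape_gate"
                      else "r2_channel_gate")
  } else if (!is.finite(peaks$d_hat_channel) || peaks$d_hat_channel <= 0) {
    flags <- c(flags, "nonpositive_d_hat_channel")
  } else {
    E <- tryCatch(young_modulus(peaks$d_hat_channel, a0, cfg),
                  error = function(e) {
                    flags <<- c(flags, "calibration_out_of_range")
                    NA_real_
                  })
    if (is.finite(E)) eta <- apparent_viscosity(chfit$tau, E)
    if (isTRUE(chfit$tau_at_bound)) flags <- c(flags, "tau_channel_at_bound")
  }
  data.frame(cell_id = trace$cell_id[1], n_frames = nrow(trace), A_um2 = A,
             a0_um = a0, d_hat_inlet = peaks$d_hat_inlet,
             d_hat_channel = peaks$d_hat_channel,
             tau_inlet_ms = if (!is.null(infit)) 1000 * infit$tau else NA_real_,
             tau_channel_ms = if (!is.null(chfit)) 1000 * chfit$tau else NA_real_,
             r2_inlet = if (!is.null(infit)) infit$r2 else NA_real_,
             r2_channel = if (!is.null(chfit)) chfit$r2 else NA_real_,
             E_pa = E, eta_pas = eta,
             flags = paste(unique(flags), collapse = ";"))
}

#' Full pipeline: frame stream to per-cell results
#'
#' Tracks all cells in a stream, decomposes each track into parity
#' deformation traces and runs the viscoelastic analysis. Per-cell
#' rejections (tracking collisions, too-short traces, reconstruction
#' failures, fit gates) are tallied in the `"rejections"` attribute of the
#' result.
#'
#' @param stream A [frame_stream].
#' @param cfg A [channel_config]; its `inlet_x_px`, `pixel_size_um` and
#'   gates are used throughout.
#' @param keep_traces If `TRUE`, attach the list of decomposed traces as
#'   attribute `"traces"`.
#' @return Data frame with one row per analysed cell (see
#'   [analyze_trace()]).
#' @export
analyze_stream <- function(stream, cfg = channel_config(),
                           keep_traces = FALSE) {
  stopifnot(inherits(stream, "frame_stream"))
  tracks <- track_cells(stream, inlet_x_px = cfg$inlet_x_px)
  rejects <- attr(tracks, "rejections")
  if (is.null(rejects))
    rejects <- data.frame(cell_id = integer(), reason = character())
  rows <- list()
  traces <- list()
  for (tr in tracks) {
    dtr <- tryCatch(decompose_trace(tr, pixel_size_um = stream$pixel_size_um),
                    error = function(e) conditionMessage(e))
    if (is.character(dtr)) {
      rejects[nrow(rejects) + 1L, ] <- list(tr$cell_id, dtr)
      next
    }
    row <- tryCatch(analyze_trace(dtr, cfg),
                    error = function(e) conditionMessage(e))
    if (is.character(row)) {
      rejects[nrow(rejects) + 1L, ] <- list(tr$cell_id, row)
      next
    }
    rows[[length(rows) + 1L]] <- row
    if (keep_traces) traces[[as.character(tr$cell_id)]] <- dtr
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_results()
  attr(out, "rejections") <- rejects
  if (keep_traces) attr(out, "traces") <- traces
  out
}

.empty_results <- function() {
  data.frame(cell_id = integer(), n_frames = integer(), A_um2 = numeric(),
             a0_um = numeric(), d_hat_inlet = numeric(),
             d_hat_channel = numeric(), tau_inlet_ms = numeric(),
             tau_channel_ms = numeric(), r2_inlet = numeric(),
             r2_channel = numeric(), E_pa = numeric(), eta_pas = numeric(),
             flags = character())
}
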