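## Measurement configuration.

#' Channel / measurement configuration
#'
#' Bundles the channel geometry, the FEM-derived mean surface stress and
#' shear rate for a given (channel, buffer, flow rate) condition, the buffer
#' viscosity model, the calibration table and the analysis gates.
#'
#' Presets via [channel_config_preset()]:
#' \describe{
#'   \item{`"cells_30um_8nls"`}{30 µm channel, 8 nl/s, 1% methylcellulose:
#'     mean stress 142 Pa, mean shear rate 5100 1/s.}
#'   \item{`"leukocytes_20um_4nls"`}{20 µm channel, 4 nl/s, 1%
#'     methylcellulose: mean stress 216 Pa, shear rate 9700 1/s.}
#'   \item{`"erythrocytes_20um_4nls"`}{20 µm channel, 4 nl/s, 0.6%
#'     methylcellulose: mean stress 128 Pa, shear rate 8600 1/s.}
#' }
#'
#' @param cross_section_um Channel cross-section side (µm), 20 or 30.
#' @param channel_length_um Channel length (µm), default 300.
#' @param flow_rate_nl_s Flow rate (nl/s).
#' @param mean_surface_stress_pa Mean stress on the cell surface
#'   \eqn{\sigma_{channel}} (Pa), an FEM-derived constant.
#' @param mean_shear_rate_s Mean shear rate (1/s), FEM-derived.
#' @param buffer A [buffer_viscosity_model] or preset name (`"mc06"`,
#'   `"mc10"`).
#' @param calibration_table A [calibration_table]; default toy saturating
#'   table at `mean_surface_stress_pa`.
#' @param r2_cutoff Creep-fit acceptance threshold (default 0.6).
#' @param inlet_fit_frac Inlet fit segment extends to this fraction of the
#'   channel length past the inlet (default 0.4).
#' @param inlet_window_frac Window for the even-parity peak search
#'   (default 0.3).
#' @param pixel_size_um,fps,inlet_x_px Acquisition geometry.
#' @param strain_scale Peak-strain estimate for the power-law fit
#'   (default 0.1).
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(cross_section_um = 30, channel_length_um = 300,
                           flow_rate_nl_s = 8, mean_surface_stress_pa = 142,
                           mean_shear_rate_s = 5100, buffer = "mc10",
                           calibration_table = NULL, r2_cutoff = 0.6,
                           inlet_fit_frac = 0.4, inlet_window_frac = 0.3,
                           pixel_size_um = 0.34, fps = 2000,
                           inlet_x_px = 103, strain_scale = 0.1) {
  stopifnot(cross_section_um > 0, channel_length_um > 0, flow_rate_nl_s > 0,
            mean_surface_stress_pa > 0, mean_shear_rate_s > 0,
            r2_cutoff <= 1, pixel_size_um > 0, fps > 0, inlet_x_px >= 0,
            strain_scale > 0)
  if (is.character(buffer)) buffer <- buffer_viscosity_model(buffer)
  if (is.null(calibration_table))
    calibration_table <- toy_calibration_table("saturating",
                                               sigma_pa = mean_surface_stress_pa)
  structure(list(cross_section_um = cross_section_um,
                 channel_length_um = channel_length_um,
                 flow_rate_nl_s = flow_rate_nl_s,
                 mean_surface_stress_pa = mean_surface_stress_pa,
                 mean_shear_rate_s = mean_shear_rate_s, buffer = buffer,
                 calibration_table = calibration_table,
                 r2_cutoff = r2_cutoff, inlet_fit_frac = inlet_fit_frac,
                 inlet_window_frac = inlet_window_frac,
                 pixel_size_um = pixel_size_um, fps = fps,
                 inlet_x_px = inlet_x_px, strain_scale = strain_scale),
            class = "channel_config")
}

#' @rdname channel_config
#' @param preset Preset name.
#' @param ... Overrides passed to [channel_config()].
#' @export
channel_config_preset <- function(preset = c("cells_30um_8nls",
                                             "leukocytes_20um_4nls",
                                             "erythrocytes_20um_4nls"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    cells_30um_8nls = list(cross_section_um = 30, flow_rate_nl_s = 8,
                           mean_surface_stress_pa = 142,
                           mean_shear_rate_s = 5100, buffer = "mc10"),
    leukocytes_20um_4nls = list(cross_section_um = 20, flow_rate_nl_s = 4,
                                mean_surface_stress_pa = 216,
                                mean_shear_rate_s = 9700, buffer = "mc10"),
    erythrocytes_20um_4nls = list(cross_section_um = 20, flow_rate_nl_s = 4,
                                  mean_surface_stress_pa = 128,
                                  mean_shear_rate_s = 8600, buffer = "mc06"))
  do.call(channel_config, utils::modifyList(args, list(...)))
}

#' Read / write a run configuration as YAML
#'
#' The YAML round trip (`read_run_config(write_run_config(cfg, f))`) is an
#' identity on the configuration values. The calibration table is stored
#' inline.
#'
#' @param cfg A [channel_config].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [channel_config].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "channel_config"))
  lst <- unclass(cfg)
  lst$buffer <- unclass(cfg$buffer)
  lst$calibration_table <- list(
    diameters_um = cfg$calibration_table$diameters_um,
    deformations = cfg$calibration_table$deformations,
    E_pa = as.vector(cfg$calibration_table$E_pa))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ct <- lst$calibration_table
  lst$calibration_table <- calibration_table(
    ct$diameters_um, ct$deformations,
    matrix(ct$E_pa, nrow = length(ct$diameters_um)))
  lst$buffer <- buffer_viscosity_model(lst$buffer$K, lst$buffer$n,
                                       lst$buffer$gamma_dot_0)
  do.call(channel_config, lst)
}
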