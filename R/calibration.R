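## Deformation -> Young's modulus calibration.
##
## The mapping from steady-state channel deformation to an apparent Young's
## modulus depends on the full hydrodynamic stress distribution around the
## cell and is supplied as a pluggable look-up table (diameter x deformation
## -> E) computed offline for a fixed channel, buffer and flow rate. The
## package ships two documented toy generators for testing: a linear-elastic
## one (E = sigma * gain / d_hat) and a saturating one
## (d_hat = c * sqrt(sigma / E)) that mimics the shape saturation of the real
## stress-deformation response.

#' Construct a calibration table
#'
#' @param diameters_um Increasing vector of cell diameters (µm).
#' @param deformations Increasing vector of channel deformations
#'   (dimensionless).
#' @param E_pa Matrix of Young's moduli, `length(diameters_um)` rows by
#'   `length(deformations)` columns; must be strictly decreasing along each
#'   row (larger deformation at fixed size means a softer cell).
#' @return An object of class `calibration_table`.
#' @export
calibration_table <- function(diameters_um, deformations, E_pa) {
  stopifnot(is.matrix(E_pa),
            nrow(E_pa) == length(diameters_um),
            ncol(E_pa) == length(deformations),
            !is.unsorted(diameters_um, strictly = TRUE),
            !is.unsorted(deformations, strictly = TRUE),
            all(E_pa > 0))
  if (any(t(apply(E_pa, 1, diff)) >= 0))
    stop("calibration table must be strictly decreasing in deformation")
  structure(list(diameters_um = diameters_um, deformations = deformations,
                 E_pa = E_pa), class = "calibration_table")
}

#' Toy calibration tables for tests and simulation studies
#'
#' `"linear"` implements the linear-elastic toy model
#' \eqn{E = \sigma \cdot g / \hat d} with gain `g`; `"saturating"` implements
#' \eqn{\hat d = c\sqrt{\sigma/E}}, i.e. \eqn{E = \sigma (c/\hat d)^2},
#' whose concave deformation response mimics the geometric saturation of the
#' real hydrodynamic model. Both are independent of cell diameter.
#'
#' @param kind `"linear"` or `"saturating"`.
#' @param sigma_pa Channel stress the table is computed for (Pa).
#' @param gain Linear toy gain (default 0.1).
#' @param c_sat Saturating toy coefficient (default 0.030).
#' @param diameters_um,deformations Grid axes.
#' @return A [calibration_table].
#' @export
toy_calibration_table <- function(kind = c("saturating", "linear"),
                                  sigma_pa = 142, gain = 0.1, c_sat = 0.030,
                                  diameters_um = seq(8, 30, by = 2),
                                  deformations = exp(seq(log(0.002), log(0.3),
                                                         length.out = 90))) {
  kind <- match.arg(kind)
  E_row <- switch(kind,
                  linear = sigma_pa * gain / deformations,
                  saturating = sigma_pa * (c_sat / deformations)^2)
  calibration_table(diameters_um, deformations,
                    matrix(E_row, nrow = length(diameters_um),
                           ncol = length(deformations), byrow = TRUE))
}

#' Apparent Young's modulus from the calibration table
#'
#' Bilinear interpolation of the calibration table at a measured channel
#' deformation and cell diameter.
#'
#' @param d_hat_channel Steady-state channel deformation (dimensionless, > 0).
#' @param diameter_um Cell diameter in µm (the shape-mode size coefficient
#'   `a0` equals the mean diameter).
#' @param table A [calibration_table], or a [channel_config] carrying one.
#' @return Apparent Young's modulus in Pa.
#' @export
young_modulus <- function(d_hat_channel, diameter_um, table) {
  if (inherits(table, "channel_config")) table <- table$calibration_table
  stopifnot(inherits(table, "calibration_table"))
  if (!is.finite(d_hat_channel) || d_hat_channel <= 0)
    stop("d_hat_channel must be positive")
  dr <- range(table$deformations); sr <- range(table$diameters_um)
  if (d_hat_channel < dr[1] || d_hat_channel > dr[2] ||
      diameter_um < sr[1] || diameter_um > sr[2])
    stop(sprintf(paste0("query (deformation = %.4g, diameter = %.4g µm) outside",
                        " calibration hull: deformation [%.4g, %.4g],",
                        " diameter [%.4g, %.4g] µm"),
                 d_hat_channel, diameter_um, dr[1], dr[2], sr[1], sr[2]))
  pracma::interp2(x = table$deformations, y = table$diameters_um,
                  Z = table$E_pa, xp = d_hat_channel, yp = diameter_um,
                  method = "linear")
}

#' Forward calibration: expected channel deformation for a given modulus
#'
#' Inverts the calibration table along its deformation axis (the table is
#' strictly monotone), interpolating between neighbouring diameter rows.
#' Used by the simulator to translate a ground-truth modulus into the
#' steady-state deformation it should produce.
#'
#' @param E_pa Apparent Young's modulus (Pa).
#' @inheritParams young_modulus
#' @return Channel deformation (dimensionless).
#' @export
calibration_deformation <- function(E_pa, diameter_um, table) {
  if (inherits(table, "channel_config")) table <- table$calibration_table
  stopifnot(inherits(table, "calibration_table"), E_pa > 0)
  dm <- table$diameters_um
  i <- findInterval(diameter_um, dm, all.inside = TRUE)
  w <- if (dm[i + 1] == dm[i]) 0 else (diameter_um - dm[i]) / (dm[i + 1] - dm[i])
  invert_row <- function(row) {
    if (E_pa > max(row) || E_pa < min(row))
      stop(sprintf("E = %.4g Pa outside calibration range [%.4g, %.4g] Pa",
                   E_pa, min(row), max(row)))
    stats::approx(row, table$deformations, xout = E_pa)$y
  }
  (1 - w) * invert_row(table$E_pa[i, ]) + w * invert_row(table$E_pa[i + 1, ])
}

#' Read / write a calibration table as CSV
#'
#' Long format with columns `cell_diameter_um`, `deformation`, `E_pa` over a
#' complete grid.
#'
#' @param path CSV file path.
#' @return `read_calibration_table` returns a [calibration_table];
#'   `write_calibration_table` returns `path` invisibly.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_diameter_um", "deformation", "E_pa")
  if (!all(need %in% names(df)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  diameters <- sort(unique(df$cell_diameter_um))
  deformations <- sort(unique(df$deformation))
  if (nrow(df) != length(diameters) * length(deformations))
    stop("calibration CSV must cover a complete diameter x deformation grid")
  E <- matrix(NA_real_, length(diameters), length(deformations))
  E[cbind(match(df$cell_diameter_um, diameters),
          match(df$deformation, deformations))] <- df$E_pa
  calibration_table(diameters, deformations, E)
}

#' @rdname read_calibration_table
#' @param table A [calibration_table].
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  df <- expand.grid(deformation = table$deformations,
                    cell_diameter_um = table$diameters_um)
  df$E_pa <- as.vector(t(table$E_pa))
  utils::write.csv(df[, c("cell_diameter_um", "deformation", "E_pa")],
                   path, row.names = FALSE)
  invisible(path)
}
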