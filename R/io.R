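## Formats: TIFF / PNG frame input, tidy CSV + JSON manifest output, and the
## simulator's on-disk layout (multi-page TIFF + JSON ground-truth sidecar +
## manifest CSV).

#' Read an image sequence into a frame stream
#'
#' Accepts a multi-page TIFF file or a directory of numbered PNG frames.
#' Acquisition metadata (frame rate, pixel size) must be supplied either as
#' arguments or through a JSON sidecar (`<stem>.json` next to the TIFF, or
#' `metadata.json` inside the PNG directory) with fields `fps` and
#' `pixel_size_um`; missing metadata is an error.
#'
#' @param path TIFF file or PNG directory.
#' @param fps,pixel_size_um Acquisition metadata; override any sidecar.
#' @return A [frame_stream].
#' @export
read_frames <- function(path, fps = NULL, pixel_size_um = NULL) {
  meta <- list(fps = fps, pixel_size_um = pixel_size_um)
  if (dir.exists(path)) {
    sidecar <- file.path(path, "metadata.json")
    files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (!length(files)) stop("no PNG frames found in ", path)
    nums <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
    if (any(is.na(nums))) stop("PNG frames must carry a frame number")
    files <- files[order(nums)]
    nums <- sort(nums)
    gap <- setdiff(seq(nums[1], nums[length(nums)]), nums)
    if (length(gap))
      stop("frame numbering has gaps; first missing index: ", gap[1])
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG directories requires the 'png' package")
    frames <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a
    })
  } else if (file.exists(path)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    frames <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(frames)) frames <- list(frames)
  } else stop("no such file or directory: ", path)
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta$fps <- meta$fps %||% sc$fps
    meta$pixel_size_um <- meta$pixel_size_um %||% sc$pixel_size_um
  }
  if (is.null(meta$fps) || is.null(meta$pixel_size_um))
    stop("fps and pixel_size_um must be given (argument or JSON sidecar)")
  frame_stream(frames, fps = meta$fps, pixel_size_um = meta$pixel_size_um)
}

#' Write a frame stream as multi-page TIFF with JSON sidecar
#'
#' @param stream A [frame_stream].
#' @param path Output TIFF path; the sidecar goes to `<stem>.json`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stream, path) {
  stopifnot(inherits(stream, "frame_stream"))
  tiff::writeTIFF(stream$frames, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(fps = stream$fps,
                            pixel_size_um = stream$pixel_size_um,
                            n_frames = length(stream$frames),
                            frame_shape = stream$frame_shape),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-cell results, traces and a run manifest
#'
#' Writes `results.csv` (one row per cell), a `traces/` directory with one
#' tidy CSV per cell (columns `cell_id`, `t_s`, `z_um`, `a0`..`a9`,
#' `b1`..`b9`, `d_raw`, `d_even`, `d_odd`), the rejection tally, the run
#' configuration, and `manifest.json` carrying the configuration hash and
#' package version. Output is byte-stable for identical inputs.
#'
#' @param results Result data frame from [analyze_stream()].
#' @param traces Optional named list of `deformation_trace` objects.
#' @param dir Output directory (created if needed).
#' @param cfg The [channel_config] used for the run.
#' @return The manifest, invisibly.
#' @export
write_results <- function(results, traces = NULL, dir, cfg = NULL) {
  need <- names(.empty_results())
  if (!all(need %in% names(results)))
    stop("results violate the schema; missing fields: ",
         paste(setdiff(need, names(results)), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(dir, "results.csv"), row.names = FALSE)
  rej <- attr(results, "rejections")
  if (!is.null(rej))
    utils::write.csv(rej, file.path(dir, "rejections.csv"), row.names = FALSE)
  trace_files <- character(0)
  if (!is.null(traces) && length(traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(traces)) {
      f <- file.path(tdir, sprintf("cell_%s.csv", nm))
      utils::write.csv(as.data.frame(traces[[nm]]), f, row.names = FALSE)
      trace_files <- c(trace_files, basename(f))
    }
  }
  cfg_hash <- NA_character_
  if (!is.null(cfg)) {
    cfg_path <- file.path(dir, "config.yaml")
    write_run_config(cfg, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  }
  manifest <- list(package = "dcrheo",
                   version = as.character(utils::packageVersion("dcrheo")),
                   n_cells = nrow(results),
                   n_rejected = if (is.null(rej)) 0L else nrow(rej),
                   config_md5 = cfg_hash,
                   files = c("results.csv",
                             if (!is.null(rej)) "rejections.csv",
                             if (!is.null(cfg)) "config.yaml",
                             file.path("traces", trace_files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated cell to disk
#'
#' Renders the trace and writes frames as multi-page TIFF, the ground truth
#' as a JSON sidecar, and appends a row to the cohort manifest CSV.
#'
#' @param truth A `ground_truth_trace` from [simulate_trace()].
#' @param dir Output directory.
#' @param cell_id Identifier used in file names.
#' @return Paths of the files written, invisibly.
#' @export
write_simulation <- function(truth, dir, cell_id = 1L) {
  stopifnot(inherits(truth, "ground_truth_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("cell_%04d", cell_id))
  stream <- render_frames(truth)
  tiff::writeTIFF(stream$frames, paste0(stem, ".tif"), bits.per.sample = 8L,
                  compression = "none")
  gt <- list(cell_id = cell_id,
             spec = unclass(truth$spec)[setdiff(names(truth$spec),
                                                "calibration")],
             tau_true = truth$tau_true,
             d_hat_inlet_true = truth$d_hat_inlet_true,
             d_hat_channel_true = truth$d_hat_channel_true,
             times = truth$times, z_um = truth$z_um,
             d_even_true = truth$d_even_true, d_odd_true = truth$d_odd_true)
  jsonlite::write_json(gt, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  manifest <- file.path(dir, "manifest.csv")
  row <- data.frame(cell_id = cell_id,
                    tif = basename(paste0(stem, ".tif")),
                    json = basename(paste0(stem, ".json")),
                    radius_um = truth$spec$radius_um,
                    E_true = truth$spec$E_true,
                    eta_true = truth$spec$eta_true,
                    tau_true = truth$tau_true,
                    noise_sd = truth$spec$noise_sd,
                    seed = truth$spec$seed,
                    n_frames = length(truth$times))
  utils::write.table(row, manifest, sep = ",", row.names = FALSE,
                     col.names = !file.exists(manifest),
                     append = file.exists(manifest))
  invisible(c(paste0(stem, ".tif"), paste0(stem, ".json"), manifest))
}

#' Export a decomposed trace as tidy CSV
#'
#' @param trace A `deformation_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
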