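## Contour extraction and cell tracking.
##
## Frames are binarized (Otsu by default), connected components are labeled,
## and each component above a minimum area is replaced by the convex hull of
## its boundary pixels. Individual cells are followed along the channel with
## a moving 250 x 80 px sub-ROI: whenever the cell's center-of-mass exceeds
## 70% of the ROI length the ROI advances by 48% of its length, so both slow
## and fast cells stay inside one ROI during their whole passage.

#' Frame stream container
#'
#' @param frames List of single-channel numeric matrices (`ny x nx`), row =
#'   y, column = x (x is the flow axis; 0-based pixel coordinates are
#'   `col - 1`, `row - 1`).
#' @param fps Frame rate (frames/s).
#' @param pixel_size_um Pixel pitch (µm/px).
#' @return An object of class `frame_stream`.
#' @export
frame_stream <- function(frames, fps, pixel_size_um) {
  stopifnot(is.list(frames), is.na(fps) || fps > 0, pixel_size_um > 0)
  shape <- if (length(frames)) dim(frames[[1]]) else c(0L, 0L)
  for (f in frames)
    if (!is.matrix(f) || !all(dim(f) == shape))
      stop("all frames must be matrices of identical shape")
  structure(list(frames = frames, fps = fps, pixel_size_um = pixel_size_um,
                 frame_shape = shape), class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("frame_stream: %d frames of %d x %d px, %s fps, %.3g µm/px\n",
              length(x$frames), x$frame_shape[1], x$frame_shape[2],
              format(x$fps), x$pixel_size_um))
  invisible(x)
}

#' Binarize a frame and extract convex cell contours
#'
#' Thresholds a single-channel frame, labels connected foreground components
#' and returns one counterclockwise convex-hull contour per component above
#' the minimum area. Coordinates are 0-based pixel indices (x = column along
#' the flow axis).
#'
#' @param frame Numeric matrix (`ny x nx`).
#' @param threshold `"otsu"` for a global Otsu threshold on the normalized
#'   frame, or a numeric value used as fixed threshold (foreground is
#'   `frame > threshold`).
#' @param min_area Minimum component area in px² (default 50); smaller blobs
#'   are treated as noise.
#' @param invert Set `TRUE` if cells are darker than the background.
#' @param edge_offset_px Outward radial correction applied to the
#'   boundary-pixel hull (px). Centers of boundary pixels of a binarized
#'   object sit systematically inside the true edge; for a 50%-coverage
#'   binarization the expected center-to-edge distance is a quarter pixel,
#'   hence the default 0.25 px.
#' @param frame_index,fps Optional bookkeeping copied onto the contours
#'   (timestamp is `frame_index / fps`).
#' @return List of [contour_polygon] sorted by centroid x; empty list if no
#'   component is found.
#' @export
binarize_and_trace <- function(frame, threshold = "otsu", min_area = 50,
                               invert = FALSE, frame_index = NA_integer_,
                               fps = NA_real_, edge_offset_px = 0.25) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (invert) frame <- -frame
  rng <- range(frame)
  if (rng[1] == rng[2]) return(list())
  if (identical(threshold, "otsu")) {
    norm <- (frame - rng[1]) / (rng[2] - rng[1])
    mask <- norm > .otsu_threshold(norm)
  } else {
    stopifnot(is.numeric(threshold))
    mask <- frame > threshold
  }
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask * 1)
  ts <- if (is.na(frame_index) || is.na(fps)) NA_real_ else frame_index / fps
  out <- list()
  for (l in seq_len(max(lab))) {
    m <- lab == l
    if (sum(m) < min_area) next
    ## boundary pixels: on the component but with a 4-neighbour off it
    ny <- nrow(m); nx <- ncol(m)
    up <- rbind(FALSE, m[-ny, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], FALSE)
    lf <- cbind(FALSE, m[, -nx, drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], FALSE)
    bnd <- which(m & !(up & dn & lf & rt), arr.ind = TRUE)
    if (nrow(bnd) < 3) next
    x <- bnd[, 2] - 1 # 0-based, x = flow axis
    y <- bnd[, 1] - 1
    h <- rev(grDevices::chull(x, y))
    hx <- x[h]; hy <- y[h]
    ## boundary-pixel centers sit systematically inside the object edge;
    ## dilate the hull radially by the calibrated offset
    cx <- mean(hx); cy <- mean(hy)
    rr <- sqrt((hx - cx)^2 + (hy - cy)^2)
    hx <- cx + (hx - cx) * (rr + edge_offset_px) / rr
    hy <- cy + (hy - cy) * (rr + edge_offset_px) / rr
    out[[length(out) + 1]] <- contour_polygon(hx, hy,
                                              frame_index = frame_index,
                                              timestamp = ts)
  }
  if (!length(out)) return(list())
  cx <- vapply(out, function(p) .polygon_geometry(p$x, p$y)$com[1], numeric(1))
  out[order(cx)]
}

## Otsu's threshold on a 256-bin histogram of values in [0, 1]:
## maximizes the between-class variance
.otsu_threshold <- function(v) {
  nb <- 256L
  h <- tabulate(pmin(floor(v * nb), nb - 1L) + 1L, nbins = nb)
  w1 <- cumsum(h)
  mu <- cumsum(h * (seq_len(nb) - 0.5))
  w2 <- w1[nb] - w1
  between <- (mu[nb] * w1 - mu * w1[nb])^2 / (w1 * w2)
  between[!is.finite(between)] <- -Inf
  (which.max(between) - 0.5) / nb
}

#' Track cells through a frame stream with a moving sub-ROI
#'
#' Opens a track when a cell appears in the inlet region, follows it with a
#' sub-ROI that advances by `shift * roi_length` whenever the center-of-mass
#' x exceeds `trigger * roi_length` inside the ROI (strictly greater than),
#' and closes the track when the cell leaves the field of view. A single cell
#' per ROI is enforced: tracks whose ROI captures two components are flagged
#' as collisions and excluded. Tracks with fewer than `min_points`
#' observations or without net displacement (stationary debris) are also
#' excluded; all rejections are tallied in the `"rejections"` attribute.
#'
#' @param stream A [frame_stream] in temporal order.
#' @param inlet_x_px Channel inlet position in pixels (x of z = 0).
#' @param roi_size ROI size `c(length, height)` in px, default `c(250, 80)`.
#' @param trigger ROI advance trigger as fraction of ROI length (default
#'   0.70).
#' @param shift ROI advance step as fraction of ROI length (default 0.48).
#' @param min_points Minimum observations for an analysable track (default
#'   14).
#' @param min_displacement_px Minimum net center-of-mass displacement
#'   (default 20 px) to reject stationary debris.
#' @param threshold,min_area,edge_offset_px Passed to
#'   [binarize_and_trace()].
#' @return List of `tracked_cell` objects, each with `cell_id`, `contours`
#'   (px), `com_px`, `z_um`, `t_s`, `roi_offsets`; attribute `"rejections"`
#'   is a data frame of excluded-track reasons.
#' @export
track_cells <- function(stream, inlet_x_px = 103, roi_size = c(250, 80),
                        trigger = 0.70, shift = 0.48, min_points = 14,
                        min_displacement_px = 20, threshold = "otsu",
                        min_area = 50, edge_offset_px = 0.25) {
  stopifnot(inherits(stream, "frame_stream"))
  roi_len <- roi_size[1]
  nx <- stream$frame_shape[2]
  open_limit <- inlet_x_px + 0.2 * roi_len # "appears in the inlet region"
  active <- list()
  done <- list()
  rejects <- data.frame(cell_id = integer(), reason = character())
  next_id <- 1L

  close_track <- function(tr) {
    if (!is.null(tr$flag)) {
      rejects[nrow(rejects) + 1L, ] <<- list(tr$id, tr$flag)
    } else if (length(tr$contours) < min_points) {
      rejects[nrow(rejects) + 1L, ] <<- list(tr$id, "too_few_points")
    } else if (diff(range(vapply(tr$com, `[`, numeric(1), 1))) <
               min_displacement_px) {
      rejects[nrow(rejects) + 1L, ] <<- list(tr$id, "no_net_displacement")
    } else {
      com <- do.call(rbind, tr$com)
      done[[length(done) + 1L]] <<- structure(
        list(cell_id = tr$id, contours = tr$contours, com_px = com,
             z_um = (com[, 1] - inlet_x_px) * stream$pixel_size_um,
             t_s = vapply(tr$contours, function(p) p$timestamp, numeric(1)),
             roi_offsets = tr$roi_offsets,
             pixel_size_um = stream$pixel_size_um),
        class = "tracked_cell")
    }
  }

  for (fi in seq_along(stream$frames)) {
    contours <- binarize_and_trace(stream$frames[[fi]], threshold = threshold,
                                   min_area = min_area,
                                   frame_index = fi - 1L, fps = stream$fps,
                                   edge_offset_px = edge_offset_px)
    if (length(contours)) {
      com <- t(vapply(contours, function(p) .polygon_geometry(p$x, p$y)$com,
                      numeric(2)))
    } else com <- matrix(numeric(0), 0, 2)
    claimed <- rep(FALSE, length(contours))
    keep <- logical(length(active))
    for (ti in seq_along(active)) {
      tr <- active[[ti]]
      inroi <- which(!claimed & com[, 1] >= tr$roi_x &
                       com[, 1] <= tr$roi_x + roi_len)
      if (length(inroi) == 0) {
        close_track(tr)
      } else if (length(inroi) > 1) {
        tr$flag <- "roi_collision"
        close_track(tr)
      } else {
        claimed[inroi] <- TRUE
        tr$contours[[length(tr$contours) + 1L]] <- contours[[inroi]]
        tr$com[[length(tr$com) + 1L]] <- com[inroi, ]
        while (com[inroi, 1] - tr$roi_x > trigger * roi_len &&
               tr$roi_x + roi_len < nx + shift * roi_len)
          tr$roi_x <- tr$roi_x + shift * roi_len
        tr$roi_offsets <- c(tr$roi_offsets, tr$roi_x)
        if (max(contours[[inroi]]$x) >= nx - 2) { # exiting the field of view
          close_track(tr)
        } else {
          active[[ti]] <- tr
          keep[ti] <- TRUE
        }
      }
    }
    active <- active[keep]
    for (ci in which(!claimed)) {
      if (com[ci, 1] <= open_limit) {
        tr <- list(id = next_id, roi_x = max(0, com[ci, 1] - roi_len / 2),
                   contours = contours[ci], com = list(com[ci, ]),
                   roi_offsets = numeric(0), flag = NULL)
        next_id <- next_id + 1L
        active[[length(active) + 1L]] <- tr
      }
    }
  }
  for (tr in active) close_track(tr)
  done <- done[order(vapply(done, function(t) t$cell_id, integer(1)))]
  attr(done, "rejections") <- rejects
  done
}

#' @export
print.tracked_cell <- function(x, ...) {
  cat(sprintf("tracked_cell %d: %d frames, z %.1f to %.1f µm\n", x$cell_id,
              length(x$contours), min(x$z_um), max(x$z_um)))
  invisible(x)
}
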