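#' Write an image or movie as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are scaled to the 16-bit range (the scale is recorded in the
#' sidecar together with pixel size and frame interval).
#'
#' @param x A [raster_image()] or [time_lapse()].
#' @param path Output `.tif` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_tiff_stack <- function(x, path) {
  if (inherits(x, "raster_image")) {
    frames <- list(x$intensities)
    meta <- list(pixel_size_um = x$pixel_size_um)
  } else if (inherits(x, "time_lapse")) {
    frames <- x$frames
    meta <- list(pixel_size_um = x$pixel_size_um,
                 frame_interval_s = x$frame_interval_s)
  } else stop("expected a raster_image or time_lapse", call. = FALSE)
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) 65535 / (hi - lo) else 1
  imgs <- lapply(frames, function(f) pmin(pmax((f - lo) * scale / 65535, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  meta$intensity_offset <- lo
  meta$intensity_scale <- scale
  meta$n_frames <- length(frames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image or movie written by [write_tiff_stack()]
#'
#' @param path TIFF path; a `<path>.json` sidecar restores physical units
#'   and the intensity scale.
#' @return A [raster_image()] (single frame) or [time_lapse()].
#' @export
read_tiff_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  off <- meta$intensity_offset %||% 0
  sc <- meta$intensity_scale %||% (1 / 65535)
  ps <- meta$pixel_size_um %||% 0.0775
  frames <- lapply(imgs, function(m) m * 65535 / sc + off)
  if (length(frames) == 1) raster_image(frames[[1]], ps)
  else time_lapse(frames, frame_interval_s = meta$frame_interval_s %||% 30,
                  pixel_size_um = ps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a filament graph as JSON
#'
#' Nodes, edges and full polyline vertex lists in micrometres.
#'
#' @param g A [filament_graph()].
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "filament_graph"))
  obj <- list(
    pixel_size_um = g$pixel_size_um,
    nodes = g$nodes,
    edges = g$edges,
    polylines = lapply(g$polylines, function(v) {
      list(x_um = unname(v[, 1]), y_um = unname(v[, 2]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a filament graph written by [write_graph_json()]
#'
#' @param path JSON path.
#' @return A [filament_graph()].
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- lapply(seq_len(nrow(obj$edges)), function(i) {
    p <- obj$polylines[i, ]
    cbind(x_um = unlist(p$x_um), y_um = unlist(p$y_um))
  })
  if (nrow(obj$edges) == 0) polys <- list()
  filament_graph(obj$nodes, obj$edges, polys,
                 pixel_size_um = obj$pixel_size_um)
}

#' Write a force-distance curve or bead track as CSV
#'
#' AFM curves use columns `z_nm,force_nN`; tweezers tracks use
#' `t_s,x_um,force_nN`.
#'
#' @param x A `force_distance_curve` or `bead_track`.
#' @param path Output `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_curve_csv <- function(x, path) {
  d <- if (inherits(x, "force_distance_curve") || inherits(x, "bead_track"))
    x$data else as.data.frame(x)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an AFM force-distance curve from CSV
#'
#' Expected columns: `z_nm`, `force_nN` (optional `deflection_nm`).
#'
#' @param path CSV path.
#' @param spring_constant Cantilever spring constant (N/m, default 0.04).
#' @param setpoint_nN Force setpoint (default 1.5).
#' @return A `force_distance_curve`.
#' @export
read_fd_csv <- function(path, spring_constant = 0.04, setpoint_nN = 1.5) {
  d <- utils::read.csv(path)
  if (!all(c("z_nm", "force_nN") %in% names(d)))
    stop("AFM CSV needs columns z_nm and force_nN", call. = FALSE)
  structure(list(data = d, spring_constant = spring_constant,
                 setpoint_nN = setpoint_nN, truth = NULL),
            class = "force_distance_curve")
}

#' Read a magnetic-tweezers bead track from CSV
#'
#' Expected columns: `t_s`, `x_um`, `force_nN`.
#'
#' @param path CSV path.
#' @return A `bead_track` (fps inferred from the median time step).
#' @export
read_track_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "x_um", "force_nN") %in% names(d)))
    stop("tweezers CSV needs columns t_s, x_um and force_nN", call. = FALSE)
  fps <- 1 / stats::median(diff(d$t_s))
  structure(list(data = d, fps = fps, schedule = NULL, truth = NULL),
            class = "bead_track")
}
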