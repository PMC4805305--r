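#' Raster image with physical pixel spacing
#'
#' Lightweight container for a 2D intensity image. Rows index y, columns
#' index x; the pixel centre of `[i, j]` sits at physical position
#' `((j - 1) * pixel_size_um, (i - 1) * pixel_size_um)`.
#'
#' @param intensities Numeric matrix of non-negative intensities.
#' @param pixel_size_um Positive pixel edge length in micrometres. The
#'   default 0.0775 corresponds to a 79.3 um field scanned at 1024 px.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(intensities, pixel_size_um = 0.0775) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  structure(
    list(intensities = intensities, pixel_size_um = pixel_size_um),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<raster_image> %d x %d px, %.4f um/px, range [%.4g, %.4g]\n",
    d[1], d[2], x$pixel_size_um,
    min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$intensities)

#' Time-lapse image stack
#'
#' @param frames List of numeric matrices (all the same dimension) or of
#'   `raster_image` objects.
#' @param frame_interval_s Positive acquisition interval in seconds
#'   (default 30, the standard live-cell recording interval).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param cell_mask Optional logical matrix marking the cell interior; when
#'   absent it can be derived with [derive_cell_mask()].
#' @return An object of class `time_lapse`.
#' @export
time_lapse <- function(frames, frame_interval_s = 30,
                       pixel_size_um = 0.0775, cell_mask = NULL) {
  frames <- lapply(frames, function(f) {
    if (inherits(f, "raster_image")) f$intensities else f
  })
  if (length(frames) < 2)
    stop("a time lapse needs at least 2 frames", call. = FALSE)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must share one dimension", call. = FALSE)
  if (frame_interval_s <= 0)
    stop("`frame_interval_s` must be positive", call. = FALSE)
  if (!is.null(cell_mask) && !identical(dim(cell_mask), d))
    stop("`cell_mask` dimension must match the frames", call. = FALSE)
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, cell_mask = cell_mask),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<time_lapse> %d frames of %d x %d px, %g s interval\n",
              length(x$frames), d[1], d[2], x$frame_interval_s))
  invisible(x)
}

#' Filament graph
#'
#' Geometric representation of a segmented filament network: nodes are
#' endpoints (degree 1) or branch points (degree >= 3), edges carry the
#' polyline traced between their two incident nodes, in micrometres.
#'
#' @param nodes Data frame with columns `id`, `x_um`, `y_um`,
#'   `kind` (`"endpoint"` or `"branch"`).
#' @param edges Data frame with columns `edge_id`, `node_a`, `node_b`,
#'   `length_um`; the polylines are a parallel list.
#' @param polylines List (one entry per edge) of two-column matrices of
#'   vertex positions `(x_um, y_um)`.
#' @param pixel_size_um Pixel size the graph was extracted at.
#' @return An object of class `filament_graph`.
#' @export
filament_graph <- function(nodes, edges, polylines,
                           pixel_size_um = 0.0775) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(edges) != length(polylines))
    stop("one polyline per edge required", call. = FALSE)
  if (nrow(edges) > 0 && any(edges$length_um < 0))
    stop("edge lengths must be non-negative", call. = FALSE)
  structure(
    list(nodes = nodes, edges = edges, polylines = polylines,
         pixel_size_um = pixel_size_um),
    class = "filament_graph"
  )
}

#' @export
print.filament_graph <- function(x, ...) {
  cat(sprintf(
    "<filament_graph> %d nodes (%d branch, %d endpoint), %d edges, total %.2f um\n",
    nrow(x$nodes), sum(x$nodes$kind == "branch"),
    sum(x$nodes$kind == "endpoint"), nrow(x$edges),
    if (nrow(x$edges)) sum(x$edges$length_um) else 0))
  invisible(x)
}

#' Polyline arc length
#'
#' Sum of Euclidean distances between consecutive vertices.
#'
#' @param verts Two-column matrix of vertex coordinates.
#' @return Scalar length in the units of `verts`.
#' @export
polyline_length <- function(verts) {
  if (is.null(dim(verts)) || nrow(verts) < 2) return(0)
  d <- diff(verts)
  sum(sqrt(rowSums(d^2)))
}

#' Node degrees of a filament graph
#'
#' @param g A `filament_graph`.
#' @return Named integer vector of degrees (self-edges count twice).
#' @export
node_degrees <- function(g) {
  deg <- setNames(integer(nrow(g$nodes)), g$nodes$id)
  if (nrow(g$edges) > 0) {
    for (nm in c("node_a", "node_b")) {
      t <- table(g$edges[[nm]])
      deg[names(t)] <- deg[names(t)] + as.integer(t)
    }
  }
  deg
}
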