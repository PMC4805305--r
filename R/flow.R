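#' Block-matching flow estimation between two frames
#'
#' Normalized cross-correlation block matching: for every point of a regular
#' grid, the template around it in `frame_a` is correlated with every
#' displacement of the search window in `frame_b`; the displacement is the
#' correlation argmax with 2D quadratic subpixel refinement. Vectors are
#' invalidated where the template mean intensity falls below
#' `min_intensity` or the peak correlation is below `min_corr`. Correlation
#' ties are broken toward the smaller displacement.
#'
#' @param frame_a,frame_b Matrices or [raster_image()]s of equal dimension.
#' @param grid_px Grid spacing in pixels (default 8).
#' @param template_px Template edge length (default 16).
#' @param search_px Search radius in pixels (default 8).
#' @param min_intensity Minimum template mean intensity for a valid vector.
#' @param min_corr Minimum peak correlation (default 0.3).
#' @param median_filter Apply a 3x3 vector-median outlier filter?
#' @return A `flow_field`: data frame with columns `x`, `y` (grid centres,
#'   px), `vx`, `vy` (px/frame), `score`, `valid`; attributes `grid_px` and
#'   `dim`.
#' @export
estimate_flow <- function(frame_a, frame_b,
                          grid_px = 8, template_px = 16, search_px = 8,
                          min_intensity = 0, min_corr = 0.3,
                          median_filter = TRUE) {
  a <- as_intensity(frame_a); b <- as_intensity(frame_b)
  if (!identical(dim(a), dim(b)))
    stop("frames must share one dimension", call. = FALSE)
  nr <- nrow(a); nc <- ncol(a)
  if (template_px > min(nr, nc))
    stop("template larger than the frame", call. = FALSE)
  ht <- template_px %/% 2
  margin <- ht + search_px + 1
  gx <- seq(margin + 1, nc - margin, by = grid_px)
  gy <- seq(margin + 1, nr - margin, by = grid_px)
  if (length(gx) == 0 || length(gy) == 0)
    stop("frame too small for the requested template/search size",
         call. = FALSE)
  G <- expand.grid(y = gy, x = gx)
  y0 <- G$y - ht; y1 <- y0 + template_px - 1L
  x0 <- G$x - ht; x1 <- x0 + template_px - 1L
  n <- template_px^2

  Sa <- integral_image(a); Sa2 <- integral_image(a * a)
  sum_a <- window_sum(Sa, y0, y1, x0, x1)
  sum_a2 <- window_sum(Sa2, y0, y1, x0, x1)
  var_a <- sum_a2 - sum_a^2 / n

  ds <- -search_px:search_px
  offsets <- expand.grid(dy = ds, dx = ds)
  ncc <- matrix(-Inf, nrow(G), nrow(offsets))
  Sb <- integral_image(b); Sb2 <- integral_image(b * b)
  for (o in seq_len(nrow(offsets))) {
    dy <- offsets$dy[o]; dx <- offsets$dx[o]
    # product image a(x) * b(x + d); windows stay in range by margin
    bsh <- matrix(0, nr, nc)
    ys <- max(1, 1 - dy):min(nr, nr - dy)
    xs <- max(1, 1 - dx):min(nc, nc - dx)
    bsh[ys, xs] <- b[ys + dy, xs + dx]
    Sab <- integral_image(a * bsh)
    sum_ab <- window_sum(Sab, y0, y1, x0, x1)
    sum_b <- window_sum(Sb, y0 + dy, y1 + dy, x0 + dx, x1 + dx)
    sum_b2 <- window_sum(Sb2, y0 + dy, y1 + dy, x0 + dx, x1 + dx)
    var_b <- sum_b2 - sum_b^2 / n
    cov_ab <- sum_ab - sum_a * sum_b / n
    denom <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
    ncc[, o] <- ifelse(denom > 1e-12, cov_ab / denom, 0)
  }

  nd <- length(ds)
  vx <- vy <- score <- numeric(nrow(G))
  valid <- logical(nrow(G))
  d2 <- offsets$dy^2 + offsets$dx^2
  for (i in seq_len(nrow(G))) {
    row <- ncc[i, ]
    best <- max(row)
    cand <- which(row >= best - 1e-12)
    o <- cand[which.min(d2[cand])]
    oy <- ((o - 1) %% nd) + 1
    ox <- ((o - 1) %/% nd) + 1
    dy <- ds[oy]; dx <- ds[ox]
    # quadratic subpixel refinement along each axis
    sub <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (is.finite(den) && abs(den) > 1e-12) {
        s <- 0.5 * (cm - cp) / den
        max(min(s, 0.5), -0.5)
      } else 0
    }
    sy <- if (oy > 1 && oy < nd)
      sub(row[(ox - 1) * nd + oy - 1], row[o], row[(ox - 1) * nd + oy + 1]) else 0
    sx <- if (ox > 1 && ox < nd)
      sub(row[(ox - 2) * nd + oy], row[o], row[ox * nd + oy]) else 0
    vx[i] <- dx + sx
    vy[i] <- dy + sy
    score[i] <- best
    valid[i] <- best >= min_corr && (sum_a[i] / n) > min_intensity
  }
  ff <- data.frame(x = G$x, y = G$y, vx = vx, vy = vy,
                   score = score, valid = valid)
  if (median_filter) ff <- median_filter_flow(ff, gy, gx)
  attr(ff, "grid_px") <- grid_px
  attr(ff, "frame_dim") <- c(nr, nc)
  class(ff) <- c("flow_field", class(ff))
  ff
}

# 3x3 component-wise median filter over the flow grid (valid vectors only)
median_filter_flow <- function(ff, gy, gx) {
  ny <- length(gy); nx <- length(gx)
  VX <- matrix(ff$vx, ny, nx); VY <- matrix(ff$vy, ny, nx)
  VAL <- matrix(ff$valid, ny, nx)
  outx <- VX; outy <- VY
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      if (!VAL[i, j]) next
      ii <- max(1, i - 1):min(ny, i + 1)
      jj <- max(1, j - 1):min(nx, j + 1)
      sel <- VAL[ii, jj]
      if (sum(sel) >= 3) {
        outx[i, j] <- stats::median(VX[ii, jj][sel])
        outy[i, j] <- stats::median(VY[ii, jj][sel])
      }
    }
  }
  ff$vx <- as.vector(outx); ff$vy <- as.vector(outy)
  ff
}

#' Estimate flow for every consecutive frame pair of a movie
#'
#' @param movie A [time_lapse()].
#' @param ... Passed to [estimate_flow()].
#' @return List of `flow_field`s (one per frame pair).
#' @export
movie_flow <- function(movie, ...) {
  stopifnot(inherits(movie, "time_lapse"))
  n <- length(movie$frames)
  lapply(seq_len(n - 1), function(t) {
    estimate_flow(movie$frames[[t]], movie$frames[[t + 1]], ...)
  })
}

#' Time-averaged speed map
#'
#' Mean vector magnitude over the supplied flow fields, interpolated from
#' the estimation grid to the pixel grid. Speeds are reported in px/min
#' (the arbitrary distance unit per minute); multiply by the pixel size to
#' obtain um/min (the factor is stored as attribute `um_per_px`).
#'
#' @param flows List of `flow_field`s.
#' @param frame_interval_s Acquisition interval in seconds.
#' @param pixel_size_um Pixel size for the um/min conversion factor.
#' @return A [raster_image()] in px/min with attribute `um_per_px`; pixels
#'   with no valid vector support are `NA`.
#' @export
speed_map <- function(flows, frame_interval_s = 30, pixel_size_um = 0.0775) {
  if (length(flows) == 0) stop("at least one flow field needed", call. = FALSE)
  f1 <- flows[[1]]
  per_min <- 60 / frame_interval_s
  sp_sum <- numeric(nrow(f1)); sp_n <- numeric(nrow(f1))
  for (ff in flows) {
    sp <- sqrt(ff$vx^2 + ff$vy^2) * per_min
    ok <- ff$valid
    sp_sum[ok] <- sp_sum[ok] + sp[ok]
    sp_n[ok] <- sp_n[ok] + 1
  }
  sp_mean <- ifelse(sp_n > 0, sp_sum / sp_n, NA_real_)
  m <- grid_to_pixels(f1$x, f1$y, sp_mean, attr(f1, "frame_dim"))
  out <- raster_image(m, pixel_size_um)
  attr(out, "um_per_px") <- pixel_size_um
  out
}

# bilinear interpolation of regular-grid values onto the pixel grid;
# NA grid values propagate, pixels outside the grid hull are NA
grid_to_pixels <- function(gxv, gyv, val, dm) {
  gy <- sort(unique(gyv)); gx <- sort(unique(gxv))
  V <- matrix(NA_real_, length(gy), length(gx))
  V[cbind(match(gyv, gy), match(gxv, gx))] <- val
  nr <- dm[1]; nc <- dm[2]
  # map pixel coords to fractional grid indices
  yi <- stats::approx(gy, seq_along(gy), xout = seq_len(nr), rule = 1)$y
  xi <- stats::approx(gx, seq_along(gx), xout = seq_len(nc), rule = 1)$y
  out <- matrix(NA_real_, nr, nc)
  okY <- which(!is.na(yi)); okX <- which(!is.na(xi))
  if (length(okY) && length(okX)) {
    yq <- rep(yi[okY], times = length(okX))
    xq <- rep(xi[okX], each = length(okY))
    vals <- bilinear_sample(V, yq, xq, fill = NA_real_)
    out[okY, okX] <- matrix(vals, length(okY), length(okX))
  }
  out
}

#' Motion-compensated bulk-flow turnover map
#'
#' For each consecutive frame pair the previous frame is pulled back along
#' the estimated flow (inverse warp with bilinear sampling) and subtracted
#' from the next frame; with keratin mass taken proportional to
#' fluorescence the residual is the local assembly (positive, source) or
#' disassembly (negative, sink) rate. The per-pair residuals are averaged,
#' scaled to intensity units per minute, masked to the cell, and lightly
#' smoothed to suppress pixel-scale motion-compensation noise.
#'
#' @param movie A [time_lapse()].
#' @param flows List of `flow_field`s, one per frame pair; ground-truth
#'   pixel flow may be supplied as a list with matrices `vx`, `vy`.
#' @param mask Optional logical matrix; defaults to the movie's cell mask
#'   or, failing that, [derive_cell_mask()].
#' @param smooth_sigma_px Gaussian SD of the turnover-map regularization
#'   (default 2 px: below the width of coherent assembly/disassembly zones
#'   but above the pixel-scale residual noise; 0 disables).
#' @return A `turnover_map`: [raster_image()] of signed rates
#'   (intensity/min), zero outside the mask.
#' @export
bulk_flow <- function(movie, flows, mask = NULL, smooth_sigma_px = 2) {
  stopifnot(inherits(movie, "time_lapse"))
  n <- length(movie$frames)
  if (length(flows) != n - 1)
    stop("need one flow field per consecutive frame pair", call. = FALSE)
  if (is.null(mask)) mask <- movie$cell_mask
  if (is.null(mask)) mask <- derive_cell_mask(movie)
  d <- dim(movie$frames[[1]])
  acc <- matrix(0, d[1], d[2])
  for (t in seq_len(n - 1)) {
    v <- flow_to_pixel_field(flows[[t]], d)
    It <- movie$frames[[t]]; It1 <- movie$frames[[t + 1]]
    Y <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
    X <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    warped <- matrix(
      bilinear_sample(It, as.vector(Y - v$vy), as.vector(X - v$vx),
                      fill = NA_real_),
      d[1], d[2])
    res <- It1 - warped
    res[is.na(res)] <- 0
    acc <- acc + res
  }
  rate <- acc / (n - 1) * (60 / movie$frame_interval_s)
  rate[!mask] <- 0
  if (smooth_sigma_px > 0) {
    rate <- gaussian_blur_mat(rate, smooth_sigma_px)
    rate[!mask] <- 0
  }
  out <- raster_image(rate, movie$pixel_size_um)
  class(out) <- c("turnover_map", class(out))
  out
}

# densify a flow field (or ground-truth vx/vy matrices) to per-pixel vectors
flow_to_pixel_field <- function(ff, d) {
  if (is.list(ff) && !inherits(ff, "flow_field") &&
      all(c("vx", "vy") %in% names(ff))) {
    return(list(vx = ff$vx, vy = ff$vy))
  }
  val <- ff$valid
  vx <- grid_to_pixels(ff$x, ff$y, ifelse(val, ff$vx, NA), d)
  vy <- grid_to_pixels(ff$x, ff$y, ifelse(val, ff$vy, NA), d)
  vx[is.na(vx)] <- 0
  vy[is.na(vy)] <- 0
  list(vx = vx, vy = vy)
}

#' Derive a cell mask from a movie
#'
#' Otsu threshold on the time-median frame, keep the largest connected
#' component and fill its holes.
#'
#' @param movie A [time_lapse()].
#' @return Logical matrix.
#' @export
derive_cell_mask <- function(movie) {
  stopifnot(inherits(movie, "time_lapse"))
  d <- dim(movie$frames[[1]])
  med <- apply(simplify2array(movie$frames), c(1, 2), stats::median)
  mask <- binarize(med, "otsu")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  tab <- table(lab[lab > 0])
  if (length(tab) == 0) return(matrix(FALSE, d[1], d[2]))
  big <- as.integer(names(tab)[which.max(tab)])
  comp <- matrix(lab == big, d[1], d[2])
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  matrix(as.numeric(filled) > 0, d[1], d[2])
}

#' Scalar summaries of keratin dynamics
#'
#' Mean speed over valid vectors inside the mask and the total bulk flow
#' (assembly plus disassembly magnitude, halved) per minute.
#'
#' @param flows List of `flow_field`s.
#' @param turnover A `turnover_map`.
#' @param mask Logical matrix.
#' @param frame_interval_s Acquisition interval (s).
#' @param pixel_size_um Pixel size (um) for the um/min co-report.
#' @return List with `mean_speed_px_min`, `mean_speed_um_min`,
#'   `total_bulk_flow` (intensity/min) and `n_vectors`.
#' @export
summarize_dynamics <- function(flows, turnover, mask,
                               frame_interval_s = 30,
                               pixel_size_um = 0.0775) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  per_min <- 60 / frame_interval_s
  speeds <- unlist(lapply(flows, function(ff) {
    inm <- mask[cbind(ff$y, ff$x)]
    sp <- sqrt(ff$vx^2 + ff$vy^2)[ff$valid & inm]
    sp
  }))
  if (length(speeds) == 0) stop("no valid vectors in the mask", call. = FALSE)
  tm <- as_intensity(turnover)
  tin <- tm[mask]
  list(mean_speed_px_min = mean(speeds) * per_min,
       mean_speed_um_min = mean(speeds) * per_min * pixel_size_um,
       total_bulk_flow = (sum(tin[tin > 0]) + sum(abs(tin[tin < 0]))) / 2,
       n_vectors = length(speeds))
}

#' Circular cell-shape normalization
#'
#' Remaps a scalar map defined on an arbitrarily shaped cell onto a
#' standard disk: each pixel at polar position `(r, theta)` about the mask
#' centroid is sent to `(r / R(theta) * R0, theta)`, where `R(theta)` is
#' the boundary radius sampled along 360 rays (linear interpolation between
#' rays). Maps from differently shaped cells then superimpose.
#'
#' @param map Matrix or [raster_image()] (scalar map on the cell).
#' @param mask Logical matrix; must contain its own centroid (star-shaped
#'   about the centroid).
#' @param R0_px Radius of the standard disk in pixels (default 256 px;
#'   reduce for small test images).
#' @param n_rays Number of boundary rays (default 360).
#' @return A `normalized_cell_map`: list with `map` (a
#'   `(2 R0 + 1)^2` matrix, `NA` outside the disk) and `count`
#'   (contributing-cell count per pixel, here 0/1).
#' @export
normalize_cell <- function(map, mask, R0_px = 256, n_rays = 360) {
  m <- as_intensity(map)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  idx <- which(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  cy <- mean(((idx - 1) %% nr) + 1)
  cx <- mean(((idx - 1) %/% nr) + 1)
  if (cy < 1 || cy > nr || cx < 1 || cx > nc ||
      !mask[round(cy), round(cx)])
    stop("mask centroid lies outside the mask; cell is not star-shaped",
         call. = FALSE)
  thetas <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  Rth <- vapply(thetas, function(th) {
    boundary_radius(mask, cy, cx, th)
  }, numeric(1))

  size <- 2 * R0_px + 1
  oy <- matrix(rep(seq_len(size), times = size), size, size) - (R0_px + 1)
  ox <- matrix(rep(seq_len(size), each = size), size, size) - (R0_px + 1)
  rr <- sqrt(ox^2 + oy^2)
  th <- atan2(oy, ox) %% (2 * pi)
  inside <- rr <= R0_px
  # interpolate R(theta) circularly
  ti <- th / (2 * pi) * n_rays
  i0 <- (floor(ti) %% n_rays) + 1
  i1 <- (i0 %% n_rays) + 1
  ft <- ti - floor(ti)
  Rq <- (1 - ft) * Rth[i0] + ft * Rth[i1]
  srcr <- rr / R0_px * Rq
  sy <- cy + srcr * sin(th)
  sx <- cx + srcr * cos(th)
  vals <- bilinear_sample(m, as.vector(sy), as.vector(sx), fill = NA_real_)
  out <- matrix(vals, size, size)
  out[!inside] <- NA_real_
  cnt <- matrix(0, size, size)
  cnt[inside & !is.na(out)] <- 1
  structure(list(map = out, count = cnt, R0_px = R0_px),
            class = "normalized_cell_map")
}

# boundary radius of the mask along one ray (0.25 px march)
boundary_radius <- function(mask, cy, cx, theta) {
  nr <- nrow(mask); nc <- ncol(mask)
  step <- 0.25
  rmax <- sqrt(nr^2 + nc^2)
  r <- 0
  last_in <- 0
  while (r <= rmax) {
    y <- cy + r * sin(theta); x <- cx + r * cos(theta)
    if (y < 1 || y > nr || x < 1 || x > nc) break
    if (mask[round(y), round(x)]) last_in <- r
    r <- r + step
  }
  max(last_in, step)
}

#' Average normalized cell maps
#'
#' Per-pixel mean over the contributing cells; the count map records how
#' many cells contributed at each pixel.
#'
#' @param maps List of `normalized_cell_map`s with identical `R0_px`.
#' @return A `normalized_cell_map`.
#' @export
aggregate_cells <- function(maps) {
  if (length(maps) == 0) stop("no maps to aggregate", call. = FALSE)
  R0 <- unique(vapply(maps, `[[`, numeric(1), "R0_px"))
  if (length(R0) != 1)
    stop("all maps must share one R0_px", call. = FALSE)
  acc <- matrix(0, nrow(maps[[1]]$map), ncol(maps[[1]]$map))
  cnt <- matrix(0, nrow(acc), ncol(acc))
  for (m in maps) {
    v <- m$map
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + m$count
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  structure(list(map = out, count = cnt, R0_px = R0),
            class = "normalized_cell_map")
}
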