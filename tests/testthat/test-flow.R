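textured_frame <- function(n = 128, seed = 5) {
  withr::with_seed(seed,
    gaussian_denoise(matrix(stats::runif(n * n, 0, 100), n, n), 2))
}

test_that("block matching is exact on identity and integer shifts", {
  a <- textured_frame()
  f0 <- estimate_flow(a, a, search_px = 4)
  expect_true(all(f0$valid))
  expect_lt(max(abs(c(f0$vx, f0$vy))), 0.05)

  b <- matrix(0, 128, 128)
  b[, 4:128] <- a[, 1:125]            # content moves +3 px in x
  ff <- estimate_flow(a, b, search_px = 6)
  v <- ff[ff$valid, ]
  expect_gt(nrow(v), 100)
  expect_lt(max(abs(v$vx - 3)), 0.2)
  expect_lt(max(abs(v$vy)), 0.2)

  # diagonal integer shift
  d <- matrix(0, 128, 128)
  d[3:128, 2:128] <- a[1:126, 1:127]  # +1 x, +2 y
  fd <- estimate_flow(a, d, search_px = 4)
  vd <- fd[fd$valid, ]
  expect_lt(max(abs(vd$vx - 1)), 0.25)
  expect_lt(max(abs(vd$vy - 2)), 0.25)
})

test_that("featureless frames produce no valid vectors", {
  z <- matrix(0, 96, 96)
  ff <- estimate_flow(z, z, search_px = 4)
  expect_false(any(ff$valid))
  expect_error(estimate_flow(matrix(0, 8, 8), matrix(0, 8, 8),
                             template_px = 16),
               "template larger")
})

test_that("speed maps convert px/frame to per-minute units", {
  a <- textured_frame()
  b <- matrix(0, 128, 128)
  b[, 4:128] <- a[, 1:125]
  ff <- estimate_flow(a, b, search_px = 6)
  sm <- speed_map(list(ff), frame_interval_s = 30, pixel_size_um = 0.0775)
  vals <- sm$intensities[!is.na(sm$intensities)]
  # 3 px/frame at 30 s -> 6 px/min
  expect_equal(mean(vals), 6, tolerance = 0.02)
  expect_equal(attr(sm, "um_per_px"), 0.0775)

  f0 <- estimate_flow(a, a, search_px = 4)
  sm0 <- speed_map(list(f0))
  expect_lt(max(sm0$intensities, na.rm = TRUE), 0.1)
})

test_that("radial phantom speed profile is recovered in the mid-annulus", {
  ph <- generate_timelapse(flow_phantom_spec(
    field_size_px = 192, cell_radius_px = 80, n_frames = 6, seed = 2))
  fl <- movie_flow(ph$movie, search_px = 4)
  sm <- speed_map(fl, frame_interval_s = 30)
  n <- 192; c0 <- (n + 1) / 2
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  rho <- sqrt((X - c0)^2 + (Y - c0)^2) / 80
  mid <- rho >= 0.45 & rho <= 0.75 & !is.na(sm$intensities)
  # truth: |v| = 1.5 rho^2 px/frame -> 3 rho^2 px/min
  truth <- 3 * rho[mid]^2
  expect_lt(mean(abs(sm$intensities[mid] - truth)) / mean(truth), 0.15)
})

test_that("turnover is zero for static movies and exact for known sources", {
  frames <- rep(list(textured_frame(96)), 4)
  mv <- time_lapse(frames, cell_mask = matrix(TRUE, 96, 96))
  zero_flow <- list(vx = matrix(0, 96, 96), vy = matrix(0, 96, 96))
  turn <- bulk_flow(mv, rep(list(zero_flow), 3))
  expect_lt(max(abs(turn$intensities)), 1e-9)

  # uniform growth c per minute inside an annulus, zero flow
  n <- 96; c0 <- (n + 1) / 2
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  rr <- sqrt((X - c0)^2 + (Y - c0)^2)
  ann <- rr >= 18 & rr <= 34
  c_rate <- 4                         # intensity units per minute
  base <- textured_frame(96)
  frames <- lapply(0:3, function(t) base + ann * (c_rate * t * 30 / 60))
  mv <- time_lapse(frames, frame_interval_s = 30,
                   cell_mask = matrix(TRUE, n, n))
  turn <- bulk_flow(mv, rep(list(zero_flow), 3), smooth_sigma_px = 0)
  expect_equal(mean(turn$intensities[ann]), c_rate, tolerance = 1e-9)
  expect_lt(max(abs(turn$intensities[rr < 14])), 1e-9)
})

test_that("conserved advection leaves a negligible turnover residual", {
  ph <- generate_timelapse(flow_phantom_spec(
    field_size_px = 128, cell_radius_px = 50, n_frames = 5,
    source_annulus = list(r = c(0.7, 0.9), rate = 0),
    sink_annulus = list(r = c(0.2, 0.4), rate = 0),
    noise_sd = 0, seed = 3))
  turn <- bulk_flow(ph$movie, rep(list(ph$flow_truth), 4))
  mask <- ph$movie$cell_mask
  mean_I <- mean(ph$movie$frames[[1]][mask])
  expect_lt(mean(abs(turn$intensities[mask])) / mean_I, 0.02)
})

test_that("dynamics summaries reduce fields and maps correctly", {
  a <- textured_frame()
  b <- matrix(0, 128, 128); b[, 4:128] <- a[, 1:125]
  ff <- estimate_flow(a, b, search_px = 6)
  mask <- matrix(TRUE, 128, 128)
  tm <- raster_image(matrix(0, 128, 128))
  dyn <- summarize_dynamics(list(ff), tm, mask, frame_interval_s = 30)
  expect_equal(dyn$mean_speed_px_min, 6, tolerance = 0.02)
  expect_equal(dyn$mean_speed_um_min, 6 * 0.0775, tolerance = 0.02)

  # antisymmetric source/sink of equal total rate Q
  rate <- matrix(0, 128, 128)
  rate[20:40, 20:40] <- 2
  rate[80:100, 80:100] <- -2
  Q <- sum(rate[rate > 0])
  dyn2 <- summarize_dynamics(list(ff), raster_image(rate), mask)
  expect_equal(dyn2$total_bulk_flow, Q, tolerance = 1e-12)
  expect_error(summarize_dynamics(list(ff), tm, matrix(FALSE, 128, 128)),
               "empty mask")
})

test_that("phantom source/sink rates are recovered within 15%", {
  totals <- vapply(1:6, function(i) {
    ph <- generate_timelapse(flow_phantom_spec(
      field_size_px = 160, cell_radius_px = 64, n_frames = 6,
      seed = 40 + i))
    fl <- movie_flow(ph$movie, search_px = 4)
    turn <- bulk_flow(ph$movie, fl)
    dyn <- summarize_dynamics(fl, turn, ph$movie$cell_mask)
    truth <- gross_flow(ph$turnover_truth)
    dyn$total_bulk_flow / truth
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1), 0.15)
})

test_that("circular normalization is the identity for a centred disk", {
  n <- 129; c0 <- 65; R0 <- 40
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  rr <- sqrt((X - c0)^2 + (Y - c0)^2)
  mask <- rr <= R0
  map <- exp(-((X - c0)^2 + (Y - c0)^2) / (2 * 25^2))   # smooth
  nm <- normalize_cell(map, mask, R0_px = R0)
  size <- 2 * R0 + 1
  Xo <- matrix(rep(seq_len(size), each = size), size, size) - (R0 + 1)
  Yo <- matrix(rep(seq_len(size), times = size), size, size) - (R0 + 1)
  expected <- exp(-(Xo^2 + Yo^2) / (2 * 25^2))
  ok <- !is.na(nm$map)
  expect_lt(mean(abs(nm$map[ok] - expected[ok])) / diff(range(map)), 0.01)
})

test_that("circular normalization maps an ellipse boundary onto the disk", {
  n <- 129; c0 <- 65
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  mask <- ((X - c0) / 50)^2 + ((Y - c0) / 28)^2 <= 1
  map <- 1 + 0.01 * (X + Y)                               # smooth
  nm <- normalize_cell(map, mask, R0_px = 40)
  rr0 <- sqrt((row(nm$map) - 41)^2 + (col(nm$map) - 41)^2)
  # support fills the disk (boundary maps to boundary)
  expect_gt(mean(!is.na(nm$map[rr0 <= 39])), 0.99)
  expect_true(all(is.na(nm$map[rr0 > 40.6])))

  # Jacobian-weighted integral oracle: the disk integral of the output
  # equals the input integrated with weight (R0 / R(theta))^2
  th <- atan2(Y - c0, X - c0)
  Rth <- 1 / sqrt((cos(th) / 50)^2 + (sin(th) / 28)^2)
  w <- (40 / Rth)^2
  oracle <- sum(map[mask] * w[mask])
  measured <- sum(nm$map, na.rm = TRUE)
  expect_lt(abs(measured / oracle - 1), 0.10)
})

test_that("normalization requires a star-shaped mask", {
  # crescent whose centroid falls outside the mask
  n <- 101
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  big <- sqrt((X - 51)^2 + (Y - 51)^2) <= 40
  hole <- sqrt((X - 41)^2 + (Y - 51)^2) <= 34
  crescent <- big & !hole
  expect_error(normalize_cell(matrix(1, n, n), crescent, R0_px = 30),
               "star-shaped")
})

test_that("aggregation of normalized maps is a per-pixel mean with counts", {
  n <- 81; c0 <- 41
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Y <- matrix(rep(seq_len(n), times = n), n, n)
  mask <- sqrt((X - c0)^2 + (Y - c0)^2) <= 30
  m1 <- normalize_cell(matrix(2, n, n), mask, R0_px = 30)
  single <- aggregate_cells(list(m1))
  expect_equal(single$map, m1$map)
  expect_equal(single$count, m1$count)

  neg <- m1; neg$map <- -m1$map
  zero <- aggregate_cells(list(m1, neg))
  expect_lt(max(abs(zero$map), na.rm = TRUE), 1e-12)

  triple <- aggregate_cells(list(m1, m1, m1))
  expect_equal(triple$map, m1$map)
  expect_equal(max(triple$count), 3)
  expect_error(aggregate_cells(list()), "no maps")
})
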