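test_that("gaussian denoising is exact on the standard kernels", {
  const <- matrix(5, 20, 20)
  expect_equal(gaussian_denoise(const, 2), const, tolerance = 1e-12)
  m <- matrix(runif(400), 20, 20)
  expect_identical(gaussian_denoise(m, 0), m)
  expect_error(gaussian_denoise(m, -1), "non-negative")

  # unit impulse vs brute-force dense convolution with the sampled kernel
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  out <- gaussian_denoise(imp, 1)
  r <- 4L
  k1 <- stats::dnorm(-r:r, sd = 1); k1 <- k1 / sum(k1)
  kern2 <- outer(k1, k1)
  brute <- matrix(0, 31, 31)
  for (dy in -r:r) for (dx in -r:r)
    brute[16 + dy, 16 + dx] <- kern2[dy + r + 1, dx + r + 1]
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("binarization reproduces the between-class-variance optimum", {
  # two-valued image: 90% at 0.1, 10% at 0.9
  set.seed(1)
  v <- c(rep(0.1, 900), rep(0.9, 100))
  m <- matrix(sample(v), 25, 40)
  mask <- binarize(m, "otsu")
  thr <- attr(mask, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  expect_equal(mean(mask), 0.1)
  # oracle: exhaustive between-class variance scan over candidate cuts
  cand <- seq(0.05, 0.95, by = 0.005)
  bcv <- vapply(cand, function(t) {
    w1 <- mean(m <= t); w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) return(0)
    w1 * w2 * (mean(m[m > t]) - mean(m[m <= t]))^2
  }, numeric(1))
  best <- cand[which.max(bcv)]
  expect_equal(m > thr, m > best)

  expect_equal(as.vector(binarize(matrix(c(0.4, 0.6), 1), "fixed",
                                  fixed_threshold = 0.5)),
               c(FALSE, TRUE))
  expect_true(all(!binarize(m, "fixed", fixed_threshold = 2)))
  expect_error(binarize(matrix(1, 5, 5), "otsu"), "degenerate")
  expect_error(binarize(m, "fixed"), "fixed_threshold")
})

test_that("thinning preserves topology and finds the medial axis", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(extract_centerline(empty), empty)

  line <- matrix(FALSE, 10, 20); line[5, 3:18] <- TRUE
  expect_equal(extract_centerline(line), line)

  bar <- matrix(FALSE, 15, 50); bar[6:10, 5:44] <- TRUE
  sk <- extract_centerline(bar)
  expect_true(all(bar[sk]))                  # skeleton within the mask
  ys <- ((which(sk) - 1) %% 15) + 1
  # oracle: ridge of the brute-force Euclidean distance transform (row 8)
  dt <- matrix(0, 15, 50)
  border <- which(!bar)
  by <- ((border - 1) %% 15) + 1; bx <- ((border - 1) %/% 15) + 1
  for (i in which(bar)) {
    yy <- ((i - 1) %% 15) + 1; xx <- ((i - 1) %/% 15) + 1
    dt[i] <- sqrt(min((by - yy)^2 + (bx - xx)^2))
  }
  ridge_row <- unique(((which(dt == max(dt)) - 1) %% 15) + 1)
  expect_true(all(abs(ys - ridge_row[1]) <= 1))

  # connected-component count preserved for separated blobs
  blobs <- matrix(FALSE, 40, 40)
  blobs[5:12, 5:12] <- TRUE; blobs[25:33, 20:30] <- TRUE
  skb <- extract_centerline(blobs)
  lab_in <- EBImage::bwlabel(EBImage::Image(blobs * 1))
  lab_out <- EBImage::bwlabel(EBImage::Image(skb * 1))
  expect_equal(max(lab_out), max(lab_in))
})

test_that("graph reconstruction recovers lines, crossings and arc length", {
  line <- matrix(FALSE, 8, 14); line[4, 3:12] <- TRUE
  g <- reconstruct_graph(line, pixel_size_um = 0.0775)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_um, 9 * 0.0775, tolerance = 1e-12)
  expect_true(all(g$nodes$kind == "endpoint"))

  g2 <- reconstruct_graph(plus_skeleton(), pixel_size_um = 1)
  expect_equal(sum(g2$nodes$kind == "branch"), 1L)
  expect_equal(sum(g2$nodes$kind == "endpoint"), 4L)
  expect_equal(nrow(g2$edges), 4L)
  expect_degree_conservation(g2)

  # arc-length oracle on a thinned random phantom: total edge length equals
  # the brute-force sum of voxel steps (1 or sqrt 2 times pixel size)
  ph <- generate_filament_image(filament_phantom_spec(
    field_size_px = c(96, 96), n_seeds = 4, noise_sd = 0,
    branch_rate_per_um = 0.3, seed = 21))
  mask <- ph$image$intensities > 30
  sk <- extract_centerline(mask)
  g3 <- reconstruct_graph(sk, pixel_size_um = 0.0775)
  total <- sum(g3$edges$length_um)
  # brute force: walk every polyline vertex pair
  brute <- 0
  for (v in g3$polylines) brute <- brute + polyline_length(v)
  expect_equal(total, brute, tolerance = 1e-6)
  # every step between consecutive skeleton vertices is a king move
  for (v in g3$polylines) {
    steps <- sqrt(rowSums(diff(v / 0.0775)^2))
    expect_true(all(abs(steps - 1) < 1e-9 | abs(steps - sqrt(2)) < 1e-9))
  }
  expect_degree_conservation(g3)
})

test_that("branch-point merging clusters adjacent branch voxels", {
  g <- toy_two_branch_graph(gap_px = 1)
  expect_identical(merge_branch_points(g, 0), g)

  gm <- merge_branch_points(g, 2)
  expect_equal(sum(gm$nodes$kind == "branch"), 1L)
  expect_equal(nrow(gm$edges), 4L)           # stub deleted, spokes kept
  expect_degree_conservation(gm)
  # oracle: exhaustive pairwise Chebyshev clustering of the two branch nodes
  b <- g$nodes[g$nodes$kind == "branch", ]
  cheb <- max(abs(b$x_um[1] - b$x_um[2]), abs(b$y_um[1] - b$y_um[2]))
  expect_true(cheb <= 2)                      # so they must merge
  # merged node sits at the centroid
  mb <- gm$nodes[gm$nodes$kind == "branch", ]
  expect_equal(mb$x_um, mean(b$x_um), tolerance = 1e-9)
  expect_equal(mb$y_um, mean(b$y_um), tolerance = 1e-9)

  far <- toy_two_branch_graph(gap_px = 10)
  gf <- merge_branch_points(far, 2)
  expect_equal(sum(gf$nodes$kind == "branch"), 2L)
  expect_equal(nrow(gf$edges), 5L)
})

test_that("polyline smoothing shortens staircase edges toward the diagonal", {
  g <- toy_two_branch_graph(gap_px = 10)
  expect_identical(smooth_polylines(g, 1), g)
  expect_error(smooth_polylines(g, 4), "odd")

  # straight line: unchanged
  line <- filament_graph(
    nodes = data.frame(id = 1:2, x_um = c(0, 10), y_um = c(0, 0),
                       kind = "endpoint"),
    edges = data.frame(edge_id = 1, node_a = 1, node_b = 2,
                       length_um = 10),
    polylines = list(cbind(x_um = seq(0, 10, by = 0.5), y_um = 0)),
    pixel_size_um = 1)
  expect_equal(smooth_polylines(line, 5)$edges$length_um, 10,
               tolerance = 1e-12)

  # 100-step staircase approximating the diagonal of a square
  n <- 100
  xs <- rep(seq_len(n), each = 2)[-1]
  ys <- rep(seq_len(n), each = 2)[-2 * n]
  stair <- filament_graph(
    nodes = data.frame(id = 1:2, x_um = c(1, n), y_um = c(1, n),
                       kind = "endpoint"),
    edges = data.frame(edge_id = 1, node_a = 1, node_b = 2,
                       length_um = 2 * (n - 1)),
    polylines = list(cbind(x_um = xs, y_um = ys)),
    pixel_size_um = 1)
  true_len <- sqrt(2) * (n - 1)
  raw_len <- polyline_length(stair$polylines[[1]])
  sm_len <- smooth_polylines(stair, 5)$edges$length_um
  expect_equal(raw_len / true_len, sqrt(2), tolerance = 1e-9)
  expect_lt(abs(sm_len - true_len), abs(raw_len - true_len))
  expect_lt(abs(sm_len / true_len - 1), 0.02)
})

test_that("branch-length distributions follow the edge classification", {
  g <- toy_two_branch_graph(gap_px = 10)
  bl <- branch_lengths(g, include_endpoint_edges = FALSE,
                       prune_floor_px = 3)
  expect_equal(nrow(bl), 1L)                 # only the branch-branch edge
  expect_equal(bl$length_um, 10, tolerance = 1e-9)
  expect_equal(bl$class, "branch-branch")

  plus <- reconstruct_graph(plus_skeleton(), pixel_size_um = 1)
  expect_equal(nrow(branch_lengths(plus, include_endpoint_edges = FALSE)),
               0L)
  expect_equal(nrow(branch_lengths(plus, include_endpoint_edges = TRUE)),
               4L)
  empty <- reconstruct_graph(matrix(FALSE, 5, 5))
  expect_equal(nrow(branch_lengths(empty)), 0L)
})

test_that("the full pipeline recovers single-filament length within 5%", {
  for (len in c(15, 40)) {
    ph <- straight_filament(len)
    res <- branch_length_pipeline(ph$image, include_endpoint_edges = TRUE)
    expect_equal(nrow(res$graph$edges), 1L)
    expect_equal(res$lengths$length_um, len, tolerance = 0.05)
  }
})

test_that("pipeline-recovered mean branch length tracks the ground truth", {
  # sparse phantoms (crossings between independent filaments would create
  # image junctions the ground-truth graph rightly does not contain), with
  # one common 1 um length floor applied to both sides so that edges at
  # the optical resolution limit do not dominate the comparison
  floor_um <- 1
  rel_err <- vapply(1:20, function(i) {
    ph <- generate_filament_image(filament_phantom_spec(
      field_size_px = c(240, 240), n_seeds = 2, filament_length_um = 14,
      branch_rate_per_um = 0.2, step_persistence = 0.99,
      noise_sd = 1, seed = 600 + i))
    res <- branch_length_pipeline(ph$image, include_endpoint_edges = TRUE,
                                  prune_floor_px = floor_um / 0.0775)
    gt <- ph$graph$edges$length_um
    gt <- gt[gt > floor_um]
    (mean(res$lengths$length_um) - mean(gt)) / mean(gt)
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.10)
})

test_that("higher branch rates shorten recovered branch lengths", {
  rates <- c(0.05, 0.15, 0.3, 0.5, 0.8)
  means <- vapply(rates, function(rt) {
    mean(vapply(1:6, function(i) {
      ph <- generate_filament_image(filament_phantom_spec(
        field_size_px = c(144, 144), n_seeds = 4, filament_length_um = 9,
        branch_rate_per_um = rt, step_persistence = 0.97, noise_sd = 1,
        seed = 700 + i))
      res <- branch_length_pipeline(ph$image,
                                    include_endpoint_edges = TRUE)
      if (nrow(res$lengths)) mean(res$lengths$length_um) else NA_real_
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  rho <- stats::cor(rates, means, method = "spearman")
  expect_lt(rho, 0)
})
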