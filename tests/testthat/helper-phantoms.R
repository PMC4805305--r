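# Shared fixtures, built in code at test time.

# a single straight horizontal filament of known length (noise-free)
straight_filament <- function(length_um = 40, pixel_size_um = 0.0775,
                              seed = 7) {
  npx <- ceiling(length_um / pixel_size_um)
  generate_filament_image(filament_phantom_spec(
    field_size_px = c(80, npx + 60),
    pixel_size_um = pixel_size_um,
    n_seeds = 1, step_persistence = 1, branch_rate_per_um = 0,
    noise_sd = 0, background = 0,
    filament_length_um = length_um,
    init_positions = matrix(c(20, 40), 1),
    init_direction_rad = 0, seed = seed))
}

# plus-sign skeleton: two 11-voxel lines crossing at the centre
plus_skeleton <- function(n = 21) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1) / 2
  m[c0, (c0 - 5):(c0 + 5)] <- TRUE
  m[(c0 - 5):(c0 + 5), c0] <- TRUE
  m
}

# hand-built toy graph: two branch nodes `gap_px` apart joined by a stub,
# each with two further spokes to endpoints
toy_two_branch_graph <- function(gap_px = 1, ps = 1) {
  seg <- function(x0, y0, x1, y1, n = 6) {
    cbind(x_um = seq(x0, x1, length.out = n) * ps,
          y_um = seq(y0, y1, length.out = n) * ps)
  }
  b1 <- c(10, 10); b2 <- c(10 + gap_px, 10)
  nodes <- data.frame(
    id = 1:6,
    x_um = c(b1[1], b2[1], 0, 10, 20 + gap_px, 10 + gap_px) * ps,
    y_um = c(b1[2], b2[2], 10, 0, 10, 20) * ps,
    kind = c("branch", "branch", rep("endpoint", 4)))
  polys <- list(
    seg(b1[1], b1[2], b2[1], b2[2], 2),     # stub between the branches
    seg(b1[1], b1[2], 0, 10),
    seg(b1[1], b1[2], 10, 0),
    seg(b2[1], b2[2], 20 + gap_px, 10),
    seg(b2[1], b2[2], 10 + gap_px, 20))
  edges <- data.frame(
    edge_id = 1:5,
    node_a = c(1, 1, 1, 2, 2),
    node_b = c(2, 3, 4, 5, 6),
    length_um = vapply(polys, polyline_length, numeric(1)))
  filament_graph(nodes, edges, polys, pixel_size_um = ps)
}

# degree-conservation helper: sum of degrees == 2 * edge-endpoint count
expect_degree_conservation <- function(g) {
  expect_equal(sum(node_degrees(g)), 2L * nrow(g$edges))
}

# gross bulk flow of a signed rate map
gross_flow <- function(v) (sum(v[v > 0]) + sum(abs(v[v < 0]))) / 2
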