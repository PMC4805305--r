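#' Specification of a branched filament phantom
#'
#' Parameters of the persistent-random-walk filament generator used to test
#' the branch-length morphometry pipeline. Filaments are grown as unit-pixel
#' steps whose heading receives Gaussian turns; branching is a Poisson
#' process along arc length. Rasterization stamps the polylines with a
#' Gaussian cross-section.
#'
#' @param field_size_px Integer pair (rows, cols) of the output image.
#' @param pixel_size_um Pixel edge length in micrometres (default 0.0775,
#'   i.e. a 79.3 um field at 1024 px).
#' @param n_seeds Number of independent filament seeds.
#' @param step_persistence In `[0, 1]`; 1 gives perfectly straight growth.
#'   The per-step turn SD is `(1 - step_persistence) * pi / 3` radians.
#' @param branch_rate_per_um Poisson branching rate per micrometre of arc.
#' @param filament_sigma_px Gaussian cross-section SD in pixels.
#' @param intensity_peak Centreline peak intensity of a filament.
#' @param background Constant background level.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param filament_length_um Arc-length budget of each seed filament;
#'   branches inherit half of the remaining parent budget.
#' @param init_positions Optional n x 2 matrix of seed positions
#'   (x, y in px, 1-based); default uniform in the field interior.
#' @param init_direction_rad Optional fixed initial heading (radians,
#'   0 = +x); default uniform.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A `filament_phantom_spec`.
#' @export
filament_phantom_spec <- function(field_size_px = c(256, 256),
                                  pixel_size_um = 0.0775,
                                  n_seeds = 10,
                                  step_persistence = 0.95,
                                  branch_rate_per_um = 0.15,
                                  filament_sigma_px = 1.5,
                                  intensity_peak = 100,
                                  background = 10,
                                  noise_sd = 2,
                                  filament_length_um = 15,
                                  init_positions = NULL,
                                  init_direction_rad = NULL,
                                  seed = 1L) {
  if (length(field_size_px) == 1) field_size_px <- rep(field_size_px, 2)
  if (any(field_size_px <= 0))
    stop("invalid spec: field_size_px must be positive", call. = FALSE)
  if (n_seeds < 0) stop("invalid spec: n_seeds >= 0 required", call. = FALSE)
  if (step_persistence < 0 || step_persistence > 1)
    stop("invalid spec: step_persistence in [0,1]", call. = FALSE)
  if (branch_rate_per_um < 0 || filament_sigma_px <= 0 || noise_sd < 0 ||
      background < 0 || intensity_peak <= 0 || pixel_size_um <= 0)
    stop("invalid spec: negative or non-positive parameter", call. = FALSE)
  structure(as.list(environment()), class = "filament_phantom_spec")
}

#' Generate a filament phantom image with ground-truth graph
#'
#' Grows persistent random walks, rasterizes them with a Gaussian
#' cross-section, and returns both the image and the exact filament graph
#' (nodes at seeds' ends and branch events, polyline edges with arc lengths
#' in micrometres).
#'
#' @param spec A [filament_phantom_spec()].
#' @return List with elements `image` (a [raster_image()]) and
#'   `graph` (a [filament_graph()]).
#' @export
generate_filament_image <- function(spec) {
  stopifnot(inherits(spec, "filament_phantom_spec"))
  withr::with_seed(spec$seed, generate_filament_image_impl(spec))
}

generate_filament_image_impl <- function(spec) {
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  ps <- spec$pixel_size_um
  step_um <- ps                       # one pixel per step
  turn_sd <- (1 - spec$step_persistence) * pi / 3
  p_branch <- spec$branch_rate_per_um * step_um

  nodes <- list(); edges <- list()
  new_node <- function(pos, kind) {
    nodes[[length(nodes) + 1]] <<- list(pos = pos, kind = kind)
    length(nodes)
  }
  # walker queue: list(pos=c(x,y) px, dir rad, budget_um, start_node)
  queue <- list()
  if (spec$n_seeds > 0) {
    for (s in seq_len(spec$n_seeds)) {
      pos <- if (!is.null(spec$init_positions)) {
        as.numeric(spec$init_positions[s, ])
      } else {
        c(stats::runif(1, 2, nc - 1), stats::runif(1, 2, nr - 1))
      }
      dir <- if (!is.null(spec$init_direction_rad)) spec$init_direction_rad
             else stats::runif(1, 0, 2 * pi)
      queue[[length(queue) + 1]] <- list(
        pos = pos, dir = dir, budget = spec$filament_length_um,
        start_node = new_node(pos, "endpoint"))
    }
  }
  max_walkers <- 20L * max(spec$n_seeds, 1L) + 200L
  n_walked <- 0L
  while (length(queue) > 0 && n_walked < max_walkers) {
    w <- queue[[1]]; queue[[1]] <- NULL
    n_walked <- n_walked + 1L
    verts <- list(w$pos)
    arc <- 0
    pos <- w$pos; dir <- w$dir
    start_node <- w$start_node
    repeat {
      ds <- min(step_um, w$budget - arc)
      if (ds <= 1e-12) { end_kind <- "endpoint"; break }
      dir <- dir + stats::rnorm(1, 0, turn_sd)
      cand <- pos + (ds / ps) * c(cos(dir), sin(dir))
      if (cand[1] < 1 || cand[1] > nc || cand[2] < 1 || cand[2] > nr) {
        # clip the final step at the field boundary
        tmax <- 1
        for (ax in 1:2) {
          d <- cand[ax] - pos[ax]
          lim <- if (ax == 1) nc else nr
          if (d > 0 && cand[ax] > lim) tmax <- min(tmax, (lim - pos[ax]) / d)
          if (d < 0 && cand[ax] < 1) tmax <- min(tmax, (1 - pos[ax]) / d)
        }
        tmax <- max(tmax, 0)
        pos <- pos + tmax * (cand - pos)
        arc <- arc + ds * tmax
        verts[[length(verts) + 1]] <- pos
        end_kind <- "endpoint"
        break
      }
      pos <- cand
      arc <- arc + ds
      verts[[length(verts) + 1]] <- pos
      branch_here <- spec$branch_rate_per_um > 0 &&
        stats::runif(1) < p_branch * (ds / step_um)
      if (branch_here) {
        bn <- new_node(pos, "branch")
        edges[[length(edges) + 1]] <- list(
          a = start_node, b = bn, verts = do.call(rbind, verts))
        # continue parent from the branch node; spawn one child
        child_dir <- dir + sample(c(-1, 1), 1) * stats::rnorm(1, pi / 3, pi / 18)
        child_budget <- (w$budget - arc) / 2
        if (child_budget > 2 * step_um) {
          queue[[length(queue) + 1]] <- list(
            pos = pos, dir = child_dir, budget = child_budget,
            start_node = bn)
        }
        start_node <- bn
        verts <- list(pos)
      }
    }
    en <- new_node(pos, end_kind)
    vm <- do.call(rbind, verts)
    if (nrow(vm) >= 2) {
      edges[[length(edges) + 1]] <- list(a = start_node, b = en, verts = vm)
    }
  }

  graph <- phantom_graph(nodes, edges, ps)
  img <- rasterize_polylines(
    lapply(edges, `[[`, "verts"), nr, nc,
    sigma = spec$filament_sigma_px, peak = spec$intensity_peak)
  img <- img + spec$background
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  list(image = raster_image(img, ps), graph = graph)
}

# assemble a filament_graph from the generator's node/edge records
phantom_graph <- function(nodes, edges, ps) {
  if (length(nodes) == 0) {
    return(filament_graph(
      nodes = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                         kind = character()),
      edges = data.frame(edge_id = integer(), node_a = integer(),
                         node_b = integer(), length_um = numeric()),
      polylines = list(), pixel_size_um = ps))
  }
  nd <- data.frame(
    id = seq_along(nodes),
    x_um = vapply(nodes, function(n) (n$pos[1] - 1) * ps, numeric(1)),
    y_um = vapply(nodes, function(n) (n$pos[2] - 1) * ps, numeric(1)),
    kind = vapply(nodes, `[[`, character(1), "kind"))
  polys <- lapply(edges, function(e) {
    v <- e$verts
    cbind(x_um = (v[, 1] - 1) * ps, y_um = (v[, 2] - 1) * ps)
  })
  ed <- data.frame(
    edge_id = seq_along(edges),
    node_a = vapply(edges, function(e) e$a, numeric(1)),
    node_b = vapply(edges, function(e) e$b, numeric(1)),
    length_um = vapply(polys, polyline_length, numeric(1)))
  filament_graph(nd, ed, polys, pixel_size_um = ps)
}

# stamp polylines (px coordinates) with a Gaussian cross-section so the
# centreline of a long filament reaches `peak`
rasterize_polylines <- function(polys, nr, nc, sigma, peak) {
  acc <- matrix(0, nr, nc)
  ds <- 0.5                          # resample spacing in px
  for (v in polys) {
    if (is.null(dim(v)) || nrow(v) < 2) next
    seg <- diff(v)
    lens <- sqrt(rowSums(seg^2))
    total <- sum(lens)
    if (total <= 0) next
    s <- seq(0, total, by = ds)
    cum <- c(0, cumsum(lens))
    idx <- findInterval(s, cum, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), nrow(seg))
    frac <- (s - cum[idx]) / pmax(lens[idx], 1e-12)
    px <- v[idx, 1] + frac * seg[idx, 1]
    py <- v[idx, 2] + frac * seg[idx, 2]
    # bilinear splat of mass ds per sample
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    for (k in 1:4) {
      xx <- x0 + (k == 2 | k == 4)
      yy <- y0 + (k >= 3)
      wgt <- (if (k %% 2 == 1) 1 - fx else fx) * (if (k <= 2) 1 - fy else fy)
      ok <- xx >= 1 & xx <= nc & yy >= 1 & yy <= nr
      if (any(ok)) {
        lin <- (xx[ok] - 1) * nr + yy[ok]
        add <- tapply(wgt[ok] * ds, lin, sum)
        acc[as.integer(names(add))] <- acc[as.integer(names(add))] + add
      }
    }
  }
  # unit linear density blurred by a 2D Gaussian peaks at 1 / (sqrt(2*pi)*sigma)
  blurred <- gaussian_blur_mat(acc, sigma)
  blurred * peak * sqrt(2 * pi) * sigma
}

#' Specification of an inward-transport time-lapse phantom
#'
#' Emulates the keratin cycle as seen in live-cell recordings: a textured
#' intensity field inside a circular cell is advected inward each frame with
#' a speed that peaks in the periphery and vanishes at the centre; an
#' assembly (source) annulus near the periphery gains intensity and a
#' disassembly (sink) annulus around the nucleus loses intensity.
#'
#' @param field_size_px Integer pair (rows, cols) of each frame.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Acquisition interval in seconds (default 30).
#' @param cell_radius_px Cell radius in pixels.
#' @param speed_profile Function of normalized radius `rho` in `[0, 1]`
#'   returning the inward speed in px/frame; must vanish at `rho = 0`.
#'   Default `1.5 * rho^2` (peripheral maximum).
#' @param source_annulus List `(r = c(lo, hi), rate)`: normalized-radius
#'   interval and assembly rate in intensity units per minute.
#' @param sink_annulus Same for disassembly (rate is the magnitude).
#' @param base_intensity Mean intensity inside the cell.
#' @param texture_sigma_px,texture_contrast Smoothing and amplitude of the
#'   static random texture that makes block matching possible.
#' @param background Intensity outside the cell.
#' @param noise_sd Per-frame additive Gaussian noise SD.
#' @param uniform_shift_px Optional `(dx, dy)` px/frame: replaces the radial
#'   field with a uniform translation (debug mode, no source/sink).
#' @param seed RNG seed.
#' @return A `flow_phantom_spec`.
#' @export
flow_phantom_spec <- function(field_size_px = c(192, 192),
                              n_frames = 10,
                              frame_interval_s = 30,
                              cell_radius_px = 80,
                              speed_profile = function(rho) 1.5 * rho^2,
                              source_annulus = list(r = c(0.70, 0.95), rate = 3),
                              sink_annulus = list(r = c(0.15, 0.40), rate = 3),
                              base_intensity = 100,
                              texture_sigma_px = 2,
                              texture_contrast = 40,
                              background = 2,
                              noise_sd = 0,
                              uniform_shift_px = NULL,
                              seed = 1L) {
  if (length(field_size_px) == 1) field_size_px <- rep(field_size_px, 2)
  if (n_frames < 2)
    stop("invalid spec: n_frames >= 2 required", call. = FALSE)
  if (cell_radius_px <= 0 || frame_interval_s <= 0 || noise_sd < 0)
    stop("invalid spec: non-positive geometry or negative noise", call. = FALSE)
  vmax <- max(speed_profile(seq(0, 1, length.out = 101)))
  if (vmax >= cell_radius_px)
    stop("invalid spec: per-frame speed exceeds the cell radius", call. = FALSE)
  structure(as.list(environment()), class = "flow_phantom_spec")
}

#' Generate an inward-transport time-lapse with ground truth
#'
#' Advects the initial texture frame by frame with a semi-Lagrangian
#' backtrace (bilinear sampling), applies the source and sink rates, then
#' adds fresh per-frame noise. The clean state is propagated internally so
#' noise does not accumulate.
#'
#' @param spec A [flow_phantom_spec()].
#' @return List with `movie` (a [time_lapse()] with `cell_mask` set),
#'   `flow_truth` (list of matrices `vx`, `vy`, px/frame, content motion)
#'   and `turnover_truth` (matrix, intensity units per minute).
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "flow_phantom_spec"))
  withr::with_seed(spec$seed, generate_timelapse_impl(spec))
}

generate_timelapse_impl <- function(spec) {
  nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  rr <- sqrt((X - cx)^2 + (Y - cy)^2)
  rho <- rr / spec$cell_radius_px
  mask <- rho <= 1

  # static texture: smoothed positive noise inside the cell
  tex <- gaussian_blur_mat(matrix(stats::rnorm(nr * nc), nr, nc),
                           spec$texture_sigma_px)
  tex <- tex / stats::sd(tex)
  frame0 <- matrix(spec$background, nr, nc)
  frame0[mask] <- pmax(spec$base_intensity + spec$texture_contrast * tex[mask], 0)

  dmin <- spec$frame_interval_s / 60
  if (!is.null(spec$uniform_shift_px)) {
    dx <- spec$uniform_shift_px[1]; dy <- spec$uniform_shift_px[2]
    vx <- matrix(dx, nr, nc); vy <- matrix(dy, nr, nc)
    turnover <- matrix(0, nr, nc)
  } else {
    sp <- spec$speed_profile(pmin(rho, 1))
    sp[rho > 1] <- 0
    ux <- ifelse(rr > 0, (X - cx) / pmax(rr, 1e-9), 0)
    uy <- ifelse(rr > 0, (Y - cy) / pmax(rr, 1e-9), 0)
    vx <- -sp * ux                     # content moves inward
    vy <- -sp * uy
    turnover <- matrix(0, nr, nc)
    sa <- spec$source_annulus; ka <- spec$sink_annulus
    turnover[rho >= sa$r[1] & rho <= sa$r[2]] <- sa$rate
    turnover[rho >= ka$r[1] & rho <= ka$r[2]] <-
      turnover[rho >= ka$r[1] & rho <= ka$r[2]] - ka$rate
    turnover[!mask] <- 0
  }

  frames <- vector("list", spec$n_frames)
  state <- frame0
  emit <- function(m) {
    if (spec$noise_sd > 0)
      m + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc) else m
  }
  frames[[1]] <- emit(state)
  for (t in 2:spec$n_frames) {
    # semi-Lagrangian: new(x) = old(x - v(x))
    state <- matrix(
      bilinear_sample(state, as.vector(Y - vy), as.vector(X - vx),
                      fill = spec$background),
      nr, nc)
    state <- state + turnover * dmin
    state[mask] <- pmax(state[mask], 0)
    frames[[t]] <- emit(state)
  }
  movie <- time_lapse(frames, frame_interval_s = spec$frame_interval_s,
                      cell_mask = mask)
  list(movie = movie,
       flow_truth = list(vx = vx, vy = vy),
       turnover_truth = turnover)
}

#' Specification of a synthetic AFM force-distance curve
#'
#' Approach curve of a spherical probe indenting a cell: a linear baseline
#' before contact and a power law `F = A * delta^b` beyond it, with `delta`
#' in metres and `A` in the N/m^2 convention used for apparent stiffness.
#'
#' @param stiffness_A Apparent stiffness `A` (N/m^2 convention, force in N
#'   for indentation in metres).
#' @param exponent_b Power-law exponent (1.8 is the fixed-exponent default
#'   used for apparent stiffness `A_1.8`).
#' @param max_indentation_nm Deepest indentation generated.
#' @param contact_offset_nm Piezo position of the contact point.
#' @param pre_contact_nm Length of the pre-contact baseline segment.
#' @param baseline_slope Baseline slope in nN per nm (drift; default 0).
#' @param baseline_noise_nN Additive force noise SD applied everywhere.
#' @param noise_fraction Multiplicative Gaussian noise on the post-contact
#'   power-law force.
#' @param n_points Number of samples along the approach.
#' @param setpoint_nN Force setpoint; fitting only uses data below it.
#' @param spring_constant Cantilever spring constant k in N/m (default 0.04).
#' @param seed RNG seed.
#' @return An `fd_curve_spec`.
#' @export
fd_curve_spec <- function(stiffness_A = 111,
                          exponent_b = 1.8,
                          max_indentation_nm = 600,
                          contact_offset_nm = 0,
                          pre_contact_nm = 500,
                          baseline_slope = 0,
                          baseline_noise_nN = 0.01,
                          noise_fraction = 0,
                          n_points = 400,
                          setpoint_nN = 1.5,
                          spring_constant = 0.04,
                          seed = 1L) {
  if (exponent_b <= 0)
    stop("invalid spec: exponent_b must be positive", call. = FALSE)
  if (stiffness_A <= 0 || max_indentation_nm <= 0 || n_points < 10 ||
      noise_fraction < 0 || baseline_noise_nN < 0)
    stop("invalid spec: bad force-curve parameter", call. = FALSE)
  structure(as.list(environment()), class = "fd_curve_spec")
}

#' Generate a synthetic force-distance curve
#'
#' @param spec An [fd_curve_spec()].
#' @return A `force_distance_curve`: list with `data`
#'   (data frame `z_nm`, `force_nN`), `spring_constant`, `setpoint_nN` and
#'   a `truth` record of the generating parameters.
#' @export
generate_fd_curve <- function(spec) {
  stopifnot(inherits(spec, "fd_curve_spec"))
  withr::with_seed(spec$seed, {
    z <- seq(spec$contact_offset_nm - spec$pre_contact_nm,
             spec$contact_offset_nm + spec$max_indentation_nm,
             length.out = spec$n_points)
    delta_nm <- pmax(z - spec$contact_offset_nm, 0)
    f_pl <- spec$stiffness_A * (delta_nm * 1e-9)^spec$exponent_b * 1e9  # nN
    if (spec$noise_fraction > 0) {
      eps <- stats::rnorm(length(z), 0, spec$noise_fraction)
      f_pl <- f_pl * (1 + eps)
    }
    f <- spec$baseline_slope * (z - spec$contact_offset_nm) + f_pl
    if (spec$baseline_noise_nN > 0)
      f <- f + stats::rnorm(length(z), 0, spec$baseline_noise_nN)
    structure(
      list(data = data.frame(z_nm = z, force_nN = f),
           spring_constant = spec$spring_constant,
           setpoint_nN = spec$setpoint_nN,
           truth = list(A = spec$stiffness_A, b = spec$exponent_b,
                        contact_nm = spec$contact_offset_nm)),
      class = "force_distance_curve")
  })
}

#' Specification of a magnetic-tweezers bead track
#'
#' Rectangular force pulses (default 5 s on in a 10 s period) drive a
#' power-law creep displacement `x(t) = F * J0 * (t / t0)^beta` measured
#' from pulse onset; between pulses the bead relaxes exponentially toward
#' its baseline.
#'
#' @param J0 Creep compliance at the reference time `t0` (um/nN).
#' @param beta Power-law exponent in `[0, 1]`.
#' @param t0_s Reference time (default 1 s).
#' @param pulse_on_s Force-on duration (default 5 s).
#' @param pulse_period_s Pulse repetition period (default 10 s).
#' @param n_pulses Number of pulses.
#' @param force_nN Pulse force amplitude in nN.
#' @param fps Sampling rate in frames per second (default 50).
#' @param tracking_noise_um Additive position noise SD.
#' @param noise_fraction Multiplicative noise on the creep displacement.
#' @param relax_tau_s Off-pulse exponential relaxation time constant.
#' @param lead_in_s Quiet time before the first pulse (baseline window).
#' @param seed RNG seed.
#' @return A `bead_track_spec`.
#' @export
bead_track_spec <- function(J0 = 0.33,
                            beta = 0.232,
                            t0_s = 1.0,
                            pulse_on_s = 5,
                            pulse_period_s = 10,
                            n_pulses = 6,
                            force_nN = 1,
                            fps = 50,
                            tracking_noise_um = 0,
                            noise_fraction = 0,
                            relax_tau_s = 0.5,
                            lead_in_s = 2,
                            seed = 1L) {
  if (pulse_on_s >= pulse_period_s)
    stop("invalid spec: pulse_on_s must be shorter than pulse_period_s",
         call. = FALSE)
  if (fps * pulse_on_s < 5)
    stop("invalid spec: fewer than 5 samples per pulse", call. = FALSE)
  if (J0 <= 0 || beta < 0 || beta > 1 || t0_s <= 0 || n_pulses < 1 ||
      force_nN <= 0)
    stop("invalid spec: bad creep parameter", call. = FALSE)
  structure(as.list(environment()), class = "bead_track_spec")
}

#' Generate a synthetic bead track and its force trace
#'
#' @param spec A [bead_track_spec()].
#' @return A `bead_track`: list with `data` (data frame `t_s`, `x_um`,
#'   `force_nN`), `fps`, the pulse `schedule` (data frame `onset_s`,
#'   `offset_s`) and a `truth` record.
#' @export
generate_bead_track <- function(spec) {
  stopifnot(inherits(spec, "bead_track_spec"))
  withr::with_seed(spec$seed, {
    dur <- spec$lead_in_s + spec$n_pulses * spec$pulse_period_s
    t <- seq(0, dur, by = 1 / spec$fps)
    onset <- spec$lead_in_s + (seq_len(spec$n_pulses) - 1) * spec$pulse_period_s
    offset <- onset + spec$pulse_on_s
    x <- numeric(length(t))
    force <- numeric(length(t))
    for (p in seq_len(spec$n_pulses)) {
      # force is on for t in [onset, offset] inclusive, so a 5 s pulse at
      # 50 fps carries 250 samples with t - onset in (0, 5]
      on <- t >= onset[p] & t <= offset[p]
      after <- t > offset[p]
      tau_rel <- (t[on] - onset[p]) / spec$t0_s
      creep <- spec$force_nN * spec$J0 * tau_rel^spec$beta
      if (spec$noise_fraction > 0)
        creep <- creep * (1 + stats::rnorm(length(creep), 0, spec$noise_fraction))
      x[on] <- x[on] + creep
      peak <- spec$force_nN * spec$J0 *
        (spec$pulse_on_s / spec$t0_s)^spec$beta
      x[after] <- x[after] +
        peak * exp(-(t[after] - offset[p]) / spec$relax_tau_s)
      force[on] <- spec$force_nN
    }
    if (spec$tracking_noise_um > 0)
      x <- x + stats::rnorm(length(x), 0, spec$tracking_noise_um)
    structure(
      list(data = data.frame(t_s = t, x_um = x, force_nN = force),
           fps = spec$fps,
           schedule = data.frame(onset_s = onset, offset_s = offset),
           truth = list(J0 = spec$J0, beta = spec$beta, t0_s = spec$t0_s)),
      class = "bead_track")
  })
}
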