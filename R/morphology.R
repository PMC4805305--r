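#' Gaussian denoising
#'
#' Discrete Gaussian convolution with reflective boundary handling;
#' `sigma_px = 0` is the identity.
#'
#' @param img A [raster_image()] or numeric matrix.
#' @param sigma_px Non-negative Gaussian SD in pixels.
#' @return Same type as `img`.
#' @export
gaussian_denoise <- function(img, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px < 0)
    stop("`sigma_px` must be a single non-negative number", call. = FALSE)
  m <- as_intensity(img)
  out <- gaussian_blur_mat(m, sigma_px)
  if (inherits(img, "raster_image")) raster_image(out, img$pixel_size_um)
  else out
}

#' Optimally oriented flux filter
#'
#' Enhances curvilinear structures. At each pixel and probe radius `r` the
#' symmetric oriented-flux matrix `Q(x; r)` is assembled, whose quadratic
#' form in a direction is the outward flux of the image gradient projected
#' on that direction through the circle of radius `r` centred at `x`
#' (normalized by the circle's boundary measure). For bright ridges the
#' per-scale response is `max(0, -lambda_min)` of `Q`; the returned response
#' is the maximum over the probed radii.
#'
#' @details The matrix entries are computed by spectral-domain convolution:
#' for probe radius `r` the Fourier multiplier of the boundary-normalized
#' flux sampler is `-u_i u_j J_1(r |u|) / |u|` (first-order Bessel), which
#' keeps the response rotation invariant. The image is treated as periodic;
#' keep structures of interest away from the border by at least the largest
#' radius.
#'
#' @param img A [raster_image()] or matrix, already Gaussian-smoothed.
#' @param radii_px Probe radii in pixels (>= 1).
#' @return An `oof_response`: list with `response` (matrix, >= 0),
#'   `radii_px`, and `argmax_radius` (matrix of the radius attaining the
#'   per-pixel maximum).
#' @export
oof_filter <- function(img, radii_px = c(1, 2, 3, 4, 6, 8)) {
  m <- as_intensity(img)
  if (any(radii_px < 1))
    stop("probe radii must be >= 1 px", call. = FALSE)
  if (max(radii_px) > min(dim(m)) / 2)
    stop("probe radius exceeds half the smallest image extent", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  ihat <- stats::fft(m)
  # angular frequency grids with wraparound
  wy <- 2 * pi * (seq_len(nr) - 1) / nr
  wy[wy > pi] <- wy[wy > pi] - 2 * pi
  wx <- 2 * pi * (seq_len(nc) - 1) / nc
  wx[wx > pi] <- wx[wx > pi] - 2 * pi
  Uy <- matrix(rep(wy, times = nc), nr, nc)
  Ux <- matrix(rep(wx, each = nr), nr, nc)
  umag <- sqrt(Ux^2 + Uy^2)
  safe <- pmax(umag, 1e-12)
  best <- matrix(0, nr, nc)
  argr <- matrix(radii_px[1], nr, nc)
  for (r in radii_px) {
    bess <- besselJ(r * umag, 1) / safe
    bess[umag == 0] <- 0
    q11 <- Re(stats::fft(-ihat * Ux * Ux * bess, inverse = TRUE)) / (nr * nc)
    q12 <- Re(stats::fft(-ihat * Ux * Uy * bess, inverse = TRUE)) / (nr * nc)
    q22 <- Re(stats::fft(-ihat * Uy * Uy * bess, inverse = TRUE)) / (nr * nc)
    mid <- (q11 + q22) / 2
    disc <- sqrt(((q11 - q22) / 2)^2 + q12^2)
    resp <- pmax(0, -(mid - disc))
    upd <- resp > best
    argr[upd] <- r
    best[upd] <- resp[upd]
  }
  structure(list(response = best, radii_px = radii_px, argmax_radius = argr),
            class = "oof_response")
}

#' Binarize a filter response
#'
#' @param resp An `oof_response`, [raster_image()] or matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold value, required when `method = "fixed"`.
#' @return Logical matrix with attribute `threshold`.
#' @export
binarize <- function(resp, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  m <- if (inherits(resp, "oof_response")) resp$response else as_intensity(resp)
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("`fixed_threshold` required for method = \"fixed\"", call. = FALSE)
    thr <- fixed_threshold
  } else {
    rng <- range(m)
    if (diff(rng) <= 0)
      stop("degenerate input: constant response has no Otsu threshold",
           call. = FALSE)
    scaled <- (m - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                           levels = 256L)
    thr <- rng[1] + thr01 * diff(rng)
  }
  mask <- m > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Topology-preserving centreline extraction
#'
#' Morphological thinning (Zhang-Suen two-subiteration scheme, 8-connected
#' foreground) reducing every structure in the mask to unit width. Skeleton
#' pixels are a subset of the mask and the number of connected components is
#' preserved.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same dimension.
#' @export
extract_centerline <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  b <- mask > 0
  if (!any(b)) return(b)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- zs_deletable(b, sub)
      if (any(del)) {
        b[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b
}

# One Zhang-Suen subiteration: logical matrix of deletable pixels.
zs_deletable <- function(b, sub) {
  nr <- nrow(b); nc <- ncol(b)
  z <- matrix(FALSE, nr + 2L, nc + 2L)
  z[2:(nr + 1), 2:(nc + 1)] <- b
  core <- function(dy, dx) z[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  # neighbours clockwise from north (P2..P9); rows are y, +1 row = +1 y
  p2 <- core(-1, 0); p3 <- core(-1, 1); p4 <- core(0, 1); p5 <- core(1, 1)
  p6 <- core(1, 0); p7 <- core(1, -1); p8 <- core(0, -1); p9 <- core(-1, -1)
  bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- matrix(0L, nr, nc)
  for (i in 1:8) a <- a + (!seqs[[i]] & seqs[[i + 1]])
  if (sub == 1) {
    cond <- (!p2 | !p4 | !p6) & (!p4 | !p6 | !p8)
  } else {
    cond <- (!p2 | !p4 | !p8) & (!p2 | !p6 | !p8)
  }
  b & bn >= 2 & bn <= 6 & a == 1 & cond
}

#' Reconstruct a filament graph from a skeleton
#'
#' Classifies skeleton pixels by 8-neighbour count (1 = endpoint, >= 3 =
#' branch voxel), traces the paths between node pixels into polyline edges
#' in physical units, and turns node-free cycles into self-edges. Clusters
#' of adjacent branch voxels are left as individual nodes; merge them with
#' [merge_branch_points()].
#'
#' @param skeleton Logical matrix (1 px wide structures).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return A [filament_graph()].
#' @export
reconstruct_graph <- function(skeleton, pixel_size_um = 0.0775) {
  b <- skeleton > 0
  nr <- nrow(b); nc <- ncol(b)
  idx <- which(b)
  if (length(idx) == 0) {
    return(phantom_graph(list(), list(), pixel_size_um))
  }
  ys <- ((idx - 1L) %% nr) + 1L
  xs <- ((idx - 1L) %/% nr) + 1L
  key <- function(y, x) (x - 1L) * nr + y
  lookup <- new.env(hash = TRUE, size = length(idx))
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  offs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  fg <- function(y, x) y >= 1 & y <= nr & x >= 1 & x <= nc & b[key(pmax(pmin(y, nr), 1L), pmax(pmin(x, nc), 1L))]
  nbrs <- function(i) {
    yy <- ys[i] + offs[, 1]; xx <- xs[i] + offs[, 2]
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    ok[ok] <- b[key(yy[ok], xx[ok])]
    # drop redundant diagonal links: a diagonal neighbour already reachable
    # through an orthogonal neighbour shared with it (prevents spurious
    # junctions where two skeleton arms cross)
    for (k in which(ok & offs[, 1] != 0 & offs[, 2] != 0)) {
      if (fg(ys[i] + offs[k, 1], xs[i]) || fg(ys[i], xs[i] + offs[k, 2]))
        ok[k] <- FALSE
    }
    kk <- key(yy[ok], xx[ok])
    vapply(as.character(kk), function(s) get(s, envir = lookup), integer(1),
           USE.NAMES = FALSE)
  }
  nb_list <- lapply(seq_along(idx), nbrs)
  deg <- lengths(nb_list)
  is_node <- deg == 1L | deg >= 3L
  # isolated pixels become lone endpoint nodes
  iso <- deg == 0L

  node_px <- which(is_node | iso)
  node_id <- integer(length(idx))
  node_id[node_px] <- seq_along(node_px)
  nodes <- lapply(node_px, function(i) {
    list(pos = c(xs[i], ys[i]),
         kind = if (deg[i] >= 3L) "branch" else "endpoint")
  })
  edges <- list()
  used <- new.env(hash = TRUE)
  mark <- function(a, via) assign(paste(a, via), TRUE, envir = used)
  seen <- function(a, via) exists(paste(a, via), envir = used)
  visited_path <- logical(length(idx))

  trace_from <- function(start, first) {
    # walk from node pixel `start` through path pixel chain beginning at
    # `first` until another node pixel is reached
    pts <- list(c(xs[start], ys[start]))
    prev <- start; cur <- first
    repeat {
      pts[[length(pts) + 1]] <- c(xs[cur], ys[cur])
      if (is_node[cur]) return(list(end = cur, pts = pts, last = prev))
      visited_path[cur] <<- TRUE
      nxt <- setdiff(nb_list[[cur]], prev)
      if (length(nxt) == 0) {
        # degenerate spur ending on a path pixel (shouldn't occur on thin
        # skeletons); treat terminus as an endpoint-like stop
        return(list(end = cur, pts = pts, last = prev))
      }
      prev <- cur
      cur <- nxt[1]
    }
  }

  for (npix in node_px) {
    if (deg[npix] == 0L) next
    for (first in nb_list[[npix]]) {
      if (seen(npix, first)) next
      mark(npix, first)
      tr <- trace_from(npix, first)
      endpix <- tr$end
      if (is_node[endpix]) {
        # mark the reverse traversal as consumed
        lastbefore <- if (length(tr$pts) >= 2) tr$last else npix
        mark(endpix, lastbefore)
        edges[[length(edges) + 1]] <- list(
          a = node_id[npix], b = node_id[endpix],
          verts = do.call(rbind, tr$pts))
      } else {
        nodes[[length(nodes) + 1]] <- list(pos = c(xs[endpix], ys[endpix]),
                                           kind = "endpoint")
        nid <- length(nodes)
        edges[[length(edges) + 1]] <- list(
          a = node_id[npix], b = nid, verts = do.call(rbind, tr$pts))
      }
    }
  }

  # remaining unvisited path pixels belong to node-free simple cycles
  for (i in seq_along(idx)) {
    if (is_node[i] || iso[i] || visited_path[i]) next
    if (deg[i] != 2L) { visited_path[i] <- TRUE; next }
    # open the cycle at i: it becomes a self-edge anchored at a new node
    nodes[[length(nodes) + 1]] <- list(pos = c(xs[i], ys[i]),
                                       kind = "endpoint")
    nid <- length(nodes)
    pts <- list(c(xs[i], ys[i]))
    visited_path[i] <- TRUE
    prev <- i; cur <- nb_list[[i]][1]
    while (cur != i) {
      pts[[length(pts) + 1]] <- c(xs[cur], ys[cur])
      visited_path[cur] <- TRUE
      nxt <- setdiff(nb_list[[cur]], prev)
      if (length(nxt) == 0) break
      prev <- cur; cur <- nxt[1]
    }
    pts[[length(pts) + 1]] <- c(xs[i], ys[i])
    edges[[length(edges) + 1]] <- list(a = nid, b = nid,
                                       verts = do.call(rbind, pts))
  }

  phantom_graph(nodes, edges, pixel_size_um)
}

#' Merge clustered branch points
#'
#' Thinning can leave a branch point represented by several adjacent branch
#' voxels. Branch nodes within a Chebyshev distance of `merge_radius_px`
#' are single-linkage clustered into one node at their centroid; incident
#' edges are re-attached and residual stub edges between merged members are
#' deleted. Genuine loops returning to the same cluster are kept as
#' self-edges.
#'
#' @param g A [filament_graph()].
#' @param merge_radius_px Non-negative merge radius in pixels.
#' @return A [filament_graph()].
#' @export
merge_branch_points <- function(g, merge_radius_px = 2) {
  stopifnot(inherits(g, "filament_graph"))
  if (merge_radius_px < 0)
    stop("`merge_radius_px` must be non-negative", call. = FALSE)
  if (merge_radius_px == 0 || nrow(g$nodes) == 0) return(g)
  ps <- g$pixel_size_um
  bidx <- which(g$nodes$kind == "branch")
  if (length(bidx) < 2) return(g)
  bx <- g$nodes$x_um[bidx] / ps
  by <- g$nodes$y_um[bidx] / ps
  parent <- uf_new(length(bidx))
  for (i in seq_along(bidx)) {
    for (j in seq_len(i - 1L)) {
      if (max(abs(bx[i] - bx[j]), abs(by[i] - by[j])) <= merge_radius_px)
        parent <- uf_union(parent, i, j)
    }
  }
  root <- vapply(seq_along(bidx), function(i) uf_find(parent, i), integer(1))
  clusters <- split(seq_along(bidx), root)

  # map every node id to its (possibly merged) new representative position
  new_pos_x <- g$nodes$x_um
  new_pos_y <- g$nodes$y_um
  rep_of <- seq_len(nrow(g$nodes))
  for (cl in clusters) {
    if (length(cl) < 2) next
    members <- bidx[cl]
    cxum <- mean(g$nodes$x_um[members])
    cyum <- mean(g$nodes$y_um[members])
    repid <- members[1]
    rep_of[members] <- repid
    new_pos_x[repid] <- cxum
    new_pos_y[repid] <- cyum
  }

  keep_edge <- logical(nrow(g$edges))
  polys <- vector("list", nrow(g$edges))
  rad_um <- merge_radius_px * ps
  for (e in seq_len(nrow(g$edges))) {
    a <- rep_of[g$edges$node_a[e]]
    b <- rep_of[g$edges$node_b[e]]
    v <- g$polylines[[e]]
    v[1, ] <- c(new_pos_x[a], new_pos_y[a])
    v[nrow(v), ] <- c(new_pos_x[b], new_pos_y[b])
    if (a == b && g$edges$node_a[e] != g$edges$node_b[e]) {
      # edge collapsed into one cluster: drop it if the whole polyline sits
      # within the merge radius of the cluster centre (a residual stub)
      d <- pmax(abs(v[, 1] - new_pos_x[a]), abs(v[, 2] - new_pos_y[a]))
      if (all(d <= 2 * rad_um + 1e-9)) {
        keep_edge[e] <- FALSE
        next
      }
    }
    keep_edge[e] <- TRUE
    polys[[e]] <- v
  }

  # surviving nodes are the cluster representatives plus all unmerged nodes
  used_nodes <- which(rep_of == seq_along(rep_of))
  remap <- integer(nrow(g$nodes))
  remap[used_nodes] <- seq_along(used_nodes)
  nd <- data.frame(
    id = seq_along(used_nodes),
    x_um = new_pos_x[used_nodes],
    y_um = new_pos_y[used_nodes],
    kind = g$nodes$kind[used_nodes])
  ekeep <- which(keep_edge)
  polys <- polys[ekeep]
  ed <- data.frame(
    edge_id = seq_along(ekeep),
    node_a = remap[rep_of[g$edges$node_a[ekeep]]],
    node_b = remap[rep_of[g$edges$node_b[ekeep]]],
    length_um = vapply(polys, polyline_length, numeric(1)))
  filament_graph(nd, ed, polys, pixel_size_um = ps)
}

#' Geometric low-pass filtering of edge polylines
#'
#' Centred moving average over the interior vertices of every edge polyline
#' (endpoints pinned), attenuating the staircase aliasing of the discrete
#' pixel grid; edge lengths are recomputed.
#'
#' @param g A [filament_graph()].
#' @param window Odd window size (>= 1); 1 is the identity.
#' @return A [filament_graph()].
#' @export
smooth_polylines <- function(g, window = 5) {
  stopifnot(inherits(g, "filament_graph"))
  if (window < 1 || window %% 2 == 0)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  if (window == 1 || nrow(g$edges) == 0) return(g)
  half <- (window - 1L) / 2L
  polys <- lapply(g$polylines, function(v) {
    n <- nrow(v)
    if (n <= 2) return(v)
    out <- v
    for (i in 2:(n - 1)) {
      h <- min(half, i - 1L, n - i)
      out[i, ] <- colMeans(v[(i - h):(i + h), , drop = FALSE])
    }
    out
  })
  ed <- g$edges
  ed$length_um <- vapply(polys, polyline_length, numeric(1))
  filament_graph(g$nodes, ed, polys, pixel_size_um = g$pixel_size_um)
}

#' Branch-length distribution of a filament graph
#'
#' Lengths of the retained graph edges. By default only edges terminating
#' at branch points on both ends ("length between branch points") enter the
#' distribution; endpoint-terminated edges are labelled separately and can
#' be included. Edges shorter than the pruning floor are discarded as
#' thinning artifacts.
#'
#' @param g A finalized [filament_graph()] (merged and smoothed).
#' @param include_endpoint_edges Keep endpoint-terminated edges too?
#' @param prune_floor_px Minimum edge length in pixel equivalents
#'   (default 3).
#' @return A `branch_length_distribution`: data frame with columns
#'   `edge_id`, `length_um`, `class` (`"branch-branch"` or
#'   `"branch-endpoint"`).
#' @export
branch_lengths <- function(g, include_endpoint_edges = FALSE,
                           prune_floor_px = 3) {
  stopifnot(inherits(g, "filament_graph"))
  floor_um <- prune_floor_px * g$pixel_size_um
  if (nrow(g$edges) == 0) {
    out <- data.frame(edge_id = integer(), length_um = numeric(),
                      class = character())
    class(out) <- c("branch_length_distribution", class(out))
    return(out)
  }
  kind <- setNames(g$nodes$kind, g$nodes$id)
  cls <- ifelse(
    kind[as.character(g$edges$node_a)] == "branch" &
      kind[as.character(g$edges$node_b)] == "branch",
    "branch-branch", "branch-endpoint")
  keep <- g$edges$length_um > floor_um
  if (!include_endpoint_edges) keep <- keep & cls == "branch-branch"
  out <- data.frame(edge_id = g$edges$edge_id[keep],
                    length_um = g$edges$length_um[keep],
                    class = cls[keep])
  rownames(out) <- NULL
  class(out) <- c("branch_length_distribution", class(out))
  out
}

#' Full branch-length pipeline
#'
#' Convenience composition: denoise, oriented-flux enhancement, threshold,
#' thin, reconstruct, merge branch points, smooth, measure.
#'
#' @param img A [raster_image()].
#' @param denoise_sigma_px Gaussian denoising SD (px).
#' @param radii_px Oriented-flux probe radii (px).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param merge_radius_px Branch-point merge radius (px).
#' @param window Polyline smoothing window (odd).
#' @param include_endpoint_edges Passed to [branch_lengths()].
#' @param prune_floor_px Passed to [branch_lengths()].
#' @return List with `graph`, `lengths` (a branch-length distribution),
#'   `skeleton` and `mask`.
#' @export
branch_length_pipeline <- function(img,
                                   denoise_sigma_px = 1,
                                   radii_px = c(1, 2, 3, 4, 6, 8),
                                   threshold = "otsu",
                                   merge_radius_px = 2,
                                   window = 5,
                                   include_endpoint_edges = FALSE,
                                   prune_floor_px = 3) {
  sm <- gaussian_denoise(img, denoise_sigma_px)
  resp <- oof_filter(sm, radii_px)
  mask <- if (identical(threshold, "otsu")) binarize(resp, "otsu")
          else binarize(resp, "fixed", fixed_threshold = threshold)
  skel <- extract_centerline(mask)
  g <- reconstruct_graph(skel, pixel_size_um = px_size(img))
  g <- merge_branch_points(g, merge_radius_px)
  g <- smooth_polylines(g, window)
  list(graph = g,
       lengths = branch_lengths(g, include_endpoint_edges,
                                prune_floor_px),
       skeleton = skel, mask = mask)
}
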