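#' Contact-point detection on an AFM approach curve
#'
#' A baseline line is fitted to the first 30% of the approach; the contact
#' point is the first sample where the force persistently exceeds the
#' baseline by `k_sd` baseline-residual standard deviations, refined by a
#' two-segment least-squares fit: baseline line before the breakpoint,
#' power law `A (z - z_c)^b` after it, with `A`, `b` and the breakpoint
#' `z_c` free (Levenberg-Marquardt, initialized at the threshold
#' crossing).
#'
#' @param curve A `force_distance_curve` (see [generate_fd_curve()]) or a
#'   data frame with columns `z_nm`, `force_nN`.
#' @param k_sd Detection threshold in baseline noise SDs (default 3).
#' @return Contact position in nm.
#' @export
detect_contact_point <- function(curve, k_sd = 3) {
  d <- fd_data(curve)
  n <- nrow(d)
  if (n < 30) stop("curve too short for contact detection", call. = FALSE)
  nb <- max(10L, floor(0.3 * n))
  base <- d[seq_len(nb), ]
  fit <- stats::lm(force_nN ~ z_nm, data = base)
  res_sd <- stats::sd(stats::residuals(fit))
  res_sd <- max(res_sd, 1e-6)          # guard for noise-free curves
  pred <- stats::predict(fit, newdata = d)
  above <- which(d$force_nN > pred + k_sd * res_sd)
  above <- above[above > nb]
  # require the excess to persist (reject single-sample noise spikes)
  cand <- NA_integer_
  for (i in above) {
    upper <- min(i + 4L, n)
    if (all(d$force_nN[i:upper] > pred[i:upper] + k_sd * res_sd)) {
      cand <- i
      break
    }
  }
  if (is.na(cand)) stop("no contact found on this curve", call. = FALSE)
  # the threshold crossing overshoots the contact because the power law
  # rises slowly; refine with the full two-segment model (baseline line
  # plus power law beyond a free breakpoint z_c)
  f_net <- d$force_nN - pred
  zcr <- d$z_nm[cand]
  post <- which(f_net > k_sd * res_sd & d$z_nm > zcr)
  ll <- stats::lm(log(f_net[post]) ~ log(d$z_nm[post] - zcr + 1e-9))
  A0 <- exp(unname(stats::coef(ll)[1]))
  b0 <- max(unname(stats::coef(ll)[2]), 0.5)
  dat <- data.frame(z = d$z_nm, f = f_net)
  ft <- tryCatch(
    minpack.lm::nlsLM(
      f ~ A * pmax(z - zc, 0)^b, data = dat,
      start = list(A = A0, b = b0, zc = zcr),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(ft)) return(zcr)
  stats::coef(ft)[["zc"]]
}

fd_data <- function(curve) {
  if (inherits(curve, "force_distance_curve")) curve$data
  else as.data.frame(curve)
}

#' Fit the indentation power law F = A delta^b
#'
#' Nonlinear least squares in linear space on the post-contact segment
#' (delta in metres, force in newtons), initialized from a log-log linear
#' fit. With `fixed_b` the exponent is held and the apparent stiffness has
#' the closed-form least-squares solution. `A` is reported in the N/m^2
#' convention (force in N at delta in m).
#'
#' @param curve A `force_distance_curve` or data frame (`z_nm`, `force_nN`).
#' @param fixed_b Optional fixed exponent (e.g. 1.8 for `A_1.8`).
#' @param contact_nm Contact position; detected with
#'   [detect_contact_point()] when `NULL`.
#' @param setpoint_nN Only data up to this force enters the fit
#'   (default 1.5).
#' @return A `power_law_fit`: list with `A`, `b`, `fixed_b`, `contact_nm`,
#'   `residual_rms_nN`, `n_points`.
#' @export
fit_power_law_fd <- function(curve, fixed_b = NULL, contact_nm = NULL,
                             setpoint_nN = NULL) {
  d <- fd_data(curve)
  if (is.null(setpoint_nN)) {
    setpoint_nN <- if (inherits(curve, "force_distance_curve"))
      curve$setpoint_nN else 1.5
  }
  if (is.null(contact_nm)) contact_nm <- detect_contact_point(curve)
  delta_m <- (d$z_nm - contact_nm) * 1e-9
  F_N <- d$force_nN * 1e-9
  sel <- delta_m > 0 & d$force_nN <= setpoint_nN
  delta_m <- delta_m[sel]; F_N <- F_N[sel]
  if (sum(F_N > 0) < 5)
    stop("insufficient data: fewer than 5 post-contact points", call. = FALSE)
  if (!is.null(fixed_b)) {
    b <- fixed_b
    xb <- delta_m^b
    A <- sum(F_N * xb) / sum(xb^2)
    resid <- F_N - A * xb
  } else {
    pos <- F_N > 0 & delta_m > 0
    ll <- stats::lm(log(F_N[pos]) ~ log(delta_m[pos]))
    b0 <- unname(stats::coef(ll)[2])
    A0 <- exp(unname(stats::coef(ll)[1]))
    fit <- minpack.lm::nlsLM(
      F_N ~ A * delta_m^b,
      start = list(A = A0, b = b0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    A <- stats::coef(fit)[["A"]]
    b <- stats::coef(fit)[["b"]]
    resid <- stats::residuals(fit)
  }
  structure(
    list(A = unname(A), b = unname(b), fixed_b = !is.null(fixed_b),
         contact_nm = contact_nm,
         residual_rms_nN = sqrt(mean(resid^2)) * 1e9,
         n_points = length(F_N)),
    class = "power_law_fit")
}

#' Force needed to reach an indentation depth
#'
#' Evaluates the fitted power law `F = A delta^b` at a depth, returning the
#' force in nN (the depth-to-force curves reported alongside apparent
#' stiffness).
#'
#' @param fit A `power_law_fit`, or a list with elements `A` (N/m^2) and
#'   `b`.
#' @param depth_nm Indentation depth in nm (calibrated range roughly
#'   100-600 nm).
#' @return Force in nN.
#' @export
force_at_depth <- function(fit, depth_nm) {
  stopifnot(is.numeric(depth_nm), all(depth_nm >= 0))
  fit$A * (depth_nm * 1e-9)^fit$b * 1e9
}

#' Aggregate repeated fits at one position
#'
#' Three force curves are recorded per position; the per-position apparent
#' stiffness is their median, flagged when the relative spread exceeds 50%.
#'
#' @param fits List of 1-3 `power_law_fit`s.
#' @return A list with `A` (median), `b`, `n`, `spread_flag`.
#' @export
aggregate_position <- function(fits) {
  if (length(fits) == 0) stop("no fits to aggregate", call. = FALSE)
  As <- vapply(fits, `[[`, numeric(1), "A")
  bs <- vapply(fits, `[[`, numeric(1), "b")
  spread <- if (length(As) > 1) diff(range(As)) / stats::median(As) else 0
  list(A = stats::median(As), b = stats::median(bs), n = length(As),
       spread_flag = spread > 0.5)
}

#' Extract force-normalized creep peaks from a bead track
#'
#' Locates the force-on intervals, subtracts the pre-pulse baseline (mean
#' position over the 0.5 s before onset) and divides the displacement by
#' the instantaneous force, yielding the creep compliance
#' `J(t) = (x(t) - baseline) / F(t)` for `t` in `(0, pulse_on_s]` measured
#' from pulse onset. Peaks with negative mean compliance or off-schedule
#' duration are rejected with a recorded reason.
#'
#' @param track A `bead_track` (see [generate_bead_track()]) or data frame
#'   with columns `t_s`, `x_um`, `force_nN`.
#' @param pulse_on_s Nominal pulse duration (default 5 s).
#' @param baseline_s Pre-pulse baseline window (default 0.5 s).
#' @param tol_s Tolerated deviation of the pulse duration from nominal.
#' @return List of `creep_peak`s: data frames with columns `t_s` (since
#'   onset), `J` (um/nN), plus attributes `pulse` and `force_nN`; rejected
#'   pulses are reported in attribute `rejected`.
#' @export
extract_creep_peaks <- function(track, pulse_on_s = 5, baseline_s = 0.5,
                                tol_s = 0.5) {
  d <- if (inherits(track, "bead_track")) track$data else as.data.frame(track)
  f <- d$force_nN
  on <- f > max(f, na.rm = TRUE) / 2
  if (!any(on)) return(structure(list(), rejected = data.frame()))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  peaks <- list()
  rejected <- list()
  pulse_id <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    pulse_id <- pulse_id + 1L
    i0 <- starts[k]; i1 <- ends[k]
    dur <- d$t_s[i1] - d$t_s[i0]
    if (abs(dur - pulse_on_s) > tol_s) {
      rejected[[length(rejected) + 1]] <-
        data.frame(pulse = pulse_id, reason = "off-schedule duration")
      next
    }
    t_on <- d$t_s[i0]
    pre <- d$t_s >= t_on - baseline_s & d$t_s < t_on
    baseline <- if (any(pre)) mean(d$x_um[pre]) else 0
    tt <- d$t_s[i0:i1] - t_on
    Fp <- d$force_nN[i0:i1]
    if (all(Fp == 0)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(pulse = pulse_id, reason = "zero force during pulse")
      next
    }
    sel <- tt > 0 & tt <= pulse_on_s & Fp > 0
    J <- (d$x_um[i0:i1][sel] - baseline) / Fp[sel]
    if (length(J) == 0 || mean(J) < 0) {
      rejected[[length(rejected) + 1]] <-
        data.frame(pulse = pulse_id, reason = "negative mean compliance")
      next
    }
    pk <- data.frame(t_s = tt[sel], J = J)
    attr(pk, "pulse") <- pulse_id
    attr(pk, "force_nN") <- mean(Fp[sel])
    class(pk) <- c("creep_peak", class(pk))
    peaks[[length(peaks) + 1]] <- pk
  }
  structure(peaks,
            rejected = if (length(rejected)) do.call(rbind, rejected)
                       else data.frame())
}

#' Fit the creep power law J(t) = J0 (t / t0)^beta
#'
#' Default fit is ordinary least squares of `log J` on `log(t / t0)` over
#' the window `[t_min, t_max]`, with the standard log-normal
#' retransformation correction `exp(s^2 / 2)` applied to `J0` (`s` the
#' residual SD of the log fit) so that multiplicative measurement noise
#' does not bias the compliance downward; a nonlinear (linear-space) fit is
#' available via `method`. Non-positive compliance samples are excluded.
#' The derived stiffness is `K0 = 1 / J0`.
#'
#' @param peak A `creep_peak` or data frame with columns `t_s`, `J`.
#' @param t0_s Reference time (default 1 s); `J0` is the compliance there.
#' @param t_min_s,t_max_s Fit window (default 0.1-5 s; the first 0.1 s is
#'   excluded as tracking transient).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return A `creep_fit`: list with `J0`, `beta`, `K0`, `t0_s`,
#'   `residual_rms`, `n_points`.
#' @export
fit_creep <- function(peak, t0_s = 1.0, t_min_s = 0.1, t_max_s = 5,
                      method = c("loglog", "nls")) {
  method <- match.arg(method)
  d <- as.data.frame(peak)
  sel <- d$t_s >= t_min_s & d$t_s <= t_max_s & d$J > 0
  d <- d[sel, ]
  if (nrow(d) < 20)
    stop("insufficient data: fewer than 20 usable creep samples",
         call. = FALSE)
  lt <- log(d$t_s / t0_s)
  if (method == "loglog") {
    ll <- stats::lm(log(d$J) ~ lt)
    s2 <- mean(stats::residuals(ll)^2)
    J0 <- exp(stats::coef(ll)[[1]] + s2 / 2)
    beta <- stats::coef(ll)[[2]]
    resid <- d$J - J0 * (d$t_s / t0_s)^beta
  } else {
    ll <- stats::lm(log(d$J) ~ lt)
    fit <- minpack.lm::nlsLM(
      J ~ J0 * (t_s / t0_s)^beta, data = d,
      start = list(J0 = exp(stats::coef(ll)[[1]]),
                   beta = stats::coef(ll)[[2]]))
    J0 <- stats::coef(fit)[["J0"]]
    beta <- stats::coef(fit)[["beta"]]
    resid <- stats::residuals(fit)
  }
  structure(
    list(J0 = J0, beta = beta, K0 = 1 / J0, t0_s = t0_s,
         residual_rms = sqrt(mean(resid^2)), n_points = nrow(d)),
    class = "creep_fit")
}

#' Average creep fits across peaks
#'
#' Mean and standard error of `J0` and `beta` across peaks, plus the
#' pointwise mean of the rescaled peaks `J(t) / J0` on a common time grid
#' with an SD band.
#'
#' @param fits List of `creep_fit`s.
#' @param peaks Matching list of `creep_peak`s (optional; rescaled average
#'   curve omitted when absent).
#' @param grid_s Common time grid for the rescaled average.
#' @return List with `mean_J0`, `sem_J0`, `mean_beta`, `sem_beta`, `n`,
#'   `single_flag` (TRUE when only one peak, SEM reported as 0), and
#'   `rescaled` (data frame `t_s`, `mean`, `sd`) when peaks are supplied.
#' @export
average_creep <- function(fits, peaks = NULL,
                          grid_s = seq(0.1, 5, by = 0.1)) {
  if (length(fits) == 0) stop("no creep fits to average", call. = FALSE)
  J0s <- vapply(fits, `[[`, numeric(1), "J0")
  betas <- vapply(fits, `[[`, numeric(1), "beta")
  n <- length(fits)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  out <- list(mean_J0 = mean(J0s), sem_J0 = sem(J0s),
              mean_beta = mean(betas), sem_beta = sem(betas),
              n = n, single_flag = n == 1)
  if (!is.null(peaks)) {
    resc <- vapply(seq_along(peaks), function(i) {
      p <- as.data.frame(peaks[[i]])
      stats::approx(p$t_s, p$J / fits[[i]]$J0, xout = grid_s, rule = 1)$y
    }, numeric(length(grid_s)))
    resc <- matrix(resc, nrow = length(grid_s))
    out$rescaled <- data.frame(
      t_s = grid_s,
      mean = rowMeans(resc, na.rm = TRUE),
      sd = apply(resc, 1, stats::sd, na.rm = TRUE))
  }
  out
}
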