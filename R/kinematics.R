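# Segment kinematics, periodic Fourier-series gait models and swimming
# phase segmentation.

# Forward kinematics shared by the generator and the reconstruction:
# segment 1 leaves the apex (origin) at phi_1 degrees below the body-frame
# horizontal; each subsequent direction adds phi_k.
.forward_kinematics <- function(lengths, phi_deg) {
  K <- length(lengths)
  stopifnot(length(phi_deg) == K)
  psi <- cumsum(c(-phi_deg[1], phi_deg[-1])) * pi / 180
  nodes <- matrix(0, K + 1L, 2L)
  for (k in seq_len(K))
    nodes[k + 1L, ] <- nodes[k, ] + lengths[k] * c(cos(psi[k]), sin(psi[k]))
  nodes
}

# Inverse of .forward_kinematics for one node polyline.
.segment_angles <- function(nodes) {
  d <- diff(nodes)
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("zero-length segment")
  psi <- atan2(d[, 2], d[, 1]) * 180 / pi
  phi <- c(-psi[1], diff(psi))
  phi <- ((phi + 180) %% 360) - 180
  list(lengths = len, phi = phi)
}

#' Segment lengths and deflection angles over time
#'
#' For each frame of a discrete bell model, computes the chord length of
#' every segment and the deflection angles: `phi_1` is the angle of
#' segment 1 below the body-frame horizontal, and `phi_k` (k >= 2) the
#' signed angle from the direction of segment k-1 to that of segment k.
#' Each angle channel is unwrapped over time so it is continuous.
#'
#' @param model a `discrete_bell_model`.
#' @param side which half to analyze (default `"right"`).
#' @return an object of class `segment_series`: list with `times`,
#'   `lengths` (frames x segments), `angles_deg` (frames x segments) and
#'   `side`.
#' @export
segment_kinematics <- function(model, side = "right") {
  stopifnot(inherits(model, "discrete_bell_model"))
  keep <- which(model$sides == side)
  if (length(keep) < 2L)
    stop("at least two frames are required")
  keep <- keep[order(model$times[keep])]
  times <- model$times[keep]
  K <- model$n_segments
  lens <- matrix(NA_real_, length(keep), K)
  phis <- matrix(NA_real_, length(keep), K)
  for (i in seq_along(keep)) {
    sa <- .segment_angles(model$nodes[[keep[i]]])
    lens[i, ] <- sa$lengths
    phis[i, ] <- sa$phi
  }
  for (k in seq_len(K)) phis[, k] <- .unwrap_deg(phis[, k])
  structure(list(times = times, lengths = lens, angles_deg = phis,
                 side = side),
            class = "segment_series")
}

#' Clip one cycle and re-origin it at contraction onset
#'
#' Selects the samples with time in `[cycle_start, cycle_end)` and rotates
#' them cyclically so that `origin` maps to time zero, preserving the
#' cycle duration; the sample multiset is unchanged.
#'
#' @param series a `segment_series`.
#' @param cycle_start,cycle_end cycle bounds in seconds.
#' @param origin time of contraction onset (default `cycle_start`).
#' @return a `segment_series` covering one cycle, times in `[0, T)`.
#' @export
clip_and_shift_cycle <- function(series, cycle_start, cycle_end,
                                 origin = cycle_start) {
  stopifnot(inherits(series, "segment_series"))
  if (cycle_end <= cycle_start) stop("cycle bounds are reversed")
  T_cyc <- cycle_end - cycle_start
  keep <- which(series$times >= cycle_start & series$times < cycle_end)
  if (!length(keep)) stop("no samples fall inside the cycle bounds")
  t_new <- (series$times[keep] - origin) %% T_cyc
  ord <- order(t_new)
  structure(list(times = t_new[ord],
                 lengths = series$lengths[keep[ord], , drop = FALSE],
                 angles_deg = series$angles_deg[keep[ord], , drop = FALSE],
                 side = series$side, period = T_cyc),
            class = "segment_series")
}

# Least-squares Fourier fit of one channel on the 9x tiled cycle.
.fit_channel <- function(t, y, period, order, tiles = 9L) {
  omega <- 2 * pi / period
  tt <- rep(t, tiles) + rep((seq_len(tiles) - 1L) * period, each = length(t))
  yy <- rep(y, tiles)
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(nf)
    cbind(cos(nf * omega * tt), sin(nf * omega * tt)))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("too few samples per cycle for the requested Fourier order")
  cf <- qr.coef(qrX, yy)
  resid <- yy - X %*% cf
  list(a0 = cf[1],
       a = cf[seq(2, length(cf), by = 2)],
       b = cf[seq(3, length(cf), by = 2)],
       rms = sqrt(mean(resid^2)))
}

#' Fit periodic Fourier-series models to segment kinematics
#'
#' Each channel (segment lengths `l1..lK`, then deflection angles
#' `phi1..phiK`) is tiled over nine consecutive cycles and fitted by
#' linear least squares on the basis `{1, cos(n w t), sin(n w t)}`,
#' `n = 1..order`, with `w = 2 pi / period`.
#'
#' @param series a one-cycle `segment_series` (see
#'   [clip_and_shift_cycle()]).
#' @param period cycle period in seconds; defaults to the period recorded
#'   on the series.
#' @param order Fourier order (default 8).
#' @param tiles number of cycle repetitions before fitting (default 9).
#' @return an object of class `fourier_kinematic_model`: list with
#'   `channels` (each `a0`, `a`, `b`, residual `rms`), `order`, `period`,
#'   `omega`.
#' @export
fit_fourier <- function(series, period = NULL, order = 8, tiles = 9L) {
  stopifnot(inherits(series, "segment_series"))
  if (is.null(period)) period <- series$period
  if (is.null(period)) stop("a cycle period is required")
  if (order < 1) stop("order must be at least 1")
  K <- ncol(series$lengths)
  channels <- list()
  for (k in seq_len(K))
    channels[[paste0("l", k)]] <-
      .fit_channel(series$times, series$lengths[, k], period, order, tiles)
  for (k in seq_len(K))
    channels[[paste0("phi", k)]] <-
      .fit_channel(series$times, series$angles_deg[, k], period, order,
                   tiles)
  structure(list(channels = channels, order = as.integer(order),
                 period = period, omega = 2 * pi / period),
            class = "fourier_kinematic_model")
}

#' Evaluate Fourier channels at arbitrary times
#'
#' `a0 + sum_n a_n cos(n w t) + b_n sin(n w t)`; the evaluation is
#' periodic with the model period and defined for all real `t`.
#'
#' @param model a `fourier_kinematic_model`.
#' @param t numeric vector of times (seconds).
#' @param channels channel names to evaluate (default all).
#' @return matrix `length(t)` x `length(channels)` with named columns.
#' @export
eval_fourier <- function(model, t, channels = NULL) {
  stopifnot(inherits(model, "fourier_kinematic_model"))
  if (is.null(channels)) channels <- names(model$channels)
  miss <- setdiff(channels, names(model$channels))
  if (length(miss))
    stop("missing channel(s): ", paste(miss, collapse = ", "))
  omega <- model$omega
  out <- vapply(channels, function(nm) {
    ch <- model$channels[[nm]]
    y <- rep(ch$a0, length(t))
    for (nf in seq_along(ch$a))
      y <- y + ch$a[nf] * cos(nf * omega * t) +
               ch$b[nf] * sin(nf * omega * t)
    y
  }, numeric(length(t)))
  matrix(out, nrow = length(t), dimnames = list(NULL, channels))
}

#' Reconstruct the discretized bell from a Fourier model
#'
#' Evaluates the length and angle channels at time `t` and rebuilds the
#' node polyline by forward kinematics from the apex at the origin:
#' segment 1 leaves the apex at `phi_1` below the horizontal, and each
#' subsequent direction adds `phi_k`.
#'
#' @param model a `fourier_kinematic_model` with channels `l1..lK` and
#'   `phi1..phiK`.
#' @param t a single time or vector of times.
#' @return a node matrix for scalar `t`, otherwise a list of node
#'   matrices.
#' @export
reconstruct_profile <- function(model, t) {
  stopifnot(inherits(model, "fourier_kinematic_model"))
  nms <- names(model$channels)
  K <- sum(grepl("^l[0-9]+$", nms))
  need <- c(paste0("l", seq_len(K)), paste0("phi", seq_len(K)))
  miss <- setdiff(need, nms)
  if (K == 0L || length(miss))
    stop("model must provide one length and one angle channel per segment")
  vals <- eval_fourier(model, t, need)
  out <- lapply(seq_along(t), function(i)
    .forward_kinematics(vals[i, seq_len(K)], vals[i, K + seq_len(K)]))
  if (length(t) == 1L) out[[1L]] else out
}

#' Segment a swimming cycle into contraction, cruise and relaxation
#'
#' Works on the angle channel of the actively driven section (the circular
#' muscles), over exactly one cycle starting at contraction onset. The
#' angular velocity is measured on each sample interval (forward
#' difference); contraction is the maximal run of intervals from the cycle
#' start with inward (negative) velocity of magnitude at least
#' `eps * peak`, cruise the following run with magnitude below
#' `eps * peak`, and relaxation the remainder. The three intervals
#' partition the cycle, so the durations sum to the period. Two duty
#' cycles are reported: contraction alone over the period (cruise counted
#' as relaxation) and contraction plus cruise over the period.
#'
#' @param times sample times covering one cycle, starting at contraction
#'   onset.
#' @param values angle values (degrees) at `times`.
#' @param period cycle period; defaults to `diff(range(times))` plus one
#'   median sample interval (i.e. the series wraps around).
#' @param eps velocity threshold as a fraction of the peak angular speed
#'   (default 0.05).
#' @return an object of class `phase_segmentation`: list with
#'   `contraction`, `cruise`, `relaxation` intervals (each `c(start,
#'   end)`), `durations`, `period`, `duty_cycle` (cruise counted as
#'   relaxation) and `duty_cycle_cruise_active` (cruise counted as
#'   contraction), both as fractions.
#' @export
detect_phases <- function(times, values, period = NULL, eps = 0.05) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 3L) stop("too few samples")
  ord <- order(times)
  t <- times[ord]; y <- values[ord]
  if (is.null(period))
    period <- diff(range(t)) + stats::median(diff(t))
  # interval velocities, including the wrap-around interval to t[1]+period
  tt <- c(t, t[1] + period)
  yy <- c(y, y[1])
  v <- diff(yy) / diff(tt)
  peak <- max(abs(v))
  if (peak == 0)
    stop("constant series; no phases to detect")
  thr <- eps * peak
  m <- length(v)
  i <- 1L
  while (i <= m && v[i] < 0 && abs(v[i]) >= thr) i <- i + 1L
  t_contr_end <- tt[i]
  j <- i
  while (j <= m && abs(v[j]) < thr) j <- j + 1L
  t_cruise_end <- tt[j]
  durations <- c(contraction = t_contr_end - tt[1],
                 cruise = t_cruise_end - t_contr_end,
                 relaxation = (tt[1] + period) - t_cruise_end)
  structure(list(contraction = c(tt[1], t_contr_end),
                 cruise = c(t_contr_end, t_cruise_end),
                 relaxation = c(t_cruise_end, tt[1] + period),
                 durations = durations,
                 period = period,
                 duty_cycle = unname(durations[1]) / period,
                 duty_cycle_cruise_active =
                   unname(durations[1] + durations[2]) / period),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(paste0("phases over T = %.3g s: contraction %.3g s, ",
                     "cruise %.3g s, relaxation %.3g s\n",
                     "duty cycle %.1f%% (cruise as relaxation), ",
                     "%.1f%% (cruise as contraction)\n"),
              x$period, x$durations[1], x$durations[2], x$durations[3],
              100 * x$duty_cycle, 100 * x$duty_cycle_cruise_active))
  invisible(x)
}
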