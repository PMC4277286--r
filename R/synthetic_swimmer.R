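# Synthetic swimmer: ground-truth bell kinematics with a known camera
# corruption model, so every pipeline stage has a parameter-recovery
# oracle.

# Trapezoidal phase waveform on [0, T): ramp 0->1 over the contraction,
# hold 1 through cruise, ramp 1->0 over the relaxation.
.trapezoid_wave <- function(t, contraction, cruise, relaxation, period) {
  u <- t %% period
  w <- numeric(length(u))
  w[u < contraction] <- u[u < contraction] / contraction
  mid <- u >= contraction & u < contraction + cruise
  w[mid] <- 1
  late <- u >= contraction + cruise &
          u < contraction + cruise + relaxation
  w[late] <- 1 - (u[late] - contraction - cruise) / relaxation
  w
}

# Antisymmetric transient: a triangular bump peaking mid-contraction
# (the flap flares outward) and a mirrored negative bump peaking
# mid-relaxation (the flap folds inward).
.bump_wave <- function(t, contraction, cruise, relaxation, period) {
  u <- t %% period
  w <- numeric(length(u))
  half <- contraction / 2
  a <- u < half
  w[a] <- u[a] / half
  b <- u >= half & u < contraction
  w[b] <- 1 - (u[b] - half) / half
  r0 <- contraction + cruise
  rhalf <- relaxation / 2
  c1 <- u >= r0 & u < r0 + rhalf
  w[c1] <- -(u[c1] - r0) / rhalf
  c2 <- u >= r0 + rhalf & u < r0 + relaxation
  w[c2] <- -(1 - (u[c2] - r0 - rhalf) / rhalf)
  w
}

#' Ground-truth swimmer specification
#'
#' Defines a four-segment bell with phase-structured, lagged deflection
#' waveforms. Each segment angle follows
#' `phi_k(t) = rest_k + amp_k w(t - lag_k) + flare_k bump(t - lag_k)`,
#' where `w` is the trapezoidal contraction/cruise/relaxation waveform and
#' `bump` a triangular transient spanning the contraction (the flap's
#' outward flare before it folds). Segment lengths pulse together,
#' `l_k(t) = rest_l_k (1 + pulse w(t))`, so the exumbrella lengthens
#' during contraction and shortens during relaxation. The defaults emulate
#' the observed gait: contraction 2 s, cruise 1 s, relaxation 2.4 s
#' (T = 5.4 s); circular muscles -42 deg; radial muscles -20 deg with a
#' 0.95 s lag and an 8 deg counter-flare; passive flap +44 deg with a
#' 1.4 s lag and a large transient flare; central disk +20 deg (passive);
#' arclength pulsation 5%. The per-channel lags are the means of the
#' observed contraction and relaxation lags of each section, since one
#' lag drives both ramps of a channel here.
#'
#' @param fractions node arclength percentages (default anatomical).
#' @param rest_phi relaxed deflection angles (degrees, sign convention of
#'   [segment_kinematics()]).
#' @param amp net angle change over a contraction (degrees).
#' @param lag per-segment waveform lag (seconds).
#' @param flare transient flare amplitude (degrees).
#' @param contraction,cruise,relaxation phase durations (seconds); their
#'   sum is the period.
#' @param pulse relative exumbrella lengthening at full contraction.
#' @param round_radius corner-rounding radius (normalized length) used to
#'   turn the segment skeleton into a smooth curve.
#' @param n points per emitted half profile (default 51).
#' @param dense_n points of the underlying dense curve (default 320).
#' @param symmetric mirror the right half to produce the left half.
#' @return an object of class `swimmer_spec`.
#' @export
swimmer_spec <- function(fractions = c(0, 40, 64, 88, 100),
                         rest_phi = c(5, 10, 15, 25),
                         amp = c(20, -42, -20, 44),
                         lag = c(0, 0, 0.95, 1.4),
                         flare = c(0, 0, 8, 60),
                         contraction = 2, cruise = 1, relaxation = 2.4,
                         pulse = 0.05,
                         round_radius = 0.04,
                         n = 51, dense_n = 320,
                         symmetric = TRUE) {
  if (any(diff(fractions) <= 0) || fractions[1] != 0 ||
      fractions[length(fractions)] != 100)
    stop("fractions must increase strictly from 0 to 100")
  K <- length(fractions) - 1L
  stopifnot(length(rest_phi) == K, length(amp) == K, length(lag) == K,
            length(flare) == K)
  if (min(contraction, cruise, relaxation) < 0 ||
      contraction + relaxation <= 0)
    stop("phase durations must be non-negative with active ramps")
  rest_l <- diff(fractions) / 100
  if (round_radius < 0 || round_radius >= min(rest_l) / 2)
    stop("round_radius must be below half the shortest segment")
  structure(list(fractions = fractions, rest_phi = rest_phi, amp = amp,
                 lag = lag, flare = flare,
                 contraction = contraction, cruise = cruise,
                 relaxation = relaxation,
                 period = contraction + cruise + relaxation,
                 pulse = pulse, rest_l = rest_l,
                 round_radius = round_radius,
                 n = as.integer(n), dense_n = as.integer(dense_n),
                 symmetric = isTRUE(symmetric)),
            class = "swimmer_spec")
}

# Planted channel values at times t: list(lengths, phi) matrices.
.swimmer_channels <- function(spec, t) {
  K <- length(spec$rest_l)
  Tp <- spec$period
  w_len <- .trapezoid_wave(t, spec$contraction, spec$cruise,
                           spec$relaxation, Tp)
  lens <- outer(1 + spec$pulse * w_len, spec$rest_l)
  phi <- matrix(NA_real_, length(t), K)
  for (k in seq_len(K)) {
    tk <- t - spec$lag[k]
    phi[, k] <- spec$rest_phi[k] +
      spec$amp[k] * .trapezoid_wave(tk, spec$contraction, spec$cruise,
                                    spec$relaxation, Tp) +
      spec$flare[k] * .bump_wave(tk, spec$contraction, spec$cruise,
                                 spec$relaxation, Tp)
  }
  list(lengths = lens, phi = phi)
}

# Replace skeleton corners by circular fillets and return a dense point
# sequence along the rounded curve.
.round_skeleton <- function(nodes, radius, arc_pts = 12L) {
  K1 <- nrow(nodes)
  path <- list(nodes[1, , drop = FALSE])
  for (k in 2:(K1 - 1L)) {
    u <- nodes[k, ] - nodes[k - 1L, ]
    v <- nodes[k + 1L, ] - nodes[k, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    u <- u / lu; v <- v / lv
    cross <- u[1] * v[2] - u[2] * v[1]
    dot <- max(-1, min(1, sum(u * v)))
    delta <- acos(dot)
    if (abs(cross) < 1e-12 || delta < 1e-9) {
      path <- c(path, list(nodes[k, , drop = FALSE]))
      next
    }
    d <- min(radius * tan(delta / 2), 0.45 * lu, 0.45 * lv)
    r <- d / tan(delta / 2)
    a <- nodes[k, ] - u * d
    b <- nodes[k, ] + v * d
    side <- sign(cross)
    nrm <- side * c(-u[2], u[1])
    cen <- a + r * nrm
    a0 <- atan2(a[2] - cen[2], a[1] - cen[1])
    a1 <- atan2(b[2] - cen[2], b[1] - cen[1])
    sweep <- (a1 - a0) %% (2 * pi)
    if (side < 0) sweep <- sweep - 2 * pi
    ang <- a0 + seq(0, sweep, length.out = arc_pts)
    path <- c(path, list(cbind(cen[1] + r * cos(ang),
                               cen[2] + r * sin(ang))))
  }
  path <- c(path, list(nodes[K1, , drop = FALSE]))
  do.call(rbind, path)
}

#' Generate ground-truth swimmer profiles
#'
#' Builds the segment skeleton from the planted waveforms at each time,
#' rounds the corners into circular fillets, and samples the smooth curve
#' uniformly in arclength. Ground truth (planted channels, skeleton node
#' positions, phase structure) is recorded alongside the profiles.
#'
#' @param spec a [swimmer_spec()].
#' @param times sample times in seconds.
#' @return an object of class `swimmer_truth`: list with `times`,
#'   `profiles` (list of [half_profile()], right and mirrored left),
#'   `dense` (per-frame dense right-half point matrices), `series`
#'   (planted channels as a `segment_series`), `model` (skeleton node
#'   positions as a `discrete_bell_model`), `phases` and `spec`.
#' @export
generate_true_profiles <- function(spec, times) {
  stopifnot(inherits(spec, "swimmer_spec"))
  ch <- .swimmer_channels(spec, times)
  K <- length(spec$rest_l)
  profiles <- list()
  dense <- vector("list", length(times))
  skeletons <- vector("list", length(times))
  for (i in seq_along(times)) {
    nodes <- .forward_kinematics(ch$lengths[i, ], ch$phi[i, ])
    skeletons[[i]] <- nodes
    dpts <- .polyline_resample(.round_skeleton(nodes, spec$round_radius),
                               spec$dense_n)
    dense[[i]] <- dpts
    right <- half_profile(.polyline_resample(dpts, spec$n),
                          time = times[i], side = "right")
    profiles <- c(profiles, list(right))
    if (spec$symmetric) {
      mir <- dpts %*% diag(c(-1, 1))
      profiles <- c(profiles,
                    list(half_profile(.polyline_resample(mir, spec$n),
                                      time = times[i], side = "left")))
    }
  }
  series <- structure(list(times = times, lengths = ch$lengths,
                           angles_deg = ch$phi, side = "right",
                           period = spec$period),
                      class = "segment_series")
  model <- structure(list(fractions = spec$fractions, times = times,
                          sides = rep("right", length(times)),
                          nodes = skeletons,
                          E_j = rep(0, length(times)), E = 0,
                          n_segments = K),
                     class = "discrete_bell_model")
  phases <- structure(list(
    contraction = c(0, spec$contraction),
    cruise = c(spec$contraction, spec$contraction + spec$cruise),
    relaxation = c(spec$contraction + spec$cruise, spec$period),
    durations = c(contraction = spec$contraction, cruise = spec$cruise,
                  relaxation = spec$relaxation),
    period = spec$period,
    duty_cycle = spec$contraction / spec$period,
    duty_cycle_cruise_active =
      (spec$contraction + spec$cruise) / spec$period),
    class = "phase_segmentation")
  structure(list(times = times, profiles = profiles, dense = dense,
                 series = series, model = model, phases = phases,
                 spec = spec),
            class = "swimmer_truth")
}

#' Camera corruption model
#'
#' The camera approaches the animal (monotone zoom about the frame
#' center), the animal drifts relative to the camera (linear residual
#' scale), the body rolls about the optical axis, and digitization adds
#' pixel noise. The background reference point tracks only the
#' camera-motion component of magnification.
#'
#' @param zoom final zoom factor reached linearly over the record, or a
#'   function of time with `zoom(0) = 1`.
#' @param drift_rate residual linear scale rate (fraction per second);
#'   the animal-relative scale is `1 + drift_rate * t`.
#' @param roll_deg roll amplitude in degrees (the roll trajectory is
#'   `roll_deg * sin(2 pi t / record duration)`), or a function of time.
#' @param noise_sd pixel noise standard deviation.
#' @param frame_center image center `c(x, y)` in pixels.
#' @param px_scale pixels per normalized body unit at frame 1.
#' @param apex_px apex position in frame-1 pixels.
#' @param reference_xy0 background reference position at frame 1.
#' @param frame_width image width in pixels; a warning is raised and
#'   `truncated = TRUE` recorded when the reference leaves the frame.
#' @param marker_frac marker position as a fraction of the right half
#'   arclength from the apex.
#' @param digitize_stride keep every k-th dense outline point to emulate
#'   manual digitization density.
#' @param fps,stride frame rate and digitization stride used to assign
#'   frame indices and times.
#' @return an object of class `camera_spec`.
#' @export
camera_spec <- function(zoom = 1, drift_rate = 0, roll_deg = 0,
                        noise_sd = 0, frame_center = c(320, 180),
                        px_scale = 140, apex_px = c(320, 250),
                        reference_xy0 = c(80, 60), frame_width = 640,
                        marker_frac = 0.04, digitize_stride = 4L,
                        fps = 25, stride = 5) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(zoom = zoom, drift_rate = drift_rate, roll_deg = roll_deg,
                 noise_sd = noise_sd, frame_center = as.numeric(frame_center),
                 px_scale = px_scale, apex_px = as.numeric(apex_px),
                 reference_xy0 = as.numeric(reference_xy0),
                 frame_width = frame_width, marker_frac = marker_frac,
                 digitize_stride = as.integer(digitize_stride),
                 fps = fps, stride = stride),
            class = "camera_spec")
}

#' Corrupt ground-truth profiles with the camera model
#'
#' Places the animal in the image, applies the roll about the apex image,
#' the zoom and residual drift scale about the frame center, and the
#' pixel noise (seeded), and emits digitized frames plus the reference
#' and marker tracks, along with the true scale and roll series.
#'
#' @param truth a `swimmer_truth` from [generate_true_profiles()].
#' @param camera a [camera_spec()].
#' @param seed integer RNG seed for the pixel noise (default 0).
#' @return an object of class `synthetic_scene`: list with `frames`
#'   (list of [digitized_frame()]), `config` (a ready-to-use
#'   [sequence_config()]), `truth`, `camera`, `true_scale` (data frame
#'   `time`, `zoom`, `drift`, `s_total`), `true_roll_deg` and
#'   `truncated`.
#' @export
apply_camera <- function(truth, camera, seed = 0) {
  stopifnot(inherits(truth, "swimmer_truth"),
            inherits(camera, "camera_spec"))
  times <- truth$times
  t_end <- max(times)
  zoom_f <- if (is.function(camera$zoom)) camera$zoom
            else function(t) 1 + (camera$zoom - 1) *
                   (if (t_end > 0) t / t_end else 0)
  roll_f <- if (is.function(camera$roll_deg)) camera$roll_deg
            else function(t) camera$roll_deg *
                   sin(2 * pi * t / max(t_end, 1e-12))
  drift_f <- function(t) 1 + camera$drift_rate * t
  cen <- camera$frame_center
  spec <- truth$spec

  .with_seed(seed, {
    frames <- vector("list", length(times))
    truncated <- FALSE
    apex_offsets <- numeric(length(times))
    for (i in seq_along(times)) {
      t <- times[i]
      zm <- zoom_f(t); dr <- drift_f(t); th <- roll_f(t) * pi / 180
      right <- truth$dense[[i]]
      outline_body <- if (spec$symmetric) {
        left <- right %*% diag(c(-1, 1))
        rbind(left[rev(seq_len(nrow(left))[-1]), , drop = FALSE], right)
      } else right
      rot <- function(p) cbind(p[, 1] * cos(th) - p[, 2] * sin(th),
                               p[, 1] * sin(th) + p[, 2] * cos(th))
      place <- function(p_body) {
        pw <- sweep(camera$px_scale * rot(p_body), 2, camera$apex_px, "+")
        .scale_about(pw, zm * dr, cen)
      }
      outline_img <- place(outline_body)
      # digitization density; always keep the apex vertex and the margins
      n_left0 <- if (spec$symmetric) nrow(right) - 1L else 0L
      keep <- sort(unique(c(seq(1, nrow(outline_img),
                                by = camera$digitize_stride),
                            n_left0 + 1L, nrow(outline_img))))
      pts <- outline_img[keep, , drop = FALSE]
      # marker: physical point at marker_frac of the right half arclength
      s_r <- .cumarc(right)
      mk_body <- as.numeric(.point_at_arclength(
        right, camera$marker_frac * s_r[length(s_r)]))
      mk_img <- as.numeric(place(rbind(mk_body)))
      # reference sees only the camera-motion (zoom) magnification
      ref_img <- cen + (camera$reference_xy0 - cen) * zm
      if (ref_img[1] < 0 || ref_img[1] > camera$frame_width)
        truncated <- TRUE
      if (camera$noise_sd > 0) {
        pts <- pts + matrix(rnorm(length(pts), 0, camera$noise_sd),
                            ncol = 2)
        mk_img <- mk_img + rnorm(2, 0, camera$noise_sd)
        ref_img <- ref_img + rnorm(2, 0, camera$noise_sd)
      }
      # arclength offset from the marker projection to the apex, as it
      # would be measured on this frame's digitized outline
      proj <- .project_on_polyline(pts, mk_img)
      ia <- which(keep == n_left0 + 1L)[1]
      apex_offsets[i] <- .cumarc(pts)[ia] - proj$s
      frames[[i]] <- digitized_frame(i, pts, time = times[i],
                                     reference_xy = ref_img,
                                     marker_xy = mk_img)
    }
    if (truncated)
      warning("reference point leaves the frame during the sequence")
    # fully contracted instants: the moment just before relaxation starts
    # in each cycle (all lagged channels have settled by then)
    dt_s <- if (length(times) > 1) stats::median(diff(times)) else 1
    n_cyc <- floor((max(times) + dt_s / 2) / spec$period) + 1L
    t_targets <- (seq_len(n_cyc) - 1L) * spec$period +
                 spec$contraction + spec$cruise
    contracted <- unique(vapply(t_targets, function(tc) {
      i <- which.min(abs(times - tc))
      if (abs(times[i] - tc) <= dt_s / 2 + 1e-9) i else NA_integer_
    }, 0L))
    contracted <- contracted[!is.na(contracted)]
    config <- sequence_config(
      fps = camera$fps, stride = camera$stride,
      contracted_frames = contracted,
      apex_offset = apex_offsets[1],
      resample_n = spec$n,
      frame_center = cen, y_down = FALSE)
    zs <- vapply(times, zoom_f, 0)
    ds <- vapply(times, drift_f, 0)
    structure(list(frames = frames, config = config, truth = truth,
                   camera = camera,
                   true_scale = data.frame(time = times, zoom = zs,
                                           drift = ds,
                                           s_total = zs * ds),
                   true_roll_deg = vapply(times, roll_f, 0),
                   truncated = truncated, seed = seed),
              class = "synthetic_scene")
  })
}

#' Recovery metrics of the pipeline on a synthetic scene
#'
#' Compares the corrected output of [correct_sequence()] (and optionally a
#' fitted discrete model and segment series) against the scene's ground
#' truth.
#'
#' @param scene a `synthetic_scene`.
#' @param corrected output of `correct_sequence(scene$frames,
#'   scene$config)`.
#' @param model optional `discrete_bell_model` fitted on `corrected`; its
#'   node fractions are compared with the planted ones.
#' @param series optional `segment_series` extracted from a model on
#'   `corrected`; angle channels and phase durations are compared with the
#'   planted waveforms.
#' @return data frame with columns `metric`, `value`, `unit`.
#' @export
recovery_report <- function(scene, corrected, model = NULL, series = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ss <- attr(corrected, "scale_series")
  if (is.null(ss) || nrow(ss) != length(scene$frames))
    stop("corrected output does not match the scene")
  est <- ss$s_total
  true_inv <- 1 / scene$true_scale$s_total
  scale_rms <- sqrt(mean((est / true_inv - 1)^2)) * 100
  bf <- attr(corrected, "body_frames")
  est_roll <- vapply(bf, function(b) b$theta, 0) * 180 / pi
  roll_rms <- sqrt(mean((est_roll - scene$true_roll_deg)^2))
  out <- data.frame(metric = c("scale_rms_error", "roll_rms_error"),
                    value = c(scale_rms, roll_rms),
                    unit = c("percent", "degree"))
  cf <- scene$config$contracted_frames
  if (length(cf) >= 2L) {
    tot <- vapply(cf, function(fi) {
      at <- corrected[vapply(corrected, function(p)
        isTRUE(all.equal(p$time, scene$truth$times[fi])), TRUE)]
      sum(vapply(at, function(p) p$L, 0))
    }, 0)
    out <- rbind(out, data.frame(metric = "contracted_arclength_cv",
                                 value = 100 * sd(tot) / mean(tot),
                                 unit = "percent"))
  }
  Tp <- scene$truth$spec$period
  d <- vapply(scene$truth$times, function(tt) {
    m1 <- .margin_of(corrected, tt, "right")
    m2 <- .margin_of(corrected, tt + Tp, "right")
    if (anyNA(m1) || anyNA(m2)) return(NA_real_)
    sqrt(sum((m1 - m2)^2))
  }, 0)
  if (any(!is.na(d)))
    out <- rbind(out, data.frame(metric = "margin_overlay_mean",
                                 value = 100 * mean(d, na.rm = TRUE),
                                 unit = "percent of half arclength"))
  if (!is.null(model)) {
    planted <- scene$truth$spec$fractions
    if (length(model$fractions) == length(planted))
      out <- rbind(out, data.frame(metric = "node_fraction_max_error",
                                   value = max(abs(model$fractions -
                                                   planted)),
                                   unit = "percent"))
  }
  if (!is.null(series)) {
    truth_ch <- .swimmer_channels(scene$truth$spec,
                                  series$times %% Tp)
    ang_rms <- sqrt(mean((series$angles_deg - truth_ch$phi)^2))
    out <- rbind(out, data.frame(metric = "angle_rms_error",
                                 value = ang_rms, unit = "degree"))
    k_active <- min(2L, ncol(series$angles_deg))
    ph <- detect_phases(series$times, series$angles_deg[, k_active],
                        period = Tp)
    derr <- max(abs(ph$durations - scene$truth$phases$durations))
    out <- rbind(out, data.frame(metric = "phase_duration_max_error",
                                 value = derr, unit = "second"))
  }
  out
}

# margin position of one side at one time, NA when absent
.margin_of <- function(profiles, tt, side, tol = 1e-6) {
  hit <- which(vapply(profiles, function(p)
    p$side == side && abs(p$time - tt) <= tol, TRUE))
  if (!length(hit)) return(c(NA_real_, NA_real_))
  p <- profiles[[hit[1]]]
  p$points[p$n, ]
}
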