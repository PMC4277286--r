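# Correction of digitized outlines: magnification (background reference +
# arclength linear fit), apex location, body-roll removal, polar low-pass
# filtering and uniform arclength resampling.

#' Polyline arclength
#'
#' Sum of Euclidean segment lengths along an ordered point set; zero for a
#' single point.
#'
#' @param points two-column matrix of ordered points, or a `half_profile`.
#' @return length, in the units of the input coordinates.
#' @export
polyline_arclength <- function(points) {
  if (inherits(points, "half_profile")) points <- points$points
  p <- .as_xy(points)
  if (nrow(p) == 0L) stop("cannot measure the arclength of an empty polyline")
  if (nrow(p) == 1L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Magnification scale from a background reference point
#'
#' The camera-motion component of magnification is estimated from the
#' horizontal distance of a tracked background point to the frame center:
#' `s_ref(j) = |x_r(1) - x_c| / |x_r(j) - x_c|`. Multiplying frame-j
#' coordinates about the frame center by `s_ref(j)` restores the scale of
#' the first frame. Assumes the camera keeps the animal centered and moves
#' along its optical axis only.
#'
#' @param frames list of [digitized_frame()], each carrying `reference_xy`.
#' @param frame_center_x x-coordinate of the frame center (pixels).
#' @param eps degeneracy guard: a reference closer than `eps` pixels to the
#'   frame center gives no usable scale signal.
#' @return data frame with columns `frame_index`, `s_ref`.
#' @export
reference_scale <- function(frames, frame_center_x, eps = 1e-6) {
  xs <- vapply(frames, function(f) {
    if (is.null(f$reference_xy)) NA_real_ else f$reference_xy[1]
  }, 0)
  if (anyNA(xs))
    stop("every frame needs a reference point for the reference scale")
  d <- abs(xs - frame_center_x)
  if (any(d < eps))
    stop("reference point lies at the frame center; scale is degenerate")
  data.frame(frame_index = vapply(frames, function(f) f$frame_index, 0L),
             s_ref = d[1] / d)
}

#' Residual magnification from contracted-instant arclengths
#'
#' After the reference-point correction, a residual scale drift remains
#' when the animal moves relative to the camera. The outline arclength is
#' assumed equal at every fully contracted instant; a least-squares line
#' `L(t) = alpha + beta t` through the contracted-frame arclengths defines
#' the residual scale `s_lf(j) = L_fit(t_1) / L_fit(t_j)`, which flattens
#' the contracted arclengths when applied.
#'
#' @param frames list of [digitized_frame()] already at reference-corrected
#'   scale, with times populated.
#' @param contracted_frames integer frame indices at full contraction
#'   (at least 2).
#' @return data frame with columns `frame_index`, `s_lf`, plus the fit as
#'   attribute `"fit"` (`alpha`, `beta`, residuals).
#' @export
arclength_lf_scale <- function(frames, contracted_frames) {
  if (length(contracted_frames) < 2L)
    stop("at least two contracted frames are required for the linear fit")
  idx <- vapply(frames, function(f) f$frame_index, 0L)
  times <- vapply(frames, function(f) f$time, 0)
  pos <- match(contracted_frames, idx)
  if (anyNA(pos))
    stop("contracted frame(s) not present in the sequence: ",
         paste(contracted_frames[is.na(pos)], collapse = ", "))
  Lc <- vapply(pos, function(i) polyline_arclength(frames[[i]]$points), 0)
  tc <- times[pos]
  fit <- lm(Lc ~ tc)
  ab <- coef(fit)
  L_fit <- ab[1] + ab[2] * times
  if (any(L_fit <= 0))
    stop("linear fit implies a non-positive arclength over the sequence")
  data.frame(frame_index = idx,
             s_lf = as.numeric(L_fit[1] / L_fit)) |>
    structure(fit = list(alpha = unname(ab[1]), beta = unname(ab[2]),
                         residuals = unname(fit$residuals)))
}

# Scale points multiplicatively about a center.
.scale_about <- function(points, s, center) {
  p <- .as_xy(points)
  cbind(center[1] + s * (p[, 1] - center[1]),
        center[2] + s * (p[, 2] - center[2]))
}

# Scale a whole frame (outline + marker) about the frame center.
.scale_frame <- function(frame, s, center) {
  frame$points <- .scale_about(frame$points, s, center)
  if (!is.null(frame$marker_xy))
    frame$marker_xy <- as.numeric(.scale_about(rbind(frame$marker_xy),
                                               s, center))
  frame
}

#' Locate the bell apex from a near-apex marker
#'
#' Projects the marker onto the outline, shifts the projection by
#' `apex_offset` along the outline (the offset is measured once, on the
#' first frame), and splits the outline into apex-rooted left and right
#' half profiles. The left half runs from the apex back towards the first
#' digitized point; both halves start exactly at the apex.
#'
#' @param points ordered outline points (margin to margin).
#' @param marker_xy marker position `c(x, y)`.
#' @param apex_offset signed arclength shift from the marker projection to
#'   the apex (positive towards larger point index).
#' @param tol maximum allowed marker-to-outline distance; default
#'   `max(2 |apex_offset|, 2%% of the outline arclength)`.
#' @return list with `apex_xy`, `s_apex` (arclength position of the apex),
#'   `left` and `right` half point matrices, and the projection distance.
#' @export
locate_apex <- function(points, marker_xy, apex_offset = 0, tol = NULL) {
  p <- .as_xy(points)
  s <- .cumarc(p)
  L <- s[length(s)]
  if (abs(apex_offset) > L / 2)
    stop("apex offset exceeds half the outline arclength")
  proj <- .project_on_polyline(p, marker_xy)
  if (is.null(tol)) tol <- max(2 * abs(apex_offset), 0.02 * L)
  if (proj$dist > tol)
    stop(sprintf("marker is %.3g from the outline (tolerance %.3g)",
                 proj$dist, tol))
  s_apex <- proj$s + apex_offset
  if (s_apex <= 0 || s_apex >= L)
    stop("apex position falls outside the outline")
  apex <- as.numeric(.point_at_arclength(p, s_apex))
  eps <- 1e-9 * L
  left <- rbind(apex, p[rev(which(s < s_apex - eps)), , drop = FALSE])
  right <- rbind(apex, p[s > s_apex + eps, , drop = FALSE])
  list(apex_xy = apex, s_apex = s_apex, left = left, right = right,
       marker_dist = proj$dist)
}

#' Body roll angle from the near-apex region
#'
#' The region around the apex deforms little during swimming, so a
#' least-squares line through the outline points within a fixed fraction
#' of each half arclength of the apex gives the body tilt about the
#' optical axis: `theta = atan(slope)`.
#'
#' @param points ordered outline points (margin to margin).
#' @param s_apex arclength position of the apex along `points`
#'   (from [locate_apex()]).
#' @param top_fraction fraction of each half arclength around the apex to
#'   include (default 0.24).
#' @return an object of class `body_frame`: `theta` (radians), `apex_xy`,
#'   fit `slope`, `intercept`, and the number of points used `n_fit`.
#' @export
body_angle <- function(points, s_apex, top_fraction = 0.24) {
  p <- .as_xy(points)
  s <- .cumarc(p)
  L <- s[length(s)]
  left_L <- s_apex
  right_L <- L - s_apex
  sel <- (s <= s_apex & (s_apex - s) <= top_fraction * left_L) |
         (s >= s_apex & (s - s_apex) <= top_fraction * right_L)
  N <- sum(sel)
  if (N < 2L)
    stop("fewer than two outline points fall in the apex region")
  x <- p[sel, 1]; y <- p[sel, 2]
  den <- N * sum(x^2) - sum(x)^2
  if (abs(den) <= 1e-12 * N * max(sum(x^2), 1))
    stop("apex-region points are vertically collinear; slope is undefined")
  m <- (N * sum(x * y) - sum(x) * sum(y)) / den
  cc <- mean(y) - m * mean(x)
  structure(list(theta = atan(m),
                 apex_xy = as.numeric(.point_at_arclength(p, s_apex)),
                 slope = m, intercept = cc, n_fit = N),
            class = "body_frame")
}

#' Transform points from the camera frame to the jellyfish body frame
#'
#' Translates so that the apex is at the origin, then rotates by `-theta`.
#' With `theta = 90` degrees the point `(1, 0)` relative to the apex maps
#' to `(0, -1)`. The map is an isometry.
#'
#' @param points two-column point matrix in camera coordinates.
#' @param frame a `body_frame` from [body_angle()].
#' @return point matrix in body coordinates.
#' @export
to_body_frame <- function(points, frame) {
  stopifnot(inherits(frame, "body_frame"))
  p <- .as_xy(points)
  ct <- cos(frame$theta); st <- sin(frame$theta)
  q <- cbind(p[, 1] - frame$apex_xy[1], p[, 2] - frame$apex_xy[2])
  # row-vector form of the rotation by -theta
  cbind(q[, 1] * ct + q[, 2] * st,
        -q[, 1] * st + q[, 2] * ct)
}

# Zero-phase IIR filtering with steady-state initial conditions and
# odd-reflection padding (the classic forward-backward scheme). The
# signal package's filtfilt() has no edge handling, which corrupts the
# ends of short profile series, so the passes are run here.
.iir_df2t <- function(b, a, x, zi) {
  n <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2)
      for (k in seq_len(n - 2L))
        z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

.filtfilt_zp <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  nfact <- 3L * (n - 1L)
  if (length(x) <= nfact)
    stop("signal too short for zero-phase filtering")
  # steady-state delay states for a unit-level input
  A <- rbind(cbind(-a[2:n], diag(1, n - 1L, n - 2L)))
  B <- b[2:n] - b[1] * a[2:n]
  zi <- solve(diag(n - 1L) - A, B)
  ext <- c(2 * x[1] - x[(nfact + 1L):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - nfact)])
  y <- .iir_df2t(b, a, ext, zi * ext[1])
  y <- rev(.iir_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + length(x))]
}

#' Low-pass filter a half profile in polar coordinates
#'
#' Converts the points to polar coordinates about the apex (the first
#' point), applies a second-order Butterworth low-pass filter to the
#' radius as a function of sample index, forward and backward for zero
#' phase, and converts back. The polar angle of each sample is kept, and
#' the two endpoints are retained exactly.
#'
#' @param half a [half_profile()] with at least 9 points whose first point
#'   is the apex.
#' @param cutoff_fraction cutoff as a fraction of the Nyquist frequency in
#'   the index domain (default 0.20).
#' @return a filtered `half_profile`.
#' @export
smooth_half_profile <- function(half, cutoff_fraction = 0.20) {
  stopifnot(inherits(half, "half_profile"))
  p <- half$points
  n <- nrow(p)
  if (n < 9L)
    stop("at least 9 points are required for stable filtering")
  origin <- p[1, ]
  dx <- p[-1, 1] - origin[1]; dy <- p[-1, 2] - origin[2]
  r <- sqrt(dx^2 + dy^2)
  a <- atan2(dy, dx)
  bw <- signal::butter(2, cutoff_fraction)
  # the apex sample itself (r = 0 by construction) stays fixed and is
  # kept out of the radius series
  rf <- .filtfilt_zp(bw$b, bw$a, r)
  out <- rbind(origin,
               cbind(origin[1] + rf * cos(a), origin[2] + rf * sin(a)))
  out[n, ] <- p[n, ]
  half_profile(out, time = half$time, side = half$side)
}

#' Resample a half profile to points uniform in arclength
#'
#' Fits a cubic spline to each coordinate parameterized by the cumulative
#' chordal arclength of the input points and evaluates it at arclength
#' fractions `k/(n-1)`, `k = 0..n-1`. Endpoints are preserved exactly;
#' resampling an already-uniform profile is a fixed point.
#'
#' @param half a [half_profile()] with at least 4 points.
#' @param n number of output points (default 51).
#' @return a resampled `half_profile`.
#' @export
resample_half_profile <- function(half, n = 51) {
  stopifnot(inherits(half, "half_profile"))
  if (n < 3) stop("n must be at least 3")
  p <- half$points
  if (nrow(p) < 4L)
    stop("at least 4 points are required for cubic-spline resampling")
  s <- .cumarc(p)
  keep <- c(TRUE, diff(s) > 0)
  p <- p[keep, , drop = FALSE]
  s <- s[keep]
  L <- s[length(s)]
  fx <- splinefun(s, p[, 1], method = "natural")
  fy <- splinefun(s, p[, 2], method = "natural")
  st <- seq(0, L, length.out = n)
  out <- cbind(fx(st), fy(st))
  out[1, ] <- p[1, ]
  out[n, ] <- p[nrow(p), ]
  half_profile(out, time = half$time, side = half$side)
}

#' Correct a digitized sequence into body-frame half profiles
#'
#' Full correction pipeline: (i) magnification from the background
#' reference point, (ii) residual magnification from the linear fit
#' through contracted-instant arclengths, (iii) apex location from the
#' marker track, (iv) body-roll removal, (v) polar low-pass filtering and
#' uniform arclength resampling, and (vi) normalization by the relaxed
#' half arclength of the first cycle (mean of the two sides).
#'
#' @param frames list of [digitized_frame()] (from
#'   [read_digitized_sequence()] or [apply_camera()]).
#' @param config a [sequence_config()]; when missing, the config attached
#'   to `frames` is used.
#' @param smooth set `FALSE` to skip the Butterworth filtering stage.
#' @param normalize set `FALSE` to keep pixel units.
#' @return list of [half_profile()] (right then left per frame), with
#'   attributes `scale_series` (data frame `frame_index`, `time`, `s_ref`,
#'   `s_lf`, `s_total`), `body_frames` (list of `body_frame`),
#'   `norm_factor` and `relaxed_frame`.
#' @export
correct_sequence <- function(frames, config = attr(frames, "config"),
                             smooth = TRUE, normalize = TRUE) {
  if (is.null(config))
    stop("a sequence_config is required")
  stopifnot(inherits(config, "sequence_config"))
  idx <- vapply(frames, function(f) f$frame_index, 0L)
  times <- vapply(frames, function(f) f$time, 0)
  if (anyNA(times))
    times <- (idx - idx[1]) * config$stride / config$fps
  for (i in seq_along(frames)) frames[[i]]$time <- times[i]

  has_ref <- all(vapply(frames, function(f) !is.null(f$reference_xy), TRUE))
  if (has_ref) {
    sr <- reference_scale(frames, config$frame_center[1])$s_ref
  } else {
    warning("no reference track; assuming unit camera magnification")
    sr <- rep(1, length(frames))
  }
  frames <- Map(function(f, s) .scale_frame(f, s, config$frame_center),
                frames, sr)

  if (length(config$contracted_frames) >= 2L) {
    slf <- arclength_lf_scale(frames, config$contracted_frames)$s_lf
  } else {
    warning("fewer than two contracted frames; skipping linear-fit scale")
    slf <- rep(1, length(frames))
  }
  frames <- Map(function(f, s) .scale_frame(f, s, config$frame_center),
                frames, slf)

  body_frames <- vector("list", length(frames))
  halves <- vector("list", 2L * length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    res <- tryCatch({
      if (is.null(f$marker_xy))
        stop("marker track is required to locate the apex")
      la <- locate_apex(f$points, f$marker_xy, config$apex_offset,
                        tol = config$marker_tol)
      bf <- body_angle(f$points, la$s_apex, config$top_fraction)
      right <- half_profile(to_body_frame(la$right, bf), f$time, "right")
      left <- half_profile(to_body_frame(la$left, bf), f$time, "left")
      if (smooth) {
        right <- smooth_half_profile(right, config$filter_cutoff_fraction)
        left <- smooth_half_profile(left, config$filter_cutoff_fraction)
      }
      list(bf = bf,
           right = resample_half_profile(right, config$resample_n),
           left = resample_half_profile(left, config$resample_n))
    }, error = function(e)
      stop(sprintf("frame %d: %s", f$frame_index, conditionMessage(e)),
           call. = FALSE))
    body_frames[[i]] <- res$bf
    halves[[2L * i - 1L]] <- res$right
    halves[[2L * i]] <- res$left
  }

  relaxed <- config$relaxed_frame
  norm <- 1
  if (normalize) {
    if (is.null(relaxed)) {
      cf <- sort(config$contracted_frames)
      cand <- if (length(cf) >= 2L) which(idx > cf[1] & idx < cf[2])
              else seq_along(frames)
      if (!length(cand)) cand <- seq_along(frames)
      # relaxed = maximum bell diameter (margin-to-margin chord); the
      # arclength itself peaks at contraction, not relaxation
      diam <- vapply(cand, function(i) {
        p <- frames[[i]]$points
        sqrt(sum((p[nrow(p), ] - p[1, ])^2))
      }, 0)
      relaxed <- idx[cand[which.max(diam)]]
    }
    ri <- match(relaxed, idx)
    if (is.na(ri)) stop("relaxed frame not present in the sequence")
    norm <- mean(c(halves[[2L * ri - 1L]]$L, halves[[2L * ri]]$L))
    halves <- lapply(halves, function(h)
      half_profile(h$points / norm, h$time, h$side))
  }

  structure(halves,
            scale_series = data.frame(frame_index = idx, time = times,
                                      s_ref = sr, s_lf = slf,
                                      s_total = sr * slf),
            body_frames = body_frames,
            norm_factor = norm,
            relaxed_frame = relaxed)
}
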