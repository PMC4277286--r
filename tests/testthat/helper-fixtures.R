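# Shared fixtures built in code. Scenes are cached per session because
# several test files reuse the same synthetic swimmer.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default swimmer truth, two full cycles at the digitized frame rate
swimmer_truth_2cyc <- function() {
  cached("truth2", function() {
    spec <- swimmer_spec()
    generate_true_profiles(spec, seq(0, 2 * spec$period - 0.2, by = 0.2))
  })
}

# the standard corrupted scene: approach zoom 1.3x, 2% residual drift per
# cycle, +/-7 degree roll, no pixel noise
swimmer_scene_std <- function() {
  cached("scene_std", function() {
    truth <- swimmer_truth_2cyc()
    Tp <- truth$spec$period
    apply_camera(truth,
                 camera_spec(zoom = 1.3, drift_rate = 0.02 / Tp,
                             roll_deg = 7, digitize_stride = 2),
                 seed = 1)
  })
}

swimmer_corrected_std <- function() {
  cached("corrected_std", function() {
    sc <- swimmer_scene_std()
    correct_sequence(sc$frames, sc$config)
  })
}

# circle arc profile: radius R, angular span, n points, centered so the
# first point is the arc start
arc_profile <- function(R = 1, span = c(0, pi), n = 51, time = 0,
                        side = "right") {
  th <- seq(span[1], span[2], length.out = n)
  half_profile(cbind(R * cos(th), R * sin(th)), time = time, side = side)
}

# quarter-circle "hemisphere" profile: apex on the axis at the origin,
# margin at (R, -R)
hemisphere_profile <- function(R = 1, n = 51) {
  th <- seq(pi / 2, 0, length.out = n)
  half_profile(cbind(R * cos(th), R * (sin(th) - 1)), time = 0,
               side = "right")
}

# piecewise-linear profile with vertices at given arclength fractions and
# per-vertex turn, sampled at n points uniform in arclength
kinked_profile <- function(kink_fracs = c(30, 60), turns_deg = c(-35, 30),
                           n = 51, time = 0) {
  fr <- c(0, kink_fracs, 100) / 100
  lens <- diff(fr)
  ang <- cumsum(c(-10, turns_deg)) * pi / 180
  verts <- matrix(0, length(lens) + 1L, 2L)
  for (k in seq_along(lens))
    verts[k + 1L, ] <- verts[k, ] + lens[k] * c(cos(ang[k]), sin(ang[k]))
  half_profile(bellkin:::.polyline_resample(verts, n), time = time,
               side = "right")
}

# smooth curve with curvature extrema planted at given arclength
# fractions (curvature is a raised cosine along arclength)
extremum_profile <- function(peak_frac = 0.3, valley_frac = 0.7,
                             scale = 1, n = 51) {
  u <- seq(0, 1, length.out = 2001)
  du <- u[2] - u[1]
  width <- valley_frac - peak_frac
  kap <- scale * (0.8 + 0.5 * cos(2 * pi * (u - peak_frac) / (2 * width)))
  psi <- cumsum(kap) * du
  pts <- rbind(c(0, 0), cbind(cumsum(cos(psi)) * du, cumsum(sin(psi)) * du))
  half_profile(bellkin:::.polyline_resample(pts, n), time = 0,
               side = "right")
}

# independent brute-force node search used as an oracle against
# optimize_nodes(); enumerates fraction tuples directly via total_error()
brute_force_nodes <- function(profiles, n_segments, grid_step) {
  interior <- seq(grid_step, 100 - grid_step, by = grid_step)
  best <- NULL
  best_E <- Inf
  combos <- if (n_segments == 1L) list(numeric())
            else asplit(utils::combn(interior, n_segments - 1L), 2)
  for (cc in combos) {
    E <- total_error(profiles, c(0, cc, 100))
    if (E < best_E - 1e-15) {
      best_E <- E
      best <- c(0, cc, 100)
    }
  }
  list(fractions = best, E = best_E)
}
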