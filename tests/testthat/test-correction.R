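test_that("polyline arclength matches closed forms", {
  expect_equal(polyline_arclength(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(polyline_arclength(rbind(c(2, 7))), 0)
  # chord sum of a unit semicircle approaches pi from below
  semi <- arc_profile(R = 1, span = c(0, pi), n = 51)
  expect_lt(abs(polyline_arclength(semi) - pi) / pi, 2e-3)
  expect_lt(polyline_arclength(semi), pi)
  expect_error(polyline_arclength(matrix(numeric(), ncol = 2)), "empty")
})

test_that("reference scale follows the center-distance ratio", {
  mk <- function(rx) digitized_frame(length(mk_idx) + 1, outline5,
                                     reference_xy = c(rx, 50))
  outline5 <- cbind(0:5, c(0, 1, 2, 1, 0, 1))
  frames <- list(digitized_frame(1, outline5, reference_xy = c(100, 50)),
                 digitized_frame(2, outline5, reference_xy = c(100, 50)),
                 digitized_frame(3, outline5, reference_xy = c(100, 50)))
  expect_equal(reference_scale(frames, 320)$s_ref, rep(1, 3))

  frames2 <- list(digitized_frame(1, outline5, reference_xy = c(220, 50)),
                  digitized_frame(2, outline5, reference_xy = c(120, 50)))
  # distance from center doubles (100 -> 200): scale halves
  expect_equal(reference_scale(frames2, 320)$s_ref, c(1, 0.5))

  frames3 <- list(digitized_frame(1, outline5, reference_xy = c(320, 50)),
                  digitized_frame(2, outline5, reference_xy = c(120, 50)))
  expect_error(reference_scale(frames3, 320), "degenerate")
})

test_that("reference scale recovers a planted camera zoom within 1%", {
  sc <- swimmer_scene_std()
  sr <- reference_scale(sc$frames, sc$config$frame_center[1])$s_ref
  expect_lt(max(abs(sr * sc$true_scale$zoom - 1)), 0.01)
})

test_that("linear-fit scale inverts a linear arclength drift exactly", {
  # straight outlines of known arclength 1.00, 1.10, 1.20 at t = 0, 1, 2
  mk <- function(idx, L) {
    x <- seq(0, L, length.out = 6)
    digitized_frame(idx, cbind(x, rep(c(0, 0), 3)[1:6] + 0))
  }
  frames <- list(mk(1, 1.0), mk(6, 1.1), mk(11, 1.2))
  for (i in seq_along(frames)) frames[[i]]$time <- (i - 1)
  out <- arclength_lf_scale(frames, c(1, 6, 11))
  expect_equal(out$s_lf, 1 / (1 + 0.1 * c(0, 1, 2)), tolerance = 1e-12)

  same <- list(mk(1, 1), mk(6, 1), mk(11, 1))
  for (i in seq_along(same)) same[[i]]$time <- (i - 1)
  expect_equal(arclength_lf_scale(same, c(1, 6, 11))$s_lf, rep(1, 3))
  expect_error(arclength_lf_scale(frames, 1), "at least two")
})

test_that("apex location splits the outline at the marker projection", {
  th <- seq(pi, 0, length.out = 41)
  outline <- cbind(cos(th), sin(th))   # symmetric dome, apex at (0, 1)
  la <- locate_apex(outline, marker_xy = c(0, 1), apex_offset = 0)
  expect_equal(la$apex_xy, c(0, 1), tolerance = 1e-6)
  # symmetric profile: halves have equal arclength within 1%
  expect_lt(abs(polyline_arclength(la$left) -
                polyline_arclength(la$right)) /
            polyline_arclength(la$right), 0.01)
  expect_equal(la$left[1, ], la$apex_xy)
  expect_equal(la$right[1, ], la$apex_xy)

  expect_error(locate_apex(outline, c(0, 1), apex_offset = pi),
               "half the outline")
  expect_error(locate_apex(outline, c(0, 3), apex_offset = 0.1),
               "from the outline")
})

test_that("body angle is exact for flat tops and equivariant under rotation", {
  th <- seq(pi, 0, length.out = 81)
  outline <- cbind(cos(th), 0.3 * sin(th))  # flattened dome
  s_apex <- polyline_arclength(outline) / 2
  bf <- body_angle(outline, s_apex)
  expect_lt(abs(bf$theta), 1e-9)

  rot <- function(p, a) p %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  # a least-squares regression line is exactly equivariant only for
  # collinear points; for the curved top region it is equivariant to the
  # extent the region is straight
  for (ang in c(10, -25, 40) * pi / 180) {
    bfr <- body_angle(rot(outline, ang), s_apex)
    expect_equal(bfr$theta, bf$theta + ang, tolerance = 1e-3)
    # invariant under uniform scaling
    bfs <- body_angle(3.7 * rot(outline, ang), 3.7 * s_apex)
    expect_equal(bfs$theta, bfr$theta, tolerance = 1e-9)
  }
  flatline <- cbind(seq(-1, 1, length.out = 21), rep(0, 21))
  bf_line <- body_angle(flatline, 1)
  for (ang in c(10, -25, 40) * pi / 180)
    expect_equal(body_angle(rot(flatline, ang), 1)$theta,
                 bf_line$theta + ang, tolerance = 1e-12)
  expect_error(body_angle(cbind(rep(0, 11), seq(-1, 1, length.out = 11)),
                          1), "collinear")
})

test_that("body-frame conversion follows the stated convention and is an isometry", {
  bf0 <- structure(list(theta = 0, apex_xy = c(2, 3)), class = "body_frame")
  expect_equal(to_body_frame(rbind(c(3, 5)), bf0), rbind(c(1, 2)))
  bf90 <- structure(list(theta = pi / 2, apex_xy = c(0, 0)),
                    class = "body_frame")
  expect_equal(to_body_frame(rbind(c(1, 0)), bf90), rbind(c(0, -1)),
               tolerance = 1e-12)
  set.seed(42)
  pts <- matrix(rnorm(40), ncol = 2)
  for (th in c(0.3, -1.2, 2.8)) {
    bf <- structure(list(theta = th, apex_xy = c(0.5, -1)),
                    class = "body_frame")
    out <- to_body_frame(pts, bf)
    expect_equal(polyline_arclength(out), polyline_arclength(pts),
                 tolerance = 1e-12)
    expect_equal(as.numeric(dist(out)), as.numeric(dist(pts)),
                 tolerance = 1e-12)
  }
})

test_that("polar filtering passes DC and attenuates per the Butterworth response", {
  # constant-radius arc about the apex is (numerically) unchanged
  n <- 60
  ang <- seq(0, pi / 2, length.out = n)
  arc <- half_profile(rbind(c(0, 0), cbind(5 * cos(ang), 5 * sin(ang))))
  sm <- smooth_half_profile(arc, 0.20)
  expect_lt(max(abs(sm$points - arc$points)), 1e-6)

  # radial sinusoid at 0.45x Nyquist attenuated by at least the two-pass
  # squared-magnitude response of the order-2 Butterworth
  n <- 200
  ang <- seq(0, pi / 2, length.out = n)
  A <- 0.05
  r <- 10 + A * sin(2 * pi * 0.225 * (0:(n - 1)))
  noisy <- half_profile(rbind(c(0, 0), cbind(r * cos(ang), r * sin(ang))))
  sm <- smooth_half_profile(noisy, 0.20)
  resid <- sqrt(rowSums(sm$points[-1, ]^2)) - 10
  H2 <- 1 / (1 + (0.45 / 0.20)^4)
  expect_lte(max(abs(resid[30:170])), H2 * A)

  # smoothing shortens convex noisy arcs
  set.seed(7)
  r2 <- 10 + rnorm(n, 0, 0.05)
  noisy2 <- half_profile(rbind(c(0, 0),
                               cbind(r2 * cos(ang), r2 * sin(ang))))
  expect_lt(smooth_half_profile(noisy2, 0.20)$L, noisy2$L)

  expect_error(smooth_half_profile(half_profile(cbind(0:4, c(0, 1, 0, 1, 0)))),
               "at least 9")
})

test_that("arclength resampling hits closed forms and is idempotent", {
  seg <- half_profile(cbind(seq(0, 10, length.out = 21), rep(0, 21)))
  rs <- resample_half_profile(seg, 51)
  expect_equal(rs$points[, 1], 0.2 * (0:50), tolerance = 1e-9)

  qc <- arc_profile(R = 1, span = c(0, pi / 2), n = 101)
  rq <- resample_half_profile(qc, 51)
  expect_lt(abs(rq$L - pi / 2), 1e-3)
  # endpoints preserved exactly
  expect_equal(rq$points[1, ], qc$points[1, ])
  expect_equal(rq$points[51, ], qc$points[101, ])

  # already-uniform profiles are a fixed point
  again <- resample_half_profile(rq, 51)
  expect_lt(max(abs(again$points - rq$points)), 1e-6)
  expect_error(resample_half_profile(qc, 2), "at least 3")
})

test_that("correction of an identity camera is a no-op up to resampling", {
  truth <- swimmer_truth_2cyc()
  sc <- apply_camera(truth, camera_spec(digitize_stride = 1), seed = 1)
  out <- correct_sequence(sc$frames, sc$config, smooth = FALSE)
  norm <- attr(out, "norm_factor")
  tr0 <- resample_half_profile(half_profile(truth$dense[[1]], 0, "right"),
                               51)
  scale_to_norm <- sc$camera$px_scale / norm
  expect_lt(max(abs(out[[1]]$points - tr0$points * scale_to_norm)), 1e-6)
  ss <- attr(out, "scale_series")
  expect_equal(ss$s_total, rep(1, length(sc$frames)), tolerance = 1e-9)
})

test_that("correction runs in degraded mode without a reference track", {
  sc <- swimmer_scene_std()
  frames <- lapply(sc$frames[1:30], function(f) {
    f$reference_xy <- NULL
    f
  })
  cfg <- sc$config
  cfg$contracted_frames <- integer()
  expect_warning(expect_warning(
    out <- correct_sequence(frames, cfg),
    "reference"), "contracted")
  expect_equal(attr(out, "scale_series")$s_ref, rep(1, 30))
})

test_that("full correction restores cycle-periodic kinematics", {
  sc <- swimmer_scene_std()
  out <- swimmer_corrected_std()
  rep <- recovery_report(sc, out)
  val <- function(m) rep$value[rep$metric == m]
  expect_lt(val("scale_rms_error"), 1)          # percent
  expect_lt(val("roll_rms_error"), 0.5)         # degrees
  expect_lt(val("contracted_arclength_cv"), 0.5)
  expect_lt(val("margin_overlay_mean"), 2)      # percent of half arclength
})
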