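make_model <- function(node_list, times = seq_along(node_list) - 1) {
  structure(list(fractions = seq(0, 100,
                                 length.out = nrow(node_list[[1]])),
                 times = times, sides = rep("right", length(node_list)),
                 nodes = node_list, E_j = rep(0, length(node_list)), E = 0,
                 n_segments = nrow(node_list[[1]]) - 1L),
            class = "discrete_bell_model")
}

test_that("segment kinematics follow the deflection-angle convention", {
  right_angle <- rbind(c(0, 0), c(1, 0), c(1, 1))
  m <- make_model(list(right_angle, right_angle, right_angle))
  ser <- segment_kinematics(m)
  expect_equal(ser$angles_deg[, 2], rep(90, 3))
  expect_equal(ser$angles_deg[, 1], rep(0, 3))
  expect_equal(ser$lengths, matrix(1, 3, 2))

  straight <- rbind(c(0, 0), c(1, -0.5), c(2, -1), c(3, -1.5))
  ser2 <- segment_kinematics(make_model(list(straight, straight)))
  expect_equal(ser2$angles_deg[, 2:3], matrix(0, 2, 2), tolerance = 1e-12)
  expect_gt(ser2$angles_deg[1, 1], 0)  # below horizontal is positive

  degenerate <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(segment_kinematics(make_model(list(degenerate, degenerate))),
               "zero-length")
})

test_that("planted generator waveforms are recovered exactly from the skeleton", {
  truth <- swimmer_truth_2cyc()
  ser <- segment_kinematics(truth$model)
  expect_lt(max(abs(ser$angles_deg - truth$series$angles_deg)), 1e-9)
  expect_lt(max(abs(ser$lengths - truth$series$lengths)), 1e-9)
})

test_that("angle channels are unwrapped across the +/-180 boundary", {
  mk <- function(a) rbind(c(0, 0), c(1, 0),
                          c(1 + cos(a * pi / 180), sin(a * pi / 180)))
  angles <- seq(120, 240, by = 20)   # crosses 180
  ser <- segment_kinematics(make_model(lapply(angles, mk)))
  expect_equal(ser$angles_deg[, 2], angles, tolerance = 1e-9)
  expect_true(all(abs(diff(ser$angles_deg[, 2])) < 180))
})

test_that("cycle clipping re-origins time and preserves the sample multiset", {
  truth <- swimmer_truth_2cyc()
  ser <- segment_kinematics(truth$model)
  Tp <- truth$spec$period
  c0 <- clip_and_shift_cycle(ser, 0, Tp)
  expect_equal(c0$times, ser$times[ser$times < Tp])
  expect_equal(c0$angles_deg, ser$angles_deg[ser$times < Tp, ])
  # shifting by a mid-cycle origin permutes but keeps the samples
  c1 <- clip_and_shift_cycle(ser, 0, Tp, origin = 2)
  expect_equal(sort(c1$angles_deg[, 2]),
               sort(c0$angles_deg[, 2]))
  expect_equal(c1$times[1], 0)
  expect_error(clip_and_shift_cycle(ser, 3, 1), "reversed")
})

test_that("Fourier fitting recovers in-basis signals to machine precision", {
  Tp <- 2.5
  omega <- 2 * pi / Tp
  t <- seq(0, Tp - 0.1, by = 0.1)
  y <- 3 * cos(omega * t) - 2 * sin(2 * omega * t) + 0.7
  ser <- structure(list(times = t, lengths = cbind(rep(1.5, length(t))),
                        angles_deg = cbind(y), side = "right",
                        period = Tp),
                   class = "segment_series")
  m <- fit_fourier(ser, order = 3)
  ch <- m$channels$phi1
  expect_equal(ch$a0, 0.7, tolerance = 1e-10)
  expect_equal(unname(ch$a), c(3, 0, 0), tolerance = 1e-10)
  expect_equal(unname(ch$b), c(0, -2, 0), tolerance = 1e-10)
  # constant channel: a0 only
  expect_equal(m$channels$l1$a0, 1.5, tolerance = 1e-12)
  expect_lt(max(abs(c(m$channels$l1$a, m$channels$l1$b))), 1e-10)
  # evaluation reproduces the samples and is T-periodic
  yy <- eval_fourier(m, t, "phi1")[, 1]
  expect_equal(yy, y, tolerance = 1e-9)
  tr <- runif(5, -3, 3)
  expect_equal(eval_fourier(m, tr + Tp), eval_fourier(m, tr),
               tolerance = 1e-9)
})

test_that("tiling, projection and order monotonicity behave as least squares", {
  Tp <- 2
  t <- seq(0, Tp - 0.05, by = 0.05)
  set.seed(11)
  noise <- rnorm(length(t))
  ser <- function(y) structure(list(times = t, lengths = cbind(rep(1,
                                 length(t))), angles_deg = cbind(y),
                                 side = "right", period = Tp),
                               class = "segment_series")
  # white noise: residual RMS cannot exceed the input RMS
  m8 <- fit_fourier(ser(noise), order = 8)
  expect_lte(m8$channels$phi1$rms, sqrt(mean(noise^2)))
  # residual non-increasing in order
  rms_by_order <- vapply(1:8, function(k)
    fit_fourier(ser(noise), order = k)$channels$phi1$rms, 0)
  expect_true(all(diff(rms_by_order) <= 1e-12))
  # tiling an exactly periodic signal does not move the coefficients
  y <- 2 * cos(2 * pi * t / Tp) + 0.5 * sin(4 * pi * t / Tp)
  m1 <- fit_fourier(ser(y), order = 4, tiles = 1L)
  m9 <- fit_fourier(ser(y), order = 4, tiles = 9L)
  expect_equal(m1$channels$phi1$a, m9$channels$phi1$a, tolerance = 1e-9)
  expect_equal(m1$channels$phi1$b, m9$channels$phi1$b, tolerance = 1e-9)
  # rank-deficient designs are refused
  short <- structure(list(times = t[1:3], lengths = cbind(rep(1, 3)),
                          angles_deg = cbind(c(1, 2, 1)), side = "right",
                          period = Tp),
                     class = "segment_series")
  expect_error(fit_fourier(short, order = 8), "too few")
})

test_that("reconstruction inverts the kinematic extraction", {
  m0 <- structure(list(channels = list(
    l1 = list(a0 = 1, a = 0, b = 0), l2 = list(a0 = 1, a = 0, b = 0),
    phi1 = list(a0 = 0, a = 0, b = 0), phi2 = list(a0 = 0, a = 0, b = 0)),
    order = 1L, period = 1, omega = 2 * pi), class = "fourier_kinematic_model")
  expect_equal(reconstruct_profile(m0, 0),
               rbind(c(0, 0), c(1, 0), c(2, 0)))
  m0$channels$phi2$a0 <- -90
  expect_equal(reconstruct_profile(m0, 0.3)[3, ], c(1, -1),
               tolerance = 1e-12)

  # full round trip on the swimmer: fit, reconstruct at sample times,
  # re-extract; node error stays within the fit residual
  truth <- swimmer_truth_2cyc()
  ser <- clip_and_shift_cycle(segment_kinematics(truth$model), 0,
                              truth$spec$period)
  fm <- fit_fourier(ser, order = 8)
  resid <- max(vapply(fm$channels, function(ch) ch$rms, 0))
  keep <- which(truth$model$times < truth$spec$period)
  err <- vapply(seq_along(ser$times), function(i) {
    rec <- reconstruct_profile(fm, ser$times[i])
    max(abs(rec - truth$model$nodes[[keep[i]]]))
  }, 0)
  expect_lt(max(err), 10 * resid + 1e-6)
  # forward/inverse kinematics round trip is exact
  set.seed(5)
  for (i in 1:10) {
    l <- runif(4, 0.1, 1)
    phi <- runif(4, -120, 120)
    sa <- bellkin:::.segment_angles(bellkin:::.forward_kinematics(l, phi))
    expect_equal(sa$lengths, l, tolerance = 1e-9)
    expect_equal(sa$phi, phi, tolerance = 1e-9)
  }
})

test_that("phase detection recovers planted plateau durations", {
  dt <- 0.2
  Tp <- 5.4
  t <- seq(0, Tp - dt, by = dt)
  trap <- function(u) {
    u <- u %% Tp
    ifelse(u < 2, 40 - 20 * u / 2,
           ifelse(u < 3, 20, 20 + 20 * (u - 3) / 2.4))
  }
  ph <- detect_phases(t, trap(t), period = Tp)
  expect_lt(max(abs(ph$durations - c(2, 1, 2.4))), dt + 1e-9)
  expect_equal(sum(ph$durations), Tp)
  expect_equal(ph$duty_cycle, ph$durations[["contraction"]] / Tp)
  expect_equal(ph$duty_cycle_cruise_active,
               sum(ph$durations[c("contraction", "cruise")]) / Tp)

  # symmetric triangle: no cruise, 50% duty cycle
  t2 <- seq(0, 3.8, by = 0.2)
  tri <- c(seq(10, 0, length.out = 11), seq(1, 9, length.out = 9))
  ph2 <- detect_phases(t2, tri, period = 4)
  expect_equal(ph2$durations[["cruise"]], 0)
  expect_equal(ph2$duty_cycle, 0.5)

  expect_error(detect_phases(t, rep(1, length(t)), period = Tp),
               "constant")
})
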