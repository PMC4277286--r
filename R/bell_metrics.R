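# Derived biomechanical quantities: node trajectory loops, margin
# excursion, subumbrella volume and bell diameter.

#' Node trajectory loops over one cycle
#'
#' For each node of a discrete bell model, the positions across the frames
#' of one cycle form a closed path (last point joined to the first). The
#' signed shoelace area measures the hysteresis (looping) between the
#' contraction and relaxation paths. When a phase segmentation is
#' supplied, the loop orientation is classified by comparing the mean
#' distance of the node from the apex during contraction and relaxation:
#' outer-on-contraction when the contraction path lies farther out.
#'
#' @param model a `discrete_bell_model` covering one cycle (>= 3 frames).
#' @param side which half to analyze (default `"right"`).
#' @param phases optional `phase_segmentation` on the same time base.
#' @param tol area magnitude below which the orientation is undefined.
#' @return an object of class `trajectory_loops`: list with `loops` (data
#'   frame `node`, `fraction`, `area`, `abs_area`, `orientation`) and
#'   `paths` (list of closed path matrices).
#' @export
node_trajectories <- function(model, side = "right", phases = NULL,
                              tol = 1e-12) {
  stopifnot(inherits(model, "discrete_bell_model"))
  keep <- which(model$sides == side)
  if (length(keep) < 3L)
    stop("at least three frames are required for a trajectory loop")
  keep <- keep[order(model$times[keep])]
  times <- model$times[keep]
  n_nodes <- length(model$fractions)
  paths <- lapply(seq_len(n_nodes), function(k)
    t(vapply(keep, function(i) model$nodes[[i]][k, ], numeric(2))))
  areas <- vapply(paths, .shoelace_signed, 0)
  orientation <- rep(NA_character_, n_nodes)
  if (!is.null(phases)) {
    in_int <- function(t, int) t >= int[1] & t < int[2]
    ic <- in_int(times, phases$contraction)
    ir <- in_int(times, phases$relaxation)
    if (any(ic) && any(ir)) {
      for (k in seq_len(n_nodes)) {
        if (abs(areas[k]) <= tol) next
        r <- sqrt(rowSums(paths[[k]]^2))
        orientation[k] <- if (mean(r[ic]) > mean(r[ir]))
          "outer_on_contraction" else "inner_on_contraction"
      }
    }
  }
  structure(list(loops = data.frame(node = seq_len(n_nodes),
                                    fraction = model$fractions,
                                    area = areas, abs_area = abs(areas),
                                    orientation = orientation),
                 paths = paths, times = times, side = side),
            class = "trajectory_loops")
}

#' Bell margin excursion between relaxed and contracted positions
#'
#' Per-axis absolute displacement of the bell margin (the last profile
#' point) between paired relaxed and contracted instants, averaged over
#' both sides and over all supplied cycle pairs.
#'
#' @param profiles list of [half_profile()] (both sides).
#' @param contracted_times,relaxed_times equal-length vectors of instants
#'   to pair, in seconds.
#' @param time_tol matching tolerance on profile times (default 1e-6).
#' @return named vector `c(dx, dy)` in profile units.
#' @export
margin_excursion <- function(profiles, contracted_times, relaxed_times,
                             time_tol = 1e-6) {
  if (length(contracted_times) != length(relaxed_times))
    stop("contracted and relaxed instants must pair up")
  if (!length(contracted_times))
    stop("no phase instants identified")
  margin_at <- function(tt, side) {
    hit <- which(vapply(profiles, function(p)
      p$side == side && abs(p$time - tt) <= time_tol, TRUE))
    if (!length(hit))
      stop(sprintf("no %s profile at t = %g s", side, tt))
    p <- profiles[[hit[1]]]
    p$points[p$n, ]
  }
  dx <- dy <- numeric()
  for (i in seq_along(contracted_times)) {
    for (side in c("right", "left")) {
      mc <- margin_at(contracted_times[i], side)
      mr <- margin_at(relaxed_times[i], side)
      dx <- c(dx, abs(mr[1] - mc[1]))
      dy <- c(dy, abs(mr[2] - mc[2]))
    }
  }
  c(dx = mean(dx), dy = mean(dy))
}

#' Subumbrella volume of one half profile
#'
#' Volume of the solid of revolution bounded by the exumbrella profile,
#' the rotation axis through the apex, and the horizontal plane through
#' the minimum profile y-position, assuming an axisymmetric bell. The
#' volume is computed as the line integral `V = | pi * closed-loop
#' integral of x^2 dy |` around the boundary polygon, which is exact for
#' polyline profiles and remains valid when the profile is multi-valued
#' in y (bell folded over the apex).
#'
#' @param half a [half_profile()] in the body frame with the apex (first
#'   point) on the rotation axis.
#' @param axis_tol how far (relative to the arclength) the profile may
#'   cross to negative x before it is rejected (default 1e-3).
#' @return volume `V >= 0` in profile units cubed.
#' @export
subumbrella_volume <- function(half, axis_tol = 1e-3) {
  stopifnot(inherits(half, "half_profile"))
  p <- half$points
  x <- abs(p[, 1] - p[1, 1])  # radial distance from the rotation axis
  if (min(p[, 1] - p[1, 1]) < -axis_tol * max(half$L, 1e-12) &&
      max(p[, 1] - p[1, 1]) > 0)
    stop("profile crosses the rotation axis")
  y <- p[, 2]
  y_min <- min(y)
  # closed boundary: profile, drop from the margin to y_min, back along
  # y = y_min to the axis, and up the axis to the apex; the two closing
  # runs have x = const and contribute analytically.
  seg_int <- function(x1, y1, x2, y2)
    (x1^2 + x1 * x2 + x2^2) / 3 * (y2 - y1)
  n <- length(x)
  total <- sum(seg_int(x[-n], y[-n], x[-1], y[-1]))
  total <- total + seg_int(x[n], y[n], x[n], y_min)   # margin wall
  # y_min run: dy = 0 contributes nothing; axis run: x = 0.
  abs(pi * total)
}

#' Volume and diameter series over a corrected sequence
#'
#' Per frame: subumbrella volume (mean of the left and right half
#' estimates), bell radius (margin |x|), diameter (2 radius) and the
#' minimum profile y. When a phase segmentation is given, the sign of the
#' volume trend in each phase is attached as attribute `"dV_sign"`.
#'
#' @param profiles list of [half_profile()] in the body frame.
#' @param phases optional `phase_segmentation`.
#' @return an object of class `volume_series`: data frame with columns
#'   `time`, `V`, `radius`, `diameter`, `y_min`.
#' @export
volume_series <- function(profiles, phases = NULL) {
  times <- sort(unique(vapply(profiles, function(p) p$time, 0)))
  rows <- lapply(times, function(tt) {
    at_t <- profiles[vapply(profiles, function(p)
      isTRUE(all.equal(p$time, tt)), TRUE)]
    V <- mean(vapply(at_t, subumbrella_volume, 0))
    rad <- mean(vapply(at_t, function(p) abs(p$points[p$n, 1]), 0))
    ymin <- min(vapply(at_t, function(p) min(p$points[, 2]), 0))
    data.frame(time = tt, V = V, radius = rad, diameter = 2 * rad,
               y_min = ymin)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("volume_series", "data.frame")
  if (!is.null(phases)) {
    sign_in <- function(int) {
      i <- out$time >= int[1] & out$time < int[2]
      if (sum(i) < 2L) return(NA_real_)
      sign(out$V[i][sum(i)] - out$V[i][1])
    }
    attr(out, "dV_sign") <- c(contraction = sign_in(phases$contraction),
                              cruise = sign_in(phases$cruise),
                              relaxation = sign_in(phases$relaxation))
  }
  out
}
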