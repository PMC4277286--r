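# Strategic bell discretization: circumcircle curvature, anatomical
# landmarks, and error-minimizing node placement with the area-between-
# curves error measure.

#' Signed discrete curvature from the circumcircle of three points
#'
#' The unsigned curvature is the reciprocal circumradius, `4 A / (f g h)`
#' with `A` the triangle area and `f, g, h` the side lengths (the
#' circumcircle diameter is `f g h / (2 A)`). The sign is taken from the
#' turn direction, `sign((p2 - p1) x (p3 - p2))`, so convex and concave
#' stretches can be told apart; collinear points give 0.
#'
#' @param p1,p2,p3 points `c(x, y)`, in order along the curve.
#' @return signed curvature (1 / length unit).
#' @export
circumcircle_curvature <- function(p1, p2, p3) {
  v1 <- p2 - p1; v2 <- p3 - p2; v3 <- p3 - p1
  f <- sqrt(sum(v1^2)); g <- sqrt(sum(v2^2)); h <- sqrt(sum(v3^2))
  if (f == 0 || g == 0 || h == 0)
    stop("coincident points have no circumcircle")
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  if (cross == 0) return(0)
  4 * (abs(cross) / 2) / (f * g * h) * sign(cross)
}

#' Curvature profile of a half profile
#'
#' Signed circumcircle curvature at every interior point (from consecutive
#' point triples) and its derivative with respect to arclength by central
#' finite differences over the cumulative chordal arclength. Curvature is
#' undefined (NA) at the two endpoints.
#'
#' @param half a [half_profile()] with at least 3 points.
#' @return an object of class `curvature_profile`: a data frame with
#'   columns `b` (0-based point index), `s`, `frac` (arclength percent),
#'   `kappa`, `dkappa_ds`.
#' @export
profile_curvature <- function(half) {
  stopifnot(inherits(half, "half_profile"))
  p <- half$points
  n <- nrow(p)
  if (n < 3L) stop("at least 3 points are required for curvature")
  s <- .cumarc(p)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1L))
    kappa[i] <- circumcircle_curvature(p[i - 1L, ], p[i, ], p[i + 1L, ])
  dk <- rep(NA_real_, n)
  if (n >= 5L) {
    for (i in 3:(n - 2L))
      dk[i] <- (kappa[i + 1L] - kappa[i - 1L]) / (s[i + 1L] - s[i - 1L])
  }
  structure(data.frame(b = 0:(n - 1L), s = s, frac = 100 * s / s[n],
                       kappa = kappa, dkappa_ds = dk),
            class = c("curvature_profile", "data.frame"))
}

#' Candidate node locations from across-frame mean curvature
#'
#' Averages the signed curvature pointwise across profiles, differentiates
#' the mean with respect to arclength, and reports the arclength fractions
#' where the derivative crosses zero -- the curvature peaks and valleys,
#' i.e. the locations of highest deformation along the bell. The
#' across-frame sample variance of curvature at each point quantifies
#' deformation over time.
#'
#' Isolated crossings whose derivative magnitude stays below
#' `noise_guard * max |dkappa/ds|` on both sides are ignored.
#'
#' @param profiles list of [half_profile()] sharing the same point count.
#' @param noise_guard relative derivative magnitude below which a sign
#'   flip is treated as noise (default 1e-3).
#' @return an object of class `curvature_nodes`: list with `candidates`
#'   (arclength percentages), and `report`, a data frame with per-point
#'   `frac`, `kappa_mean`, `kappa_var`, `dkappa_ds`.
#' @export
curvature_nodes <- function(profiles, noise_guard = 1e-3) {
  if (length(profiles) < 2L)
    stop("at least two profiles are required")
  ns <- vapply(profiles, function(p) p$n, 0L)
  if (length(unique(ns)) != 1L)
    stop("profiles must share a common resampling")
  n <- ns[1]
  kap <- vapply(profiles, function(p) profile_curvature(p)$kappa,
                numeric(n))
  sbar <- rowMeans(vapply(profiles, function(p) .cumarc(p$points),
                          numeric(n)))
  frac <- 100 * sbar / sbar[n]
  kbar <- rowMeans(kap)
  kvar <- apply(kap, 1, var)
  dk <- rep(NA_real_, n)
  if (n >= 5L)
    for (i in 3:(n - 2L))
      dk[i] <- (kbar[i + 1L] - kbar[i - 1L]) / (sbar[i + 1L] - sbar[i - 1L])
  ok <- which(!is.na(dk))
  candidates <- numeric()
  kappa_span <- diff(range(kbar, na.rm = TRUE))
  flat <- kappa_span < 1e-6 * max(abs(kbar), na.rm = TRUE)
  if (length(ok) >= 2L && !flat) {
    mx <- max(abs(dk[ok]))
    if (mx > 0) {
      for (j in seq_len(length(ok) - 1L)) {
        i1 <- ok[j]; i2 <- ok[j + 1L]
        d1 <- dk[i1]; d2 <- dk[i2]
        if (d1 == 0) {
          candidates <- c(candidates, frac[i1])
        } else if (sign(d1) != sign(d2) && d2 != 0) {
          if (max(abs(d1), abs(d2)) < noise_guard * mx) next
          w <- d1 / (d1 - d2)
          candidates <- c(candidates, frac[i1] + w * (frac[i2] - frac[i1]))
        }
      }
      if (!is.na(dk[ok[length(ok)]]) && dk[ok[length(ok)]] == 0)
        candidates <- c(candidates, frac[ok[length(ok)]])
    }
  }
  structure(list(candidates = unique(candidates),
                 report = data.frame(b = 0:(n - 1L), frac = frac,
                                     kappa_mean = kbar, kappa_var = kvar,
                                     dkappa_ds = dk),
                 n_profiles = length(profiles)),
            class = "curvature_nodes")
}

#' Anatomical node locations of the segmented bell
#'
#' The fixed landmark set from the bell anatomy, as arclength percentages
#' of the half profile: apex (0), coronal joint / circular muscle onset
#' (40), radial muscle onset (64), flap root (88), bell margin (100).
#' Segment 1 is the passive central disk, segment 2 the circular muscles,
#' segment 3 the radial muscles, segment 4 the passive flap.
#'
#' @return list with `fractions`, `segment_labels` and `node_labels`.
#' @export
anatomical_nodes <- function() {
  list(fractions = c(0, 40, 64, 88, 100),
       segment_labels = c("central disk", "circular muscles",
                          "radial muscles", "flap"),
       node_labels = c("apex", "coronal joint / circular muscle onset",
                       "radial muscle onset", "flap root", "bell margin"))
}

#' Place model nodes on a profile at given arclength fractions
#'
#' Nodes are interpolated linearly on the profile polyline, so every node
#' lies exactly on the profile; consecutive nodes are joined by straight
#' chords to form the discrete exumbrella model.
#'
#' @param half a [half_profile()].
#' @param fractions arclength percentages in `[0, 100]`.
#' @return list with `nodes` (matrix), `fractions`, `chord_lengths`.
#' @export
model_from_fractions <- function(half, fractions) {
  stopifnot(inherits(half, "half_profile"))
  if (any(fractions < 0 | fractions > 100))
    stop("node fractions must lie in [0, 100]")
  nodes <- .point_at_arclength(half$points, half$L * fractions / 100)
  chords <- if (nrow(nodes) > 1L) sqrt(rowSums(diff(nodes)^2)) else numeric()
  list(nodes = nodes, fractions = fractions, chord_lengths = chords)
}

# Absolute area enclosed between the profile arc from arclength sa to sb
# and its chord, via the shoelace formula on the closed arc+chord polygon.
.arc_chord_area <- function(points, s, sa, sb) {
  if (sb <= sa) return(0)
  pa <- as.numeric(.point_at_arclength(points, sa))
  pb <- as.numeric(.point_at_arclength(points, sb))
  interior <- which(s > sa & s < sb)
  poly <- rbind(pa, points[interior, , drop = FALSE], pb)
  abs(.shoelace_signed(poly))
}

#' Model-versus-profile error of one frame
#'
#' The discrepancy between a profile and its discrete model is the total
#' absolute area enclosed between the profile and the model chords,
#' normalized by the profile arclength; with normalized profiles the error
#' is dimensionless.
#'
#' @param half a [half_profile()].
#' @param fractions node arclength percentages (must include the span to
#'   be scored; typically starting at 0 and ending at 100).
#' @return scalar error `E_j >= 0`.
#' @export
profile_model_error <- function(half, fractions) {
  stopifnot(inherits(half, "half_profile"))
  if (any(fractions < 0 | fractions > 100))
    stop("node fractions must lie in [0, 100]")
  fr <- sort(fractions)
  s <- .cumarc(half$points)
  st <- half$L * fr / 100
  total <- 0
  for (k in seq_len(length(st) - 1L))
    total <- total + .arc_chord_area(half$points, s, st[k], st[k + 1L])
  total / half$L
}

#' Total discretization error over a profile set
#'
#' Sum of the per-frame errors [profile_model_error()] over all profiles
#' (both halves, all frames).
#'
#' @param profiles list of [half_profile()].
#' @param fractions node arclength percentages.
#' @return scalar total error `E`.
#' @export
total_error <- function(profiles, fractions) {
  sum(vapply(profiles, profile_model_error, 0, fractions = fractions))
}

# Build a discrete bell model object for a fixed fraction set.
discrete_bell_model <- function(profiles, fractions) {
  E_j <- vapply(profiles, profile_model_error, 0, fractions = fractions)
  structure(list(fractions = fractions,
                 times = vapply(profiles, function(p) p$time, 0),
                 sides = vapply(profiles, function(p) p$side, ""),
                 nodes = lapply(profiles, function(p)
                   model_from_fractions(p, fractions)$nodes),
                 E_j = E_j, E = sum(E_j),
                 n_segments = length(fractions) - 1L),
            class = "discrete_bell_model")
}

#' @export
print.discrete_bell_model <- function(x, ...) {
  cat(sprintf("discrete_bell_model: %d segments, nodes at %s%%, E = %.4g (%d profiles)\n",
              x$n_segments, paste(round(x$fractions, 2), collapse = "/"),
              x$E, length(x$times)))
  invisible(x)
}

# Exhaustive search over interior node positions drawn from `grid_fracs`
# (first and last entries are the fixed endpoints). Ties are broken by the
# lexicographically smallest fraction tuple.
.search_nodes <- function(profiles, grid_fracs, n_segments) {
  G <- length(grid_fracs)
  n_int <- n_segments - 1L
  if (n_int > G - 2L)
    stop("not enough candidate positions for the requested segment count")
  # pairwise error contributions, summed over profiles
  A <- matrix(0, G, G)
  for (p in profiles) {
    s <- .cumarc(p$points)
    st <- p$L * grid_fracs / 100
    for (i in seq_len(G - 1L))
      for (j in (i + 1L):G)
        A[i, j] <- A[i, j] +
          .arc_chord_area(p$points, s, st[i], st[j]) / p$L
  }
  interior <- seq.int(2L, G - 1L)
  combos <- if (n_int == 0L) matrix(integer(), nrow = 0, ncol = 1)
            else if (length(interior) == 1L) matrix(interior)
            else combn(interior, n_int)
  n_combo <- ncol(combos)
  idx <- rbind(rep(1L, n_combo), combos, rep(G, n_combo))
  E <- numeric(n_combo)
  for (r in seq_len(nrow(idx) - 1L))
    E <- E + A[cbind(idx[r, ], idx[r + 1L, ])]
  best <- which.min(E)  # first minimum = lexicographically smallest combo
  list(fractions = grid_fracs[idx[, best]], E = E[best])
}

#' Error-minimizing node placement on a percentage grid
#'
#' Exhaustive search for the interior node locations (endpoints fixed at 0
#' and 100%) that minimize the total area error [total_error()] for a given
#' number of segments, over an even percentage grid.
#'
#' @param profiles list of [half_profile()].
#' @param n_segments number of chords in the model (>= 1).
#' @param grid_step grid spacing in percent (default 2).
#' @return the optimal `discrete_bell_model`.
#' @export
optimize_nodes <- function(profiles, n_segments, grid_step = 2) {
  if (n_segments < 1L) stop("n_segments must be at least 1")
  gf <- seq(0, 100, by = grid_step)
  if (gf[length(gf)] != 100) gf <- c(gf, 100)
  res <- .search_nodes(profiles, gf, n_segments)
  discrete_bell_model(profiles, res$fractions)
}

#' Error-minimizing node subset from curvature candidates
#'
#' Chooses the best `n_segments - 1` interior nodes from a fixed candidate
#' list (e.g. the curvature peaks and valleys), endpoints fixed at 0 and
#' 100%, by exhaustive enumeration of subsets.
#'
#' @param profiles list of [half_profile()].
#' @param candidates interior candidate fractions (percent, in (0, 100)).
#' @param n_segments number of chords in the model.
#' @return the optimal `discrete_bell_model` restricted to the candidates.
#' @export
optimize_from_candidates <- function(profiles, candidates, n_segments) {
  candidates <- sort(unique(candidates))
  if (any(candidates <= 0 | candidates >= 100))
    stop("candidates must be interior fractions in (0, 100)")
  if (length(candidates) < n_segments - 1L)
    stop("too few candidates for the requested segment count")
  gf <- c(0, candidates, 100)
  res <- .search_nodes(profiles, gf, n_segments)
  discrete_bell_model(profiles, res$fractions)
}
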