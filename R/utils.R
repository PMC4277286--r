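# Internal polyline geometry helpers shared across modules.

.as_xy <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop("points must have two columns (x, y)")
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  p
}

# Cumulative chordal arclength, starting at 0 for the first point.
.cumarc <- function(points) {
  p <- .as_xy(points)
  if (nrow(p) == 1L) return(0)
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

# Point(s) on the polyline at given arclength position(s), by linear
# interpolation along segments. Targets are clamped to [0, L].
.point_at_arclength <- function(points, s_target) {
  p <- .as_xy(points)
  s <- .cumarc(p)
  L <- s[length(s)]
  st <- pmin(pmax(s_target, 0), L)
  cbind(approx(s, p[, 1], xout = st)$y,
        approx(s, p[, 2], xout = st)$y)
}

# Orthogonal projection of one point onto a polyline: closest point,
# its arclength position and the distance.
.project_on_polyline <- function(points, xy) {
  p <- .as_xy(points)
  n <- nrow(p)
  if (n == 1L) {
    return(list(point = p[1, ], s = 0,
                dist = sqrt(sum((xy - p[1, ])^2))))
  }
  a <- p[-n, , drop = FALSE]
  d <- diff(p)
  len2 <- rowSums(d^2)
  t_raw <- ((xy[1] - a[, 1]) * d[, 1] + (xy[2] - a[, 2]) * d[, 2]) / len2
  t_cl <- pmin(pmax(ifelse(is.finite(t_raw), t_raw, 0), 0), 1)
  px <- a[, 1] + t_cl * d[, 1]
  py <- a[, 2] + t_cl * d[, 2]
  dist2 <- (px - xy[1])^2 + (py - xy[2])^2
  k <- which.min(dist2)
  s <- .cumarc(p)
  list(point = c(px[k], py[k]),
       s = s[k] + t_cl[k] * sqrt(len2[k]),
       dist = sqrt(dist2[k]))
}

# Resample a polyline to n points uniform in chordal arclength (linear
# interpolation; every output point lies on the input polyline).
.polyline_resample <- function(points, n) {
  p <- .as_xy(points)
  s <- .cumarc(p)
  keep <- c(TRUE, diff(s) > 0)
  p <- p[keep, , drop = FALSE]
  s <- s[keep]
  L <- s[length(s)]
  .point_at_arclength(p, seq(0, L, length.out = n))
}

# Signed shoelace area of a closed polygon (vertices in order, not repeated).
.shoelace_signed <- function(points) {
  p <- .as_xy(points)
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Unwrap an angle series (degrees) so no step exceeds 180 in magnitude.
.unwrap_deg <- function(a) {
  if (length(a) < 2L) return(a)
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  cumsum(c(a[1], d))
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
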