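# Domain constructors and on-disk formats (CSV for point data, JSON for
# coefficient tables and node sets, YAML for configuration).

#' Acquisition and processing settings for a digitized swimming sequence
#'
#' Bundles the constants that describe how a sequence was filmed and
#' digitized and how it should be processed: frame rate, digitization
#' stride, the frame indices at full bell contraction (used by the
#' arclength linear-fit magnification adjustment), the arclength offset
#' from the tracked body marker to the apex, the fraction of the half
#' arclength used for the body-roll linear fit, the per-profile resampling
#' count, and the low-pass cutoff as a fraction of the Nyquist frequency.
#'
#' @param fps frames per second of the source footage (default 25).
#' @param stride digitization stride in frames (default 5, i.e. every 5th
#'   frame was digitized).
#' @param contracted_frames integer frame indices at full contraction; at
#'   least two are needed for the linear-fit scale adjustment.
#' @param relaxed_frame optional frame index of the fully relaxed instant of
#'   the first cycle, used for arclength normalization. When `NULL` the
#'   frame of maximum outline arclength between the first two contracted
#'   frames is used.
#' @param apex_offset signed arclength offset (pixels, at first-frame scale)
#'   from the marker's projection on the outline to the apex; positive
#'   moves towards larger point index.
#' @param top_fraction fraction of each half arclength around the apex used
#'   for the body-angle linear fit (default 0.24).
#' @param resample_n points per resampled half profile (default 51).
#' @param filter_cutoff_fraction Butterworth cutoff as a fraction of the
#'   Nyquist frequency in the sample-index domain (default 0.20).
#' @param frame_center image center `c(x, y)` in pixels; magnification is
#'   corrected about this point (default `c(320, 180)` for 640x360 footage).
#' @param y_down `TRUE` when the input files use image-style coordinates
#'   with y increasing downwards; they are flipped to y-up on ingest.
#' @param marker_tol optional maximum allowed distance (pixels) from the
#'   marker to the outline; default `max(2 * |apex_offset|, 2%% of outline)`.
#' @return an object of class `sequence_config`.
#' @export
sequence_config <- function(fps = 25, stride = 5,
                            contracted_frames = integer(),
                            relaxed_frame = NULL,
                            apex_offset = 0,
                            top_fraction = 0.24,
                            resample_n = 51,
                            filter_cutoff_fraction = 0.20,
                            frame_center = c(320, 180),
                            y_down = TRUE,
                            marker_tol = NULL) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(stride) || stride < 1) stop("stride must be >= 1")
  if (!(top_fraction > 0 && top_fraction < 0.5))
    stop("top_fraction must lie in (0, 0.5)")
  if (resample_n < 3) stop("resample_n must be at least 3")
  if (!(filter_cutoff_fraction > 0 && filter_cutoff_fraction < 1))
    stop("filter_cutoff_fraction must lie in (0, 1)")
  if (length(frame_center) != 2L) stop("frame_center must be c(x, y)")
  structure(list(fps = fps, stride = stride,
                 contracted_frames = as.integer(contracted_frames),
                 relaxed_frame = if (is.null(relaxed_frame)) NULL
                                 else as.integer(relaxed_frame),
                 apex_offset = apex_offset,
                 top_fraction = top_fraction,
                 resample_n = as.integer(resample_n),
                 filter_cutoff_fraction = filter_cutoff_fraction,
                 frame_center = as.numeric(frame_center),
                 y_down = isTRUE(y_down),
                 marker_tol = marker_tol),
            class = "sequence_config")
}

#' Read a sequence configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [sequence_config()].
#' @return a `sequence_config`.
#' @export
read_sequence_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sequence_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  do.call(sequence_config, vals)
}

#' @rdname read_sequence_config
#' @param config a `sequence_config` to serialize.
#' @export
write_sequence_config <- function(config, path) {
  stopifnot(inherits(config, "sequence_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' One digitized video frame
#'
#' An ordered exumbrella outline (one bell margin to the other) together
#' with the optional background reference point and near-apex body marker
#' for that frame. Coordinates are pixels with y increasing upwards.
#'
#' @param frame_index integer frame index (>= 1).
#' @param points ordered two-column matrix of outline points.
#' @param time time in seconds (filled by [read_digitized_sequence()]).
#' @param reference_xy optional background reference position `c(x, y)`.
#' @param marker_xy optional body-marker position `c(x, y)`.
#' @return an object of class `digitized_frame`.
#' @export
digitized_frame <- function(frame_index, points, time = NA_real_,
                            reference_xy = NULL, marker_xy = NULL) {
  p <- .as_xy(points)
  if (nrow(p) < 5L)
    stop(sprintf("frame %d has %d outline points; at least 5 are required",
                 frame_index, nrow(p)))
  if (any(rowSums(abs(diff(p))) == 0))
    stop(sprintf("frame %d contains duplicate consecutive points",
                 frame_index))
  structure(list(frame_index = as.integer(frame_index),
                 time = as.numeric(time),
                 points = p,
                 reference_xy = if (is.null(reference_xy)) NULL
                                else as.numeric(reference_xy),
                 marker_xy = if (is.null(marker_xy)) NULL
                             else as.numeric(marker_xy)),
            class = "digitized_frame")
}

#' Read a digitized outline sequence and its tracks
#'
#' The points file must contain columns `frame`, `point_idx`, `x`, `y`;
#' the tracks file columns `frame`, `kind`, `x`, `y` with `kind` either
#' `"reference"` or `"marker"`. Point order within a frame is taken from
#' `point_idx` and never altered. Times are derived as
#' `(frame - first_frame) * stride / fps`.
#'
#' @param points_path delimited-text file of outline points.
#' @param tracks_path optional delimited-text file of reference/marker
#'   tracks; `NULL` for none.
#' @param config a [sequence_config()].
#' @return list of [digitized_frame()] sorted by frame index, with the
#'   config attached as attribute `"config"`.
#' @export
read_digitized_sequence <- function(points_path, tracks_path = NULL,
                                    config = sequence_config()) {
  stopifnot(inherits(config, "sequence_config"))
  pts <- read.csv(points_path, stringsAsFactors = FALSE)
  need <- c("frame", "point_idx", "x", "y")
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop("points file is missing column(s): ", paste(miss, collapse = ", "))
  trk <- NULL
  if (!is.null(tracks_path)) {
    trk <- read.csv(tracks_path, stringsAsFactors = FALSE)
    need_t <- c("frame", "kind", "x", "y")
    miss_t <- setdiff(need_t, names(trk))
    if (length(miss_t))
      stop("tracks file is missing column(s): ",
           paste(miss_t, collapse = ", "))
    if (!all(trk$kind %in% c("reference", "marker")))
      stop("track kind must be 'reference' or 'marker'")
  }
  ysign <- if (config$y_down) -1 else 1
  idx <- sort(unique(pts$frame))
  first <- idx[1]
  frames <- lapply(idx, function(fi) {
    sub <- pts[pts$frame == fi, , drop = FALSE]
    sub <- sub[order(sub$point_idx), , drop = FALSE]
    ref <- mark <- NULL
    if (!is.null(trk)) {
      r <- trk[trk$frame == fi & trk$kind == "reference", , drop = FALSE]
      m <- trk[trk$frame == fi & trk$kind == "marker", , drop = FALSE]
      if (nrow(r)) ref <- c(r$x[1], ysign * r$y[1])
      if (nrow(m)) mark <- c(m$x[1], ysign * m$y[1])
    }
    digitized_frame(fi, cbind(sub$x, ysign * sub$y),
                    time = (fi - first) * config$stride / config$fps,
                    reference_xy = ref, marker_xy = mark)
  })
  attr(frames, "config") <- config
  frames
}

#' Write a digitized sequence back to delimited text
#'
#' Inverse of [read_digitized_sequence()]: with the same `config`,
#' `read(write(x))` reproduces `x`.
#'
#' @param frames list of [digitized_frame()].
#' @param points_path,tracks_path output CSV paths.
#' @inheritParams read_digitized_sequence
#' @return `points_path`, invisibly.
#' @export
write_digitized_sequence <- function(frames, points_path, tracks_path = NULL,
                                     config = sequence_config()) {
  ysign <- if (config$y_down) -1 else 1
  ptab <- do.call(rbind, lapply(frames, function(f) {
    data.frame(frame = f$frame_index,
               point_idx = seq_len(nrow(f$points)),
               x = f$points[, 1], y = ysign * f$points[, 2])
  }))
  write.csv(ptab, points_path, row.names = FALSE)
  if (!is.null(tracks_path)) {
    rows <- lapply(frames, function(f) {
      out <- NULL
      if (!is.null(f$reference_xy))
        out <- rbind(out, data.frame(frame = f$frame_index,
                                     kind = "reference",
                                     x = f$reference_xy[1],
                                     y = ysign * f$reference_xy[2]))
      if (!is.null(f$marker_xy))
        out <- rbind(out, data.frame(frame = f$frame_index, kind = "marker",
                                     x = f$marker_xy[1],
                                     y = ysign * f$marker_xy[2]))
      out
    })
    ttab <- do.call(rbind, rows)
    if (is.null(ttab))
      ttab <- data.frame(frame = integer(), kind = character(),
                         x = numeric(), y = numeric())
    write.csv(ttab, tracks_path, row.names = FALSE)
  }
  invisible(points_path)
}

#' Apex-rooted half profile at one time sample
#'
#' Ordered points from the apex (index `b = 0`) to the bell margin, in the
#' jellyfish body frame once corrected, with coordinates normalized by the
#' relaxed half exumbrella arclength of the first cycle.
#'
#' @param points two-column matrix of ordered points.
#' @param time time in seconds.
#' @param side `"left"` or `"right"`.
#' @return an object of class `half_profile` with fields `points`, `time`,
#'   `side`, `n` and polyline arclength `L`.
#' @export
half_profile <- function(points, time = 0, side = c("right", "left")) {
  side <- match.arg(side)
  p <- .as_xy(points)
  structure(list(time = as.numeric(time), side = side, points = p,
                 n = nrow(p), L = polyline_arclength(p)),
            class = "half_profile")
}

#' @export
print.half_profile <- function(x, ...) {
  cat(sprintf("half_profile: %s side, t = %.3f s, %d points, L = %.6g\n",
              x$side, x$time, x$n, x$L))
  invisible(x)
}

#' Write half profiles to delimited text
#'
#' One row per point with columns `time`, `side`, `b` (0-based index from
#' the apex) and normalized coordinates `x_n`, `y_n`. All profiles must
#' share the same point count. Values round-trip to better than 1e-9.
#'
#' @param profiles list of [half_profile()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_half_profiles <- function(profiles, path) {
  if (length(profiles)) {
    ns <- vapply(profiles, function(p) p$n, 0L)
    if (length(unique(ns)) != 1L)
      stop("all half profiles must share the same number of points")
    tab <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(time = p$time, side = p$side, b = 0:(p$n - 1L),
                 x_n = p$points[, 1], y_n = p$points[, 2])
    }))
  } else {
    tab <- data.frame(time = numeric(), side = character(), b = integer(),
                      x_n = numeric(), y_n = numeric())
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read half profiles written by [write_half_profiles()]
#'
#' @param path CSV path.
#' @return list of [half_profile()], ordered by time then side.
#' @export
read_half_profiles <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "side", "b", "x_n", "y_n")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("half-profile file is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(tab)) return(list())
  key <- paste(format(tab$time, digits = 17), tab$side)
  out <- lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
                function(i) {
                  sub <- tab[i, , drop = FALSE]
                  sub <- sub[order(sub$b), , drop = FALSE]
                  half_profile(cbind(sub$x_n, sub$y_n),
                               time = sub$time[1], side = sub$side[1])
                })
  names(out) <- NULL
  ord <- order(vapply(out, function(p) p$time, 0),
               vapply(out, function(p) p$side, ""))
  out[ord]
}

#' Write a Fourier kinematic model to JSON
#'
#' Stores, per channel, the mean coefficient `a0` and the cosine/sine
#' coefficient pairs up to the model order, together with the order and
#' the cycle period, so a fitted gait can be shared as a small
#' coefficient table.
#'
#' @param model a `fourier_kinematic_model` from [fit_fourier()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fourier_model <- function(model, path) {
  stopifnot(inherits(model, "fourier_kinematic_model"))
  payload <- list(order = model$order, period = model$period,
                  channels = lapply(model$channels, function(ch)
                    list(a0 = ch$a0, a = as.numeric(ch$a),
                         b = as.numeric(ch$b))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Fourier kinematic model written by [write_fourier_model()]
#'
#' @param path JSON path.
#' @return a `fourier_kinematic_model`.
#' @export
read_fourier_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- lapply(raw$channels, function(ch)
    list(a0 = as.numeric(ch$a0),
         a = if (length(ch$a)) as.numeric(ch$a) else numeric(),
         b = if (length(ch$b)) as.numeric(ch$b) else numeric()))
  structure(list(channels = channels, order = as.integer(raw$order),
                 period = as.numeric(raw$period),
                 omega = 2 * pi / as.numeric(raw$period)),
            class = "fourier_kinematic_model")
}

#' Write a discrete bell model (node set) to JSON
#'
#' @param model a `discrete_bell_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_bell_model <- function(model, path) {
  stopifnot(inherits(model, "discrete_bell_model"))
  payload <- list(fractions = model$fractions, E = model$E, E_j = model$E_j,
                  times = model$times, sides = model$sides,
                  nodes = lapply(model$nodes, function(m)
                    list(x = m[, 1], y = m[, 2])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a discrete bell model written by [write_bell_model()]
#'
#' @param path JSON path.
#' @return a `discrete_bell_model`.
#' @export
read_bell_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- if (is.data.frame(raw$nodes)) {
    lapply(seq_len(nrow(raw$nodes)), function(i)
      cbind(unlist(raw$nodes$x[i]), unlist(raw$nodes$y[i])))
  } else {
    lapply(raw$nodes, function(nd) cbind(as.numeric(nd$x),
                                         as.numeric(nd$y)))
  }
  structure(list(fractions = as.numeric(raw$fractions),
                 times = as.numeric(raw$times),
                 sides = as.character(raw$sides),
                 nodes = nodes,
                 E_j = as.numeric(raw$E_j), E = as.numeric(raw$E),
                 n_segments = length(raw$fractions) - 1L),
            class = "discrete_bell_model")
}
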