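#' Detect tongue-base-retraction onset and offset
#'
#' Onset is the frame at which the posterior superficial marker is at its
#' most anterior (maximum X) before beginning to move posteriorly; offset is
#' the frame at which the vallecular marker is at its most posterior
#' (minimum X) after onset. When the vallecular series is missing, offset
#' falls back to the end of the posterior superficial marker's posterior
#' movement (its minimum X after onset) and the method is flagged.
#'
#' Extrema are located on a moving-average smoothed copy of each series
#' (precision-scale marker noise can displace a raw extremum by several
#' frames); pass \code{smooth_window = 1} for raw argmax/argmin.
#'
#' @param posterior_surface_x numeric series of posterior superficial marker
#'   X (positive anterior), cranial frame.
#' @param vallecular_x numeric series of vallecular marker X, or NULL when
#'   unavailable.
#' @param window length-2 integer: per-cycle search bounds (frames)
#'   containing one swallow.
#' @param smooth_window moving-average width, frames (odd; default 21).
#' @return list with \code{onset}, \code{offset} (frame indices) and
#'   \code{method} ("vallecular" or "posterior-surface fallback").
#' @export
detect_tbr <- function(posterior_surface_x, vallecular_x = NULL,
                       window = c(1, length(posterior_surface_x)),
                       smooth_window = 21) {
  n <- length(posterior_surface_x)
  w1 <- max(1L, as.integer(window[1])); w2 <- min(n, as.integer(window[2]))
  if (w2 <= w1) stop("empty search window")
  ps <- smooth_ma(posterior_surface_x, smooth_window)
  idx <- w1:w2
  onset <- idx[which.max(ps[idx])]
  if (onset == w1 || onset == w2)
    stop("detection failure: no interior maximum of posterior surface X in window")
  use_vall <- !is.null(vallecular_x) && !all(is.na(vallecular_x))
  if (use_vall) {
    vx <- smooth_ma(vallecular_x, smooth_window)
    method <- "vallecular"
  } else {
    vx <- ps
    method <- "posterior-surface fallback"
    log_stage("detect_tbr", fallback = "vallecular series missing")
  }
  idx2 <- (onset + 1L):w2
  offset <- idx2[which.min(vx[idx2])]
  if (offset == w2)
    stop("detection failure: no interior minimum after onset in window")
  list(onset = onset, offset = offset, method = method)
}

# centered moving average, width w (odd), shrinking at the edges
smooth_ma <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cx <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cx[hi + 1L] - cx[lo]) / pmax(1L, cn[hi + 1L] - cn[lo])
}

#' Detect intercuspal phase intervals
#'
#' The intercuspal phase (IP) is the period when mandibular pitch velocity
#' stays within two standard deviations of the precision-study zero
#' velocity. Returns the maximal intervals of in-band velocity lasting at
#' least \code{min_frames}.
#'
#' @param pitch_velocity mandibular pitch velocity series, deg/s.
#' @param band length-2 numeric from \code{\link{zero_velocity_band}}.
#' @param min_frames minimum interval duration, frames (default 2).
#' @return data.frame with columns \code{start}, \code{end} (frame indices,
#'   inclusive); zero rows when velocity never stays in band.
#' @export
detect_ip <- function(pitch_velocity, band, min_frames = 2) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  inband <- !is.na(pitch_velocity) &
    pitch_velocity >= band[1] & pitch_velocity <= band[2]
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_frames)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Change relative to TBR onset
#'
#' \code{delta_series(x, onset)} returns \code{x - x[onset]}: the per-frame
#' change of a kinematic or volumetric series referenced to its value at
#' tongue-base-retraction onset.
#'
#' @param x numeric series.
#' @param onset onset frame index.
#' @return numeric series, exactly 0 at the onset frame.
#' @export
delta_series <- function(x, onset) {
  if (onset < 1 || onset > length(x)) stop("onset outside series")
  if (is.na(x[onset])) {
    log_stage("delta_series", error = "missing value at onset")
    return(rep(NA_real_, length(x)))
  }
  x - x[onset]
}

#' Per-cycle swallow record
#'
#' Bundles the event times and delta series of one swallow cycle.
#'
#' @param cycle_id identifier.
#' @param onset,offset TBR onset/offset frames (onset < offset).
#' @param method offset method from \code{\link{detect_tbr}}.
#' @param ip data.frame of IP intervals (may be empty).
#' @param series named list of per-frame series; each is converted to a
#'   delta series referenced to \code{onset}.
#' @return object of class \code{swallow_cycle_record}.
#' @export
swallow_cycle_record <- function(cycle_id, onset, offset, method,
                                 ip = NULL, series = list()) {
  stopifnot(onset < offset)
  if (!is.null(ip) && nrow(ip) > 1) {
    o <- order(ip$start)
    if (any(ip$start[o][-1] <= ip$end[o][-nrow(ip)]))
      stop("IP intervals overlap")
  }
  deltas <- lapply(series, delta_series, onset = onset)
  structure(list(cycle_id = cycle_id, onset = onset, offset = offset,
                 method = method, ip = ip, deltas = deltas),
            class = "swallow_cycle_record")
}

#' @export
print.swallow_cycle_record <- function(x, ...) {
  cat(sprintf("swallow_cycle_record '%s': TBR %d-%d (%s), %d delta series\n",
              x$cycle_id, x$onset, x$offset, x$method, length(x$deltas)))
  invisible(x)
}
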