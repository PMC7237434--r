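#' Coronal marker rings
#'
#' A \code{coronal_ring} is a closed 3D curve through an ordered set of
#' control points (normally the 4 markers bounding a coronal tongue
#' cross-section). It stores \code{points}, an n x 3 matrix of ordered curve
#' samples with the closure implied (the first point follows the last), the
#' control points, and the index of the designated start control (middle deep
#' marker or reconstructed dorsal hyoid point).
#'
#' \code{coronal_ring} builds a ring directly from an explicit sample loop;
#' \code{\link{fit_coronal_ring}} builds one from 4 control markers by spline
#' interpolation.
#'
#' @param points n x 3 matrix of ordered samples (first point is the start
#'   point; do not duplicate the closing point).
#' @param control_points optional k x 3 matrix of the controls the ring
#'   interpolates.
#' @return object of class \code{coronal_ring}.
#' @export
coronal_ring <- function(points, control_points = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 8)
  if (sum((points[1, ] - points[nrow(points), ])^2) < 1e-20)
    points <- points[-nrow(points), , drop = FALSE]   # drop duplicated closure
  structure(list(points = points, control_points = control_points),
            class = "coronal_ring")
}

#' @export
print.coronal_ring <- function(x, ...) {
  cat(sprintf("coronal_ring: %d samples, circumference %.3f mm\n",
              nrow(x$points), ring_circumference(x)))
  invisible(x)
}

#' Ring circumference (closed polyline length)
#' @param ring a \code{coronal_ring}.
#' @return total arc length, mm.
#' @export
ring_circumference <- function(ring) {
  p <- ring$points
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

#' Fit a closed coronal spline ring through 4 control points
#'
#' A natural cubic spline (per coordinate, \code{stats::splinefun} with
#' \code{method = "natural"}) is fit through the ordered control set wrapped
#' for three full loops, starting and ending at the designated start control;
#' only the middle (second) loop is retained, giving a closed ring free of
#' natural-spline end-condition artifacts. The spline is parameterized by
#' cumulative chord length and sampled at \code{n} points per loop.
#'
#' @param control_points 4 x 3 matrix of distinct ordered control points; the
#'   first row is the start control (middle deep marker for the middle ring,
#'   reconstructed dorsal hyoid for the posterior ring).
#' @param n samples per loop (default 300).
#' @return a \code{coronal_ring} with \code{n} samples, sample 1 at the start
#'   control.
#' @export
fit_coronal_ring <- function(control_points, n = 300) {
  cp <- as.matrix(control_points)
  stopifnot(nrow(cp) == 4, ncol(cp) == 3)
  if (anyNA(cp)) stop("missing control point")
  d <- as.matrix(stats::dist(cp))
  if (any(d[upper.tri(d)] < 1e-9))
    stop("degenerate ring: duplicate control points")
  # three full loops: s a b c | s a b c | s a b c | s  (13 knots, 12 segments)
  knots <- cp[c(rep(1:4, 3), 1), , drop = FALSE]
  seg <- sqrt(rowSums(diff(knots)^2))
  tk <- c(0, cumsum(seg))                       # chord-length parameter
  fx <- stats::splinefun(tk, knots[, 1], method = "natural")
  fy <- stats::splinefun(tk, knots[, 2], method = "natural")
  fz <- stats::splinefun(tk, knots[, 3], method = "natural")
  # middle loop spans knots 5..9, i.e. parameter [tk[5], tk[9]]
  ts <- seq(tk[5], tk[9], length.out = n + 1)[seq_len(n)]
  pts <- cbind(fx(ts), fy(ts), fz(ts))
  coronal_ring(pts, control_points = cp)
}

# unit normal giving the ring's winding sense (area vector about centroid)
ring_area_vector <- function(points) {
  ctr <- colMeans(points)
  p <- sweep(points, 2, ctr)
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  av <- c(sum(p[, 2] * q[, 3] - p[, 3] * q[, 2]),
          sum(p[, 3] * q[, 1] - p[, 1] * q[, 3]),
          sum(p[, 1] * q[, 2] - p[, 2] * q[, 1])) / 2
  av
}

#' Resample a ring at equal arc length
#'
#' Returns \code{n} points along the closed ring polyline at equal arc-length
#' spacing, the first at the ring's start point, ordered with the ring's
#' winding.
#'
#' @param ring a \code{coronal_ring}.
#' @param n number of samples (>= 8).
#' @return n x 3 matrix.
#' @export
resample_ring <- function(ring, n) {
  stopifnot(n >= 8)
  p <- ring$points
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(q)] <- nrow(q) - 1
  w <- (s - cum[idx]) / seg[idx]
  q[idx, , drop = FALSE] + (q[idx + 1, , drop = FALSE] - q[idx, , drop = FALSE]) * w
}

#' Arc-length resampling of two rings into matched correspondence
#'
#' Both rings are resampled to \code{n} equal-arc-length points; index 1 on
#' each ring is its start control (middle deep marker on the middle ring,
#' reconstructed dorsal hyoid on the posterior ring), establishing the
#' canonical one-to-one correspondence between the two loops. Both sequences
#' are ordered with the same handedness: each ring is oriented
#' counterclockwise as viewed from anterior (+X); a ring arriving with the
#' opposite handedness is reversed automatically (logged).
#'
#' @param middle,posterior \code{coronal_ring}s.
#' @param n samples per ring (>= 8).
#' @param axis viewing axis used to fix handedness (default +X, anterior).
#' @return list with \code{middle} and \code{posterior}, each an n x 3 matrix
#'   of matched samples.
#' @export
resample_matched_rings <- function(middle, posterior, n = 300, axis = c(1, 0, 0)) {
  orient <- function(r, who) {
    if (sum(ring_area_vector(r$points) * axis) < 0) {
      log_stage("resample_matched_rings", reversed = who)
      pts <- r$points[c(1, nrow(r$points):2), , drop = FALSE]  # keep start first
      r <- coronal_ring(pts, r$control_points)
    }
    r
  }
  middle <- orient(middle, "middle")
  posterior <- orient(posterior, "posterior")
  list(middle = resample_ring(middle, n),
       posterior = resample_ring(posterior, n))
}
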