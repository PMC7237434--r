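#' Rigid-body pose from a marker cluster (one frame)
#'
#' Closed-form least-squares rigid registration (SVD / Kabsch) of a bone-fixed
#' marker cluster onto its observed positions, with a reflection guard so the
#' returned rotation has determinant +1. Markers missing (NA) in either
#' configuration are dropped; at least three non-collinear common markers are
#' required.
#'
#' @param ref k x 3 reference (bone-fixed) marker positions.
#' @param obs k x 3 observed positions in the target (cranial) frame.
#' @return list with \code{R} (3 x 3 rotation), \code{t} (translation,
#'   \code{obs ~ ref \%*\% t(R) + t}), and \code{residual_rms} (mm).
#' @export
estimate_pose <- function(ref, obs) {
  ref <- as.matrix(ref); obs <- as.matrix(obs)
  stopifnot(ncol(ref) == 3, ncol(obs) == 3, nrow(ref) == nrow(obs))
  ok <- stats::complete.cases(ref) & stats::complete.cases(obs)
  if (sum(ok) < 3)
    stop("insufficient markers: need >= 3 usable markers, have ", sum(ok))
  A <- ref[ok, , drop = FALSE]; B <- obs[ok, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Ac, Bc))        # t(Ac) %*% Bc
  if (svd(Ac)$d[2] < 1e-9 * max(1, svd(Ac)$d[1]))
    stop("degenerate marker cluster: markers are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.vector(R %*% ca)
  fit <- sweep(Ac %*% t(R), 2, cb, `+`)
  res <- sqrt(mean(rowSums((fit - B)^2)))
  list(R = R, t = t, residual_rms = res)
}

#' Rigid-body pose series from a marker-cluster trajectory
#'
#' Applies \code{\link{estimate_pose}} frame by frame. Frames with fewer than
#' three usable markers yield NA pose entries.
#'
#' @param ref k x 3 reference (bone-fixed) cluster.
#' @param markers a \code{marker_set} containing the cluster markers, in the
#'   target frame.
#' @param names marker names of the cluster, in the row order of \code{ref};
#'   defaults to all markers.
#' @return object of class \code{rigid_pose}: list with \code{R}
#'   (3 x 3 x frames), \code{t} (frames x 3), \code{residual_rms} (frames),
#'   \code{frame_rate}.
#' @export
pose_series <- function(ref, markers, names = NULL) {
  if (is.null(names)) names <- marker_names(markers)
  nfr <- n_frames(markers)
  obs_all <- markers$coords[, names, , drop = FALSE]
  Rarr <- array(NA_real_, c(3, 3, nfr))
  tmat <- matrix(NA_real_, nfr, 3)
  res <- rep(NA_real_, nfr)
  for (f in seq_len(nfr)) {
    obs <- matrix(obs_all[f, , ], ncol = 3)
    p <- tryCatch(estimate_pose(ref, obs), error = function(e) NULL)
    if (is.null(p)) next
    Rarr[, , f] <- p$R; tmat[f, ] <- p$t; res[f] <- p$residual_rms
  }
  structure(list(R = Rarr, t = tmat, residual_rms = res,
                 frame_rate = markers$frame_rate),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: %d frames @ %g Hz, median residual %.4g mm\n",
              dim(x$R)[3], x$frame_rate,
              stats::median(x$residual_rms, na.rm = TRUE)))
  invisible(x)
}

#' Mandibular pitch (gape) angle
#'
#' Pitch is the rotation of the mandible about the cranial Z (mediolateral)
#' axis, extracted from the per-frame rotation by a Z-X-Y intrinsic Euler
#' decomposition, and signed so that jaw opening (anterior mandible moving
#' inferiorly) is positive. The angle is zeroed at a reference frame,
#' by default the frame of minimum gape in the sequence (intercuspation
#' proxy).
#'
#' @param pose a \code{rigid_pose} of the mandible in the cranial frame.
#' @param reference reference frame index, or \code{"min_gape"}.
#' @return numeric vector of pitch angles, degrees, per frame.
#' @export
gape_pitch_angle <- function(pose, reference = "min_gape") {
  nfr <- dim(pose$R)[3]
  raw <- rep(NA_real_, nfr)
  for (f in seq_len(nfr)) {
    R <- pose$R[, , f]
    if (anyNA(R)) next
    raw[f] <- -euler_z_zxy(R)   # opening rotates X toward -Y: negative about +Z
  }
  ref <- if (identical(reference, "min_gape")) which.min(raw) else as.integer(reference)
  if (!length(ref) || is.na(ref) || ref < 1 || ref > nfr)
    stop("reference frame outside series")
  log_stage("gape_pitch_angle", reference_frame = ref)
  raw - raw[ref]
}

# Z angle (radians -> degrees) of the intrinsic Z-X-Y decomposition
# R = Rz(g) %*% Rx(a) %*% Ry(b); column 2 of Rx%*%Ry is (0, cos a, sin a),
# so g = atan2(-R[1,2], R[2,2]).
euler_z_zxy <- function(R) atan2(-R[1, 2], R[2, 2]) * 180 / pi

#' Hyoid excursion (protraction, elevation)
#'
#' Change in the hyoid reference point's anteroposterior (X) and
#' superoinferior (Y) position relative to its value at a reference frame.
#' Protraction is positive anterior, elevation positive superior.
#'
#' @param xyz frames x 3 matrix of the hyoid reference point (basihyoid
#'   centroid) in the cranial frame, or a \code{rigid_pose} whose translation
#'   tracks that point.
#' @param reference_frame frame index at which excursion is zero.
#' @return data.frame with columns \code{protraction}, \code{elevation} (mm).
#' @export
hyoid_excursion <- function(xyz, reference_frame = 1) {
  if (inherits(xyz, "rigid_pose")) xyz <- xyz$t
  xyz <- as.matrix(xyz)
  if (reference_frame < 1 || reference_frame > nrow(xyz))
    stop("reference frame outside series")
  data.frame(protraction = xyz[, 1] - xyz[reference_frame, 1],
             elevation   = xyz[, 2] - xyz[reference_frame, 2])
}

#' Pooled standard deviation across animals
#'
#' \code{sqrt((s_1^2 + ... + s_k^2) / k)}: the root mean square of the
#' per-animal standard deviations, the precision summary reported for
#' static-specimen recordings.
#'
#' @param sds numeric vector of per-animal standard deviations (>= 0).
#' @return pooled SD (scalar).
#' @export
pooled_sd <- function(sds) {
  if (!length(sds)) stop("empty SD list")
  stopifnot(all(sds >= 0))
  sqrt(mean(sds^2))
}

#' Zero-velocity band from a precision recording
#'
#' The band of velocities treated as indistinguishable from zero:
#' +/- 2 standard deviations of the velocity measured on a static specimen.
#'
#' @param velocity numeric velocity series from a static (precision)
#'   recording.
#' @return numeric length-2 vector \code{c(lo, hi)} symmetric about 0.
#' @export
zero_velocity_band <- function(velocity) {
  v <- velocity[!is.na(velocity)]
  s <- if (length(v) > 1) stats::sd(v) else 0
  if (s == 0) warning("constant precision series: zero-width band")
  c(-2 * s, 2 * s)
}

#' Central-difference velocity at the native frame rate
#'
#' Central differences in the interior, one-sided at the endpoints.
#'
#' @param x numeric series.
#' @param frame_rate sampling rate, Hz.
#' @return velocity series, units of \code{x} per second.
#' @export
central_velocity <- function(x, frame_rate) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  v <- rep(NA_real_, n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  v[1] <- x[2] - x[1]
  v[n] <- x[n] - x[n - 1]
  v * frame_rate
}

#' Track a bone-fixed point through a pose series
#'
#' Applies each frame's rigid transform to a point given in bone-fixed
#' coordinates (e.g. reconstructing the dorsal hyoid landmark from the hyoid
#' marker cluster's pose).
#'
#' @param pose a \code{rigid_pose}.
#' @param point 3-vector in bone-fixed coordinates.
#' @return frames x 3 matrix of the point in the target frame.
#' @export
posed_point <- function(pose, point) {
  nfr <- dim(pose$R)[3]
  out <- matrix(NA_real_, nfr, 3)
  p <- as.numeric(point)
  for (f in seq_len(nfr)) {
    if (anyNA(pose$R[, , f])) next
    out[f, ] <- pose$R[, , f] %*% p + pose$t[f, ]
  }
  colnames(out) <- c("X", "Y", "Z")
  out
}
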