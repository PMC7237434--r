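#' Muscle attachment definitions
#'
#' A muscle is measured between two attachments: each is either the name of a
#' marker in the trajectory set or a fixed reconstructed point (3-vector, mm,
#' already in the working frame). Attachments must be distinct.
#'
#' @param name muscle name.
#' @param origin attachment at the skeletal origin: marker name or 3-vector.
#' @param insertion attachment at the (lingual) insertion: marker name or
#'   3-vector.
#' @return object of class \code{muscle_def}.
#' @export
muscle_def <- function(name, origin, insertion) {
  if (is.character(origin) && is.character(insertion) &&
      identical(origin, insertion))
    stop("muscle attachments must be distinct")
  structure(list(name = name, origin = origin, insertion = insertion),
            class = "muscle_def")
}

# per-frame coordinates of an attachment: frames x 3
resolve_attachment <- function(att, markers) {
  if (is.character(att)) return(marker_xyz(markers, att))
  matrix(rep(as.numeric(att), each = n_frames(markers)), ncol = 3)
}

#' Muscle length per frame
#'
#' Euclidean distance between the two attachments; NA whenever either
#' endpoint is missing in a frame.
#'
#' @param def a \code{muscle_def}.
#' @param markers a \code{marker_set}.
#' @return numeric vector, mm per frame.
#' @export
muscle_length <- function(def, markers) {
  o <- resolve_attachment(def$origin, markers)
  i <- resolve_attachment(def$insertion, markers)
  sqrt(rowSums((o - i)^2))
}

#' Sagittal orientation angle of a muscle line of action
#'
#' Angle of the insertion-to-origin line projected into the cranial X-Y
#' (sagittal) plane, measured from +X with anterior = 0 degrees, increasing
#' toward superior (90), posterior (180) and inferior (270), wrapped to
#' [0, 360). Measuring insertion -> origin makes a retracting line of action
#' read near 180 degrees.
#'
#' @param def a \code{muscle_def}.
#' @param markers a \code{marker_set} already expressed in the cranial frame
#'   (or pass \code{frame} to convert).
#' @param frame optional \code{anatomical_frame}; when supplied, coordinates
#'   are converted before projecting.
#' @return numeric vector of angles in degrees; NA where an endpoint is
#'   missing or the sagittal projection has zero length.
#' @export
sagittal_angle <- function(def, markers, frame = NULL) {
  if (!is.null(frame)) markers <- markers_to_frame(markers, frame)
  o <- resolve_attachment(def$origin, markers)
  i <- resolve_attachment(def$insertion, markers)
  dx <- unname(o[, 1] - i[, 1])
  dy <- unname(o[, 2] - i[, 2])
  ang <- atan2(dy, dx) * 180 / pi
  ang <- ang %% 360
  zero <- !is.na(dx) & !is.na(dy) & (dx^2 + dy^2) < 1e-20
  ang[zero] <- NA_real_
  if (any(zero)) log_stage("sagittal_angle", undefined_frames = sum(zero))
  ang
}

#' Is an orientation predominantly posterior?
#'
#' The posterior band convention: 135 < theta < 225 degrees.
#' @param theta sagittal angle(s), degrees.
#' @return logical vector.
#' @export
is_posterior_oriented <- function(theta) !is.na(theta) & theta > 135 & theta < 225

#' Contraction-state classification
#'
#' Combines velocity with the zero-velocity band and EMG activity:
#' active frames are concentric (shortening) when velocity is below the band,
#' eccentric (lengthening) above it, isometric within it; inactive frames are
#' labelled inactive regardless of velocity.
#'
#' @param velocity muscle velocity series, mm/s (negative = shortening).
#' @param band length-2 numeric \code{c(lo, hi)} from
#'   \code{\link{zero_velocity_band}}.
#' @param active logical series of EMG supra-threshold activity.
#' @return factor series with levels concentric, isometric, eccentric,
#'   inactive; NA where velocity is missing.
#' @export
classify_state <- function(velocity, band, active) {
  if (length(band) != 2 || band[1] > band[2])
    stop("malformed zero-velocity band")
  stopifnot(length(velocity) == length(active))
  lab <- rep(NA_character_, length(velocity))
  ok <- !is.na(velocity) & !is.na(active)
  lab[ok & !active] <- "inactive"
  lab[ok & active & velocity < band[1]] <- "concentric"
  lab[ok & active & velocity > band[2]] <- "eccentric"
  lab[ok & active & velocity >= band[1] & velocity <= band[2]] <- "isometric"
  factor(lab, levels = c("concentric", "isometric", "eccentric", "inactive"))
}

#' Linear tongue dimensions per frame
#'
#' Axis-projected distances between lingual markers in the cranial frame:
#' \itemize{
#'   \item posterior width: |Z| distance between the two lateral posterior
#'     markers; posterior depth (height): |Y| distance between the posterior
#'     surface marker and the dorsal hyoid point; posterior length: |X|
#'     distance between the posterior and middle surface markers.
#'   \item anterior width: |Z| between the two (middle) lateral markers;
#'     anterior depth: |Y| between middle surface and middle deep markers;
#'     anterior length: |X| between the anterior (tip) and middle surface
#'     markers. The same axis-projection scheme as the posterior dimensions
#'     is assumed.
#'   \item tongue base: width and depth share the posterior ring (the TB-POT
#'     interface); TB length is the |X| distance between the midpoint of the
#'     two posterolateral markers and the vallecular marker.
#' }
#' Missing required markers give NA for the affected dimension.
#'
#' @param markers a \code{marker_set} in the cranial frame with markers named
#'   \code{anterior}, \code{lateral_right}, \code{lateral_left},
#'   \code{middle_surface}, \code{middle_deep}, \code{posterior_surface},
#'   \code{posterior_right}, \code{posterior_left}, and optionally
#'   \code{vallecula}.
#' @param hyoid_dorsal frames x 3 matrix of the reconstructed dorsal hyoid
#'   point in the same frame.
#' @return data.frame of per-frame dimensions (mm): anterior/posterior/tb
#'   width, depth, length.
#' @export
tongue_dimensions <- function(markers, hyoid_dorsal) {
  g <- function(nm) if (nm %in% marker_names(markers)) marker_xyz(markers, nm) else
    matrix(NA_real_, n_frames(markers), 3)
  ant <- g("anterior"); lr <- g("lateral_right"); ll <- g("lateral_left")
  ms <- g("middle_surface"); md <- g("middle_deep")
  ps <- g("posterior_surface"); pr <- g("posterior_right"); pl <- g("posterior_left")
  va <- g("vallecula")
  hy <- as.matrix(hyoid_dorsal)
  data.frame(
    anterior_width   = abs(lr[, 3] - ll[, 3]),
    anterior_depth   = abs(ms[, 2] - md[, 2]),
    anterior_length  = abs(ant[, 1] - ms[, 1]),
    posterior_width  = abs(pr[, 3] - pl[, 3]),
    posterior_depth  = abs(ps[, 2] - hy[, 2]),
    posterior_length = abs(ps[, 1] - ms[, 1]),
    tb_width         = abs(pr[, 3] - pl[, 3]),
    tb_depth         = abs(ps[, 2] - hy[, 2]),
    tb_length        = abs((pr[, 1] + pl[, 1]) / 2 - va[, 1])
  )
}
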