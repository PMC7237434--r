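#' Anatomical (cranial) coordinate frames
#'
#' The cranial anatomical frame has its X axis anteroposterior (+X anterior),
#' Y axis superoinferior (+Y superior) and Z axis mediolateral (+Z toward the
#' animal's right), with the palate plane containing the X axis. Angles (jaw
#' pitch, muscle sagittal orientation) are measured relative to the palate
#' plane, anterior = 0 degrees.
#'
#' \code{build_anatomical_frame} constructs the frame from landmarks: the
#' palate plane is the least-squares plane of \code{palate_landmarks}
#' (>= 3, non-collinear); the +X direction is the in-plane projection of the
#' vector from the first to the last \code{midline_landmarks} point (ordered
#' posterior to anterior). The +Y (superior) sign is fixed so the first three
#' palate landmarks wind counterclockwise when viewed from above, making the
#' construction equivariant under rigid transforms of all inputs. The origin
#' is the palate-landmark centroid.
#'
#' @param palate_landmarks k x 3 matrix, k >= 3 non-collinear points on the
#'   palate.
#' @param midline_landmarks j x 3 matrix, j >= 2 midline points ordered
#'   posterior to anterior.
#' @return an object of class \code{anatomical_frame} with fields
#'   \code{origin} (3-vector) and \code{axes} (3 x 3 rotation whose columns
#'   are the world directions of the frame's X, Y, Z axes).
#' @export
build_anatomical_frame <- function(palate_landmarks, midline_landmarks) {
  P <- as.matrix(palate_landmarks)
  M <- as.matrix(midline_landmarks)
  stopifnot(ncol(P) == 3, ncol(M) == 3, nrow(P) >= 3, nrow(M) >= 2)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate geometry: palate landmarks are collinear")
  n <- sv$v[, 3]                              # least-squares plane normal
  w <- crossprod3(P[2, ] - P[1, ], P[3, ] - P[1, ])
  s <- sum(w * n)
  if (abs(s) < 1e-12)
    stop("degenerate geometry: first three palate landmarks are collinear")
  y <- n * sign(s)
  ant <- M[nrow(M), ] - M[1, ]
  ant <- ant - sum(ant * y) * y               # project into palate plane
  if (sqrt(sum(ant^2)) < 1e-12)
    stop("degenerate geometry: midline landmarks give no in-plane anterior direction")
  x <- ant / sqrt(sum(ant^2))
  z <- crossprod3(x, y)
  axes <- cbind(X = x, Y = y, Z = z)
  structure(list(origin = ctr, axes = axes), class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("anatomical_frame: origin", paste(sprintf("%.3f", x$origin), collapse = " "), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' Express world coordinates in an anatomical frame
#'
#' @param points n x 3 matrix of world coordinates (or a 3-vector).
#' @param frame an \code{anatomical_frame}.
#' @return n x 3 matrix of frame coordinates (columns X, Y, Z).
#' @export
to_frame <- function(points, frame) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  out <- sweep(p, 2, frame$origin) %*% frame$axes
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' @rdname to_frame
#' @export
from_frame <- function(points, frame) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  sweep(p %*% t(frame$axes), 2, -frame$origin)
}

#' Express a whole marker set in an anatomical frame
#' @param markers a \code{marker_set}.
#' @param frame an \code{anatomical_frame}.
#' @return a \code{marker_set} in frame coordinates.
#' @export
markers_to_frame <- function(markers, frame) {
  co <- markers$coords
  for (j in seq_len(dim(co)[2]))
    co[, j, ] <- to_frame(co[, j, ], frame)
  marker_set(co, marker_names(markers), markers$frame_rate)
}

# cross product of two 3-vectors
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' The identity (canonical) anatomical frame
#' @return an \code{anatomical_frame} with zero origin and identity axes.
#' @export
canonical_frame <- function() {
  structure(list(origin = c(0, 0, 0), axes = diag(3)), class = "anatomical_frame")
}
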