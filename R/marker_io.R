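#' Marker trajectory sets
#'
#' A \code{marker_set} holds per-frame 3D positions (mm) for a named set of
#' markers as a frames x markers x 3 array, together with the capture frame
#' rate. Missing observations are \code{NA} (never silently zero).
#'
#' @param coords numeric array, frames x markers x 3, or a frames x (3*m)
#'   matrix whose columns are grouped in X, Y, Z triplets.
#' @param marker_names character vector of marker names.
#' @param frame_rate capture rate, Hz (> 0).
#' @return An object of class \code{marker_set}.
#' @export
marker_set <- function(coords, marker_names = NULL, frame_rate = 200) {
  if (length(dim(coords)) == 2) {
    stopifnot(ncol(coords) %% 3 == 0)
    m <- ncol(coords) / 3
    coords <- array(as.numeric(coords), dim = c(nrow(coords), 3, m))
    coords <- aperm(coords, c(1, 3, 2))  # frames x markers x 3 when input is X1 Y1 Z1 X2...
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3, frame_rate > 0)
  if (is.null(marker_names)) marker_names <- dimnames(coords)[[2]]
  if (is.null(marker_names)) marker_names <- paste0("m", seq_len(dim(coords)[2]))
  stopifnot(length(marker_names) == dim(coords)[2])
  dimnames(coords) <- list(NULL, marker_names, c("X", "Y", "Z"))
  structure(list(coords = coords, frame_rate = frame_rate),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("marker_set: %d frames x %d markers @ %g Hz (%.1f%% missing)\n",
              d[1], d[2], x$frame_rate,
              100 * mean(is.na(x$coords))))
  cat("  markers:", paste(dimnames(x$coords)[[2]], collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_set <- function(x) dim(x$coords)

#' Number of frames / marker names of a marker set
#' @param markers a \code{marker_set}.
#' @return integer count / character vector.
#' @export
n_frames <- function(markers) dim(markers$coords)[1]

#' @rdname n_frames
#' @export
marker_names <- function(markers) dimnames(markers$coords)[[2]]

#' Extract one marker's trajectory
#'
#' @param markers a \code{marker_set}.
#' @param name marker name.
#' @return frames x 3 matrix (columns X, Y, Z).
#' @export
marker_xyz <- function(markers, name) {
  if (!name %in% marker_names(markers))
    stop("unknown marker: ", name)
  out <- markers$coords[, name, , drop = FALSE]
  matrix(out, ncol = 3, dimnames = list(NULL, c("X", "Y", "Z")))
}

#' Read marker trajectories from a delimited table
#'
#' Expects a comma-delimited text file with a header naming markers as
#' \code{<name>_X}, \code{<name>_Y}, \code{<name>_Z} triplets, one row per
#' frame. A frame-index column (any column not part of a coordinate triplet
#' named \code{frame} or \code{time}) is ignored. Non-numeric or blank cells
#' become missing values.
#'
#' @param path file path.
#' @param frame_rate capture rate, Hz.
#' @return a \code{marker_set}.
#' @export
read_marker_table <- function(path, frame_rate = 200) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty marker table: ", path)
  cn <- names(df)
  is_coord <- grepl("_[XYZ]$", cn)
  extra <- cn[!is_coord]
  bad <- setdiff(extra, c("frame", "time", "t"))
  if (length(bad))
    stop("columns are not <name>_X/_Y/_Z triplets: ", paste(bad, collapse = ", "))
  cn <- cn[is_coord]
  base <- sub("_[XYZ]$", "", cn)
  nms <- unique(base)
  for (nm in nms) {
    want <- paste0(nm, "_", c("X", "Y", "Z"))
    if (!all(want %in% cn))
      stop("incomplete coordinate triplet for marker '", nm, "': have ",
           paste(intersect(want, cn), collapse = ", "))
  }
  nfr <- nrow(df)
  coords <- array(NA_real_, dim = c(nfr, length(nms), 3))
  for (j in seq_along(nms)) {
    for (k in 1:3) {
      col <- df[[paste0(nms[j], "_", c("X", "Y", "Z")[k])]]
      coords[, j, k] <- suppressWarnings(as.numeric(col))
    }
  }
  log_stage("read_marker_table", path = path, markers = length(nms), frames = nfr)
  marker_set(coords, nms, frame_rate)
}

#' Write marker trajectories to a delimited table
#'
#' Inverse of \code{\link{read_marker_table}}: comma-delimited, header row of
#' \code{<name>_X/_Y/_Z} triplets preceded by a \code{frame} column, one row
#' per frame.
#'
#' @param markers a \code{marker_set}.
#' @param path output file path.
#' @param digits significant digits written.
#' @return \code{path}, invisibly.
#' @export
write_marker_table <- function(markers, path, digits = 10) {
  stopifnot(inherits(markers, "marker_set"))
  nms <- marker_names(markers)
  nfr <- n_frames(markers)
  cols <- list(frame = seq_len(nfr))
  for (nm in nms) {
    xyz <- marker_xyz(markers, nm)
    for (k in 1:3)
      cols[[paste0(nm, "_", c("X", "Y", "Z")[k])]] <- signif(xyz[, k], digits)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate short gaps in marker trajectories
#'
#' Linear interpolation of interior missing runs no longer than
#' \code{max_gap} frames. Interpolation never happens silently: this is an
#' explicit call, and each filled gap is logged.
#'
#' @param markers a \code{marker_set}.
#' @param max_gap longest gap (frames) to fill.
#' @return a \code{marker_set} with short gaps filled.
#' @export
interpolate_gaps <- function(markers, max_gap = 5) {
  co <- markers$coords
  for (j in seq_len(dim(co)[2])) for (k in 1:3) {
    v <- co[, j, k]
    na <- is.na(v)
    if (!any(na) || all(na)) next
    r <- rle(na)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      a <- starts[i] - 1; b <- ends[i] + 1
      if (a < 1 || b > length(v)) next        # leading/trailing gaps stay missing
      if (r$lengths[i] > max_gap) next
      idx <- (a + 1):(b - 1)
      v[idx] <- v[a] + (v[b] - v[a]) * (idx - a) / (b - a)
      log_stage("interpolate_gaps", marker = dimnames(co)[[2]][j],
                axis = c("X", "Y", "Z")[k], frames = paste(a + 1, b - 1, sep = "-"))
    }
    co[, j, k] <- v
  }
  marker_set(co, marker_names(markers), markers$frame_rate)
}
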