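#' Pipeline configuration
#'
#' Bundles the tunable parameters shared across pipeline stages, with the
#' defaults used throughout: coordinate conventions (+X anterior, +Y superior,
#' +Z right), EMG filter cutoffs, the alpha radius for oral-cavity volume,
#' ring resampling counts, numeric tolerances and the random seed recorded in
#' all generated outputs.
#'
#' @param frame_rate motion capture frame rate, Hz.
#' @param emg_highpass_hz EMG high-pass cutoff, Hz.
#' @param emg_lowpass_hz EMG low-pass cutoff, Hz (NULL disables low-pass).
#' @param emg_rms_window_s RMS integration window, seconds; also sets the
#'   envelope rate (1 / window).
#' @param alpha alpha radius for the oral-cavity alpha shape, mm.
#' @param n_ring number of equal-arc-length samples per coronal ring.
#' @param clamp_cotangent logical; clamp negative cotangent weights at zero in
#'   the harmonic surface solver (default keeps them, matching the cotangent
#'   Laplacian formulation).
#' @param interpolate_gaps logical; linearly interpolate missing marker frames.
#' @param max_gap_frames largest gap (frames) interpolated when
#'   \code{interpolate_gaps} is TRUE.
#' @param smooth_window moving-average window (frames) used by event
#'   detection before locating extrema.
#' @param tol generic numeric tolerance.
#' @param seed integer random seed recorded in generated outputs.
#'
#' @return An object of class \code{pipeline_config} (a named list).
#' @export
pipeline_config <- function(frame_rate = 200,
                            emg_highpass_hz = 30,
                            emg_lowpass_hz = 1000,
                            emg_rms_window_s = 0.005,
                            alpha = 6,
                            n_ring = 300,
                            clamp_cotangent = FALSE,
                            interpolate_gaps = FALSE,
                            max_gap_frames = 5,
                            smooth_window = 21,
                            tol = 1e-9,
                            seed = 1L) {
  stopifnot(frame_rate > 0, emg_highpass_hz > 0, alpha > 0,
            n_ring >= 8, max_gap_frames >= 1, tol > 0)
  cfg <- list(frame_rate = frame_rate,
              emg_highpass_hz = emg_highpass_hz,
              emg_lowpass_hz = emg_lowpass_hz,
              emg_rms_window_s = emg_rms_window_s,
              alpha = alpha,
              n_ring = as.integer(n_ring),
              clamp_cotangent = isTRUE(clamp_cotangent),
              interpolate_gaps = isTRUE(interpolate_gaps),
              max_gap_frames = as.integer(max_gap_frames),
              smooth_window = as.integer(smooth_window),
              tol = tol,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("hyolingual pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @return \code{read_config} returns a \code{pipeline_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stage logging
#'
#' One timestamped line per pipeline stage, with the stage's parameters and
#' the active seed. Logging goes to the file set by \code{log_file()}, or is
#' silently skipped when no log file is set.
#'
#' @param stage stage name.
#' @param ... named parameters to record.
#' @param seed seed to record (optional).
#' @keywords internal
log_stage <- function(stage, ..., seed = NULL) {
  path <- getOption("hyolingual.log_file", NULL)
  if (is.null(path)) return(invisible(NULL))
  prm <- list(...)
  txt <- if (length(prm))
    paste(names(prm), vapply(prm, function(v) paste(format(v), collapse = ","),
                             character(1)), sep = "=", collapse = " ") else ""
  if (!is.null(seed)) txt <- paste(txt, sprintf("seed=%d", seed))
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"), stage, txt)
  cat(line, "\n", file = path, append = TRUE)
  invisible(line)
}

#' @rdname log_stage
#' @param path log file path, or NULL to disable logging.
#' @export
log_file <- function(path) {
  options(hyolingual.log_file = path)
  invisible(path)
}
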