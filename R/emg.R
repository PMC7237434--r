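#' Condition a raw EMG signal into a 200 Hz envelope
#'
#' Zero-phase (forward-backward) Butterworth filtering — 30 Hz high-pass and
#' an optional low-pass in the 1000-3000 Hz range — followed by full-wave
#' rectification and root-mean-square integration over non-overlapping 5 ms
#' windows. The RMS windows double as the downsampling step: one envelope
#' sample per window, i.e. 200 Hz for the default window.
#'
#' Window boundaries are defined by time; a partial trailing window is
#' dropped (logged).
#'
#' @param raw numeric raw signal (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param hp high-pass cutoff, Hz (default 30); NULL disables.
#' @param lp low-pass cutoff, Hz; NULL disables. Must satisfy
#'   \code{fs >= 2 * lp}.
#' @param window_s RMS window, s (default 0.005 giving a 200 Hz envelope).
#' @param order Butterworth order (4; forward-backward filtering doubles the
#'   effective order).
#' @return object of class \code{emg_envelope}: list with \code{envelope}
#'   (non-negative numeric), \code{rate} (Hz), \code{fs}, \code{window_s}.
#' @export
condition_signal <- function(raw, fs, hp = 30, lp = NULL,
                             window_s = 0.005, order = 4) {
  stopifnot(fs > 0, window_s > 0)
  x <- as.numeric(raw)
  if (!is.null(lp)) {
    if (fs < 2 * lp) stop("sampling rate below Nyquist for requested low-pass")
    bf <- signal::butter(order, lp / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  if (!is.null(hp)) {
    bf <- signal::butter(order, hp / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  x <- abs(x)                                  # full-wave rectification
  w <- round(fs * window_s)
  if (w < 1) stop("window shorter than one sample")
  nwin <- floor(length(x) / w)
  if (nwin < 1) stop("signal shorter than one RMS window")
  if (length(x) > nwin * w)
    log_stage("condition_signal", dropped_samples = length(x) - nwin * w)
  env <- sqrt(colMeans(matrix(x[seq_len(nwin * w)]^2, nrow = w)))
  structure(list(envelope = env, rate = 1 / window_s, fs = fs,
                 window_s = window_s),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("emg_envelope: %d samples @ %g Hz (from %g Hz raw)\n",
              length(x$envelope), x$rate, x$fs))
  invisible(x)
}

#' Count runs above/below a threshold
#'
#' A run is a maximal block of consecutive samples on the same side of the
#' threshold (side = value > threshold).
#'
#' @param x numeric series.
#' @param threshold scalar.
#' @return integer run count (>= 1 for non-empty series).
#' @export
count_runs <- function(x, threshold) {
  b <- x > threshold
  if (!length(b)) return(0L)
  1L + sum(b[-1] != b[-length(b)])
}

# run counts for every threshold in an ascending grid, in O((n+G) log n):
# a run boundary between x[i], x[i+1] exists for thresholds in
# [min(xi, xi+1), max(xi, xi+1)), so runs(t) = 1 + #{lo <= t} - #{hi <= t}.
runs_over_grid <- function(x, grid) {
  lo <- pmin(x[-length(x)], x[-1])
  hi <- pmax(x[-length(x)], x[-1])
  1L + findInterval(grid, sort(lo)) - findInterval(grid, sort(hi))
}

#' Runs-test noise threshold for an EMG envelope
#'
#' Selects the noise threshold that best separates activity from noise by a
#' runs test: for each candidate threshold, the number of runs in the
#' ordered envelope is compared with the number of runs in a randomly
#' permuted copy; the candidate maximizing the difference
#' (randomized - ordered) is selected. The procedure is repeated
#' \code{n_reps} times with fresh permutations and the final threshold is
#' the mean of the per-replicate selections. Ties among equally optimal
#' candidates go to the lowest threshold (conservative toward detecting
#' activity).
#'
#' When activity occupies much more time than noise, restrict the input with
#' \code{subset} to a window in which activity and noise durations are
#' roughly equal.
#'
#' @param envelope an \code{emg_envelope} or non-negative numeric series
#'   (>= 200 samples).
#' @param n_reps number of runs-test replicates averaged (default 30).
#' @param grid_size number of candidate thresholds between the envelope
#'   minimum and maximum (default 200).
#' @param subset optional index vector restricting the series.
#' @param seed integer; per-replicate permutation seeds are derived from it
#'   deterministically.
#' @return object of class \code{runs_test_result}: list with
#'   \code{threshold} (final averaged threshold), \code{per_replicate}
#'   (selected threshold per replicate), \code{grid},
#'   \code{runs_ordered} (run counts over the grid), \code{seed},
#'   \code{n_reps}.
#' @export
thexton_threshold <- function(envelope, n_reps = 30, grid_size = 200,
                              subset = NULL, seed = 1L) {
  env <- if (inherits(envelope, "emg_envelope")) envelope$envelope else as.numeric(envelope)
  if (!is.null(subset)) env <- env[subset]
  if (length(env) < 200) stop("envelope too short for a runs test (need >= 200 samples)")
  if (any(env < 0)) stop("envelope must be non-negative")
  rng <- range(env)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant envelope: threshold set to its value")
    return(structure(list(threshold = rng[1], per_replicate = rep(rng[1], n_reps),
                          grid = rng[1], runs_ordered = NA_integer_,
                          seed = seed, n_reps = n_reps),
                     class = "runs_test_result"))
  }
  grid <- seq(rng[1], rng[2], length.out = grid_size + 2)[-c(1, grid_size + 2)]
  runs_ord <- runs_over_grid(env, grid)
  sel <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    perm <- with_seed(seed + r, sample.int(length(env)))
    runs_rnd <- runs_over_grid(env[perm], grid)
    diff_r <- runs_rnd - runs_ord
    sel[r] <- grid[which.max(diff_r)]          # which.max takes the lowest tie
  }
  log_stage("thexton_threshold", n = length(env), reps = n_reps, seed = seed)
  structure(list(threshold = mean(sel), per_replicate = sel, grid = grid,
                 runs_ordered = runs_ord, seed = seed, n_reps = n_reps),
            class = "runs_test_result")
}

#' @export
print.runs_test_result <- function(x, ...) {
  cat(sprintf("runs_test_result: threshold %.5g (mean of %d replicates, sd %.3g)\n",
              x$threshold, x$n_reps, stats::sd(x$per_replicate)))
  invisible(x)
}

# evaluate expr under a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Supra-threshold activity flags and burst intervals
#'
#' @param envelope an \code{emg_envelope} or numeric series.
#' @param threshold noise threshold (from \code{\link{thexton_threshold}}).
#' @return list with \code{active} (logical series, envelope > threshold)
#'   and \code{bursts} (data.frame of onset/offset sample indices, inclusive,
#'   one row per maximal supra-threshold run).
#' @export
activity_flags <- function(envelope, threshold) {
  env <- if (inherits(envelope, "emg_envelope")) envelope$envelope else as.numeric(envelope)
  act <- env > threshold
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  list(active = act,
       bursts = data.frame(onset = starts[keep], offset = ends[keep]))
}
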