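#' Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Runs one-sample (median = 0) or paired signed-rank tests for each
#' requested comparison on a per-cycle summary table, and applies a
#' Bonferroni-adjusted decision threshold \code{alpha / m} across the
#' \code{m} comparisons. The exact distribution is used for n <= 25
#' (no ties/zeros permitting), the normal approximation with continuity
#' correction above. Zero differences are dropped (the standard signed-rank
#' convention); comparisons whose differences are all zero are reported as
#' undefined.
#'
#' @param table data.frame, one row per swallow cycle.
#' @param comparisons list of comparisons; each element is either a single
#'   column name (one-sample test against 0) or a character vector of two
#'   column names (paired test, x - y).
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{n} (non-zero pairs used), \code{statistic} (V), \code{p},
#'   \code{p_threshold} (alpha / m), \code{significant}.
#' @export
signed_rank_tests <- function(table, comparisons, alpha = 0.05) {
  m <- length(comparisons)
  stopifnot(m >= 1)
  out <- lapply(comparisons, function(cmp) {
    if (length(cmp) == 1) {
      d <- table[[cmp]]
      label <- cmp
    } else {
      d <- table[[cmp[1]]] - table[[cmp[2]]]
      label <- paste(cmp[1], "vs", cmp[2])
    }
    d <- d[!is.na(d)]
    if (length(d) < 6)
      stop("fewer than 6 non-missing pairs for comparison ", label)
    dnz <- d[d != 0]
    if (!length(dnz))
      return(data.frame(comparison = label, n = 0L, statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    n <- length(dnz)
    exact <- n <= 25 && !any(duplicated(abs(dnz)))
    wt <- suppressWarnings(
      stats::wilcox.test(dnz, mu = 0, exact = exact, correct = TRUE))
    data.frame(comparison = label, n = n,
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_threshold <- alpha / m
  res$significant <- !is.na(res$p) & res$p < res$p_threshold
  res
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise-complete Pearson correlations among the requested kinematic
#' variables, with two-sided t-based p-values. Zero-variance columns give
#' NA (flagged by a warning).
#'
#' @param table data.frame of per-cycle variables.
#' @param vars character vector of column names (default: all numeric).
#' @return list with matrices \code{r}, \code{p}, and \code{n} (complete
#'   pairs per cell).
#' @export
correlation_matrix <- function(table, vars = NULL) {
  if (is.null(vars))
    vars <- names(table)[vapply(table, is.numeric, logical(1))]
  stopifnot(length(vars) >= 2)
  k <- length(vars)
  r <- p <- nm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- table[[vars[i]]]; y <- table[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    nij <- sum(ok)
    nm[i, j] <- nij
    if (nij < 3) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      if (i < j) warning("zero-variance column in pair ", vars[i], "/", vars[j])
      next
    }
    rij <- stats::cor(x[ok], y[ok])
    r[i, j] <- rij
    if (i == j) { p[i, j] <- NA_real_; next }
    tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- 2 * stats::pt(-abs(tt), df = nij - 2)
  }
  diag(r) <- 1
  list(r = r, p = p, n = nm)
}
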