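## MCMC convergence diagnostics: effective sample size from trace series and
## the per-statistic convergence report (fraction of runs whose ESS falls
## below the threshold, 100 by default).

#' Effective sample size of an MCMC trace
#'
#' `ESS = N / tau` with integrated autocorrelation time
#' `tau = 1 + 2 * sum_{k=1..K} rho_k`, where `rho_k` is the lag-`k` sample
#' autocorrelation and `K` is the smallest lag with `rho_k < 0` (else
#' `min(N - 1, 2000)`) -- the initial-positive truncation rule. The result
#' is capped at `N`, so anticorrelated series cannot report more
#' independent draws than samples.
#'
#' @param series Numeric vector of at least 4 finite, non-constant values.
#' @return The effective sample size (a real in `(0, N]`).
#' @export
ess <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4L) stop("need at least 4 samples to estimate ESS")
  if (!all(is.finite(series))) stop("trace values must be finite")
  if (stats::var(series) == 0)
    stop("constant trace: autocorrelation undefined")
  lag_max <- min(n - 1L, 2000L)
  rho <- stats::acf(series, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  neg <- which(rho < 0)
  K <- if (length(neg)) neg[1L] - 1L else lag_max
  tau <- 1 + 2 * sum(rho[seq_len(K)])
  min(n, n / max(tau, .Machine$double.eps))
}

#' Convergence report across runs
#'
#' For each named statistic, the fraction of runs whose ESS falls below the
#' threshold (100 by default, the customary minimum for an MCMC analysis to
#' be considered converged).
#'
#' @param runs List of runs; each run is a named list of numeric trace
#'   series.
#' @param statistics Ordered character vector of statistic names; every run
#'   must contain each of them.
#' @param threshold ESS threshold (default 100).
#' @return An object of class `convergence_report`: a data frame with
#'   columns `statistic`, `proportion_below` and the per-run ESS matrix in
#'   attribute `ess`.
#' @export
convergence_report <- function(runs, statistics, threshold = 100) {
  stopifnot(is.list(runs), length(runs) >= 1L,
            is.character(statistics), length(statistics) >= 1L)
  run_names <- names(runs)
  if (is.null(run_names)) run_names <- paste0("run", seq_along(runs))
  ess_mat <- matrix(NA_real_, length(runs), length(statistics),
                    dimnames = list(run_names, statistics))
  for (i in seq_along(runs)) {
    for (s in statistics) {
      if (is.null(runs[[i]][[s]]))
        stop("run '", run_names[i], "' is missing statistic '", s, "'")
      ess_mat[i, s] <- ess(runs[[i]][[s]])
    }
  }
  prop <- colMeans(ess_mat < threshold)
  rep_ <- data.frame(statistic = statistics, proportion_below = prop,
                     row.names = NULL)
  attr(rep_, "ess") <- ess_mat
  attr(rep_, "threshold") <- threshold
  class(rep_) <- c("convergence_report", class(rep_))
  rep_
}

#' Write a convergence report as key-value text
#' @param report A `convergence_report`.
#' @param path Output file.
#' @export
write_convergence_report <- function(report, path) {
  stopifnot(inherits(report, "convergence_report"))
  lines <- c(paste("threshold =", attr(report, "threshold")),
             sprintf("proportion_below %s = %.6g", report$statistic,
                     report$proportion_below))
  writeLines(lines, path)
  invisible(path)
}

#' Read an MCMC trace log
#'
#' Tab-delimited with a header row; the first column is the MCMC state
#' index. The first `burnin_fraction` of rows is dropped (burn-in removal
#' happens per chain, before any combination).
#'
#' @param path Trace-log file. Comment lines starting with `#` are skipped.
#' @param burnin_fraction Fraction of rows discarded (default 0.5).
#' @return A named list of numeric trace series (one per non-state column),
#'   with attribute `sampling_interval` (state step between rows).
#' @export
read_trace_log <- function(path, burnin_fraction = 0.5) {
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("'burnin_fraction' must be in [0, 1)")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("trace log ", path, ": no data rows")
  toks <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(toks[[1L]])
  ncol_ <- length(header)
  if (ncol_ < 2L) stop("trace log ", path, ": need a state column and at ",
                       "least one statistic")
  if (!grepl("state|gen|iter|sample", header[1L], ignore.case = TRUE))
    stop("trace log ", path, ": first column must be the MCMC state index ",
         "(got '", header[1L], "')")
  rows <- toks[-1L]
  bad <- which(lengths(rows) != ncol_)
  if (length(bad))
    stop("trace log ", path, ": ragged row at line ", line_no[bad[1L] + 1L],
         " (", lengths(rows)[bad[1L]], " fields, expected ", ncol_, ")")
  mat <- matrix(as.numeric(unlist(rows)), ncol = ncol_, byrow = TRUE)
  drop <- floor(burnin_fraction * nrow(mat))
  if (drop >= nrow(mat)) stop("no rows remain after burn-in removal")
  mat <- mat[(drop + 1L):nrow(mat), , drop = FALSE]
  interval <- if (nrow(mat) > 1L) mat[2L, 1L] - mat[1L, 1L] else NA_real_
  out <- lapply(2:ncol_, function(j) mat[, j])
  names(out) <- header[-1L]
  attr(out, "sampling_interval") <- interval
  out
}
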