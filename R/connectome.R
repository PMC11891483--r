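# Construction of thresholded Fisher-z functional connectivity matrices
# from regional time series. Fixed pipeline order: confound regression ->
# band-pass -> Pearson correlation -> threshold + Fisher z.

#' Regress nuisance confounds out of regional time series
#'
#' Removes nuisance signals (e.g. the global signal and six rigid-body motion
#' parameters, k = 7) from every regional time series by ordinary least
#' squares. An intercept is always included, so the residuals are also
#' mean-centred.
#'
#' @param ts Numeric matrix, T time points x N regions.
#' @param confounds Numeric matrix with T rows, one column per confound.
#' @return Matrix of residual time series, same shape as `ts`; every column
#'   is orthogonal to every confound column.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as.matrix(ts)
  confounds <- as.matrix(confounds)
  if (anyNA(ts) || anyNA(confounds)) stop("missing values are not allowed")
  if (nrow(confounds) != nrow(ts))
    stop("confounds have ", nrow(confounds), " rows but time series have ", nrow(ts))
  X <- cbind(1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("confound matrix is rank deficient after adding an intercept")
  res <- qr.resid(qx, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Band-pass filter regional time series
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass, by default
#' retaining the canonical resting-state band 0.01-0.1 Hz. Columns are
#' demeaned before filtering; the DC component is removed.
#'
#' @param ts Numeric matrix, T x N.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)` (the Nyquist frequency).
#' @return Filtered matrix, same shape as `ts`.
#' @export
bandpass <- function(ts, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 8) stop("need at least 8 time points")
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive")
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist))
    stop("band must satisfy 0 < low_hz < high_hz < Nyquist (", signif(nyquist, 3), " Hz)")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  centered <- sweep(ts, 2, colMeans(ts))
  out <- apply(centered, 2, function(x) signal::filtfilt(bf, x))
  dimnames(out) <- dimnames(ts)
  out
}

#' Pearson correlation matrix of regional time series
#'
#' @param ts Numeric matrix, T x N, every column with nonzero variance.
#' @return N x N correlation matrix (unit diagonal, symmetric).
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("missing values are not allowed")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("zero-variance time series for node(s): ", paste(bad, collapse = ", "))
  }
  r <- cor(ts)
  # guard tiny asymmetries from floating point
  (r + t(r)) / 2
}

#' Threshold a correlation matrix and apply the Fisher z-transform
#'
#' Off-diagonal correlations below `threshold_r` (including all negative
#' values) are set to zero; retained entries are mapped by `atanh`. The
#' comparison is an exact `>=`, so ties at the threshold are retained. The
#' diagonal is zeroed. Idempotent on its own output (retained z-values are
#' at least `atanh(threshold_r) > threshold_r` for thresholds in (0, 1)).
#'
#' @param r_mat Correlation matrix (symmetric, entries in \[-1, 1\]).
#' @param threshold_r Retention cut-off on r, default 0.2.
#' @return Symmetric matrix of Fisher-z weights with zero diagonal, of class
#'   `"conn_matrix"` with attribute `threshold_r`. Passing a `conn_matrix`
#'   back in returns it unchanged (the values are already on the z scale),
#'   which makes the operation idempotent.
#' @export
threshold_fisher <- function(r_mat, threshold_r = 0.2) {
  if (inherits(r_mat, "conn_matrix")) return(r_mat)
  r_mat <- as.matrix(r_mat)
  if (nrow(r_mat) != ncol(r_mat)) stop("`r_mat` must be square")
  off <- abs(r_mat) >= 1 & row(r_mat) != col(r_mat)
  if (any(off)) {
    idx <- sort(which(off, arr.ind = TRUE)[1, ])
    stop("off-diagonal |r| = 1 between nodes ", idx[1], " and ", idx[2],
         ": Fisher z is infinite")
  }
  z <- r_mat
  z[z < threshold_r] <- 0
  keep <- z != 0
  z[keep] <- atanh(z[keep])
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(z, class = c("conn_matrix", class(z)), threshold_r = threshold_r)
}
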