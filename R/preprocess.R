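#' Amplitude-threshold epoch rejection
#'
#' Discards epochs in which any sample at any channel strictly exceeds
#' +/-threshold microvolts. Boundary equality keeps the epoch. Must run in the
#' microvolt domain, i.e. before the surface Laplacian.
#'
#' @param epochs an \code{\link{EpochSet}} with units "uV".
#' @param threshold rejection threshold in microvolts (> 0).
#' @return list with \code{epochs} (survivors only, data values untouched) and
#'   \code{log} (data.frame: subject, trial, max_abs_uV, kept).
#' @export
rejectEpochs <- function(epochs, threshold = 75) {
  if (epochUnits(epochs) != "uV")
    stop("epoch rejection must precede the Laplacian (units are ",
         epochUnits(epochs), ", expected uV)")
  stopifnot(threshold > 0)
  ntr <- nTrials(epochs)
  maxabs <- vapply(seq_len(ntr),
                   function(i) max(abs(epochs@data[i, , ])), numeric(1))
  kept <- maxabs <= threshold        # strictly exceeding is discarded
  log <- data.frame(subject = trialInfo(epochs)$subject,
                    trial = seq_len(ntr), max_abs_uV = maxabs, kept = kept)
  if (!any(kept))
    stop("no usable trials for subject ",
         unique(trialInfo(epochs)$subject)[1L],
         ": all epochs exceed +/-", threshold, " uV")
  list(epochs = subsetTrials(epochs, kept), log = log)
}

# IIR filter (direct form II transposed) applied down the rows of a matrix,
# vectorized across columns; b, a are coefficient vectors with a[1] == 1
.filterMatrix <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- nrow(x); m <- ncol(x)
  y <- matrix(0, n, m)
  z <- if (is.null(zi)) matrix(0, nfilt - 1L, m) else zi
  for (i in seq_len(n)) {
    xi <- x[i, ]
    yi <- b[1L] * xi + z[1L, ]
    for (k in seq_len(nfilt - 2L))
      z[k, ] <- b[k + 1L] * xi + z[k + 1L, ] - a[k + 1L] * yi
    z[nfilt - 1L, ] <- b[nfilt] * xi - a[nfilt] * yi
    y[i, ] <- yi
  }
  y
}

# steady-state filter state for a unit step (per unit of input)
.filterZi <- function(b, a) {
  nfilt <- max(length(b), length(a))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  if (nfilt == 1L) return(matrix(0, 0L, 0L))
  # companion matrix of a, transposed
  A <- rbind(-a[2:nfilt], cbind(diag(1, nfilt - 2L), rep(0, nfilt - 2L)))
  B <- b[2:nfilt] - a[2:nfilt] * b[1L]
  solve(diag(nfilt - 1L) - t(A), B)
}

# zero-phase filtering down matrix rows: forward and reverse passes with
# odd-reflection edge padding and steady-state initialization
.filtfiltMatrix <- function(b, a, x) {
  n <- nrow(x)
  padlen <- min(3L * max(length(a), length(b)), n - 1L)
  zi <- .filterZi(b, a)
  onepass <- function(v) {
    ext <- rbind(2 * matrix(v[1L, ], padlen, ncol(v), byrow = TRUE) -
                   v[(padlen + 1L):2, , drop = FALSE],
                 v,
                 2 * matrix(v[n, ], padlen, ncol(v), byrow = TRUE) -
                   v[(n - 1L):(n - padlen), , drop = FALSE])
    z0 <- zi %o% ext[1L, ]
    yf <- .filterMatrix(b, a, ext, zi = z0)
    yf <- yf[nrow(yf):1L, , drop = FALSE]
    z0 <- zi %o% yf[1L, ]
    yb <- .filterMatrix(b, a, yf, zi = z0)
    yb <- yb[nrow(yb):1L, , drop = FALSE]
    yb[(padlen + 1L):(padlen + n), , drop = FALSE]
  }
  onepass(x)
}

#' Ocular-artifact correction stage (extension point)
#'
#' Placeholder for ICA-based removal of ocular components. The synthetic
#' generator injects no ocular artifacts, so the only built-in method is
#' "none" (identity). Real-data users can slot a decomposition of their
#' choice in here; the stage contract is EpochSet in, EpochSet out, in the
#' microvolt domain.
#'
#' @param epochs an \code{\link{EpochSet}} with units "uV".
#' @param method currently only "none".
#' @return the unchanged \code{\link{EpochSet}}.
#' @export
removeOcularArtifacts <- function(epochs, method = c("none")) {
  method <- match.arg(method)
  if (epochUnits(epochs) != "uV")
    stop("ocular correction must precede the Laplacian")
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass (defaults 0.05-25 Hz, first order) and
#' applies it forward and backward (zero phase, so peak latencies are not
#' shifted; the effective magnitude response is |H(f)|^2).
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param low,high band edges in Hz; 0 < low < high < sampleRate/2.
#' @param order Butterworth order of the underlying design.
#' @return the filtered \code{\link{EpochSet}}.
#' @export
bandpassFilter <- function(epochs, low = 0.05, high = 25, order = 1) {
  fs <- sampleRate(epochs)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  d <- epochs@data
  dm <- dim(d)
  # samples x (trials*channels): time runs down the rows
  x <- t(matrix(d, dm[1L] * dm[2L], dm[3L]))
  y <- .filtfiltMatrix(bf$b, bf$a, x)
  out <- array(t(y), dim = dm)
  new("EpochSet", data = out, sampleRate = fs, time = epochs@time,
      targetTime = epochs@targetTime, trials = epochs@trials,
      montage = epochs@montage, units = epochs@units)
}

#' Baseline subtraction
#'
#' Subtracts, per trial and channel, the mean over a baseline window from the
#' whole series.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param window (ms, ms) relative to the reference event.
#' @param reference "target" or "cue".
#' @return the baselined \code{\link{EpochSet}}.
#' @export
baselineSubtract <- function(epochs, window = c(-200, 0),
                             reference = c("target", "cue")) {
  reference <- match.arg(reference)
  off <- if (reference == "target") targetTime(epochs) else 0
  if (min(epochTime(epochs)) > window[1L] + off ||
      max(epochTime(epochs)) < window[2L] + off)
    stop("baseline window extends past the epoch")
  idx <- .timeIndex(epochTime(epochs), window + off)
  if (!length(idx)) stop("baseline window contains no samples")
  d <- epochs@data
  bl <- rowMeans(d[, , idx, drop = FALSE], dims = 2L)
  out <- sweep(d, c(1L, 2L), bl, "-")
  new("EpochSet", data = out, sampleRate = epochs@sampleRate,
      time = epochs@time, targetTime = epochs@targetTime,
      trials = epochs@trials, montage = epochs@montage, units = epochs@units)
}
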