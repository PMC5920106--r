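# Legendre polynomials P_1..P_L evaluated at every element of x (recurrence);
# returns a list of matrices/vectors shaped like x
.legendreSeries <- function(x, L) {
  out <- vector("list", L)
  pm1 <- x * 0 + 1            # P_0
  p <- x                      # P_1
  out[[1L]] <- p
  if (L >= 2L) for (l in 2:L) {
    pn <- ((2 * l - 1) * x * p - (l - 1) * pm1) / l
    pm1 <- p; p <- pn
    out[[l]] <- pn
  }
  out
}

# g and h kernels of the spherical-spline interpolator (stiffness m, series
# truncated at L terms), evaluated at cos(angle) values in x
.splineKernels <- function(x, m, L) {
  P <- .legendreSeries(x, L)
  g <- x * 0; h <- x * 0
  for (l in seq_len(L)) {
    cl <- (2 * l + 1) / (l^m * (l + 1)^m)
    g <- g + cl * P[[l]]
    h <- h + cl * l * (l + 1) * P[[l]]   # = (2l+1)/(l^(m-1)(l+1)^(m-1))
  }
  list(g = g / (4 * pi), h = h / (4 * pi))
}

#' Spherical-spline interpolation and surface-Laplacian operators
#'
#' Builds the two channel-by-channel linear operators of the spherical-spline
#' framework: smoothing interpolation of the scalp potential, and the surface
#' Laplacian (current scalp density, sign convention positive at sources:
#' a degree-l spherical-harmonic potential maps to ~ l(l+1) times itself).
#' Operators depend only on the montage and the parameters.
#'
#' @param montage a \code{\link{Montage}} with at least 4 channels.
#' @param m spline stiffness (>= 2).
#' @param lambda ridge regularization added to the diagonal of the g matrix.
#' @param nLegendre number of Legendre terms in the series.
#' @return list with matrices \code{interpolation} and \code{laplacian}, and
#'   the solver pieces (\code{Gi}, kernel closures) reused by
#'   \code{\link{interpolateChannels}}.
#' @export
sphericalSplineOperators <- function(montage, m = 4, lambda = 1e-5,
                                     nLegendre = 50) {
  pos <- channelPositions(montage)
  n <- nrow(pos)
  if (n < 4L) stop("need at least 4 channels")
  stopifnot(m >= 2, lambda >= 0)
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  offdiag <- abs(cosang - 1) < 1e-12
  diag(offdiag) <- FALSE
  if (any(offdiag))
    stop("coincident electrode positions make the spline geometry singular")
  K <- .splineKernels(cosang, m, nLegendre)
  G <- K$g + diag(lambda, n)
  Gi <- solve(G)
  gsum <- colSums(Gi)                       # 1' Gi
  tot <- sum(gsum)
  # c = M v with sum(c) = 0;  c0 = (1' Gi v) / (1' Gi 1)
  M <- Gi - outer(rowSums(Gi), gsum) / tot
  interp <- K$g %*% M + outer(rep(1, n), gsum) / tot
  lap <- K$h %*% M
  list(interpolation = interp, laplacian = lap, Gi = Gi,
       m = m, lambda = lambda, nLegendre = nLegendre)
}

#' Apply the surface Laplacian to an EpochSet
#'
#' Transforms raw potentials (microvolts) into current scalp density. The unit
#' tag flips to "uV.cm2"; applying the Laplacian twice is refused. The head is
#' the unit sphere, so magnitudes are in consistent-but-arbitrary units;
#' condition contrasts are invariant to that overall scale.
#'
#' @param epochs an \code{\link{EpochSet}} with units "uV".
#' @param m,lambda,nLegendre spline parameters, see
#'   \code{\link{sphericalSplineOperators}}.
#' @return the transformed \code{\link{EpochSet}} (units "uV.cm2").
#' @export
applyLaplacian <- function(epochs, m = 4, lambda = 1e-5, nLegendre = 50) {
  if (epochUnits(epochs) != "uV")
    stop("Laplacian already applied (units are ", epochUnits(epochs), ")")
  ops <- sphericalSplineOperators(montage(epochs), m, lambda, nLegendre)
  d <- epochs@data
  dm <- dim(d)
  flat <- matrix(aperm(d, c(2L, 1L, 3L)), dm[2L], dm[1L] * dm[3L])
  out <- ops$laplacian %*% flat
  res <- aperm(array(out, dim = c(dm[2L], dm[1L], dm[3L])), c(2L, 1L, 3L))
  new("EpochSet", data = res, sampleRate = epochs@sampleRate,
      time = epochs@time, targetTime = epochs@targetTime,
      trials = epochs@trials, montage = epochs@montage, units = "uV.cm2")
}

#' Spherical interpolation of bad channels
#'
#' Replaces the listed channels with the spherical-spline potential
#' interpolated from the remaining (good) channels; good channels are
#' untouched. Re-interpolating the same channels is idempotent because the
#' result depends only on the good channels.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param bad character vector of channel labels to rebuild (may be empty).
#' @param m,lambda,nLegendre spline parameters.
#' @return the \code{\link{EpochSet}} with bad channels reconstructed.
#' @export
interpolateChannels <- function(epochs, bad, m = 4, lambda = 1e-5,
                                nLegendre = 50) {
  if (!length(bad)) return(epochs)
  mon <- montage(epochs)
  badIdx <- .resolveGroup(mon, bad)
  goodIdx <- setdiff(seq_along(channelLabels(mon)), badIdx)
  if (length(goodIdx) < 4L)
    stop("fewer than 4 good channels remain; cannot interpolate")
  pos <- channelPositions(mon)
  sub <- .subsetMontage(mon, goodIdx)
  ops <- sphericalSplineOperators(sub, m, lambda, nLegendre)
  ng <- length(goodIdx)
  gsum <- colSums(ops$Gi); tot <- sum(gsum)
  M <- ops$Gi - outer(rowSums(ops$Gi), gsum) / tot
  cosbg <- pos[badIdx, , drop = FALSE] %*% t(pos[goodIdx, , drop = FALSE])
  cosbg[cosbg > 1] <- 1; cosbg[cosbg < -1] <- -1
  gbg <- .splineKernels(cosbg, m, nLegendre)$g
  # V(bad) = c0 + g(bad,good) c  with  c = M v,  c0 = (1'Gi v)/(1'Gi 1)
  op <- gbg %*% M + outer(rep(1, length(badIdx)), gsum) / tot
  d <- epochs@data
  dm <- dim(d)
  flat <- matrix(aperm(d, c(2L, 1L, 3L)), dm[2L], dm[1L] * dm[3L])
  rebuilt <- op %*% flat[goodIdx, , drop = FALSE]
  flat[badIdx, ] <- rebuilt
  res <- aperm(array(flat, dim = c(dm[2L], dm[1L], dm[3L])), c(2L, 1L, 3L))
  new("EpochSet", data = res, sampleRate = epochs@sampleRate,
      time = epochs@time, targetTime = epochs@targetTime,
      trials = epochs@trials, montage = epochs@montage, units = epochs@units)
}
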