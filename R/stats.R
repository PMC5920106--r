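# maximal runs of same-sign supra-threshold samples
# returns data.frame(startIdx, endIdx, size, sign)
.thresholdRuns <- function(t, thr) {
  code <- integer(length(t))
  code[t > thr] <- 1L
  code[t < -thr] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values != 0L
  data.frame(startIdx = starts[sel], endIdx = ends[sel],
             size = r$lengths[sel], sign = r$values[sel])
}

# largest same-sign supra-threshold run length per row of a t matrix
.maxRunLengths <- function(T, thr) {
  apply(T, 1L, function(t) {
    r <- .thresholdRuns(t, thr)
    if (nrow(r)) max(r$size) else 0L
  })
}

#' Cluster-corrected paired permutation test over time
#'
#' Computes the per-timepoint paired t statistic between two aligned
#' subject x time matrices, forms clusters as maximal runs of same-sign
#' samples exceeding the two-tailed t critical value at \code{alpha}
#' (df = n - 1), and builds the null distribution of maximum run lengths by
#' independently sign-flipping each subject's difference time course. A
#' cluster's p is the fraction of permutations whose maximum run length is at
#' least the cluster's size; a cluster is significant when its size strictly
#' exceeds the null 95th percentile. The observed labeling is included in the
#' null. When 2^n <= nPerm all sign flips are enumerated exactly instead of
#' sampled.
#'
#' @param a,b subject x time matrices (paired, aligned).
#' @param nPerm number of permutations.
#' @param alpha cluster-forming (and cluster-level) alpha.
#' @param seed RNG seed for the sampled case.
#' @param time optional time axis (ms) for cluster bounds.
#' @return a \code{\link{ClusterTestResult}}.
#' @export
clusterPermutationPaired <- function(a, b, nPerm = 10000, alpha = 0.05,
                                     seed = 1, time = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("a and b must have identical dimensions")
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 subjects")
  if (nPerm < 100) warning("fewer than 100 permutations")
  if (is.null(time)) time <- seq_len(ncol(a))
  d <- a - b
  ssq <- colSums(d^2)
  tFromMeans <- function(mn) {
    # paired t from per-permutation means; sum of squares is flip-invariant
    v <- (ssq - n * mn^2) / (n - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    mn / sqrt(v / n)
  }
  tObs <- tFromMeans(colMeans(d))
  thr <- stats::qt(1 - alpha / 2, df = n - 1)

  exact <- 2^n <= nPerm
  if (exact) {
    nP <- as.integer(2^n)
    signs <- matrix(1, nP, n)
    for (j in seq_len(n))
      signs[, j] <- ifelse(bitwAnd(seq_len(nP) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                           -1, 1)
  } else {
    nP <- as.integer(nPerm)
    set.seed(as.integer(seed %% 2147483629))
    signs <- matrix(sample(c(-1, 1), nP * n, replace = TRUE), nP, n)
    signs[1L, ] <- 1          # observed labeling included in the null
  }
  permMeans <- (signs %*% d) / n
  permT <- t(apply(permMeans, 1L, tFromMeans))
  if (ncol(a) == 1L) permT <- matrix(permT, ncol = 1L)
  nullSizes <- .maxRunLengths(permT, thr)

  cl <- .thresholdRuns(tObs, thr)
  q95 <- as.numeric(stats::quantile(nullSizes, 0.95, type = 1))
  if (nrow(cl)) {
    cl$p <- vapply(cl$size, function(s) mean(nullSizes >= s), numeric(1))
    cl$significant <- cl$size > q95
    clusters <- data.frame(start_ms = time[cl$startIdx],
                           end_ms = time[cl$endIdx], size = cl$size,
                           sign = cl$sign, p = cl$p,
                           significant = cl$significant)
  } else {
    clusters <- data.frame(start_ms = numeric(), end_ms = numeric(),
                           size = integer(), sign = integer(), p = numeric(),
                           significant = logical())
  }
  new("ClusterTestResult", tStat = tObs, time = as.numeric(time),
      threshold = thr, clusters = clusters, nullSizes = as.numeric(nullSizes),
      null95 = q95, nPerm = nP, exact = exact)
}

#' @describeIn ClusterTestResult the cluster table
#' @param x a ClusterTestResult.
#' @export
setMethod("clusters", "ClusterTestResult", function(x) x@clusters)

#' @describeIn ClusterTestResult permutation maximum run lengths
#' @export
setMethod("nullSizes", "ClusterTestResult", function(x) x@nullSizes)

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult: |t| threshold %.3f, %d permutations%s, null 95th pct = %g\n",
    object@threshold, object@nPerm, if (object@exact) " (exact)" else "",
    object@null95))
  if (nrow(object@clusters)) print(object@clusters) else cat("  no clusters\n")
})

#' Paired t test
#'
#' Classical two-tailed paired t with the 95 percent CI of the mean
#' difference.
#'
#' @param a,b paired per-subject scalars.
#' @return list(t, df, p, ci, meanDiff).
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    # degenerate pairing: a constant non-zero difference has an exact,
    # zero-width CI; an identically-zero difference has no defined t
    if (mean(d) == 0)
      stop("zero variance and zero mean of paired differences; t undefined")
    warning("zero variance of paired differences; returning degenerate result")
    return(list(t = sign(mean(d)) * Inf, df = length(a) - 1, p = 0,
                ci = c(mean(d), mean(d)), meanDiff = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, ci = as.numeric(ht$conf.int),
       meanDiff = unname(ht$estimate))
}

#' Balanced 2x2 repeated-measures ANOVA
#'
#' Within-subject two-factor ANOVA on a complete balanced design with one
#' observation per subject x cell. For two-level factors each F equals the
#' square of the paired t on the corresponding contrast.
#'
#' @param data data.frame with columns \code{subject}, \code{A}, \code{B}
#'   (two levels each) and \code{value}, one row per subject x cell.
#' @return data.frame with rows A, B, A:B and columns F, df1, df2, p.
#' @export
rmAnova2x2 <- function(data) {
  need <- c("subject", "A", "B", "value")
  if (!all(need %in% names(data))) stop("need columns subject, A, B, value")
  data$subject <- factor(data$subject)
  data$A <- factor(data$A); data$B <- factor(data$B)
  if (nlevels(data$A) != 2L || nlevels(data$B) != 2L)
    stop("A and B must each have exactly 2 levels")
  counts <- table(data$subject, data$A, data$B)
  if (any(counts != 1L))
    stop("design must be complete and balanced (one value per cell)")
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = data)
  sm <- summary(fit)
  scaleSS <- sum((data$value - mean(data$value))^2)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1L]]
    i <- match(term, trimws(rownames(tab)))
    F <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    if (tab[i, "Sum Sq"] <= 1e-10 * max(scaleSS, .Machine$double.eps)) {
      F <- 0; p <- 1        # no effect variance at all: report F = 0
    }
    c(F = F, df1 = tab[i, "Df"], df2 = tab[nrow(tab), "Df"], p = p)
  }
  out <- rbind(pull("Error: subject:A", "A"),
               pull("Error: subject:B", "B"),
               pull("Error: subject:A:B", "A:B"))
  data.frame(effect = c("A", "B", "A:B"), out, row.names = NULL)
}

# Spearman rho with a guard for zero-variance input
.spearman <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation with bootstrap CI
#'
#' Spearman rank coefficient on mid-ranks, two-tailed p from the t
#' approximation, and a percentile bootstrap confidence interval over
#' subject resamples (with replacement). Deterministic given the seed.
#'
#' @param x,y per-subject scalars (n >= 4).
#' @param nBoot bootstrap draws (default 20000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list(rho, p, ci, boot) where \code{boot} holds the bootstrap rho
#'   draws (NA draws from degenerate resamples removed).
#' @export
spearmanBootstrap <- function(x, y, nBoot = 20000, seed = 1, conf = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; Spearman rho undefined")
  rho <- .spearman(x, y)
  if (abs(rho) < 1) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else p <- 0
  set.seed(as.integer(seed %% 2147483629))
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    .spearman(x[idx], y[idx])
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(rho = rho, p = p, ci = qs, boot = boot)
}

#' Bootstrap difference between two correlations sharing x
#'
#' Resamples subjects once per draw (jointly for all three vectors), computes
#' rho(x, yL) - rho(x, yR) per draw, and reports the percentile CI of the
#' difference and the two-tailed bootstrap p
#' = 2 min(P(diff <= 0), P(diff >= 0)).
#'
#' @param x,yL,yR per-subject scalars on the same subjects.
#' @param nBoot bootstrap draws.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list(deltaRho, ci, p, boot).
#' @export
correlationDifference <- function(x, yL, yR, nBoot = 20000, seed = 1,
                                  conf = 0.95) {
  n <- length(x)
  stopifnot(length(yL) == n, length(yR) == n, n >= 4L)
  if (stats::sd(x) == 0 || stats::sd(yL) == 0 || stats::sd(yR) == 0)
    stop("constant input; Spearman rho undefined")
  delta <- .spearman(x, yL) - .spearman(x, yR)
  set.seed(as.integer(seed %% 2147483629))
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    .spearman(x[idx], yL[idx]) - .spearman(x[idx], yR[idx])
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(deltaRho = delta, ci = qs, p = p, boot = boot)
}
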