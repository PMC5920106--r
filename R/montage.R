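#' Construct a Montage
#'
#' @param labels character vector of channel labels.
#' @param positions numeric channels x 3 matrix of unit-sphere positions.
#' @param groups named list of channel groups; defaults to the left/right
#'   occipito-parietal clusters when their members are present.
#' @return a \code{\link{Montage}}.
#' @export
Montage <- function(labels, positions, groups = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  rownames(positions) <- labels
  if (is.null(groups)) {
    groups <- posteriorGroups()
    groups <- groups[vapply(groups, function(g) all(g %in% labels), logical(1))]
  }
  new("Montage", labels = as.character(labels), positions = positions,
      groups = groups)
}

#' Occipito-parietal analysis clusters
#'
#' The left and right posterior channel groups used for both the P1 and the
#' pre-target alpha analyses.
#'
#' @return named list with \code{leftPosterior} and \code{rightPosterior}.
#' @export
posteriorGroups <- function() {
  list(leftPosterior  = c("PO3", "P3", "P7", "P9", "O1"),
       rightPosterior = c("PO4", "P4", "P8", "P10", "O2"))
}

#' Read a montage from a delimited text table
#'
#' The table must have columns \code{label}, \code{x}, \code{y}, \code{z};
#' positions are renormalized to the unit sphere.
#'
#' @param path path to a tab- or comma-delimited file.
#' @param groups named list of channel groups (default posterior clusters).
#' @return a \code{\link{Montage}}.
#' @export
readMontage <- function(path, groups = NULL) {
  tab <- utils::read.delim(path, sep = "", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("montage table must have columns label, x, y, z")
  pos <- as.matrix(tab[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  Montage(tab$label, pos, groups = groups)
}

#' The bundled 60-channel extended 10-20 montage
#'
#' Idealized unit-sphere positions for a 60-channel extended 10-20 layout,
#' including the left (PO3, P3, P7, P9, O1) and right (PO4, P4, P8, P10, O2)
#' posterior analysis clusters.
#'
#' @return a \code{\link{Montage}}.
#' @export
standardMontage <- function() {
  readMontage(system.file("extdata", "montage60.tsv", package = "alphaP1"))
}

#' Dense synthetic montage for analytic checks
#'
#' Fibonacci-lattice points on the unit sphere, useful for testing operators
#' against closed-form spherical-harmonic identities. This is a synthetic
#' layout, not a physiological electrode placement.
#'
#' @param n number of channels (>= 4).
#' @return a \code{\link{Montage}} with labels S1..Sn and no groups.
#' @export
denseMontage <- function(n = 128L) {
  stopifnot(n >= 4L)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pos <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  Montage(paste0("S", seq_len(n)), pos, groups = list())
}

#' @describeIn Montage channel labels
#' @param x a Montage.
#' @export
setMethod("channelLabels", "Montage", function(x) x@labels)

#' @describeIn Montage unit-sphere positions (channels x 3)
#' @export
setMethod("channelPositions", "Montage", function(x) x@positions)

#' @describeIn Montage named channel groups
#' @export
setMethod("channelGroups", "Montage", function(x) x@groups)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels", length(object@labels)))
  if (length(object@groups))
    cat(sprintf("; groups: %s",
                paste(sprintf("%s(%d)", names(object@groups),
                              lengths(object@groups)), collapse = ", ")))
  cat("\n")
})

# resolve a group name or explicit channel vector to channel indices
.resolveGroup <- function(montage, group) {
  if (length(group) == 1L && group %in% names(montage@groups))
    group <- montage@groups[[group]]
  idx <- match(group, montage@labels)
  if (anyNA(idx))
    stop("unknown channels: ", paste(group[is.na(idx)], collapse = ", "))
  idx
}

# montage restricted to a subset of channels (keeps group members present)
.subsetMontage <- function(montage, idx) {
  labs <- montage@labels[idx]
  groups <- lapply(montage@groups, function(g) g[g %in% labs])
  groups <- groups[lengths(groups) > 0L]
  new("Montage", labels = labs,
      positions = montage@positions[idx, , drop = FALSE], groups = groups)
}
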