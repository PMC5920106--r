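#' Write an EpochSet container
#'
#' Persists an \code{\link{EpochSet}} as a directory container holding the
#' datasets \code{data.bin} (IEEE-754 doubles, trial-major), \code{time_ms.txt},
#' \code{trials.csv}, \code{montage.tsv} and a \code{meta.json} with the
#' sampling rate, unit tag, target-onset time, dimensions and channel groups.
#' The round trip through \code{\link{readEpochs}} is bit-exact for the data
#' and schema-exact for the metadata.
#'
#' @param epochs an \code{\link{EpochSet}}.
#' @param path directory to create/overwrite.
#' @return path, invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- epochData(epochs)
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.vector(d), con, size = 8L)
  close(con)
  writeLines(format(epochTime(epochs), digits = 17, trim = TRUE,
                    scientific = FALSE),
             file.path(path, "time_ms.txt"))
  utils::write.csv(trialInfo(epochs), file.path(path, "trials.csv"),
                   row.names = FALSE)
  mon <- montage(epochs)
  mtab <- data.frame(label = channelLabels(mon), channelPositions(mon))
  names(mtab) <- c("label", "x", "y", "z")
  utils::write.table(mtab, file.path(path, "montage.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(format = "alphaP1-epochs-v1",
               dim = dim(d), sampling_rate = sampleRate(epochs),
               units = epochUnits(epochs), target_time_ms = targetTime(epochs),
               channels = channelLabels(mon), groups = channelGroups(mon))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a TFRPower container
#'
#' Persists a \code{\link{TFRPower}} in the same directory-container style as
#' \code{\link{writeEpochs}}: \code{power.bin} (doubles, trial-major),
#' \code{edge.bin} (edge flags), and \code{meta.json} with the channel,
#' frequency and time axes, units and baseline window.
#'
#' @param tfr a \code{\link{TFRPower}}.
#' @param path directory to create/overwrite.
#' @return path, invisibly.
#' @export
writeTFR <- function(tfr, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(path, "power.bin"), "wb")
  writeBin(as.vector(tfr@power), con, size = 8L)
  close(con)
  con <- file(file.path(path, "edge.bin"), "wb")
  writeBin(as.integer(tfr@edgeFlags), con, size = 4L)
  close(con)
  meta <- list(format = "alphaP1-tfr-v1", dim = dim(tfr@power),
               channels = tfr@channels, frequencies = tfr@frequencies,
               time_ms = tfr@time, units = tfr@units)
  if (!anyNA(tfr@baseline)) meta$baseline <- tfr@baseline
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a TFRPower container
#'
#' Inverse of \code{\link{writeTFR}}; missing pieces raise schema errors.
#'
#' @param path container directory.
#' @return a \code{\link{TFRPower}}.
#' @export
readTFR <- function(path) {
  need <- c("meta.json", "power.bin", "edge.bin")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("TFR container schema error: missing ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dm <- as.integer(meta$dim)
  con <- file(file.path(path, "power.bin"), "rb")
  vals <- readBin(con, "double", n = prod(dm), size = 8L)
  close(con)
  con <- file(file.path(path, "edge.bin"), "rb")
  ed <- readBin(con, "integer", n = dm[3L] * dm[4L], size = 4L)
  close(con)
  new("TFRPower", power = array(vals, dm),
      channels = as.character(meta$channels),
      frequencies = as.numeric(meta$frequencies),
      time = as.numeric(meta$time_ms), units = meta$units,
      baseline = if (is.null(meta$baseline)) NA_real_
                 else as.numeric(meta$baseline),
      edgeFlags = matrix(as.logical(ed), dm[3L], dm[4L]))
}

#' Read an EpochSet container
#'
#' Inverse of \code{\link{writeEpochs}}; missing datasets or attributes raise
#' a schema error naming the missing key, and a truncated data file is
#' detected by its size.
#'
#' @param path container directory.
#' @return an \code{\link{EpochSet}}.
#' @export
readEpochs <- function(path) {
  need <- c("meta.json", "data.bin", "time_ms.txt", "trials.csv",
            "montage.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("epoch container schema error: missing ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  needKeys <- c("dim", "sampling_rate", "units", "target_time_ms", "channels")
  missK <- needKeys[!needKeys %in% names(meta)]
  if (length(missK))
    stop("epoch container schema error: meta.json lacks ",
         paste(missK, collapse = ", "))
  dm <- as.integer(meta$dim)
  nvals <- prod(dm)
  fsize <- file.info(file.path(path, "data.bin"))$size
  if (fsize != nvals * 8)
    stop("epoch container schema error: data.bin has ", fsize,
         " bytes, expected ", nvals * 8)
  con <- file(file.path(path, "data.bin"), "rb")
  vals <- readBin(con, "double", n = nvals, size = 8L)
  close(con)
  time <- as.numeric(readLines(file.path(path, "time_ms.txt")))
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  groups <- if (!is.null(meta$groups) && length(meta$groups))
    lapply(meta$groups, as.character) else NULL
  mon <- readMontage(file.path(path, "montage.tsv"), groups = groups)
  if (!identical(channelLabels(mon), as.character(meta$channels)))
    stop("epoch container schema error: montage/channel label mismatch")
  EpochSet(array(vals, dim = dm), meta$sampling_rate, time,
           meta$target_time_ms, trials, mon, units = meta$units)
}
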