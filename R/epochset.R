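#' Construct an EpochSet
#'
#' @param data numeric array, trials x channels x samples.
#' @param sampleRate sampling rate, Hz.
#' @param time sample times in ms relative to cue onset.
#' @param targetTime target onset in ms relative to cue onset.
#' @param trials per-trial data.frame (subject, condition, trialType, kept).
#' @param montage a \code{\link{Montage}} matching the channel dimension.
#' @param units "uV" (raw potentials) or "uV.cm2" (after the Laplacian).
#' @return an \code{\link{EpochSet}}.
#' @export
EpochSet <- function(data, sampleRate, time, targetTime, trials, montage,
                     units = "uV") {
  if (!"kept" %in% names(trials)) trials$kept <- TRUE
  if (!"trialType" %in% names(trials)) trials$trialType <- "identical"
  new("EpochSet", data = data, sampleRate = sampleRate, time = as.numeric(time),
      targetTime = targetTime, trials = trials, montage = montage,
      units = units)
}

#' @describeIn EpochSet trials x channels x samples array
#' @param x an EpochSet.
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @describeIn EpochSet sampling rate in Hz
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)

#' @describeIn EpochSet time axis, ms relative to cue onset
#' @export
setMethod("epochTime", "EpochSet", function(x) x@time)

#' @describeIn EpochSet target onset, ms relative to cue onset
#' @export
setMethod("targetTime", "EpochSet", function(x) x@targetTime)

#' @describeIn EpochSet per-trial label table
#' @export
setMethod("trialInfo", "EpochSet", function(x) x@trials)

#' @describeIn EpochSet the montage
#' @export
setMethod("montage", "EpochSet", function(x) x@montage)

#' @describeIn EpochSet unit tag ("uV" or "uV.cm2")
#' @export
setMethod("epochUnits", "EpochSet", function(x) x@units)

#' @describeIn EpochSet number of trials
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz [%s]\n",
              d[1L], d[2L], d[3L], object@sampleRate, object@units))
  cat(sprintf("  time %g..%g ms (cue at 0, target at %g ms)\n",
              object@time[1L], object@time[length(object@time)],
              object@targetTime))
  tb <- table(object@trials$condition)
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
})

#' Subset an EpochSet by trials
#'
#' @param x an EpochSet.
#' @param trials integer or logical index over trials.
#' @return an EpochSet with the selected trials, labels kept in order.
#' @export
subsetTrials <- function(x, trials) {
  new("EpochSet", data = x@data[trials, , , drop = FALSE],
      sampleRate = x@sampleRate, time = x@time, targetTime = x@targetTime,
      trials = x@trials[trials, , drop = FALSE], montage = x@montage,
      units = x@units)
}

#' Subset an EpochSet by channels
#'
#' @param x an EpochSet.
#' @param channels channel labels or a group name from the montage.
#' @return an EpochSet restricted to the selected channels.
#' @export
selectChannels <- function(x, channels) {
  idx <- .resolveGroup(x@montage, channels)
  new("EpochSet", data = x@data[, idx, , drop = FALSE],
      sampleRate = x@sampleRate, time = x@time, targetTime = x@targetTime,
      trials = x@trials, montage = .subsetMontage(x@montage, idx),
      units = x@units)
}

# indices of the time axis inside [from, to] ms (relative to cue)
.timeIndex <- function(time, window) {
  which(time >= window[1L] & time <= window[2L])
}
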