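#' @include AllClasses.R
NULL

#' Accessors for normnet data classes
#'
#' Small accessor generics: number of trials, channel labels, per-trial
#' condition labels, sampling rate, epoch time axis, and raw amplitudes.
#'
#' @param object an [EpochSet-class], [ChannelLayout-class], [SocialGraph-class]
#'   or [PLVStack-class] object, as applicable.
#' @return the requested component; see individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(object) standardGeneric("conditionLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("regionList", function(object) standardGeneric("regionList"))

#' @rdname accessors
#' @export
setGeneric("excludedChannels", function(object) standardGeneric("excludedChannels"))

#' @rdname accessors
#' @export
setGeneric("neighborMatrix", function(object) standardGeneric("neighborMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setGeneric("edgeList", function(object) standardGeneric("edgeList"))

#' @rdname accessors
#' @export
setGeneric("realLifeSize", function(object) standardGeneric("realLifeSize"))

#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(object) dim(object@amplitudes)[1])

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "ChannelLayout", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "PLVStack", function(object) object@channels)

#' @rdname accessors
#' @export
setMethod("conditionLabels", "EpochSet", function(object) object@condition)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@srate)

#' @rdname accessors
#' @export
setMethod("epochTimes", "EpochSet", function(object) {
  ns <- dim(object@amplitudes)[3]
  object@epochStart + (seq_len(ns) - 1) / object@srate * 1000
})

#' @rdname accessors
#' @export
setMethod("amplitudes", "EpochSet", function(object) object@amplitudes)

#' @rdname accessors
#' @export
setMethod("regionList", "ChannelLayout", function(object) object@regions)

#' @rdname accessors
#' @export
setMethod("excludedChannels", "ChannelLayout", function(object) object@excluded)

#' @rdname accessors
#' @export
setMethod("neighborMatrix", "ChannelLayout", function(object) object@neighbors)

#' @rdname accessors
#' @export
setMethod("nodeNames", "SocialGraph", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("edgeList", "SocialGraph", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("realLifeSize", "SocialGraph", function(object) object@realLifeSize)

setMethod("show", "ChannelLayout", function(object) {
  cat("ChannelLayout:", length(object@channels), "channels,",
      length(object@regions), "regions,",
      length(object@excluded), "excluded\n")
  cat("  regions:", paste(names(object@regions), collapse = ", "), "\n")
  cat("  neighbor threshold:", object@neighborThreshold,
      "| median neighbor count:",
      stats::median(rowSums(object@neighbors)), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@amplitudes)
  tms <- range(epochTimes(object))
  cat(sprintf("EpochSet '%s': %d trials x %d channels x %d samples\n",
              object@subject, d[1], d[2], d[3]))
  cat(sprintf("  %g Hz, %g..%g ms; conditions: %s\n",
              object@srate, tms[1], tms[2],
              paste(sprintf("%s (%d)", names(table(object@condition)),
                            table(object@condition)), collapse = ", ")))
})

setMethod("show", "SocialGraph", function(object) {
  cat(sprintf("SocialGraph: %d nodes, %d directed nomination edges%s\n",
              length(object@nodes), nrow(object@edges),
              if (length(object@realLifeSize))
                ", with real-life size counts" else ""))
})

setMethod("show", "PLVStack", function(object) {
  cat(sprintf("PLVStack: %d channels; bands: %s; conditions: %s\n",
              length(object@channels),
              paste(object@bands, collapse = ", "),
              paste(object@conditions, collapse = ", ")))
})
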