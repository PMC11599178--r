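#' @import methods
NULL

#' ChannelLayout: electrode geometry, regions and neighbor structure
#'
#' Holds the ordered channel labels of a 10-20 extended montage, their 2D
#' head-schematic coordinates, the nine scalp regions used for windowed ERP
#' statistics, the channels excluded from network analysis, and a symmetric
#' channel-neighbor relation used for spatiotemporal clustering.
#'
#' @slot channels ordered character vector of channel labels.
#' @slot positions numeric matrix (channels x 2) of schematic x/y coordinates;
#'   units are arbitrary, only relative distances matter.
#' @slot regions named list mapping region label to a character vector of
#'   member channels. Regions are disjoint.
#' @slot excluded character vector of channels removed from brain-network
#'   analysis (mastoids and cerebellar leads in the default montage).
#' @slot neighbors symmetric, irreflexive logical matrix (channels x
#'   channels); TRUE marks spatial neighbors.
#' @slot neighborThreshold numeric distance threshold that generated
#'   \code{neighbors}.
#'
#' @seealso [loadLayout()]
#' @exportClass ChannelLayout
setClass("ChannelLayout",
  representation(
    channels = "character",
    positions = "matrix",
    regions = "list",
    excluded = "character",
    neighbors = "matrix",
    neighborThreshold = "numeric"
  )
)

setValidity("ChannelLayout", function(object) {
  msgs <- character(0)
  ch <- object@channels
  if (anyDuplicated(ch)) msgs <- c(msgs, "duplicated channel labels")
  if (!identical(rownames(object@positions), ch) || ncol(object@positions) != 2)
    msgs <- c(msgs, "positions must be a (channels x 2) matrix with channel rownames")
  regch <- unlist(object@regions, use.names = FALSE)
  if (anyDuplicated(regch))
    msgs <- c(msgs, "regions must be disjoint")
  bad <- setdiff(regch, ch)
  if (length(bad))
    msgs <- c(msgs, paste0("region channel(s) not in montage: ",
                           paste(bad, collapse = ", ")))
  if (length(setdiff(object@excluded, ch)))
    msgs <- c(msgs, "excluded channels not in montage")
  nb <- object@neighbors
  if (!identical(dimnames(nb), list(ch, ch)))
    msgs <- c(msgs, "neighbors must be (channels x channels) with channel dimnames")
  else {
    if (!isTRUE(all(nb == t(nb)))) msgs <- c(msgs, "neighbor relation must be symmetric")
    if (any(diag(nb))) msgs <- c(msgs, "neighbor relation must be irreflexive")
  }
  if (length(msgs)) msgs else TRUE
})

#' EpochSet: epoched multi-channel EEG with condition labels
#'
#' A trial x channel x sample array of amplitudes (microvolts) at a fixed
#' sampling rate, time-locked to stimulus onset, together with a per-trial
#' condition label (\code{"peer_feedback"} or \code{"non_feedback"}).
#' Sample 1 corresponds to \code{epochStart} milliseconds relative to
#' stimulus onset.
#'
#' @slot amplitudes numeric array, trial x channel x sample, in microvolts.
#' @slot srate sampling rate in samples per second.
#' @slot epochStart epoch start in ms relative to stimulus onset (negative
#'   values are pre-stimulus baseline).
#' @slot condition character vector, one label per trial.
#' @slot channels channel labels, in layout order.
#' @slot subject subject identifier.
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    amplitudes = "array",
    srate = "numeric",
    epochStart = "numeric",
    condition = "character",
    channels = "character",
    subject = "character"
  )
)

.CONDITIONS <- c("peer_feedback", "non_feedback")

setValidity("EpochSet", function(object) {
  msgs <- character(0)
  d <- dim(object@amplitudes)
  if (length(d) != 3)
    return("amplitudes must be a 3-d array (trial x channel x sample)")
  if (length(object@condition) != d[1])
    msgs <- c(msgs, "one condition label per trial required")
  if (length(object@channels) != d[2])
    msgs <- c(msgs, "channel labels must match array dimension 2")
  if (!all(object@condition %in% .CONDITIONS))
    msgs <- c(msgs, paste0("condition labels must be in {",
                           paste(.CONDITIONS, collapse = ", "), "}"))
  if (length(object@srate) != 1 || object@srate <= 0)
    msgs <- c(msgs, "srate must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' SocialGraph: directed friend-nomination network
#'
#' A directed graph of friend nominations within a group, optionally with a
#' per-person count of regularly contacted real-life friends and family
#' ("real-life social network size").
#'
#' @slot nodes character vector of person identifiers.
#' @slot edges character matrix (m x 2); column 1 nominator, column 2
#'   nominee. No self-loops, no duplicates.
#' @slot realLifeSize named numeric vector of per-node counts, or length 0.
#'
#' @seealso [buildGraph()], [simulateSocialNetwork()]
#' @exportClass SocialGraph
setClass("SocialGraph",
  representation(
    nodes = "character",
    edges = "matrix",
    realLifeSize = "numeric"
  )
)

setValidity("SocialGraph", function(object) {
  msgs <- character(0)
  e <- object@edges
  if (ncol(e) != 2) return("edges must be an (m x 2) matrix")
  if (nrow(e)) {
    if (!all(e %in% object@nodes))
      msgs <- c(msgs, "edges reference unknown nodes")
    if (any(e[, 1] == e[, 2]))
      msgs <- c(msgs, "self-nominations are not allowed")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      msgs <- c(msgs, "duplicate edges are not allowed")
  }
  s <- object@realLifeSize
  if (length(s)) {
    if (!identical(sort(names(s)), sort(object@nodes)))
      msgs <- c(msgs, "realLifeSize must be named by node")
    if (any(s < 0)) msgs <- c(msgs, "realLifeSize must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' PLVStack: phase-locking-value matrices per condition and band
#'
#' Symmetric channel-pair phase-locking matrices (values in [0, 1], unit
#' diagonal) for each frequency band and experimental condition, computed over
#' the post-stimulus analysis window.
#'
#' @slot plv nested named list: \code{plv[[band]][[condition]]} is a symmetric
#'   numeric matrix over the retained channels.
#' @slot channels retained channel labels (network nodes).
#' @slot bands band labels present.
#' @slot conditions condition labels present.
#'
#' @seealso [plvStack()], [plvMatrix()]
#' @exportClass PLVStack
setClass("PLVStack",
  representation(
    plv = "list",
    channels = "character",
    bands = "character",
    conditions = "character"
  )
)

setValidity("PLVStack", function(object) {
  msgs <- character(0)
  for (b in object@bands) {
    for (cnd in names(object@plv[[b]])) {
      m <- object@plv[[b]][[cnd]]
      if (!is.matrix(m) || !identical(dimnames(m),
                                      list(object@channels, object@channels)))
        msgs <- c(msgs, sprintf("malformed PLV matrix [%s, %s]", b, cnd))
      else {
        if (max(abs(m - t(m))) > 1e-8)
          msgs <- c(msgs, sprintf("PLV matrix not symmetric [%s, %s]", b, cnd))
        if (any(m < -1e-12) || any(m > 1 + 1e-8))
          msgs <- c(msgs, sprintf("PLV values outside [0,1] [%s, %s]", b, cnd))
        if (max(abs(diag(m) - 1)) > 1e-8)
          msgs <- c(msgs, sprintf("PLV diagonal must be 1 [%s, %s]", b, cnd))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})
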