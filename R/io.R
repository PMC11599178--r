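#' @include AllClasses.R
NULL

# Epoch container: a flat little-endian float32 array (<stem>.f32, sample
# index fastest, then channel, then trial) plus a JSON sidecar (<stem>.json)
# holding dims, srate, epoch start, conditions, channels and subject id.
# Portable and diffable; values are stored at float32 precision.

#' Write an EpochSet to the package's epoch container
#'
#' @param epochs an [EpochSet-class].
#' @param stem output path stem; \code{<stem>.f32} (binary amplitudes) and
#'   \code{<stem>.json} (metadata sidecar) are written.
#' @return the stem, invisibly.
#' @seealso [readEpochs()]
#' @export
writeEpochs <- function(epochs, stem) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@amplitudes)
  meta <- list(dims = d, srate = epochs@srate,
               epoch_start = epochs@epochStart,
               conditions = epochs@condition,
               channels = epochs@channels,
               subject = epochs@subject,
               dtype = "float32-le")
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  # aperm so the sample index varies fastest within a (trial, channel) trace
  writeBin(as.numeric(aperm(epochs@amplitudes, c(3, 2, 1))), con,
           size = 4, endian = "little")
  invisible(stem)
}

#' Read an EpochSet from the package's epoch container
#'
#' @param stem path stem previously passed to [writeEpochs()].
#' @return an [EpochSet-class]; amplitudes at float32 precision.
#' @export
readEpochs <- function(stem) {
  jpath <- paste0(stem, ".json")
  bpath <- paste0(stem, ".f32")
  if (!file.exists(jpath) || !file.exists(bpath))
    stop("epoch container incomplete at stem: ", stem)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  n <- prod(d)
  raw <- readBin(bpath, what = "numeric", n = n + 1, size = 4,
                 endian = "little")
  if (length(raw) != n)
    stop("epoch container format error: sidecar declares ", n,
         " values but binary holds ", length(raw))
  arr <- aperm(array(raw, dim = rev(d)), c(3, 2, 1))
  new("EpochSet", amplitudes = arr, srate = as.numeric(meta$srate),
      epochStart = as.numeric(meta$epoch_start),
      condition = as.character(meta$conditions %||% character(0)),
      channels = as.character(meta$channels),
      subject = as.character(meta$subject))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an EpochSet
#'
#' @param amplitudes trial x channel x sample numeric array (microvolts).
#' @param srate sampling rate (Hz).
#' @param epochStart epoch start (ms relative to stimulus onset).
#' @param condition per-trial condition labels.
#' @param channels channel labels.
#' @param subject subject identifier.
#' @return an [EpochSet-class].
#' @export
epochSet <- function(amplitudes, srate = 500, epochStart = -200,
                     condition, channels, subject = "s01") {
  new("EpochSet", amplitudes = amplitudes, srate = srate,
      epochStart = epochStart, condition = as.character(condition),
      channels = as.character(channels), subject = as.character(subject))
}

.TRIAL_COLS <- c("subject", "stimulus", "condition", "initial", "offset",
                 "shown", "final", "rt_ms")

#' Read behavioral trial records from CSV
#'
#' Expected columns: subject, stimulus, condition, initial, offset, shown,
#' final, rt_ms. Ratings are integers on the 0-9 scale; feedback offsets are
#' in \{-3,-2,-1,1,2,3\}; non-feedback trials leave offset and shown empty.
#' Malformed rows raise an error naming the row.
#'
#' @param path CSV file path.
#' @return data.frame of validated trial records.
#' @export
readTrials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRIAL_COLS, names(df))
  if (length(missing))
    stop("trials file missing column(s): ", paste(missing, collapse = ", "))
  validateTrials(df)
  df
}

#' @keywords internal
validateTrials <- function(df) {
  chk <- function(bad, what) {
    if (any(bad, na.rm = TRUE))
      stop("invalid trial record (", what, ") at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  rating_ok <- function(x) !is.na(x) & x >= 0 & x <= 9 & x == round(x)
  chk(!df$condition %in% .CONDITIONS, "unknown condition label")
  chk(!rating_ok(df$initial), "initial rating outside 0-9")
  chk(!rating_ok(df$final), "final rating outside 0-9")
  fb <- df$condition == "peer_feedback"
  chk(fb & !(abs(df$offset) %in% 1:3), "feedback offset not in {±1,±2,±3}")
  chk(fb & !rating_ok(df$shown), "shown rating outside 0-9")
  chk(!fb & !is.na(df$offset), "offset present on non-feedback trial")
  chk(!fb & !is.na(df$shown), "shown rating present on non-feedback trial")
  chk(!is.na(df$rt_ms) & df$rt_ms <= 0, "non-positive reaction time")
  invisible(df)
}

#' Write behavioral trial records to CSV
#'
#' @param trials data.frame of trial records.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrials <- function(trials, path) {
  utils::write.csv(trials[, .TRIAL_COLS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a directed nomination edge list from CSV
#'
#' Expected columns: nominator, nominee (one directed edge per row).
#'
#' @param path CSV file path.
#' @param nodes optional character vector of known node ids; edges naming
#'   other ids raise an error with the row number.
#' @return data.frame with columns nominator, nominee.
#' @export
readSocialEdges <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nominator", "nominee") %in% names(df)))
    stop("edge file must have columns nominator, nominee")
  df$nominator <- as.character(df$nominator)
  df$nominee <- as.character(df$nominee)
  if (!is.null(nodes)) {
    bad <- !(df$nominator %in% nodes & df$nominee %in% nodes)
    if (any(bad))
      stop("edge references unknown node id at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  df
}

#' Read per-node real-life network-size counts from CSV
#'
#' Expected columns: id, real_life_size (non-negative counts).
#'
#' @param path CSV file path.
#' @return named numeric vector of counts.
#' @export
readNodeSizes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "real_life_size") %in% names(df)))
    stop("size file must have columns id, real_life_size")
  bad <- is.na(df$real_life_size) | df$real_life_size < 0
  if (any(bad))
    stop("negative or missing real_life_size at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  stats::setNames(as.numeric(df$real_life_size), as.character(df$id))
}

#' Write a SocialGraph to a pair of CSV files
#'
#' @param graph a [SocialGraph-class].
#' @param edgePath output CSV for the edge list (nominator, nominee).
#' @param sizePath optional output CSV for per-node sizes (id,
#'   real_life_size); skipped when the graph carries no sizes.
#' @return edgePath, invisibly.
#' @export
writeSocialGraph <- function(graph, edgePath, sizePath = NULL) {
  utils::write.csv(data.frame(nominator = graph@edges[, 1],
                              nominee = graph@edges[, 2]),
                   edgePath, row.names = FALSE)
  if (!is.null(sizePath) && length(graph@realLifeSize))
    utils::write.csv(data.frame(id = names(graph@realLifeSize),
                                real_life_size = unname(graph@realLifeSize)),
                     sizePath, row.names = FALSE)
  invisible(edgePath)
}
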