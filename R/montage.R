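#' @include AllClasses.R
NULL

#' Load a channel layout from a YAML/JSON montage configuration
#'
#' Reads channel labels, 2D schematic positions, the nine-region grouping
#' used for windowed ERP statistics, the network-excluded channel set, and a
#' distance threshold from which the spatial neighbor relation is built.
#' The packaged default describes a 64-channel 10-20 extended montage with
#' regions left/medial/right x frontal/central/parietal and excluded
#' channels CB1, CB2, M1, M2.
#'
#' Neighbor adjacency is derived by thresholding pairwise Euclidean distance
#' between the schematic positions; the threshold is part of the
#' configuration so alternative adjacency conventions can be swapped in.
#'
#' @param path path to a YAML (or JSON) configuration with keys
#'   \code{channels}, \code{positions}, \code{regions}, \code{excluded} and
#'   \code{neighbor_threshold}. Defaults to the packaged montage.
#' @return a [ChannelLayout-class] object.
#' @examples
#' lay <- loadLayout()
#' regionList(lay)[["left frontal"]]
#' @export
loadLayout <- function(path = system.file("extdata", "montage64.yaml",
                                          package = "normnet")) {
  if (!file.exists(path)) stop("layout configuration not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (k in c("channels", "positions", "regions", "excluded",
              "neighbor_threshold"))
    if (is.null(cfg[[k]])) stop("layout configuration missing key '", k, "'")
  channels <- as.character(unlist(cfg$channels))
  pos <- t(vapply(channels, function(ch) {
    p <- cfg$positions[[ch]]
    if (is.null(p) || length(p) != 2)
      stop("missing or malformed position for channel '", ch, "'")
    as.numeric(p)
  }, numeric(2)))
  rownames(pos) <- channels
  regions <- lapply(cfg$regions, function(x) as.character(unlist(x)))
  for (rg in names(regions)) {
    unknown <- setdiff(regions[[rg]], channels)
    if (length(unknown))
      stop("region '", rg, "' contains unknown channel label(s): ",
           paste(unknown, collapse = ", "))
  }
  excluded <- as.character(unlist(cfg$excluded))
  unknown <- setdiff(excluded, channels)
  if (length(unknown))
    stop("excluded list contains unknown channel label(s): ",
         paste(unknown, collapse = ", "))
  thr <- as.numeric(cfg$neighbor_threshold)
  nb <- buildNeighbors(pos, thr)
  new("ChannelLayout", channels = channels, positions = pos,
      regions = regions, excluded = excluded, neighbors = nb,
      neighborThreshold = thr)
}

#' Build a neighbor adjacency matrix by distance thresholding
#'
#' @param positions numeric matrix (channels x 2) with channel rownames.
#' @param threshold channels at Euclidean distance <= threshold are neighbors.
#' @return symmetric, irreflexive logical matrix.
#' @keywords internal
buildNeighbors <- function(positions, threshold) {
  d <- as.matrix(stats::dist(positions))
  nb <- d <= threshold
  diag(nb) <- FALSE
  dimnames(nb) <- list(rownames(positions), rownames(positions))
  nb
}

#' Channels retained for brain-network analysis
#'
#' All montage channels minus the layout's excluded set (CB1, CB2, M1, M2 in
#' the default montage), in layout order.
#'
#' @param layout a [ChannelLayout-class].
#' @return character vector of retained channel labels.
#' @export
retainedChannels <- function(layout) {
  setdiff(layout@channels, layout@excluded)
}

#' Map region labels to hemisphere and lobe factors
#'
#' Region labels of the form "<hemisphere> <lobe>" (e.g. "left frontal") are
#' split into the two within-subject factors used by the repeated-measures
#' ANOVA.
#'
#' @param regions character vector of region labels.
#' @return data.frame with columns \code{region}, \code{hemisphere},
#'   \code{lobe}.
#' @export
regionFactors <- function(regions) {
  parts <- strsplit(regions, " ", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("region label(s) not of the form '<hemisphere> <lobe>': ",
         paste(regions[bad], collapse = ", "))
  data.frame(region = regions,
             hemisphere = vapply(parts, `[`, "", 1),
             lobe = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Restrict a layout to a subset of its channels
#'
#' Keeps positions and neighbor structure (recomputed from the same
#' distance threshold), drops excluded/region channels outside the subset.
#'
#' @param layout a [ChannelLayout-class].
#' @param channels channels to keep (layout order is preserved).
#' @return a [ChannelLayout-class] over the subset.
#' @export
subsetLayout <- function(layout, channels) {
  keep <- intersect(layout@channels, channels)
  if (!length(keep)) stop("no channels left after subsetting")
  pos <- layout@positions[keep, , drop = FALSE]
  regions <- lapply(layout@regions, intersect, keep)
  regions <- regions[lengths(regions) > 0]
  new("ChannelLayout", channels = keep, positions = pos, regions = regions,
      excluded = intersect(layout@excluded, keep),
      neighbors = buildNeighbors(pos, layout@neighborThreshold),
      neighborThreshold = layout@neighborThreshold)
}
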