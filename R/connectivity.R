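#' @include AllClasses.R
NULL

# Band-limited analytic signal for the retained channels of an EpochSet,
# restricted to the analysis window. Returns a complex array
# (trial x channel x sample). One FFT pass applies the band response and
# the analytic-signal operator together, after reflection padding.
.analyticBand <- function(epochs, band, window = c(0, 1000), order = 2,
                          padMs = 200) {
  edges <- .bandEdges(band)
  if (is.null(edges)) stop("unknown band: ", paste(band, collapse = ","))
  nyq <- epochs@srate / 2
  if (edges[2] >= nyq) stop("band above the Nyquist frequency")
  tr <- .asTraces(epochs)
  z <- .applyFreqDomain(tr$x, epochs@srate,
                        function(f) butterGain2(f, edges[1], edges[2], order),
                        analytic = TRUE, padMs = padMs)
  zz <- aperm(array(z, dim = tr$d[c(3, 2, 1)]), c(3, 2, 1))
  tms <- epochTimes(epochs)
  sel <- which(tms >= window[1] & tms <= window[2])
  zz[, , sel, drop = FALSE]
}

#' Phase-locking value matrix for one condition and band
#'
#' For every channel pair (i, j), PLV = | mean of exp(1i (phi_i - phi_j)) |
#' with the mean taken over all samples of the analysis window and all
#' trials of the condition (pooled, the default) or per trial with the
#' trial PLVs averaged (\code{perTrial = TRUE}). Phases come from the
#' band-limited analytic signal. Channels in the layout's excluded set are
#' dropped. The matrix is symmetric with unit diagonal and values in
#' [0, 1]; PLV is invariant to any common phase shift of both channels.
#'
#' @param epochs a preprocessed [EpochSet-class].
#' @param band band label or c(low, high) Hz (see [frequencyBands()]).
#' @param condition condition label selecting trials.
#' @param layout a [ChannelLayout-class]; its excluded channels are removed.
#' @param window analysis window in ms (default the post-stimulus second).
#' @param perTrial average per-trial phasor means instead of pooling all
#'   samples and trials into one mean (the text convention is ambiguous;
#'   both are supported).
#' @return symmetric numeric matrix over retained channels.
#' @export
plvMatrix <- function(epochs, band, condition, layout = NULL,
                      window = c(0, 1000), perTrial = FALSE) {
  keep <- if (is.null(layout)) epochs@channels else
    intersect(epochs@channels, retainedChannels(layout))
  tri <- which(epochs@condition == condition)
  if (!length(tri)) stop("no trials in condition '", condition, "'")
  sub <- epochs
  sub@amplitudes <- epochs@amplitudes[tri, match(keep, epochs@channels), ,
                                      drop = FALSE]
  sub@condition <- epochs@condition[tri]
  sub@channels <- keep
  z <- .analyticBand(sub, band, window)
  d <- dim(z)
  u <- z / Mod(z)                                 # unit phasors
  if (perTrial) {
    acc <- matrix(0, d[2], d[2])
    for (i in seq_len(d[1])) {
      ui <- matrix(u[i, , ], d[2], d[3])
      acc <- acc + Mod(ui %*% Conj(t(ui))) / d[3]
    }
    plv <- acc / d[1]
  } else {
    um <- matrix(aperm(u, c(2, 1, 3)), d[2], d[1] * d[3])
    plv <- Mod(um %*% Conj(t(um))) / (d[1] * d[3])
  }
  plv <- pmin(pmax((plv + t(plv)) / 2, 0), 1)
  diag(plv) <- 1
  dimnames(plv) <- list(keep, keep)
  plv
}

#' PLV matrices for every band and condition
#'
#' @param epochs a preprocessed [EpochSet-class].
#' @param layout a [ChannelLayout-class].
#' @param bands named list of band edges (default [frequencyBands()]).
#' @param window,perTrial passed to [plvMatrix()].
#' @return a [PLVStack-class].
#' @export
plvStack <- function(epochs, layout, bands = frequencyBands(),
                     window = c(0, 1000), perTrial = FALSE) {
  conds <- intersect(.CONDITIONS, unique(epochs@condition))
  keep <- intersect(epochs@channels, retainedChannels(layout))
  plv <- lapply(names(bands), function(b) {
    out <- lapply(conds, function(cnd)
      plvMatrix(epochs, bands[[b]], cnd, layout, window, perTrial))
    names(out) <- conds
    out
  })
  names(plv) <- names(bands)
  new("PLVStack", plv = plv, channels = keep, bands = names(bands),
      conditions = conds)
}

#' Condition difference of PLV matrices (peer-feedback minus non-feedback)
#'
#' @param stack a [PLVStack-class] holding both conditions.
#' @return named list of symmetric difference matrices, one per band.
#' @export
deltaPlv <- function(stack) {
  if (!all(.CONDITIONS %in% stack@conditions))
    stop("both conditions required for a PLV difference")
  out <- lapply(stack@bands, function(b)
    stack@plv[[b]][["peer_feedback"]] - stack@plv[[b]][["non_feedback"]])
  names(out) <- stack@bands
  out
}

#' Edgewise association between PLV condition differences and centrality
#'
#' Correlates, for every channel pair, the across-subject PLV condition
#' difference with a per-subject centrality value; retains edges whose raw
#' (uncorrected) p-value falls below \code{alpha} and reports the connected
#' components of the retained-edge graph, annotated by scalp region. This
#' is the network-based descriptive screen used for the delta/beta
#' synchrony findings (uncorrected p < 0.01).
#'
#' @param deltas list (one element per subject) of symmetric PLV-difference
#'   matrices over identical channels, as from [deltaPlv()] for one band.
#' @param centrality numeric vector, one value per subject.
#' @param alpha raw edgewise significance level (default 0.01).
#' @param layout optional [ChannelLayout-class] for region annotation.
#' @return list with \code{edges} (data.frame channel_a, channel_b, r, p,
#'   plus regions when a layout is given), \code{components} (list of
#'   character vectors of channels), \code{r} and \code{p} (full matrices).
#' @export
edgewiseCentralityAssociation <- function(deltas, centrality, alpha = 0.01,
                                          layout = NULL) {
  n <- length(deltas)
  if (n < 4) stop("at least 4 subjects required")
  if (length(centrality) != n)
    stop("one centrality value per subject required")
  if (stats::sd(centrality) == 0)
    stop("centrality has zero variance; correlation undefined")
  ch <- rownames(deltas[[1]])
  p <- length(ch)
  flat <- vapply(deltas, function(m) m[upper.tri(m)],
                 numeric(p * (p - 1) / 2))          # edges x subjects
  zc <- as.numeric(scale(centrality))
  xs <- scale(t(flat))                               # subjects x edges
  sd0 <- attr(xs, "scaled:scale") == 0
  r <- as.numeric(crossprod(zc, xs)) / (n - 1)
  r[sd0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  pval <- 2 * stats::pt(-abs(tstat), n - 2)
  rmat <- matrix(NA_real_, p, p, dimnames = list(ch, ch))
  pmat <- rmat
  rmat[upper.tri(rmat)] <- r
  pmat[upper.tri(pmat)] <- pval
  rmat[lower.tri(rmat)] <- t(rmat)[lower.tri(rmat)]
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  ut <- which(upper.tri(rmat), arr.ind = TRUE)
  keep <- which(!is.na(pval) & pval < alpha)
  edges <- data.frame(channel_a = ch[ut[keep, 1]],
                      channel_b = ch[ut[keep, 2]],
                      r = r[keep], p = pval[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    reg <- rep(NA_character_, length(ch))
    for (rg in names(layout@regions))
      reg[ch %in% layout@regions[[rg]]] <- rg
    names(reg) <- ch
    edges$region_a <- unname(reg[edges$channel_a])
    edges$region_b <- unname(reg[edges$channel_b])
  }
  comps <- list()
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
    mem <- igraph::components(g)$membership
    comps <- split(names(mem), mem)
    names(comps) <- NULL
  }
  list(edges = edges, components = comps, r = rmat, p = pmat)
}
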