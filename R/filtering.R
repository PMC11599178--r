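#' @include AllClasses.R
NULL

# Zero-phase filtering is done in the frequency domain: each trace is
# reflection-padded, transformed with the FFT, multiplied by the squared
# magnitude response of an order-2 Butterworth band-pass (the response a
# forward-backward order-2 filter applies; 4th-order effective roll-off),
# and transformed back. This applies no phase shift by construction and
# vectorizes across all trials and channels of an EpochSet in one pass.

#' Squared-magnitude Butterworth band-pass response
#'
#' Response applied by zero-phase (forward-backward) filtering with an
#' order-\code{order} Butterworth band-pass: |H(f)|^2 with
#' |H(f)|^2 = 1 / (1 + Q(f)^(2*order)), Q(f) = (f^2 - f_l f_h) / (f B),
#' B = f_h - f_l. Pass NA for \code{low} (pure low-pass) or \code{high}
#' (pure high-pass).
#'
#' @param f frequencies (Hz).
#' @param low,high band edges (Hz).
#' @param order analog prototype order (default 2; applied twice).
#' @return attenuation factors in [0, 1].
#' @keywords internal
butterGain2 <- function(f, low, high, order = 2) {
  g <- rep(1, length(f))
  if (!is.na(low) && !is.na(high)) {
    q <- (f^2 - low * high) / (f * (high - low))
    q[f == 0] <- Inf
    g <- 1 / (1 + q^(2 * order))
  } else if (!is.na(high)) {
    g <- 1 / (1 + (f / high)^(2 * order))
  } else if (!is.na(low)) {
    q <- low / f
    q[f == 0] <- Inf
    g <- 1 / (1 + q^(2 * order))
  }
  g^2
}

# Reflection-pad a samples x traces matrix at both ends, then zero-extend to
# an FFT-friendly length. Returns list(x, keep).
.padTraces <- function(x, pad) {
  ns <- nrow(x)
  pad <- min(pad, ns - 1)
  top <- x[pad:1 + 1, , drop = FALSE]       # reflect head (excl. endpoint)
  bot <- x[ns - (1:pad), , drop = FALSE]    # reflect tail
  xp <- rbind(top, x, bot)
  nf <- nextFastLength(nrow(xp))
  if (nf > nrow(xp))
    xp <- rbind(xp, matrix(0, nf - nrow(xp), ncol(xp)))
  list(x = xp, keep = pad + seq_len(ns))
}

# Apply a frequency response (and optionally the analytic-signal operator)
# to a samples x traces matrix. gainFun(freqHz) -> multiplier.
.applyFreqDomain <- function(x, srate, gainFun, analytic = FALSE,
                             padMs = 200) {
  p <- .padTraces(x, round(padMs / 1000 * srate))
  nf <- nrow(p$x)
  freqs <- c(0:(floor(nf / 2)), -(ceiling(nf / 2) - 1):-1) * srate / nf
  gain <- gainFun(abs(freqs))
  if (analytic) {
    mult <- numeric(nf)
    mult[freqs > 0] <- 2
    mult[freqs == 0] <- 1
    if (nf %% 2 == 0) mult[nf / 2 + 1] <- 1
    gain <- gain * mult
  }
  X <- stats::mvfft(p$x) * gain
  out <- stats::mvfft(X, inverse = TRUE) / nf
  if (!analytic) out <- Re(out)
  out[p$keep, , drop = FALSE]
}

# EpochSet amplitudes as a samples x (channel*trial) matrix and back.
.asTraces <- function(epochs) {
  a <- epochs@amplitudes
  d <- dim(a)
  list(x = matrix(aperm(a, c(3, 2, 1)), nrow = d[3]), d = d)
}

.fromTraces <- function(x, d) aperm(array(x, dim = d[c(3, 2, 1)]), c(3, 2, 1))

#' Zero-phase band-pass filter an EpochSet
#'
#' Filters every trial and channel with a zero-phase Butterworth band-pass
#' (order-2 prototype applied forward-backward, i.e. 4th-order effective)
#' realized in the frequency domain after 200 ms reflection padding.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz (NA for one-sided filtering). Both must
#'   be below the Nyquist frequency.
#' @param order Butterworth prototype order (default 2).
#' @param padMs reflection padding in ms to suppress edge transients.
#' @return a filtered [EpochSet-class].
#' @export
filterEpochs <- function(epochs, low, high, order = 2, padMs = 200) {
  nyq <- epochs@srate / 2
  if ((!is.na(low) && low >= nyq) || (!is.na(high) && high >= nyq))
    stop("band edges must lie below the Nyquist frequency (", nyq, " Hz)")
  if (!is.na(low) && !is.na(high) && low >= high)
    stop("low edge must be below high edge")
  if (nTrials(epochs) == 0) return(epochs)
  tr <- .asTraces(epochs)
  y <- .applyFreqDomain(tr$x, epochs@srate,
                        function(f) butterGain2(f, low, high, order),
                        padMs = padMs)
  out <- epochs
  out@amplitudes <- .fromTraces(y, tr$d)
  out
}

#' Band-pass filter into a named frequency band
#'
#' @param epochs an [EpochSet-class].
#' @param band band label (see [frequencyBands()]) or a length-2 numeric
#'   c(low, high) in Hz.
#' @param ... passed to [filterEpochs()].
#' @return a filtered [EpochSet-class].
#' @export
bandFilter <- function(epochs, band, ...) {
  edges <- if (is.character(band)) frequencyBands()[[band]] else band
  if (is.null(edges) || length(edges) != 2)
    stop("unknown band: ", paste(band, collapse = ","))
  filterEpochs(epochs, edges[1], edges[2], ...)
}

#' Canonical analysis bands
#'
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 14-20 Hz. The gamma
#' band is deliberately absent: with a 30 Hz low-pass applied against
#' muscle artifacts there is no usable gamma signal.
#'
#' @return named list of c(low, high) edges in Hz.
#' @export
frequencyBands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(14, 20))
}

#' Preprocess epochs: band-pass filter and average reference
#'
#' Applies the standard ERP preprocessing: zero-phase band-pass (default
#' 0.1-30 Hz) followed by common-average referencing over the scalp
#' channels (channels listed in \code{excludeFromReference} take no part in
#' the average but are re-referenced too). Referencing is idempotent:
#' applying it twice changes nothing.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high filter band edges in Hz.
#' @param excludeFromReference channels excluded from the reference average
#'   (mastoid and cerebellar leads by default).
#' @return a preprocessed [EpochSet-class].
#' @export
preprocessEpochs <- function(epochs, low = 0.1, high = 30,
                             excludeFromReference = c("CB1", "CB2",
                                                      "M1", "M2")) {
  out <- filterEpochs(epochs, low, high)
  refch <- which(!out@channels %in% excludeFromReference)
  if (!length(refch)) stop("no channels left for the reference average")
  a <- out@amplitudes
  ref <- apply(a[, refch, , drop = FALSE], c(1, 3), mean)  # trial x sample
  for (ch in seq_len(dim(a)[2])) a[, ch, ] <- a[, ch, ] - ref
  out@amplitudes <- a
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default the 200 ms pre-stimulus interval).
#'
#' @param epochs an [EpochSet-class].
#' @param window closed interval c(from, to) in ms; must lie inside the
#'   epoch.
#' @return a baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-200, 0)) {
  tms <- epochTimes(epochs)
  if (window[1] < min(tms) - 1e-9 || window[2] > max(tms) + 1e-9)
    stop("baseline window outside the epoch")
  sel <- which(tms >= window[1] & tms <= window[2])
  if (!length(sel)) stop("baseline window contains no samples")
  a <- epochs@amplitudes
  bl <- rowMeans(a[, , sel, drop = FALSE], dims = 2)
  epochs@amplitudes <- a - as.vector(bl)  # recycles over samples
  epochs
}

#' Reject trials exceeding an absolute amplitude threshold
#'
#' Removes every trial on which any retained channel exceeds the threshold
#' in absolute value at any sample (the +/-75 microvolt convention by
#' default).
#'
#' @param epochs an [EpochSet-class].
#' @param threshold rejection threshold in microvolts (> 0).
#' @param ignoreChannels channels not screened (none by default).
#' @return list with elements \code{epochs} (cleaned [EpochSet-class]) and
#'   \code{rejected} (indices of removed trials).
#' @export
rejectArtifacts <- function(epochs, threshold = 75,
                            ignoreChannels = character(0)) {
  if (threshold <= 0) stop("threshold must be positive")
  keepch <- which(!epochs@channels %in% ignoreChannels)
  a <- epochs@amplitudes[, keepch, , drop = FALSE]
  peak <- vapply(seq_len(dim(a)[1]), function(i) max(abs(a[i, , ])), numeric(1))
  bad <- which(peak > threshold)
  if (length(bad) == nTrials(epochs))
    stop("all trials exceed the artifact threshold; nothing retained")
  out <- epochs
  if (length(bad)) {
    out@amplitudes <- epochs@amplitudes[-bad, , , drop = FALSE]
    out@condition <- epochs@condition[-bad]
  }
  list(epochs = out, rejected = bad)
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal, obtained by zeroing negative frequencies
#' in the spectrum (FFT method) after reflection padding. For a pure
#' sinusoid the unwrapped phase advances at 2*pi*f per second. A constant
#' (zero-variance) input has no defined phase and returns NA with a
#' warning.
#'
#' @param x numeric vector (one band-limited trace) or samples x traces
#'   matrix.
#' @param srate sampling rate in Hz (only used for padding bookkeeping).
#' @return phase in radians (-pi, pi], same shape as \code{x}.
#' @export
instantaneousPhase <- function(x, srate = 500) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  const <- apply(xm, 2, function(v) stats::sd(v) == 0)
  z <- .applyFreqDomain(xm, srate, function(f) rep(1, length(f)),
                        analytic = TRUE)
  ph <- Arg(z)
  if (any(const)) {
    warning("constant signal: instantaneous phase undefined")
    ph[, const] <- NA_real_
  }
  if (vec) ph[, 1] else ph
}
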