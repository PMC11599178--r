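#' @include AllClasses.R
NULL

#' Ground-truth effect specification for the EEG generator
#'
#' Collects every free parameter of the synthetic EEG: the ERP component
#' effects, the per-band phase-coupling targets, the slopes tying a
#' subject's standardized social-network centrality to their effect
#' magnitudes, and the background-noise model.
#'
#' Default effects emulate the reported condition differences: a posterior
#' N2 made more negative by peer feedback (-1 microvolt over the parietal
#' regions, 180-280 ms), a broad centro-parietal P3 increase (+0.3, 300-500
#' ms), a frontal LPP increase (+0.5, 600-800 ms), and a beta-band coupling
#' drop under feedback that lowers local efficiency. The default centrality
#' link puts a 0.6 microvolt-per-SD slope on the LPP condition difference.
#'
#' @param erpEffects list of components; each a list with \code{label},
#'   \code{window} (c(from, to) ms), \code{regions} (region labels whose
#'   channels receive the bump), \code{base} (amplitude in both conditions,
#'   microvolts) and \code{diff} (peer-feedback minus non-feedback
#'   amplitude, microvolts).
#' @param coupling list of coupling groups; each a list with \code{band}
#'   (label or c(low, high) Hz), \code{channels} (coupled set),
#'   \code{plv} (named c(peer_feedback=, non_feedback=) target phase
#'   locking), optionally \code{amplitude} (oscillation amplitude in
#'   microvolts; by default six times the in-band noise RMS, which keeps
#'   noise-induced phase jitter small in every band) and optionally
#'   \code{link} (target-PLV slope per SD centrality, applied to
#'   the peer-feedback condition).
#' @param centralityLink named numeric vector: ERP component label ->
#'   slope (microvolts per SD of centrality) added to that component's
#'   condition difference.
#' @param noise list with \code{exponent} (1/f spectral exponent),
#'   \code{knee} (Hz; the spectrum flattens below this frequency, as real
#'   EEG background spectra do, keeping near-DC drift bounded) and
#'   \code{rms} (broadband RMS, microvolts).
#' @return an object of class \code{EffectSpec} (a validated list).
#' @export
effectSpec <- function(erpEffects = list(
                         list(label = "N2", window = c(180, 280),
                              regions = c("left parietal", "medial parietal",
                                          "right parietal"),
                              base = -1.5, diff = -1.0),
                         list(label = "P3", window = c(300, 500),
                              regions = c("left central", "medial central",
                                          "right central", "medial parietal"),
                              base = 1.5, diff = 0.3),
                         list(label = "LPP", window = c(600, 800),
                              regions = c("left frontal", "medial frontal",
                                          "right frontal"),
                              base = 1.0, diff = 0.5)),
                       coupling = list(
                         list(band = "beta",
                              channels = c("F3", "F1", "FZ", "F2", "F4",
                                           "FC3", "FC1", "FCZ", "FC2", "FC4"),
                              plv = c(peer_feedback = 0.35,
                                      non_feedback = 0.55)),
                         list(band = "delta",
                              channels = c("C3", "CZ", "C4", "CP3", "CPZ",
                                           "CP4", "P3", "PZ", "P4"),
                              plv = c(peer_feedback = 0.5,
                                      non_feedback = 0.4))),
                       centralityLink = c(LPP = 0.6),
                       noise = list(exponent = 1, rms = 4, knee = 2)) {
  for (ef in erpEffects) {
    stopifnot(is.character(ef$label), length(ef$window) == 2)
    if (ef$window[1] >= ef$window[2]) stop("degenerate component window")
  }
  for (cg in coupling) {
    if (any(cg$plv < 0 | cg$plv > 1))
      stop("target PLV must lie in [0, 1]")
  }
  if (noise$rms <= 0) stop("noise RMS must be positive")
  noise$knee <- noise$knee %||% 1
  if (noise$knee <= 0) stop("noise knee must be positive")
  structure(list(erpEffects = erpEffects, coupling = coupling,
                 centralityLink = centralityLink, noise = noise),
            class = "EffectSpec")
}

# In-band noise RMS under the generator's spectral-shaping model, given the
# band-pass response used for phase extraction. Needed to correct the
# von Mises concentration for noise-induced phase jitter.
.bandNoiseRms <- function(noise, band, srate = 500, n = 601) {
  nf <- nextFastLength(n)
  f <- (1:(nf %/% 2)) * srate / nf
  w <- pmax(f, noise$knee %||% 1)^(-noise$exponent)
  g <- butterGain2(f, band[1], band[2])
  sqrt(noise$rms^2 * sum(w * g) / sum(w))
}

# Von Mises concentration reproducing a target empirical PLV for a channel
# pair, correcting for in-band additive-noise phase jitter: each channel's
# phasor is attenuated by roughly exp(-sigma_phi^2 / 2) with
# sigma_phi^2 = (noise power in band) / (oscillation power), scaled by a
# pooling factor (calibrated once empirically) that accounts for the
# within-trial averaging of band-limited noise phase errors by the pooled
# PLV estimator.
.PHASE_JITTER_POOLING <- 0.36

.kappaForPlv <- function(target, amplitude, noise, band, srate = 500) {
  sigb <- .bandNoiseRms(noise, band, srate)
  varphi <- .PHASE_JITTER_POOLING * sigb^2 / (amplitude^2 / 2)
  atten <- exp(-varphi / 2)
  rho <- sqrt(target) / atten
  kappaForResultant(min(rho, 0.9999))
}

.bandEdges <- function(band) {
  if (is.character(band)) frequencyBands()[[band]] else band
}

#' Simulate epoched EEG for one session with known ground truth
#'
#' Each trial is the sum of (i) spectrally shaped 1/f background noise,
#' (ii) per-band oscillations whose inter-channel phase lags follow a von
#' Mises jitter around a common trial-wise oscillator, with concentration
#' chosen so the empirical phase-locking of designated channel pairs
#' approaches the spec's targets, and (iii) raised-cosine ERP bumps over
#' the component windows, whose peer-feedback-minus-non-feedback amplitude
#' difference grows with the subject's standardized centrality through the
#' spec's centrality link.
#'
#' @param session data.frame of trial records (see [simulateSession()]);
#'   row order defines trial order.
#' @param layout a [ChannelLayout-class].
#' @param spec an [effectSpec()].
#' @param centralityZ the subject's standardized centrality (drives the
#'   centrality-linked effect and coupling slopes).
#' @param seed integer seed.
#' @param srate sampling rate (Hz).
#' @param epochWindow c(from, to) ms of the epoch relative to stimulus
#'   onset.
#' @return an [EpochSet-class] (trial x channel x sample, microvolts).
#' @examples
#' lay <- loadLayout()
#' ses <- simulateSession(10, seed = 1)
#' ep <- simulateEEG(ses, lay, seed = 1)
#' @export
simulateEEG <- function(session, layout, spec = effectSpec(),
                        centralityZ = 0, seed = NULL, srate = 500,
                        epochWindow = c(-200, 1000)) {
  stopifnot(inherits(spec, "EffectSpec"))
  withSeed(seed, {
    ch <- layout@channels
    nch <- length(ch)
    ntr <- nrow(session)
    ns <- round(diff(epochWindow) / 1000 * srate) + 1
    tsec <- (epochWindow[1] + (seq_len(ns) - 1) / srate * 1000) / 1000
    fb <- session$condition == "peer_feedback"

    # --- 1/f background noise, spectrally shaped, per trial x channel ---
    m <- ntr * nch
    nf <- nextFastLength(ns)
    w <- matrix(stats::rnorm(nf * m), nf, m)
    freqs <- c(0:(nf %/% 2), -((nf - 1) %/% 2):-1) * srate / nf
    shape <- pmax(abs(freqs), spec$noise$knee %||% 1)^(-spec$noise$exponent / 2)
    shape[freqs == 0] <- 0
    x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / nf
    x <- x[seq_len(ns), , drop = FALSE]
    x <- x * (spec$noise$rms / sqrt(mean(x^2)))
    a <- aperm(array(x, dim = c(ns, nch, ntr)), c(3, 2, 1))

    # --- band-limited oscillations with controlled phase coupling ---
    for (cg in spec$coupling) {
      edges <- .bandEdges(cg$band)
      if (is.null(edges)) stop("unknown band in coupling spec")
      if (epochWindow[1] >= epochWindow[2]) stop("degenerate epoch")
      f0 <- sqrt(edges[1] * edges[2])
      amp <- cg$amplitude %||% (6 * .bandNoiseRms(spec$noise, edges, srate))
      gch <- match(intersect(cg$channels, ch), ch)
      if (!length(gch)) stop("no coupling channel present in the layout")
      target <- cg$plv
      if (!is.null(cg$link)) {
        target["peer_feedback"] <- min(0.98, max(0,
          target[["peer_feedback"]] + cg$link * centralityZ))
      }
      common <- stats::runif(ntr, -pi, pi)
      carrier <- 2 * pi * f0 * tsec
      for (cond in .CONDITIONS) {
        tri <- which(session$condition == cond)
        if (!length(tri)) next
        kap <- .kappaForPlv(target[[cond]], amp, spec$noise, edges, srate)
        for (jc in seq_along(gch)) {
          jit <- if (is.infinite(kap)) numeric(length(tri)) else
            rvonmises(length(tri), kap)
          ph <- common[tri] + jit
          a[tri, gch[jc], ] <- a[tri, gch[jc], ] +
            amp * sin(outer(ph, carrier, `+`))
        }
      }
    }

    # --- ERP component bumps, condition- and centrality-scaled ---
    for (ef in spec$erpEffects) {
      win <- ef$window
      if (win[1] < epochWindow[1] || win[2] > epochWindow[2])
        stop("component window outside the epoch: ", ef$label)
      u <- (tsec * 1000 - win[1]) / (win[2] - win[1])
      tmpl <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
      inwin <- u >= 0 & u <= 1
      tmpl <- tmpl / mean(tmpl[inwin])   # unit window mean: diff in
                                         # microvolts equals the measured
                                         # window-mean condition difference
      slope <- if (ef$label %in% names(spec$centralityLink))
        spec$centralityLink[[ef$label]] else 0
      ampPerTrial <- ef$base + (ef$diff + slope * centralityZ) * fb
      effch <- match(intersect(unlist(layout@regions[ef$regions]), ch), ch)
      bump <- outer(ampPerTrial, tmpl)           # trial x sample
      for (jc in effch) a[, jc, ] <- a[, jc, ] + bump
    }

    epochSet(a, srate = srate, epochStart = epochWindow[1],
             condition = session$condition, channels = ch,
             subject = session$subject[1])
  })
}

#' Inject threshold-exceeding artifacts into a fraction of trials
#'
#' Adds a large square-pulse deflection to one random channel of each
#' selected trial, guaranteeing the trial exceeds the +/-\code{amplitude}
#' screening threshold. Returns the contaminated trial indices as ground
#' truth for rejection-accuracy tests.
#'
#' @param epochs an [EpochSet-class].
#' @param fraction fraction of trials to contaminate, in [0, 1].
#' @param amplitude artifact scale in microvolts; must exceed 75 so the
#'   standard screening threshold catches it.
#' @param seed integer seed.
#' @return list with \code{epochs} (contaminated [EpochSet-class]) and
#'   \code{contaminated} (sorted trial indices).
#' @export
injectArtifacts <- function(epochs, fraction, amplitude = 100,
                            seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (amplitude <= 75)
    stop("artifact amplitude must exceed the 75 microvolt threshold")
  withSeed(seed, {
    n <- nTrials(epochs)
    k <- round(fraction * n)
    if (k == 0) return(list(epochs = epochs, contaminated = integer(0)))
    picks <- sort(sample.int(n, k))
    d <- dim(epochs@amplitudes)
    for (i in picks) {
      chn <- sample.int(d[2], 1)
      s0 <- sample.int(max(1, d[3] - 50), 1)
      sgn <- sample(c(-1, 1), 1)
      epochs@amplitudes[i, chn, s0:min(d[3], s0 + 49)] <-
        epochs@amplitudes[i, chn, s0:min(d[3], s0 + 49)] + sgn * 2 * amplitude
    }
    list(epochs = epochs, contaminated = picks)
  })
}
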