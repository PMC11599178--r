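# Shared fixtures built in code at test time.

defaultLayout <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- loadLayout()
    cache
  }
})

# A small frontal/central montage for fast EEG-generator tests.
miniLayout <- function() {
  subsetLayout(defaultLayout(),
               c("F3", "FZ", "F4", "C3", "CZ", "C4"))
}

# The 16-channel grid used for cluster-permutation simulations.
grid16Layout <- function() {
  subsetLayout(defaultLayout(),
               c("F3", "FZ", "F4", "FC3", "FCZ", "FC4",
                 "C3", "CZ", "C4", "CP3", "CPZ", "CP4",
                 "P3", "PZ", "P4", "OZ"))
}

# EpochSet of pure white noise for estimator null checks.
noiseEpochs <- function(nTrials, channels, nSamples, sd = 1,
                        srate = 500, epochStart = 0,
                        condition = "peer_feedback") {
  a <- array(stats::rnorm(nTrials * length(channels) * nSamples, sd = sd),
             dim = c(nTrials, length(channels), nSamples))
  epochSet(a, srate = srate, epochStart = epochStart,
           condition = rep(condition, length.out = nTrials),
           channels = channels)
}
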