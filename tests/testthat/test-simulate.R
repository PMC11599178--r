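test_that("session generator balances conditions and offsets", {
  tr <- simulateSession(60, seed = 1)
  expect_equal(unname(table(tr$condition)["peer_feedback"]), 30L)
  expect_equal(unname(table(tr$condition)["non_feedback"]), 30L)
  fb <- tr[tr$condition == "peer_feedback", ]
  expect_equal(as.vector(table(fb$offset)), rep(5L, 6))   # 30 / 6 exactly
  expect_equal(fb$shown, makeGroupRating(fb$initial, fb$offset))
  nf <- tr[tr$condition == "non_feedback", ]
  expect_true(all(is.na(nf$offset)) && all(is.na(nf$shown)))
  expect_error(simulateSession(61), "even")
  # determinism
  expect_identical(simulateSession(60, seed = 5), simulateSession(60, seed = 5))
  expect_false(identical(simulateSession(60, seed = 5),
                         simulateSession(60, seed = 6)))
})

test_that("EEG generator is seed-deterministic", {
  lay <- miniLayout()
  ses <- simulateSession(8, seed = 2)
  e1 <- simulateEEG(ses, lay, seed = 3)
  e2 <- simulateEEG(ses, lay, seed = 3)
  expect_identical(amplitudes(e1), amplitudes(e2))
  e3 <- simulateEEG(ses, lay, seed = 4)
  expect_false(identical(amplitudes(e1), amplitudes(e3)))
  expect_equal(dim(amplitudes(e1)), c(8, 6, 601))
  expect_equal(epochTimes(e1)[1], -200)
  expect_equal(epochTimes(e1)[601], 1000)
})

test_that("injected ERP condition differences are recovered as window means", {
  lay <- defaultLayout()
  ses <- simulateSession(200, seed = 11)
  sp <- effectSpec(coupling = list())
  ep <- baselineCorrect(simulateEEG(ses, lay, sp, seed = 12))
  d <- amplitudeDifferences(windowRegionMeans(ep, lay))
  n2p <- mean(d$diff[d$component == "N2" & d$region %in%
                     c("left parietal", "medial parietal", "right parietal")])
  expect_lt(abs(n2p - (-1.0)), 0.25)               # Monte Carlo error
  lpf <- mean(d$diff[d$component == "LPP" & grepl("frontal", d$region)])
  expect_lt(abs(lpf - 0.5), 0.25)
  # regions without an injected effect stay near zero
  expect_lt(abs(mean(d$diff[d$component == "N2" & grepl("frontal", d$region)])),
            0.3)
})

test_that("ERP effects scale linearly with the specified amplitude", {
  lay <- miniLayout()
  ses <- simulateSession(60, seed = 21)
  mk <- function(diff) {
    sp <- effectSpec(erpEffects = list(
      list(label = "LPP", window = c(600, 800),
           regions = c("medial frontal", "left frontal", "right frontal"),
           base = 0, diff = diff)),
      coupling = list(), noise = list(exponent = 1, rms = 0.5, knee = 2))
    ep <- baselineCorrect(simulateEEG(ses, lay, sp, seed = 22))
    d <- amplitudeDifferences(windowRegionMeans(ep, lay))
    mean(d$diff[d$component == "LPP" & grepl("frontal", d$region)])
  }
  m1 <- mk(0.5); m2 <- mk(1.0)
  expect_equal(m2 / m1, 2, tolerance = 0.1)
})

test_that("a zero-effect spec produces no condition difference beyond noise", {
  lay <- defaultLayout()
  sp <- effectSpec(erpEffects = list(), coupling = list())
  ps <- sapply(1:8, function(i) {
    ses <- simulateSession(60, seed = 700 + i)
    ep <- baselineCorrect(simulateEEG(ses, lay, sp, seed = 800 + i))
    d <- amplitudeDifferences(windowRegionMeans(ep, lay))
    t.test(d$diff)$p.value
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("phase-coupling calibration reaches its targets", {
  lay <- miniLayout()
  ses <- simulateSession(400, seed = 31)      # 200 trials per condition
  for (target in c(0.3, 0.6, 0.85)) {
    sp <- effectSpec(erpEffects = list(),
                     coupling = list(list(band = "beta",
                                          channels = c("F3", "F4"),
                                          plv = c(peer_feedback = target,
                                                  non_feedback = target))))
    meas <- sapply(1:6, function(s) {
      ep <- simulateEEG(ses, lay, sp, seed = 40 + s)
      plvMatrix(ep, "beta", "peer_feedback", lay)["F3", "F4"]
    })
    expect_lt(abs(mean(meas) - target), 0.05)
  }
})

test_that("perfect coupling yields near-unit phase locking", {
  lay <- miniLayout()
  ses <- simulateSession(60, seed = 33)
  sp <- effectSpec(erpEffects = list(),
                   coupling = list(list(band = "delta",
                                        channels = c("F3", "F4"),
                                        plv = c(peer_feedback = 1,
                                                non_feedback = 1))))
  ep <- simulateEEG(ses, lay, sp, seed = 34)
  expect_gt(plvMatrix(ep, "delta", "peer_feedback", lay)["F3", "F4"], 0.95)
})

test_that("artifact injection marks exactly the contaminated trials", {
  lay <- miniLayout()
  ses <- simulateSession(100, seed = 41)
  ep <- simulateEEG(ses, lay, seed = 42)
  inj <- injectArtifacts(ep, fraction = 0.1, amplitude = 100, seed = 43)
  expect_length(inj$contaminated, 10)
  peaks <- sapply(inj$contaminated, function(i)
    max(abs(amplitudes(inj$epochs)[i, , ])))
  expect_true(all(peaks > 100))
  inj0 <- injectArtifacts(ep, fraction = 0, seed = 44)
  expect_identical(amplitudes(inj0$epochs), amplitudes(ep))
  expect_length(inj0$contaminated, 0)
  expect_error(injectArtifacts(ep, fraction = 1.5), "fraction")
  expect_error(injectArtifacts(ep, fraction = 0.1, amplitude = 50), "exceed")
})

test_that("invalid effect specifications are rejected", {
  expect_error(effectSpec(noise = list(exponent = 1, rms = 0)), "RMS")
  expect_error(effectSpec(coupling = list(list(band = "beta",
    channels = c("F3", "F4"), plv = c(peer_feedback = 1.2,
                                      non_feedback = 0.5)))), "PLV")
  lay <- miniLayout()
  ses <- simulateSession(4, seed = 1)
  sp <- effectSpec(erpEffects = list(list(label = "X", window = c(900, 1300),
                                          regions = "medial frontal",
                                          base = 0, diff = 1)),
                   coupling = list())
  expect_error(simulateEEG(ses, lay, sp, seed = 1), "outside the epoch")
})
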