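test_that("band filters pass their band and attenuate the rest", {
  t <- (0:600) / 500
  mk <- function(f) epochSet(array(rep(sin(2 * pi * f * t), each = 2),
                                   c(1, 2, 601)),
                             condition = "peer_feedback",
                             channels = c("F3", "F4"))
  mid <- 250:350
  alpha10 <- bandFilter(mk(10), "alpha")
  expect_equal(max(abs(amplitudes(alpha10)[1, 1, mid])), 1, tolerance = 0.05)
  delta10 <- bandFilter(mk(10), "delta")
  expect_lt(max(abs(amplitudes(delta10)[1, 1, mid])), 0.1)
  expect_error(bandFilter(mk(10), "gamma"), "unknown band")
  expect_error(bandFilter(mk(10), c(100, 300)), "Nyquist")
  # white noise: filtered power concentrates inside the passband
  set.seed(31)
  ep <- noiseEpochs(1, c("F3", "F4"), 2000)
  filt <- bandFilter(ep, "alpha")
  x <- amplitudes(filt)[1, 1, ]
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(sp) - 1) * 500 / length(sp)
  inband <- freqs >= 7 & freqs <= 13
  half <- freqs <= 250
  expect_gt(sum(sp[inband & half]) / sum(sp[half]), 0.9)
})

test_that("instantaneous phase follows analytic identities", {
  t <- (0:600) / 500
  ph <- instantaneousPhase(sin(2 * pi * 5 * t))
  slope <- mean(diff(ph[100:500]) %% (2 * pi)) * 500
  expect_equal(slope, 2 * pi * 5, tolerance = 0.01 * 2 * pi * 5)
  x <- sin(2 * pi * 7 * t + 0.4)
  expect_equal(instantaneousPhase(x), instantaneousPhase(x))
  d <- instantaneousPhase(x) - instantaneousPhase(-x)
  expect_equal(abs(Arg(exp(1i * d[100:500]))), rep(pi, 401), tolerance = 1e-6)
  expect_warning(phc <- instantaneousPhase(rep(1, 100)), "undefined")
  expect_true(all(is.na(phc)))
})

test_that("PLV satisfies its defining identities", {
  set.seed(41)
  # constant-lag sinusoids lock perfectly; the epoch extends 1 s past the
  # analysis window on both sides so phases are estimated away from the
  # filter/transform edge transients
  ns <- 1501
  t <- (0:(ns - 1)) / 500
  a <- array(0, c(3, 2, ns))
  for (i in 1:3) {
    a[i, 1, ] <- sin(2 * pi * 10 * t + i)
    a[i, 2, ] <- sin(2 * pi * 10 * t + i + 0.8)
  }
  ep <- epochSet(a, epochStart = -1000, condition = rep("peer_feedback", 3),
                 channels = c("F3", "F4"))
  m <- plvMatrix(ep, "alpha", "peer_feedback")
  expect_gt(m["F3", "F4"], 1 - 1e-6)
  expect_equal(unname(diag(m)), c(1, 1))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  # identical channels lock exactly
  a[, 2, ] <- a[, 1, ]
  ep2 <- epochSet(a, epochStart = -1000,
                  condition = rep("peer_feedback", 3),
                  channels = c("F3", "F4"))
  expect_equal(plvMatrix(ep2, "alpha", "peer_feedback")["F3", "F4"], 1,
               tolerance = 1e-9)
  # common phase shift leaves PLV unchanged
  b <- a
  for (i in 1:3) {
    b[i, 1, ] <- sin(2 * pi * 10 * t + i + 1.1)
    b[i, 2, ] <- sin(2 * pi * 10 * t + i + 0.8 + 1.1)
  }
  ep3 <- epochSet(b, epochStart = -1000,
                  condition = rep("peer_feedback", 3),
                  channels = c("F3", "F4"))
  expect_equal(plvMatrix(ep3, "alpha", "peer_feedback")["F3", "F4"],
               m["F3", "F4"], tolerance = 1e-6)
  expect_error(plvMatrix(ep, "alpha", "non_feedback"), "no trials")
})

test_that("independent noise channels show near-zero locking", {
  set.seed(42)
  ep <- noiseEpochs(200, c("F3", "F4"), 500)
  m <- plvMatrix(ep, "alpha", "peer_feedback")
  expect_lt(m["F3", "F4"], 0.1)
})

test_that("vectorized PLV equals the brute-force phasor mean", {
  set.seed(43)
  ep <- noiseEpochs(5, c("F3", "F4"), 80)
  m <- plvMatrix(ep, "alpha", "peer_feedback")
  z <- normnet:::.analyticBand(ep, "alpha", c(0, 1000))
  oracle <- brutePLVOracle(matrix(Arg(z[, 1, ]), 5), matrix(Arg(z[, 2, ]), 5))
  expect_equal(m["F3", "F4"], oracle, tolerance = 1e-10)
  # per-trial averaging variant also matches its own brute force
  mt <- plvMatrix(ep, "alpha", "peer_feedback", perTrial = TRUE)
  per <- mean(sapply(1:5, function(i)
    brutePLVOracle(matrix(Arg(z[i, 1, ]), 1), matrix(Arg(z[i, 2, ]), 1))))
  expect_equal(mt["F3", "F4"], per, tolerance = 1e-10)
})

test_that("PLV stacks difference antisymmetrically across conditions", {
  lay <- miniLayout()
  ses <- simulateSession(40, seed = 51)
  ep <- simulateEEG(ses, lay, effectSpec(erpEffects = list(), coupling =
    list(list(band = "beta", channels = c("F3", "F4"),
              plv = c(peer_feedback = 0.7, non_feedback = 0.3)))),
    seed = 52)
  st <- plvStack(ep, lay, bands = frequencyBands()["beta"])
  d <- deltaPlv(st)
  expect_equal(d$beta, -(st@plv$beta$non_feedback - st@plv$beta$peer_feedback))
  expect_true(all(abs(diag(d$beta)) < 1e-12))
  expect_gt(d$beta["F3", "F4"], 0.15)    # injected coupling difference
  # identical conditions difference to zero
  st2 <- st
  st2@plv$beta$non_feedback <- st2@plv$beta$peer_feedback
  expect_true(all(deltaPlv(st2)$beta == 0))
})

test_that("edgewise centrality screening finds linked edges at the set rate", {
  set.seed(61)
  ch <- c("F3", "F4", "P3", "P4")
  n <- 24
  cen <- rnorm(n)
  mkDelta <- function(link) {
    lapply(seq_len(n), function(i) {
      m <- matrix(rnorm(16, sd = 0.1), 4, 4, dimnames = list(ch, ch))
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m["F3", "P3"] <- m["P3", "F3"] <- 0.3 * cen[i] + rnorm(1, sd = 0.05)
      if (!link) { m["F3", "P3"] <- m["P3", "F3"] <- rnorm(1, sd = 0.1) }
      m
    })
  }
  res <- edgewiseCentralityAssociation(mkDelta(TRUE), cen, alpha = 0.01,
                                       layout = defaultLayout())
  expect_true(any(res$edges$channel_a == "F3" & res$edges$channel_b == "P3"))
  expect_true("region_a" %in% names(res$edges))
  expect_gt(length(res$components), 0)
  # null: per-edge retention rate near the nominal alpha
  hits <- replicate(60, {
    r0 <- edgewiseCentralityAssociation(mkDelta(FALSE), rnorm(n),
                                        alpha = 0.01)
    nrow(r0$edges)
  })
  expect_lt(mean(hits) / 6, 0.05)        # 6 edges screened per replicate
  expect_error(edgewiseCentralityAssociation(mkDelta(TRUE), rep(1, n)),
               "zero variance")
  expect_error(edgewiseCentralityAssociation(mkDelta(TRUE)[1:3], cen[1:3]),
               "4 subjects")
})
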