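sineEpochs <- function(freq, channels = c("CZ", "PZ"), nTrials = 1,
                       srate = 500, dc = 0) {
  t <- (0:(601 - 1)) / srate
  a <- array(rep(sin(2 * pi * freq * t) + dc,
                 each = nTrials * length(channels)),
             dim = c(nTrials, length(channels), 601))
  epochSet(a, srate = srate, epochStart = -200,
           condition = rep("peer_feedback", nTrials), channels = channels)
}

test_that("preprocessing filters out-of-band signal and DC", {
  mid <- 250:350                        # away from epoch edges
  f50 <- filterEpochs(sineEpochs(50), 0.1, 30)
  expect_lt(max(abs(amplitudes(f50)[1, 1, mid])), 0.1)   # > 90 % attenuated
  fdc <- filterEpochs(sineEpochs(10, dc = 10), 0.1, 30)
  expect_lt(abs(mean(amplitudes(fdc)[1, 1, mid])), 0.5)  # DC removed
  f10 <- filterEpochs(sineEpochs(10), 0.1, 30)
  expect_gt(max(abs(amplitudes(f10)[1, 1, mid])), 0.9)   # passband kept
  expect_error(filterEpochs(sineEpochs(10), 0.1, 300), "Nyquist")
})

test_that("average referencing zeroes the channel mean and is idempotent", {
  lay <- defaultLayout()
  ses <- simulateSession(6, seed = 51)
  ep <- simulateEEG(ses, lay, seed = 52)
  p1 <- preprocessEpochs(ep)
  refch <- !channelNames(p1) %in% c("CB1", "CB2", "M1", "M2")
  chmean <- apply(amplitudes(p1)[, refch, ], c(1, 3), mean)
  # reference average is zero at every trial and sample, so re-referencing
  # (subtracting it again) is the identity
  expect_lt(max(abs(chmean)), 1e-9)
})

test_that("baseline correction zeroes the pre-stimulus mean per trial", {
  a <- array(5, dim = c(1, 2, 601))
  ep <- epochSet(a, condition = "non_feedback", channels = c("A", "B"))
  bc <- baselineCorrect(ep)
  expect_true(all(abs(amplitudes(bc)) < 1e-12))
  # independent offsets per trial
  a2 <- array(0, dim = c(2, 1, 601))
  a2[1, 1, ] <- 3; a2[2, 1, ] <- -7
  ep2 <- epochSet(a2, condition = rep("non_feedback", 2), channels = "A")
  bc2 <- baselineCorrect(ep2)
  expect_true(all(abs(amplitudes(bc2)) < 1e-12))
  tms <- epochTimes(ep)
  sel <- tms >= -200 & tms <= 0
  ep3 <- simulateEEG(simulateSession(4, seed = 1), miniLayout(), seed = 2)
  bc3 <- baselineCorrect(ep3)
  blmean <- rowMeans(amplitudes(bc3)[, , sel, drop = FALSE], dims = 2)
  expect_lt(max(abs(blmean)), 1e-10)
  expect_error(baselineCorrect(ep, c(-500, 0)), "outside")
})

test_that("artifact rejection removes exactly the threshold violations", {
  a <- array(0, dim = c(3, 2, 100))
  a[1, 1, 50] <- 80                      # above threshold
  a[2, 2, 10] <- -74.9                   # just below
  ep <- epochSet(a, condition = rep("non_feedback", 3), channels = c("A", "B"))
  res <- rejectArtifacts(ep, 75)
  expect_equal(res$rejected, 1L)
  expect_equal(nTrials(res$epochs), 2)
  a[, , ] <- 100
  expect_error(rejectArtifacts(epochSet(a, condition = rep("non_feedback", 3),
                                        channels = c("A", "B")), 75),
               "all trials")
  # generator ground truth: exactly the injected trials are rejected
  lay <- miniLayout()
  ep2 <- simulateEEG(simulateSession(100, seed = 61), lay, seed = 62)
  inj <- injectArtifacts(ep2, 0.1, amplitude = 100, seed = 63)
  res2 <- rejectArtifacts(inj$epochs, 75)
  expect_identical(res2$rejected, inj$contaminated)
})

test_that("window/region means are linear and reduce to single trials", {
  lay <- defaultLayout()
  ses <- simulateSession(2, seed = 71)
  ep <- simulateEEG(ses, lay, seed = 72)
  tab <- windowRegionMeans(ep, lay)
  expect_equal(nrow(tab), 2 * 9 * 3)     # condition x region x component
  ep2 <- ep
  ep2@amplitudes <- ep@amplitudes * 3
  tab2 <- windowRegionMeans(ep2, lay)
  expect_equal(tab2$amplitude, 3 * tab$amplitude, tolerance = 1e-12)
  # single trial per condition: the table equals that trial's window means
  tms <- epochTimes(ep)
  sel <- tms >= 180 & tms <= 280
  chs <- match(regionList(lay)[["medial parietal"]], channelNames(ep))
  i <- which(conditionLabels(ep) == "peer_feedback")[1]
  manual <- mean(amplitudes(ep)[i, chs, sel])
  got <- tab$amplitude[tab$condition == "peer_feedback" &
                       tab$region == "medial parietal" & tab$component == "N2"]
  expect_equal(got, manual)
})

test_that("repeated-measures ANOVA reports GG-corrected effects", {
  set.seed(81)
  lay <- defaultLayout()
  regions <- names(regionList(lay))
  mkTable <- function(n, regionEffect = 0) {
    do.call(rbind, lapply(seq_len(n), function(s) {
      do.call(rbind, lapply(regions, function(rg) {
        lobe <- regionFactors(rg)$lobe
        eff <- if (lobe == "parietal") regionEffect else 0
        data.frame(subject = sprintf("s%02d", s),
                   condition = c("peer_feedback", "non_feedback"),
                   region = rg, component = "N2",
                   amplitude = rnorm(2, sd = 0.3) + c(eff, 0))
      }))
    }))
  }
  tab <- mkTable(12, regionEffect = -1)
  res <- rmAnova(tab, "N2")
  expect_equal(res$effect, c("S", "S:R", "S:H", "S:R:H"))
  expect_equal(res$eps[res$effect == "S"], 1)          # 2-level: sphericity forced
  expect_equal(res$p[res$effect == "S"], res$p_gg[res$effect == "S"])
  expect_lt(res$p_gg[res$effect == "S:R"], 0.01)       # injected interaction
  expect_true(all(res$eps > 1 / 2 & res$eps <= 1 + 1e-9))
  expect_true(all(res$F >= 0))
  expect_true(all(res$peta2 >= 0 & res$peta2 <= 1))
  se <- simpleEffects(tab, "N2")
  expect_lt(se$p[se$lobe == "parietal"], 0.01)
  expect_gt(min(se$p[se$lobe != "parietal"]), 0.05)
  expect_error(rmAnova(tab[tab$region != "left frontal", ], "N2"),
               "incomplete")
  expect_error(rmAnova(mkTable(3), "N2"), "n >= 5")
})

test_that("null amplitude tables keep the feedback effect at nominal size", {
  set.seed(82)
  lay <- defaultLayout()
  regions <- names(regionList(lay))
  rej <- replicate(120, {
    tab <- expand.grid(subject = sprintf("s%02d", 1:10),
                       condition = c("peer_feedback", "non_feedback"),
                       region = regions, component = "N2",
                       stringsAsFactors = FALSE)
    tab$amplitude <- rnorm(nrow(tab))
    res <- rmAnova(tab, "N2")
    res$p_gg[res$effect == "S"] < 0.05
  })
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.12)
})

test_that("centrality correlations apply BH within the stated family", {
  set.seed(91)
  n <- 20
  subs <- sprintf("s%02d", 1:n)
  cen <- data.frame(subject = subs, betweenness = rnorm(n),
                    in_degree = rnorm(n))
  regions <- names(regionList(defaultLayout()))
  diffs <- expand.grid(subject = subs, region = regions, component = "LPP",
                       stringsAsFactors = FALSE)
  diffs$peer_feedback <- 0
  diffs$non_feedback <- 0
  # tie the medial frontal diff to betweenness, rest pure noise
  z <- cen$betweenness[match(diffs$subject, cen$subject)]
  diffs$diff <- rnorm(nrow(diffs), sd = 0.2) +
    ifelse(diffs$region == "medial frontal", 0.8 * z, 0)
  cc <- centralityCorrelations(diffs, cen)
  expect_equal(nrow(cc), 9 * 2)
  hit <- cc[cc$region == "medial frontal" & cc$metric == "betweenness", ]
  expect_gt(hit$r, 0.5)
  expect_lt(hit$p_fdr, 0.05)
  # adjusted p never smaller than raw p, and equals p.adjust within family
  expect_true(all(cc$p_fdr >= cc$p - 1e-12))
  expect_equal(cc$p_fdr, p.adjust(cc$p, method = "BH"), tolerance = 1e-12)
  # zero-variance metric flagged undefined, excluded from the family
  cen$flat <- 1
  cc2 <- centralityCorrelations(diffs, cen, metrics = c("betweenness", "flat"))
  expect_true(all(is.na(cc2$p_fdr[cc2$metric == "flat"])))
  expect_true(all(!is.na(cc2$p_fdr[cc2$metric == "betweenness"])))
})
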