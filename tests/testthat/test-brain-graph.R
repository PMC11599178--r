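test_that("binarization retains exactly the requested edge budget", {
  set.seed(11)
  w <- matrix(runif(25), 5); w <- (w + t(w)) / 2; diag(w) <- 0
  adj <- binarizeNetwork(w, 0.2)
  expect_equal(sum(adj) / 2, 2)          # round(0.2 * 10)
  expect_true(all(adj == t(adj)))
  expect_false(any(diag(adj)))
  adj9 <- binarizeNetwork(w, 0.95)
  expect_equal(sum(adj9) / 2, round(0.95 * 10))
  expect_error(binarizeNetwork(w, 0.01), "retains no edges")
  expect_error(binarizeNetwork(matrix(runif(25), 5), 0.2), "symmetric")
  # equal weights: deterministic lexicographic tie-break
  w1 <- matrix(1, 5, 5); diag(w1) <- 0
  expect_identical(binarizeNetwork(w1, 0.3), binarizeNetwork(w1, 0.3))
  # the edge-count identity holds across the whole sweep on 60 nodes
  w60 <- matrix(runif(3600), 60); w60 <- (w60 + t(w60)) / 2; diag(w60) <- 0
  for (s in seq(0.05, 0.5, by = 0.05))
    expect_equal(sum(binarizeNetwork(w60, s)) / 2, round(s * 60 * 59 / 2))
})

test_that("topology metrics match closed forms on canonical graphs", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(globalEfficiency(k5 > 0), 1)
  expect_equal(clusteringCoefficient(k5 > 0), 1)
  expect_equal(localEfficiency(k5 > 0), 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(clusteringCoefficient(star > 0), 0)
  expect_equal(assortativityCoefficient(star > 0), -1)
  expect_equal(localEfficiency(star > 0), 0)
  ring <- matrix(0, 6, 6)
  ring[cbind(1:6, c(2:6, 1))] <- 1; ring <- ring + t(ring)
  expect_warning(ac <- assortativityCoefficient(ring > 0), "undefined")
  expect_true(is.na(ac))                 # regular graph: no degree variance
  path4 <- matrix(0, 4, 4); path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  expect_equal(globalEfficiency(path4 > 0), 13 / 18)   # 0.7222...
  iso2 <- diag(2) * 0
  expect_equal(globalEfficiency(iso2 > 0), 0)
})

test_that("all four metrics equal brute-force oracles on random graphs", {
  set.seed(12)
  for (i in 1:40) {
    adj <- randomAdjOracle(sample(4:8, 1))
    expect_equal(globalEfficiency(adj), bruteGEOracle(adj), tolerance = 1e-12)
    expect_equal(clusteringCoefficient(adj), bruteCCOracle(adj),
                 tolerance = 1e-12)
    expect_equal(localEfficiency(adj), bruteLEOracle(adj), tolerance = 1e-12)
    aco <- bruteACOracle(adj)
    if (!is.na(aco)) {
      expect_equal(suppressWarnings(assortativityCoefficient(adj)), aco,
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(13)
  adj <- randomAdjOracle(8)
  p <- sample(8)
  padj <- adj[p, p]
  expect_equal(globalEfficiency(adj), globalEfficiency(padj))
  expect_equal(clusteringCoefficient(adj), clusteringCoefficient(padj))
  expect_equal(localEfficiency(adj), localEfficiency(padj))
  expect_equal(suppressWarnings(assortativityCoefficient(adj)),
               suppressWarnings(assortativityCoefficient(padj)))
})

test_that("topology curves sweep sparsity and integrate to an AUC", {
  set.seed(14)
  w <- matrix(runif(400), 20); w <- (w + t(w)) / 2; diag(w) <- 0
  tc <- topologyCurve(w, "GE")
  expect_length(tc$values, 10)
  expect_equal(tc$sparsities, seq(0.05, 0.5, by = 0.05))
  # GE never decreases when edges are added
  expect_true(all(diff(tc$values) >= -1e-12))
  le <- topologyCurve(w, "LE")
  expect_true(all(diff(le$values) >= -1e-12))
  # constant curve integrates to value x range; trapezoid vs step variants
  expect_equal(aucUnderCurve(seq(0.05, 0.5, by = 0.05), rep(0.7, 10)),
               0.7 * 0.45)
  expect_equal(aucUnderCurve(seq(0.05, 0.5, by = 0.05), rep(0.7, 10),
                             method = "step"), 0.7 * 0.45)
  expect_equal(aucUnderCurve(0.3, 0.5), 0)   # single level: no area
  tc1 <- topologyCurve(w, "GE", sparsities = 0.3)
  expect_equal(tc1$auc, 0)
  expect_length(tc1$values, 1)
  # literal inverse-average variant stays within [0, 1] and below standard
  g1 <- topologyCurve(w, "GE", variant = "inverse_average")
  expect_true(all(g1$values <= tc$values + 1e-12))
})

test_that("condition contrasts of AUCs use the paired-test conventions", {
  set.seed(15)
  subj <- sprintf("s%02d", 1:10)
  aucs <- expand.grid(subject = subj,
                      condition = c("peer_feedback", "non_feedback"),
                      band = "beta", metric = c("LE", "GE"),
                      stringsAsFactors = FALSE)
  aucs$auc <- 0.3 + rnorm(nrow(aucs), sd = 0.01)
  fb <- aucs$condition == "peer_feedback" & aucs$metric == "LE"
  aucs$auc[fb] <- aucs$auc[fb] - 0.05    # feedback lowers LE
  cc <- conditionContrast(aucs)
  le <- cc[cc$metric == "LE", ]
  expect_lt(le$t, 0)
  expect_lt(le$p, 0.01)
  expect_equal(le$d, 2 * le$t / sqrt(9))
  # identical conditions give t = 0
  aucs$auc[aucs$condition == "non_feedback"] <-
    aucs$auc[aucs$condition == "peer_feedback"]
  cc0 <- conditionContrast(aucs)
  expect_true(all(cc0$t == 0))
  expect_error(conditionContrast(aucs[-1, ]), "unpaired")
})
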