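#' Simulate one behavioral session of the peer-feedback rating task
#'
#' Generates a session of rating trials split evenly between the
#' peer-feedback and non-feedback contexts (30 + 30 by default). On
#' feedback trials the displayed group rating is the initial rating shifted
#' by an offset drawn from a balanced allocation over \{-3,-2,-1,+1,+2,+3\}
#' (exactly balanced as far as divisibility allows), passed through the
#' boundary-reflection rule of [makeGroupRating()]. With probability
#' \code{conformity} the final rating then steps 1-3 points toward the
#' displayed rating (never past it); otherwise, and on non-feedback trials,
#' the rating changes spontaneously with probability
#' \code{spontaneousRate}, in a random direction. Reaction times are drawn
#' with a positive feedback-vs-none mean shift.
#'
#' Default rates follow the reported behavior: a non-feedback change rate
#' near 24% and RT means near 1372 ms (feedback) and 1204 ms (non-feedback).
#'
#' @param nTrials total number of trials (even; half per condition).
#' @param conformity probability that a feedback trial is resolved by
#'   conforming toward the displayed rating.
#' @param spontaneousRate probability of a spontaneous rating change on
#'   trials not resolved by conforming.
#' @param seed integer seed.
#' @param subject subject identifier.
#' @param rtMeans,rtSds length-2 vectors (feedback, non-feedback) of RT
#'   means and SDs in ms.
#' @return data.frame of trial records (columns subject, stimulus,
#'   condition, initial, offset, shown, final, rt_ms).
#' @examples
#' tr <- simulateSession(60, conformity = 0.7, seed = 1)
#' table(tr$condition)
#' @export
simulateSession <- function(nTrials = 60, conformity = 0.7,
                            spontaneousRate = 0.24, seed = NULL,
                            subject = "s01",
                            rtMeans = c(1372, 1204),
                            rtSds = c(363, 250)) {
  if (nTrials %% 2 != 0) stop("nTrials must be even (half per condition)")
  if (conformity < 0 || conformity > 1 || spontaneousRate < 0 ||
      spontaneousRate > 1)
    stop("conformity and spontaneousRate must be probabilities")
  withSeed(seed, {
    half <- nTrials / 2
    condition <- sample(rep(.CONDITIONS, each = half))
    initial <- sample(0:9, nTrials, replace = TRUE)
    offsets_all <- c(-3, -2, -1, 1, 2, 3)
    alloc <- rep(offsets_all, length.out = half)[sample.int(half)]
    offset <- rep(NA_real_, nTrials)
    offset[condition == "peer_feedback"] <- alloc
    shown <- rep(NA_integer_, nTrials)
    fb <- condition == "peer_feedback"
    shown[fb] <- makeGroupRating(initial[fb], offset[fb])
    final <- initial
    for (i in seq_len(nTrials)) {
      if (fb[i] && stats::runif(1) < conformity) {
        gap <- shown[i] - initial[i]
        step <- min(sample(1:3, 1), abs(gap))
        final[i] <- initial[i] + sign(gap) * step
      } else if (stats::runif(1) < spontaneousRate) {
        step <- sample(1:2, 1) * sample(c(-1, 1), 1)
        cand <- initial[i] + step
        if (cand < 0 || cand > 9) cand <- initial[i] - step
        final[i] <- max(0, min(9, cand))
      }
    }
    ci <- ifelse(fb, 1, 2)
    rt <- round(pmax(200, stats::rnorm(nTrials, rtMeans[ci], rtSds[ci])))
    data.frame(subject = subject,
               stimulus = sprintf("img%02d", sample.int(nTrials)),
               condition = condition, initial = initial, offset = offset,
               shown = shown, final = final, rt_ms = rt,
               stringsAsFactors = FALSE)
  })
}
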