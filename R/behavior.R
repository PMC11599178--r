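#' Adaptive group-rating with boundary reflection
#'
#' The displayed "group rating" is the participant's initial rating shifted
#' by 1, 2 or 3 points up or down. When the shifted value leaves the 0-9
#' rating scale the direction of the shift is reversed: an initial rating of
#' 2 with an intended offset of -3 displays 5 (= 2 + 3), and an initial
#' rating of 9 with +1 displays 8. The result is always within 0-9.
#'
#' @param initial integer rating(s) on the 0-9 scale.
#' @param offset signed intended difference; absolute value must be 1, 2
#'   or 3. Recycled against \code{initial}.
#' @return integer displayed group rating(s) in 0-9.
#' @examples
#' makeGroupRating(2,  3)  # 5
#' makeGroupRating(2, -3)  # reflected: 5
#' @export
makeGroupRating <- function(initial, offset) {
  if (any(is.na(initial)) || any(initial < 0 | initial > 9 |
                                 initial != round(initial)))
    stop("initial rating must be an integer in 0-9")
  if (any(is.na(offset)) || any(!abs(offset) %in% 1:3))
    stop("offset must have absolute value 1, 2 or 3")
  out <- initial + offset
  flip <- out < 0 | out > 9
  out[flip] <- (initial - offset)[flip]
  as.integer(out)
}

#' Influence score: proportion of trials with a changed rating
#'
#' The proportion of trials, within one condition, on which the final rating
#' differs from the initial rating.
#'
#' @param trials data.frame of trial records (see [readTrials()]).
#' @param condition condition label, \code{"peer_feedback"} or
#'   \code{"non_feedback"}.
#' @param bySubject if TRUE (default) return a named vector per subject,
#'   else a single pooled proportion.
#' @return proportion(s) in [0, 1].
#' @export
influenceScore <- function(trials, condition = "peer_feedback",
                           bySubject = TRUE) {
  sel <- trials[trials$condition == condition, , drop = FALSE]
  if (!nrow(sel))
    stop("no trials in condition '", condition, "'")
  changed <- sel$final != sel$initial
  if (!bySubject) return(mean(changed))
  vapply(split(changed, sel$subject), mean, numeric(1))
}

#' Conforming rate among peer-feedback trials
#'
#' A changed trial conforms when the final rating moved toward the displayed
#' group rating, i.e. sign(final - initial) equals sign(shown - initial).
#' The default denominator is the set of changed feedback trials ("tendency
#' to conform among adjustments"); \code{denominator = "all_feedback"}
#' divides by every feedback trial instead.
#'
#' @param trials data.frame of trial records.
#' @param denominator \code{"changed"} (default) or \code{"all_feedback"}.
#' @param bySubject if TRUE (default) return a named vector per subject.
#' @return proportion(s) in [0, 1]; NA (with a warning) for subjects whose
#'   denominator is empty.
#' @export
conformingRate <- function(trials, denominator = c("changed", "all_feedback"),
                           bySubject = TRUE) {
  denominator <- match.arg(denominator)
  fb <- trials[trials$condition == "peer_feedback", , drop = FALSE]
  if (!nrow(fb)) stop("no peer-feedback trials present")
  changed <- fb$final != fb$initial
  conform <- changed & sign(fb$final - fb$initial) == sign(fb$shown - fb$initial)
  rate1 <- function(conf, chg) {
    den <- if (denominator == "changed") sum(chg) else length(chg)
    if (den == 0) NA_real_ else sum(conf) / den
  }
  if (!bySubject) {
    r <- rate1(conform, changed)
    if (is.na(r)) warning("conforming rate undefined: no changed feedback trials")
    return(r)
  }
  out <- vapply(split(seq_len(nrow(fb)), fb$subject), function(i)
    rate1(conform[i], changed[i]), numeric(1))
  if (anyNA(out))
    warning("conforming rate undefined (no changed feedback trials) for: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Convert a paired t statistic to the reported effect-size convention
#'
#' The effect sizes printed alongside the paired tests follow the conversion
#' d = 2t / sqrt(df) (e.g. t = 3.66 on 26 df gives d = 1.44). This is the
#' between-groups conversion formula applied to a paired design; it differs
#' from the conventional paired d_z = mean(diff)/sd(diff) = t/sqrt(n). Both
#' are reported by [pairedContrast()] so the convention is explicit.
#'
#' @param t t statistic.
#' @param df degrees of freedom (n - 1 for a paired test).
#' @return effect size d = 2t/sqrt(df).
#' @export
cohensDFromT <- function(t, df) 2 * t / sqrt(df)

#' Paired contrast with both effect-size conventions
#'
#' Paired t test (df = n - 1, two-sided) for per-subject value pairs,
#' reporting the 2t/sqrt(df) effect-size convention used in the reported
#' behavioral and network contrasts as \code{d}, and the conventional paired
#' d_z as \code{dz}.
#'
#' @param x,y equal-length numeric vectors of per-subject paired values
#'   (x - y is tested).
#' @return data.frame with columns mean_x, sd_x, mean_y, sd_y, t, df, p, d,
#'   dz.
#' @examples
#' set.seed(1)
#' pairedContrast(rnorm(10, 1), rnorm(10))
#' @export
pairedContrast <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("paired contrast requires n >= 3")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tt <- 0
    p <- 1
  } else {
    ht <- stats::t.test(x, y, paired = TRUE)
    tt <- unname(ht$statistic)
    p <- ht$p.value
  }
  data.frame(mean_x = mean(x), sd_x = stats::sd(x),
             mean_y = mean(y), sd_y = stats::sd(y),
             t = tt, df = n - 1, p = p,
             d = cohensDFromT(tt, n - 1),
             dz = if (sdd == 0) 0 else mean(d) / sdd)
}

#' Per-subject behavioral summary
#'
#' Mean reaction times per condition, influence scores per condition, and the
#' conforming rate, one row per subject, plus the group-level paired
#' contrasts (feedback vs non-feedback) for RT and influence score.
#'
#' @param trials data.frame of trial records.
#' @return list with elements \code{subjects} (per-subject data.frame) and
#'   \code{contrasts} (data.frame with rows rt and influence; NULL when
#'   fewer than 3 subjects are present).
#' @export
behaviorSummary <- function(trials) {
  validateTrials(trials)
  subj <- sort(unique(trials$subject))
  per <- do.call(rbind, lapply(subj, function(s) {
    tr <- trials[trials$subject == s, ]
    fb <- tr$condition == "peer_feedback"
    data.frame(subject = s,
               rt_feedback = mean(tr$rt_ms[fb]),
               rt_nonfeedback = mean(tr$rt_ms[!fb]),
               influence_feedback = mean(tr$final[fb] != tr$initial[fb]),
               influence_nonfeedback = mean(tr$final[!fb] != tr$initial[!fb]),
               conforming_rate = conformingRate(tr, bySubject = FALSE))
  }))
  contrasts <- NULL
  if (length(subj) >= 3) {
    contrasts <- rbind(
      cbind(measure = "rt",
            pairedContrast(per$rt_feedback, per$rt_nonfeedback)),
      cbind(measure = "influence",
            pairedContrast(per$influence_feedback,
                           per$influence_nonfeedback)))
  }
  list(subjects = per, contrasts = contrasts)
}
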