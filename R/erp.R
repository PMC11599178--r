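#' @include AllClasses.R
NULL

#' Default ERP component windows
#'
#' N2 180-280 ms, P3 300-500 ms, LPP 600-800 ms. The first window goes by
#' several names in the feedback literature (FRN/N2/N2pc); the neutral
#' label N2 is used here and the window is the operational definition.
#'
#' @return data.frame with columns label, from, to (ms).
#' @export
erpComponents <- function() {
  data.frame(label = c("N2", "P3", "LPP"),
             from = c(180, 300, 600),
             to = c(280, 500, 800),
             stringsAsFactors = FALSE)
}

#' Window x region mean amplitudes per condition
#'
#' For each condition the trials are averaged into an ERP, then the ERP is
#' averaged over the samples of each component window (closed interval,
#' boundary samples included) and over the channels of each scalp region.
#'
#' @param epochs a preprocessed, baseline-corrected [EpochSet-class] (one
#'   subject).
#' @param layout a [ChannelLayout-class] supplying the nine regions.
#' @param components component definition (default [erpComponents()]).
#' @return data.frame with columns subject, condition, region, component,
#'   amplitude (microvolts), one row per cell.
#' @export
windowRegionMeans <- function(epochs, layout, components = erpComponents()) {
  tms <- epochTimes(epochs)
  conds <- intersect(.CONDITIONS, unique(epochs@condition))
  out <- list()
  for (cnd in conds) {
    tri <- which(epochs@condition == cnd)
    erp <- colMeans(epochs@amplitudes[tri, , , drop = FALSE])
    rownames(erp) <- epochs@channels
    for (rg in names(layout@regions)) {
      chs <- intersect(layout@regions[[rg]], epochs@channels)
      if (!length(chs))
        stop("region '", rg, "' has no retained channels")
      for (i in seq_len(nrow(components))) {
        sel <- which(tms >= components$from[i] & tms <= components$to[i])
        out[[length(out) + 1L]] <- data.frame(
          subject = epochs@subject, condition = cnd, region = rg,
          component = components$label[i],
          amplitude = mean(erp[chs, sel, drop = FALSE]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-subject condition differences of window amplitudes
#'
#' Reshapes a window-amplitude table into one row per subject x region x
#' component with columns for both conditions and their difference
#' (peer-feedback minus non-feedback).
#'
#' @param table data.frame from [windowRegionMeans()] (rows from several
#'   subjects may be concatenated).
#' @return data.frame with columns subject, region, component,
#'   peer_feedback, non_feedback, diff.
#' @export
amplitudeDifferences <- function(table) {
  wide <- stats::reshape(table, idvar = c("subject", "region", "component"),
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^amplitude\\.", "", names(wide))
  if (!all(.CONDITIONS %in% names(wide)))
    stop("both conditions required to form differences")
  wide$diff <- wide$peer_feedback - wide$non_feedback
  rownames(wide) <- NULL
  wide
}

#' Three-way repeated-measures ANOVA on one ERP component
#'
#' Social feedback (2: peer-feedback, non-feedback) x hemisphere (3: left,
#' medial, right) x lobe (3: frontal, central, parietal), all within
#' subject. Sphericity deviations are handled with the Greenhouse-Geisser
#' epsilon estimated from the within-factor covariance (via the
#' multivariate-model machinery of \code{car::Anova}); epsilon is 1 by
#' construction for the 1-df feedback main effect. Reported per effect:
#' F, uncorrected dfs, epsilon, GG-corrected p and partial eta squared.
#'
#' @param table data.frame from [windowRegionMeans()] covering >= 5
#'   subjects with all 18 cells each.
#' @param component component label to analyze.
#' @return data.frame with rows S, S:R, S:H, S:R:H (S = social feedback,
#'   R = region, i.e. frontal/central/parietal, H = hemisphere) and columns
#'   effect, df1, df2, F, eps, p, p_gg, peta2.
#' @export
rmAnova <- function(table, component) {
  tab <- table[table$component == component, ]
  if (!nrow(tab)) stop("component '", component, "' not in table")
  rf <- regionFactors(tab$region)
  tab$hemisphere <- rf$hemisphere
  tab$lobe <- rf$lobe
  subj <- sort(unique(tab$subject))
  if (length(subj) < 5) stop("repeated-measures ANOVA requires n >= 5")
  cells <- expand.grid(condition = .CONDITIONS,
                       hemisphere = c("left", "medial", "right"),
                       lobe = c("frontal", "central", "parietal"),
                       stringsAsFactors = FALSE)
  y <- matrix(NA_real_, length(subj), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    sel <- tab$condition == cells$condition[j] &
      tab$hemisphere == cells$hemisphere[j] & tab$lobe == cells$lobe[j]
    v <- tab[sel, c("subject", "amplitude")]
    y[, j] <- v$amplitude[match(subj, v$subject)]
  }
  if (anyNA(y)) stop("incomplete 2x3x3 within-subject design")
  idata <- data.frame(S = factor(cells$condition, levels = .CONDITIONS),
                      H = factor(cells$hemisphere),
                      R = factor(cells$lobe))
  fit <- stats::lm(y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ S * R * H, type = "III")
  sm <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      # car warns when the Huynh-Feldt estimate exceeds 1; only GG is used
      if (grepl("HF eps", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  uni <- sm$univariate.tests
  gg <- sm$pval.adjustments
  pick <- c("S", "S:R", "S:H", "S:R:H")
  res <- lapply(pick, function(ef) {
    row <- uni[ef, ]
    eps <- 1
    pgg <- row[["Pr(>F)"]]
    if (!is.null(gg) && ef %in% rownames(gg)) {
      eps <- gg[ef, "GG eps"]
      pgg <- gg[ef, "Pr(>F[GG])"]
    }
    ss <- row[["Sum Sq"]]
    sse <- row[["Error SS"]]
    data.frame(effect = ef, df1 = row[["num Df"]], df2 = row[["den Df"]],
               F = row[["F value"]], eps = eps, p = row[["Pr(>F)"]],
               p_gg = pgg, peta2 = ss / (ss + sse),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simple effect of social feedback within each lobe
#'
#' Follow-up to a feedback x lobe interaction: for each lobe, hemisphere
#' cells are pooled per condition per subject and the feedback effect is
#' tested as a one-way repeated-measures contrast.
#'
#' @param table data.frame from [windowRegionMeans()].
#' @param component component label.
#' @return data.frame, one row per lobe, with the paired-contrast columns
#'   of [pairedContrast()].
#' @export
simpleEffects <- function(table, component) {
  tab <- table[table$component == component, ]
  rf <- regionFactors(tab$region)
  tab$lobe <- rf$lobe
  out <- list()
  for (lb in unique(tab$lobe)) {
    sub <- tab[tab$lobe == lb, ]
    agg <- stats::aggregate(amplitude ~ subject + condition, sub, mean)
    wide <- stats::reshape(agg, idvar = "subject", timevar = "condition",
                           direction = "wide")
    out[[lb]] <- cbind(lobe = lb,
                       pairedContrast(wide$amplitude.peer_feedback,
                                      wide$amplitude.non_feedback))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlations between condition-difference amplitudes and centralities
#'
#' Pearson correlation of each social-network metric with the per-subject
#' condition-difference amplitude in every region, per component, with
#' Benjamini-Hochberg FDR adjustment. The default correction family is all
#' region x metric tests of one component (9 x 4 = 36 with the standard
#' metrics); \code{family = "per_metric"} adjusts within each metric's nine
#' regions instead. Zero-variance inputs yield NA and are excluded from
#' the family size.
#'
#' @param diffs data.frame from [amplitudeDifferences()].
#' @param centralities data.frame with a \code{node} or \code{subject}
#'   column naming subjects plus one column per metric.
#' @param metrics metric columns to use (default: every numeric column).
#' @param family \code{"per_component"} (default) or \code{"per_metric"}.
#' @return data.frame with columns component, region, metric, n, r, p,
#'   p_fdr.
#' @export
centralityCorrelations <- function(diffs, centralities, metrics = NULL,
                                   family = c("per_component",
                                              "per_metric")) {
  family <- match.arg(family)
  idcol <- intersect(c("subject", "node"), names(centralities))[1]
  if (is.na(idcol)) stop("centralities must have a subject or node column")
  if (is.null(metrics))
    metrics <- names(centralities)[vapply(centralities, is.numeric,
                                          TRUE)]
  subj <- intersect(unique(diffs$subject), centralities[[idcol]])
  if (length(subj) < 4) stop("at least 4 subjects with both measures required")
  cen <- centralities[match(subj, centralities[[idcol]]), , drop = FALSE]
  rows <- list()
  for (comp in unique(diffs$component)) {
    dsub <- diffs[diffs$component == comp, ]
    for (rg in unique(dsub$region)) {
      v <- dsub[dsub$region == rg, ]
      amp <- v$diff[match(subj, v$subject)]
      for (m in metrics) {
        x <- cen[[m]]
        if (stats::sd(x) == 0 || stats::sd(amp) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(x, amp)
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          component = comp, region = rg, metric = m, n = length(subj),
          r = r, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  grp <- if (family == "per_component") out$component else
    paste(out$component, out$metric)
  for (g in unique(grp)) {
    i <- which(grp == g & !is.na(out$p))
    out$p_fdr[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out
}
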