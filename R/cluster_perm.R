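#' @include AllClasses.R
NULL

#' Pointwise paired t map over channels and samples
#'
#' Paired t statistic at every (channel, sample) for two conditions of
#' per-subject trial-averaged ERPs. Zero-variance points with a nonzero
#' mean difference yield +/-Inf (treated as a very large finite mass when
#' clusters are summed); zero-variance, zero-mean points yield t = 0.
#'
#' @param condA,condB numeric arrays, subject x channel x sample, same
#'   subjects in the same order.
#' @return numeric matrix (channel x sample) of t values, with an
#'   attribute \code{"df"} = n - 1.
#' @export
pointwiseT <- function(condA, condB) {
  if (!identical(dim(condA), dim(condB)))
    stop("condition arrays must have identical subject/channel/sample dims")
  n <- dim(condA)[1]
  if (n < 3) stop("paired t map requires n >= 3 subjects")
  d <- condA - condB
  dm <- matrix(d, n)                       # subjects x (channel*sample)
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tt <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf),
               m / sqrt(v / n))
  out <- matrix(tt, dim(condA)[2], dim(condA)[3])
  rownames(out) <- dimnames(condA)[[2]]
  attr(out, "df") <- n - 1
  out
}

# Internal: cluster a channel x sample t map. Supra-threshold points
# (|t| > crit) are partitioned into maximal connected components under
# (neighboring channel at the same sample) OR (adjacent sample on the same
# channel) adjacency, polarity-pure. Runs of consecutive supra samples per
# channel are the union-find atoms. Returns per-cluster summed t (infinite
# t capped at +/-1e12) and, unless massOnly, the member points.
.clusterT <- function(t, crit, nbList, massOnly = FALSE) {
  nch <- nrow(t); ns <- ncol(t)
  sg <- matrix(0L, nch, ns)
  sg[t > crit] <- 1L
  sg[t < -crit] <- -1L
  runs <- list()   # each: c(ch, start, end, sign) ; mass kept separately
  rmass <- numeric(0)
  runIndex <- vector("list", nch)
  tc <- t
  tc[is.infinite(tc)] <- sign(tc[is.infinite(tc)]) * 1e12
  for (ch in seq_len(nch)) {
    r <- rle(sg[ch, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ids <- integer(0)
    for (k in which(r$values != 0L)) {
      runs[[length(runs) + 1L]] <- c(ch, starts[k], ends[k], r$values[k])
      rmass <- c(rmass, sum(tc[ch, starts[k]:ends[k]]))
      ids <- c(ids, length(runs))
    }
    runIndex[[ch]] <- ids
  }
  nr <- length(runs)
  if (nr == 0)
    return(list(mass = numeric(0), members = list()))
  parent <- seq_len(nr)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (ch in seq_len(nch)) {
    for (nb in nbList[[ch]]) {
      if (nb <= ch) next                  # each channel pair once
      for (i in runIndex[[ch]]) {
        a <- runs[[i]]
        for (j in runIndex[[nb]]) {
          b <- runs[[j]]
          if (a[4] == b[4] && a[2] <= b[3] && b[2] <= a[3]) unite(i, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(nr), findRoot, integer(1))
  mass <- vapply(split(rmass, roots), sum, numeric(1))
  if (massOnly) return(list(mass = unname(mass), members = list()))
  members <- lapply(split(seq_len(nr), roots), function(ids) {
    do.call(rbind, lapply(ids, function(i) {
      a <- runs[[i]]
      cbind(channel = a[1], sample = a[2]:a[3])
    }))
  })
  ord <- order(-abs(mass))
  list(mass = unname(mass)[ord], members = unname(members)[ord])
}

# Neighbor index list for the channels of a t map, from a layout.
.nbIndexList <- function(channels, layout) {
  nb <- layout@neighbors[channels, channels, drop = FALSE]
  lapply(seq_along(channels), function(i) which(nb[i, ]))
}

#' Form spatiotemporal clusters from a t map
#'
#' Points with |t| above the two-sided critical value at level \code{alpha}
#' are grouped into maximal connected components under spatial (neighboring
#' channels) and temporal (adjacent samples) adjacency; clusters are
#' polarity-pure and their mass is the summed t. No minimum cluster size is
#' imposed.
#'
#' @param tmap channel x sample t matrix with channel rownames (as from
#'   [pointwiseT()]).
#' @param layout a [ChannelLayout-class] supplying channel neighbors.
#' @param alpha two-sided cluster-forming significance level.
#' @param df degrees of freedom of the t map (defaults to its \code{"df"}
#'   attribute).
#' @return list with \code{mass} (per-cluster summed t, decreasing |mass|),
#'   \code{members} (per-cluster matrix of channel/sample indices) and
#'   \code{crit} (the threshold used). Empty when nothing is
#'   supra-threshold.
#' @export
formClusters <- function(tmap, layout, alpha = 0.05,
                         df = attr(tmap, "df")) {
  if (is.null(df)) stop("df must be supplied (or carried by the t map)")
  crit <- stats::qt(1 - alpha / 2, df)
  ch <- rownames(tmap)
  if (is.null(ch)) stop("t map must carry channel rownames")
  res <- .clusterT(tmap, crit, .nbIndexList(ch, layout))
  res$crit <- crit
  res
}

#' Cluster-based permutation test for a paired ERP contrast
#'
#' Nonparametric family-wise test: the observed t map is clustered
#' ([formClusters()]), and a null distribution of the maximum absolute
#' cluster mass is built by randomly flipping the sign of each subject's
#' condition difference (the exchangeability move for a paired design).
#' Each observed cluster's Monte Carlo p-value is
#' (1 + #\{null >= |mass|\}) / (1 + nPerm); with \code{exact = TRUE} all
#' 2^n sign patterns are enumerated instead and p = #\{null >= |mass|\} /
#' 2^n (the identity pattern included).
#'
#' @param condA,condB subject x channel x sample arrays of per-subject
#'   trial-averaged ERPs (channel dimnames required).
#' @param layout a [ChannelLayout-class].
#' @param nPerm number of random sign-flip partitions (default 5000).
#' @param alpha two-sided cluster-forming level for the t threshold.
#' @param seed integer seed for the random partitions.
#' @param exact enumerate all 2^n sign patterns (n <= 12 only).
#' @return object of class \code{ClusterResult}: list with \code{tmap},
#'   \code{crit}, \code{mass}, \code{members}, \code{p} (per cluster),
#'   \code{null} (per-partition max |mass|), \code{nPerm}.
#' @export
clusterPermutation <- function(condA, condB, layout, nPerm = 5000,
                               alpha = 0.05, seed = NULL, exact = FALSE) {
  n <- dim(condA)[1]
  if (n < 5) warning("fewer than 5 subjects: at most 2^", n,
                     " distinct sign partitions exist")
  if (!exact && nPerm < 100) warning("nPerm < 100 gives a very coarse p")
  tmap <- pointwiseT(condA, condB)
  obs <- formClusters(tmap, layout, alpha)
  ch <- rownames(tmap)
  nbList <- .nbIndexList(ch, layout)
  crit <- obs$crit
  d <- matrix(condA - condB, n)            # subjects x points
  ss <- colSums(d^2)
  nch <- dim(condA)[2]
  maxMass <- function(signs) {
    m <- as.vector(signs %*% d) / n
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    tt <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(v / n))
    cl <- .clusterT(matrix(tt, nch), crit, nbList, massOnly = TRUE)
    if (length(cl$mass)) max(abs(cl$mass)) else 0
  }
  if (exact) {
    if (n > 12) stop("exact enumeration limited to n <= 12 subjects")
    patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- apply(patterns, 1, maxMass)
    p <- vapply(obs$mass, function(ms) mean(null >= abs(ms)), numeric(1))
    nPerm <- nrow(patterns)
  } else {
    null <- withSeed(seed, {
      vapply(seq_len(nPerm), function(i)
        maxMass(matrix(sample(c(-1, 1), n, replace = TRUE), 1)),
        numeric(1))
    })
    p <- vapply(obs$mass, function(ms)
      (1 + sum(null >= abs(ms))) / (1 + nPerm), numeric(1))
  }
  structure(list(tmap = tmap, crit = crit, mass = obs$mass,
                 members = obs$members, p = p, null = null, nPerm = nPerm),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cluster(s), %d permutations, |t| > %.3f\n",
              length(x$mass), x$nPerm, x$crit))
  if (length(x$mass)) {
    for (i in seq_along(x$mass))
      cat(sprintf("  cluster %d: mass %.2f, %d points, p = %.4g\n", i,
                  x$mass[i], nrow(x$members[[i]]), x$p[i]))
  }
  invisible(x)
}
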