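#' Binarize a weighted connectivity matrix at a target sparsity
#'
#' Keeps the K strongest edges, K = round(sparsity * N(N-1)/2), of the
#' upper triangle of a symmetric weight matrix. Ties are broken by a fixed
#' lexicographic (row, column) pair order so binarization is deterministic.
#'
#' @param w symmetric numeric weight matrix (diagonal ignored).
#' @param sparsity retained-edge fraction in (0, 1).
#' @return symmetric logical adjacency matrix with zero diagonal and an
#'   attribute \code{"sparsity"}.
#' @examples
#' w <- matrix(runif(25), 5); w <- (w + t(w)) / 2
#' sum(binarizeNetwork(w, 0.2)) / 2  # 2 edges
#' @export
binarizeNetwork <- function(w, sparsity) {
  if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
  if (max(abs(w - t(w))) > 1e-8) stop("weight matrix must be symmetric")
  n <- nrow(w)
  npairs <- n * (n - 1) / 2
  k <- round(sparsity * npairs)
  if (k < 1) stop("sparsity ", sparsity, " retains no edges on ", n, " nodes")
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  adj <- matrix(FALSE, n, n, dimnames = dimnames(w))
  adj[ut[keep, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  attr(adj, "sparsity") <- sparsity
  adj
}

# All-pairs shortest-path lengths on an unweighted undirected graph, by
# repeated frontier expansion with boolean matrix products. Inf marks
# disconnected pairs. Fast for the dense <=60-node graphs used here.
.bfsDistances <- function(adj) {
  n <- nrow(adj)
  a <- matrix(as.numeric(adj), n, n)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- diag(n)
  step <- 0
  repeat {
    step <- step + 1
    reach_new <- (reach %*% a > 0) * 1
    newly <- reach_new > 0 & !is.finite(d)
    if (!any(newly)) break
    d[newly] <- step
    reach <- reach_new
    if (step > n) break
  }
  d
}

#' Global efficiency of a binary graph
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing zero (\code{variant =
#' "average_inverse"}, the standard efficiency and the default). The
#' literal reading "inverse of the average shortest path length" is
#' available as \code{variant = "inverse_average"}; it is undefined on
#' disconnected graphs (returns 0 there) and is provided for comparison
#' only.
#'
#' @param adj symmetric logical/0-1 adjacency matrix.
#' @param variant see description.
#' @return efficiency in [0, 1].
#' @export
globalEfficiency <- function(adj,
                             variant = c("average_inverse",
                                         "inverse_average")) {
  variant <- match.arg(variant)
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- .bfsDistances(adj)
  off <- d[row(d) != col(d)]
  if (variant == "average_inverse") return(mean(1 / off))
  if (any(!is.finite(off))) return(0)
  1 / mean(off)
}

#' Average clustering coefficient of a binary graph
#'
#' Mean over nodes of 2 * triangles / (k (k - 1)); nodes with degree below
#' 2 contribute zero.
#'
#' @param adj symmetric logical/0-1 adjacency matrix.
#' @return clustering coefficient in [0, 1].
#' @export
clusteringCoefficient <- function(adj) {
  a <- matrix(as.numeric(adj), nrow(adj))
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)       # 2 * triangles at each node
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(cc)
}

#' Degree assortativity of a binary graph
#'
#' Pearson correlation of the degrees at the two endpoints of every edge,
#' each undirected edge contributing both orientations (the standard
#' Newman degree-assortativity estimator for undirected graphs). Undefined
#' (NA, with a warning) when endpoint degrees have no variance, e.g. on
#' regular graphs.
#'
#' @param adj symmetric logical/0-1 adjacency matrix.
#' @return assortativity in [-1, 1], or NA if undefined.
#' @export
assortativityCoefficient <- function(adj) {
  k <- rowSums(adj)
  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(e) < 2) {
    warning("assortativity undefined: fewer than 2 edges")
    return(NA_real_)
  }
  di <- c(k[e[, 1]], k[e[, 2]])
  dj <- c(k[e[, 2]], k[e[, 1]])
  if (stats::sd(di) == 0 || stats::sd(dj) == 0) {
    warning("assortativity undefined: zero degree variance over edges")
    return(NA_real_)
  }
  stats::cor(di, dj)
}

#' Average local efficiency of a binary graph
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (the node itself removed); nodes with fewer than 2 neighbors
#' contribute zero. The mean over nodes is returned.
#'
#' @param adj symmetric logical/0-1 adjacency matrix.
#' @return local efficiency in [0, 1].
#' @export
localEfficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    globalEfficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

.GRAPH_METRICS <- c(GE = "globalEfficiency", CC = "clusteringCoefficient",
                    AC = "assortativityCoefficient",
                    LE = "localEfficiency")

#' Topology metric across a sparsity sweep, with AUC
#'
#' Binarizes a weight matrix at each sparsity level (0.05 to 0.5 in steps
#' of 0.05 by default), evaluates one topology metric (GE, CC, AC or LE)
#' per level, and summarizes the curve by its area under the curve over the
#' sparsity axis (trapezoidal rule by default; a left-Riemann step variant
#' is available).
#'
#' @param w symmetric numeric weight matrix.
#' @param metric one of "GE", "CC", "AC", "LE".
#' @param sparsities sparsity grid.
#' @param aucMethod \code{"trapezoid"} (default) or \code{"step"}
#'   (left-Riemann, step width times sum of all but the last value).
#' @param ... passed to the metric (e.g. \code{variant} for GE).
#' @return object of class \code{TopologyCurve}: list with \code{metric},
#'   \code{sparsities}, \code{values}, \code{auc}.
#' @export
topologyCurve <- function(w, metric = c("GE", "CC", "AC", "LE"),
                          sparsities = seq(0.05, 0.5, by = 0.05),
                          aucMethod = c("trapezoid", "step"), ...) {
  metric <- match.arg(metric)
  aucMethod <- match.arg(aucMethod)
  fn <- get(.GRAPH_METRICS[[metric]], mode = "function")
  values <- vapply(sparsities, function(s) fn(binarizeNetwork(w, s), ...),
                   numeric(1))
  structure(list(metric = metric, sparsities = sparsities, values = values,
                 auc = aucUnderCurve(sparsities, values, aucMethod)),
            class = "TopologyCurve")
}

#' Area under a sparsity-metric curve
#'
#' @param x sparsity grid (increasing).
#' @param y metric values at each level.
#' @param method \code{"trapezoid"} or \code{"step"}.
#' @return the AUC; 0 when fewer than 2 grid points are given.
#' @export
aucUnderCurve <- function(x, y, method = c("trapezoid", "step")) {
  method <- match.arg(method)
  if (length(x) < 2) return(0)
  if (method == "trapezoid")
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  else
    sum(diff(x) * utils::head(y, -1))
}

#' @export
print.TopologyCurve <- function(x, ...) {
  cat(sprintf("TopologyCurve [%s]: %d sparsity levels (%.2f..%.2f), AUC = %.4f\n",
              x$metric, length(x$sparsities), min(x$sparsities),
              max(x$sparsities), x$auc))
  invisible(x)
}

#' Paired condition contrast of per-subject topology AUCs
#'
#' For each band x metric cell: condition means and SDs, the paired t test
#' and both effect-size conventions (see [pairedContrast()]).
#'
#' @param aucs data.frame with columns subject, condition, band, metric,
#'   auc; every subject must appear in both conditions.
#' @return data.frame, one row per band x metric.
#' @export
conditionContrast <- function(aucs) {
  need <- c("subject", "condition", "band", "metric", "auc")
  if (!all(need %in% names(aucs)))
    stop("aucs must have columns ", paste(need, collapse = ", "))
  out <- list()
  for (b in unique(aucs$band)) for (m in unique(aucs$metric)) {
    cell <- aucs[aucs$band == b & aucs$metric == m, ]
    wide <- stats::reshape(cell[, c("subject", "condition", "auc")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
    x <- wide$auc.peer_feedback
    y <- wide$auc.non_feedback
    if (anyNA(x) || anyNA(y))
      stop("unpaired subjects in band ", b, ", metric ", m)
    out[[paste(b, m)]] <- cbind(band = b, metric = m,
                                pairedContrast(x, y))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
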