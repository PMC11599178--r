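#' @include AllClasses.R
NULL

#' Build a validated directed nomination graph
#'
#' Self-nominations are rejected; duplicate nominations are collapsed to a
#' single edge with a warning.
#'
#' @param edges two-column object (matrix or data.frame) of
#'   (nominator, nominee) pairs, or a data.frame from [readSocialEdges()].
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in \code{edges}. Edges referencing ids outside \code{nodes}
#'   are an error.
#' @param sizes optional named numeric vector of per-node real-life
#'   network-size counts.
#' @return a [SocialGraph-class].
#' @examples
#' g <- buildGraph(rbind(c("A", "B"), c("B", "A")))
#' degreeCentrality(g)
#' @export
buildGraph <- function(edges, nodes = NULL, sizes = NULL) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(e) <- "character"
  dimnames(e) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(as.vector(e)))
  nodes <- as.character(nodes)
  if (nrow(e)) {
    unknown <- setdiff(as.vector(e), nodes)
    if (length(unknown))
      stop("edges reference undeclared node(s): ",
           paste(unknown, collapse = ", "))
    if (any(e[, 1] == e[, 2]))
      stop("self-nomination not allowed: ",
           paste(unique(e[e[, 1] == e[, 2], 1]), collapse = ", "))
    key <- paste(e[, 1], e[, 2], sep = "\r")
    if (anyDuplicated(key)) {
      warning("duplicate nomination(s) collapsed: ",
              sum(duplicated(key)), " edge(s)")
      e <- e[!duplicated(key), , drop = FALSE]
    }
  }
  if (!is.null(sizes)) {
    if (is.null(names(sizes)) || !all(nodes %in% names(sizes)))
      stop("sizes must be a named vector covering every node")
    sizes <- sizes[nodes]
  } else sizes <- numeric(0)
  new("SocialGraph", nodes = nodes, edges = e, realLifeSize = sizes)
}

#' In- and out-degree of every node
#'
#' In-degree counts received nominations; out-degree counts sent
#' nominations.
#'
#' @param graph a [SocialGraph-class].
#' @return data.frame with columns node, in_degree, out_degree.
#' @export
degreeCentrality <- function(graph) {
  nodes <- graph@nodes
  e <- graph@edges
  data.frame(node = nodes,
             in_degree = as.vector(table(factor(e[, 2], levels = nodes))),
             out_degree = as.vector(table(factor(e[, 1], levels = nodes))),
             stringsAsFactors = FALSE)
}

#' Betweenness centrality on the nomination graph
#'
#' For each node v, the sum over ordered pairs (s, t), s != t != v, of
#' sigma_st(v)/sigma_st, where sigma_st counts shortest directed paths from
#' s to t and sigma_st(v) those passing through v. Disconnected pairs
#' contribute nothing. Computed with Brandes' dependency-accumulation
#' algorithm on unweighted graphs. The nomination network is directed; an
#' undirected (symmetrized) variant and conventional normalization are
#' available because reporting conventions vary.
#'
#' @param graph a [SocialGraph-class].
#' @param directed treat edges as directed (default TRUE); FALSE symmetrizes.
#' @param normalized divide by the number of eligible ordered pairs,
#'   (n-1)(n-2) directed or (n-1)(n-2)/2 undirected. Default FALSE (raw
#'   shortest-path membership counts).
#' @return named numeric vector of betweenness values.
#' @export
betweennessCentrality <- function(graph, directed = TRUE,
                                  normalized = FALSE) {
  nodes <- graph@nodes
  n <- length(nodes)
  e <- graph@edges
  idx <- function(x) match(x, nodes)
  adj <- vector("list", n)          # adj[[v]]: out-neighbors of v
  if (nrow(e)) {
    from <- idx(e[, 1]); to <- idx(e[, 2])
    if (!directed) {
      both <- cbind(c(from, to), c(to, from))
      both <- both[!duplicated(paste(both[, 1], both[, 2])), , drop = FALSE]
      from <- both[, 1]; to <- both[, 2]
    }
    sp <- split(to, from)
    adj[as.integer(names(sp))] <- sp
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s recording shortest-path counts and predecessors
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  if (!directed) bc <- bc / 2
  if (normalized && n > 2) {
    denom <- (n - 1) * (n - 2)
    if (!directed) denom <- denom / 2
    bc <- bc / denom
  }
  stats::setNames(bc, nodes)
}

#' Full centrality table for a nomination graph
#'
#' In-degree, out-degree, betweenness and (when available) real-life
#' network size, one row per node.
#'
#' @param graph a [SocialGraph-class].
#' @param directed,normalized passed to [betweennessCentrality()].
#' @return data.frame with columns node, in_degree, out_degree, betweenness
#'   and, if the graph carries sizes, real_life_size.
#' @export
centralityTable <- function(graph, directed = TRUE, normalized = FALSE) {
  tab <- degreeCentrality(graph)
  tab$betweenness <- unname(betweennessCentrality(graph, directed,
                                                  normalized)[tab$node])
  if (length(graph@realLifeSize))
    tab$real_life_size <- unname(graph@realLifeSize[tab$node])
  tab
}
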