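# Independent brute-force oracles used to verify the fast implementations.
# These deliberately use naive enumeration / textbook formulas and share no
# code with the package internals.

# --- shortest-path and betweenness oracles (directed, unweighted) ---------

# adjacency list of out-neighbors from an n x n logical matrix
adjListFromMatrix <- function(m) {
  lapply(seq_len(nrow(m)), function(i) which(m[i, ]))
}

bfsDistOracle <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      q <- c(q, w)
    }
  }
  d
}

# Enumerate every shortest path s -> t by depth-first search pruned with
# exact distances-to-target, and accumulate per-node path memberships.
bruteBetweennessOracle <- function(m) {
  n <- nrow(m)
  adj <- adjListFromMatrix(m)
  radj <- adjListFromMatrix(t(m))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    ds <- bfsDistOracle(adj, s)
    for (t in seq_len(n)) {
      if (t == s || !is.finite(ds[t])) next
      dt <- bfsDistOracle(radj, t)       # distance to t in original graph
      paths <- list()
      walk <- function(path) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1L]] <<- path
          return()
        }
        for (w in adj[[v]])
          if (is.finite(dt[w]) && dt[w] == dt[v] - 1) walk(c(path, w))
      }
      walk(s)
      stopifnot(length(paths) > 0)
      for (p in paths) for (v in setdiff(p, c(s, t)))
        bc[v] <- bc[v] + 1 / length(paths)
    }
  }
  bc
}

# --- binary-graph topology oracles ---------------------------------------

floydDistOracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bruteGEOracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- floydDistOracle(adj)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + (if (is.finite(d[i, j])) 1 / d[i, j] else 0)
  tot / (n * (n - 1))
}

bruteCCOracle <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in nb) for (j in nb) if (i < j && adj[i, j] > 0) links <- links + 1
    vals[v] <- 2 * links / (k * (k - 1))
  }
  mean(vals)
}

bruteACOracle <- function(adj) {
  deg <- rowSums(adj)
  xs <- c(); ys <- c()
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && adj[i, j] > 0) {
    xs <- c(xs, deg[i]); ys <- c(ys, deg[j])
  }
  if (length(xs) < 2) return(NA_real_)
  mx <- mean(xs); my <- mean(ys)
  sx <- sqrt(mean(xs^2) - mx^2); sy <- sqrt(mean(ys^2) - my^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (mean(xs * ys) - mx * my) / (sx * sy)
}

bruteLEOracle <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) next
    vals[v] <- bruteGEOracle(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

randomAdjOracle <- function(n, p = 0.45) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  m <- m | t(m)
  diag(m) <- FALSE
  m
}

# --- PLV oracle: per-sample complex mean over explicit loops --------------

brutePLVOracle <- function(phiA, phiB) {
  acc <- 0 + 0i
  cnt <- 0
  for (i in seq_len(nrow(phiA))) for (s in seq_len(ncol(phiA))) {
    acc <- acc + exp(1i * (phiA[i, s] - phiB[i, s]))
    cnt <- cnt + 1
  }
  Mod(acc / cnt)
}

# --- Benjamini-Hochberg step-up oracles -----------------------------------

bhRejectOracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

bhAdjustOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- prev
  }
  adj
}
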