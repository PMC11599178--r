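#' Simulate a directed friend-nomination network
#'
#' Emulates a class-room nomination study: every person nominates between 1
#' and \code{maxNominations} "particularly close" friends. Nominees are
#' drawn preferentially toward a latent popularity gradient, producing
#' in-degree heterogeneity, and a fraction of nominations reciprocate
#' existing ones. Per-node real-life network sizes are drawn so that they
#' correlate positively with out-degree, mirroring the positive correlations
#' reported between questionnaire-based network size and in-class
#' sociability.
#'
#' Defaults reflect the study conditions: 43 people, at most 5 nominations
#' each, real-life sizes with mean about 9.3 and SD about 3.6, and a
#' size/out-degree correlation near 0.6.
#'
#' @param n number of people (>= 2).
#' @param maxNominations maximum nominations per person (1 <=
#'   maxNominations <= n - 1).
#' @param seed integer seed for reproducibility.
#' @param popularitySd SD of the latent log-popularity gradient controlling
#'   in-degree heterogeneity (0 = uniform targets).
#' @param reciprocity probability that a nomination is directed toward
#'   someone who already nominated the sender, when such a person remains
#'   available.
#' @param sizeMean,sizeSd mean and SD of the real-life network-size count
#'   distribution.
#' @param sizeOutdegCor target correlation between real-life size and
#'   out-degree.
#' @return a [SocialGraph-class] with real-life sizes and a
#'   \code{"popularity"} attribute carrying the latent gradient (ground
#'   truth for recovery tests).
#' @examples
#' g <- simulateSocialNetwork(43, seed = 1)
#' range(degreeCentrality(g)$out_degree)
#' @export
simulateSocialNetwork <- function(n = 43, maxNominations = 5, seed = NULL,
                                  popularitySd = 0.8, reciprocity = 0.3,
                                  sizeMean = 9.33, sizeSd = 3.57,
                                  sizeOutdegCor = 0.59) {
  if (n < 2) stop("a nomination network needs at least 2 people")
  if (maxNominations < 1 || maxNominations > n - 1)
    stop("maxNominations must be in [1, n-1]")
  withSeed(seed, {
    nodes <- sprintf("p%02d", seq_len(n))
    pop <- exp(stats::rnorm(n, 0, popularitySd))
    outdeg <- sample(seq_len(maxNominations), n, replace = TRUE)
    nominated_by <- vector("list", n)  # who nominated node i so far
    edges <- matrix(character(0), 0, 2)
    order_people <- sample.int(n)
    for (i in order_people) {
      chosen <- integer(0)
      for (k in seq_len(outdeg[i])) {
        recip_pool <- setdiff(nominated_by[[i]], chosen)
        if (length(recip_pool) && stats::runif(1) < reciprocity) {
          pick <- recip_pool[sample.int(length(recip_pool), 1)]
        } else {
          pool <- setdiff(seq_len(n)[-i], chosen)
          pick <- pool[sample.int(length(pool), 1, prob = pop[pool])]
        }
        chosen <- c(chosen, pick)
      }
      for (j in chosen) nominated_by[[j]] <- c(nominated_by[[j]], i)
      edges <- rbind(edges, cbind(nodes[i], nodes[chosen]))
    }
    zo <- as.numeric(scale(outdeg))
    if (any(!is.finite(zo))) zo <- rep(0, n)
    sizes <- round(sizeMean + sizeSd * (sizeOutdegCor * zo +
             sqrt(max(0, 1 - sizeOutdegCor^2)) * stats::rnorm(n)))
    sizes <- pmax(sizes, 0)
    g <- buildGraph(edges, nodes = nodes,
                    sizes = stats::setNames(sizes, nodes))
    attr(g, "popularity") <- stats::setNames(pop, nodes)
    g
  })
}
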