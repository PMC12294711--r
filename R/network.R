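## internal: column-stochastic walk matrix of the undirected graph,
## confidence-weighted when weights are present. Column v holds the
## transition probabilities out of v; dangling (isolated) columns are
## all-zero and handled by the callers as full teleport.
.walkMatrix <- function(net) {
    stopifnot(is(net, "PPINetwork"))
    nd <- nodes(net)
    e <- edges(net)
    i <- match(c(e$from, e$to), nd)
    j <- match(c(e$to, e$from), nd)
    w <- c(e$weight, e$weight)
    A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                              dims = c(length(nd), length(nd)),
                              dimnames = list(nd, nd))
    strength <- Matrix::colSums(A)
    dangling <- strength == 0
    scale <- ifelse(dangling, 0, 1 / pmax(strength, .Machine$double.xmin))
    W <- A %*% Matrix::Diagonal(x = scale)
    list(W = W, dangling = dangling, nodes = nd)
}

## internal: teleport/prior vector from a seed set (uniform over the
## seeds present in the network) or a user prior
.priorVector <- function(net, seeds, prior = NULL) {
    nd <- nodes(net)
    if (!is.null(prior)) {
        stopifnot(length(prior) == length(nd))
        if (abs(sum(prior) - 1) > 1e-8)
            stop("prior must sum to 1")
        p <- as.numeric(prior)
        names(p) <- nd
        return(p)
    }
    sd <- geneIds(seeds)
    present <- intersect(sd, nd)
    if (!length(present))
        stop(sprintf("no seed present in the network; missing: %s%s",
             paste(utils::head(sd, 5L), collapse = ", "),
             if (length(sd) > 5L) ", ..." else ""))
    p <- numeric(length(nd))
    names(p) <- nd
    p[present] <- 1 / length(present)
    p
}

#' PageRank with priors on a PPI network
#'
#' Scores every node by the stationary distribution of a damped random
#' walk whose teleport distribution is the prior — by default uniform
#' over the seed (training) genes — so nodes strongly connected to the
#' seeds score high:
#' \deqn{PR = (1-d)\,prior + d\,(W\,PR + m\,prior)}
#' where `W` is the column-stochastic walk matrix (undirected edges
#' traversed both ways, transition probability proportional to edge
#' confidence, `L(v)` the weighted degree of `v`) and `m` the mass on
#' dangling nodes, which teleport with probability 1. With a uniform
#' prior over all nodes this is classical PageRank with teleport
#' `(1-d)/N`. Power iteration stops when the L1 change drops below
#' `tol`; scores always sum to 1.
#'
#' @param net A [PPINetwork-class].
#' @param seeds A [GeneSet-class] of seed genes (ignored when `prior`
#'   is given).
#' @param d Damping factor in \[0, 1); default 0.85.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param maxIter Iteration cap (default 1000); non-convergence warns
#'   and returns the last iterate.
#' @param prior Optional explicit teleport probability vector over
#'   `nodes(net)` (must sum to 1).
#' @return Named numeric vector of scores over all nodes, summing to 1.
#' @export
pagerankWithPriors <- function(net, seeds = NULL, d = 0.85, tol = 1e-10,
                               maxIter = 1000L, prior = NULL) {
    stopifnot(d >= 0, d < 1, tol > 0)
    wm <- .walkMatrix(net)
    p0 <- .priorVector(net, seeds, prior)
    if (d == 0) return(p0)
    x <- p0
    for (it in seq_len(maxIter)) {
        m <- sum(x[wm$dangling])
        xNew <- as.numeric(d * (wm$W %*% x + m * p0) + (1 - d) * p0)
        names(xNew) <- wm$nodes
        if (sum(abs(xNew - x)) < tol) {
            xNew <- xNew / sum(xNew)
            return(xNew)
        }
        x <- xNew
    }
    warning(sprintf("PageRank did not converge in %d iterations", maxIter))
    x / sum(x)
}

#' K-step Markov diffusion from the seed genes
#'
#' Simulates information spreading from the seeds over a fixed horizon:
#' starting from the uniform distribution over seeds, the walk matrix
#' is applied `k` times and the visit mass per node is averaged over
#' steps 1..k (cumulative diffusion, not the final step alone). Mass
#' on dangling nodes is re-injected through the start distribution so
#' each step remains a probability distribution.
#'
#' @param net A [PPINetwork-class].
#' @param seeds A [GeneSet-class].
#' @param kSteps Number of steps (default 3).
#' @return Named numeric vector of visit mass per node, summing to 1.
#' @export
kStepMarkov <- function(net, seeds, kSteps = 3L) {
    stopifnot(kSteps >= 1L)
    wm <- .walkMatrix(net)
    p0 <- .priorVector(net, seeds)
    x <- p0
    acc <- numeric(length(p0))
    for (s in seq_len(kSteps)) {
        m <- sum(x[wm$dangling])
        x <- as.numeric(wm$W %*% x + m * p0)
        names(x) <- wm$nodes
        acc <- acc + x
    }
    out <- acc / kSteps
    names(out) <- wm$nodes
    out
}

#' Degree and betweenness centrality
#'
#' Degree is the incident-edge count; betweenness the number of
#' shortest paths between node pairs passing through the node
#' (unweighted, unnormalized, fractional over tied shortest paths), as
#' computed by igraph.
#'
#' @param net A [PPINetwork-class].
#' @return data.frame with columns `gene`, `degree`, `betweenness`.
#' @export
networkCentralities <- function(net) {
    g <- .asIgraph(net)
    data.frame(
        gene = nodes(net),
        degree = as.integer(igraph::degree(g)),
        betweenness = as.numeric(igraph::betweenness(
            g, directed = FALSE, weights = NA, normalized = FALSE)),
        stringsAsFactors = FALSE, row.names = NULL)
}

## internal: igraph view of a PPINetwork
.asIgraph <- function(net) {
    stopifnot(is(net, "PPINetwork"))
    e <- edges(net)
    igraph::graph_from_data_frame(e, directed = FALSE,
                                  vertices = data.frame(name = nodes(net)))
}

#' All network evidence for candidate scoring
#'
#' Runs [pagerankWithPriors()], [kStepMarkov()] and
#' [networkCentralities()] on the network seeded by the training genes
#' and assembles the per-gene table. The score fed to integration
#' (`net_score`) is the PageRank-with-priors value by default; the
#' rank-average of all four statistics is available as an alternative.
#' Candidates absent from the network score 0 everywhere (with a
#' warning).
#'
#' @param candidates A [GeneSet-class] of test genes.
#' @param seeds A [GeneSet-class] of training genes.
#' @param net A [PPINetwork-class].
#' @param d,tol,maxIter,kSteps See [pagerankWithPriors()] and
#'   [kStepMarkov()].
#' @param netScore `"pagerank"` (default) or `"rank_average"` (mean of
#'   the descending ranks of all four statistics, negated so larger is
#'   better).
#' @return data.frame with one row per candidate: `gene`,
#'   `pagerank_prior`, `kstep_mass`, `degree`, `betweenness`,
#'   `net_score`.
#' @export
networkScores <- function(candidates, seeds, net, d = 0.85, tol = 1e-10,
                          maxIter = 1000L, kSteps = 3L,
                          netScore = c("pagerank", "rank_average")) {
    stopifnot(is(candidates, "GeneSet"), length(candidates) > 0L)
    netScore <- match.arg(netScore)
    pr <- pagerankWithPriors(net, seeds, d = d, tol = tol,
                             maxIter = maxIter)
    ks <- kStepMarkov(net, seeds, kSteps = kSteps)
    cen <- networkCentralities(net)
    rownames(cen) <- cen$gene
    cand <- geneIds(candidates)
    absent <- setdiff(cand, nodes(net))
    if (length(absent))
        warning(sprintf("candidate(s) absent from the network score 0: %s",
                        paste(absent, collapse = ", ")))
    pick <- function(v, default = 0) {
        out <- v[cand]
        out[is.na(out)] <- default
        unname(out)
    }
    deg <- stats::setNames(cen$degree, cen$gene)
    btw <- stats::setNames(cen$betweenness, cen$gene)
    out <- data.frame(
        gene = cand,
        pagerank_prior = pick(pr),
        kstep_mass = pick(ks),
        degree = as.integer(pick(deg)),
        betweenness = pick(btw),
        stringsAsFactors = FALSE, row.names = NULL)
    out$net_score <- if (netScore == "pagerank") {
        out$pagerank_prior
    } else {
        stats <- cbind(out$pagerank_prior, out$kstep_mass, out$degree,
                       out$betweenness)
        -rowMeans(apply(stats, 2L, function(col) rank(-col,
            ties.method = "average")))
    }
    out
}
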