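# Independent oracles kept deliberately naive: they re-derive expected
# values by enumeration or dense linear algebra, never by calling the
# implementation under test.

# hypergeometric upper tail by direct combinatorial summation
oracleHyperTail <- function(N, K, n, k) {
    hi <- min(K, n)
    if (k > hi) return(0)
    total <- choose(N, n)
    sum(vapply(k:hi, function(i)
        choose(K, i) * choose(N - K, n - i), numeric(1))) / total
}

# PageRank with priors by solving the fixed point as a dense linear
# system: x = (1-d) p + d (W x + m(x) p), with m(x) the mass on
# dangling columns, folded into the matrix as a rank-one term.
oraclePagerank <- function(adj, prior, d) {
    n <- nrow(adj)
    colsum <- colSums(adj)
    W <- adj
    dang <- colsum == 0
    W[, !dang] <- sweep(adj[, !dang, drop = FALSE], 2,
                        colsum[!dang], "/")
    D <- matrix(0, n, n)
    D[, dang] <- prior        # dangling columns teleport to the prior
    A <- diag(n) - d * (W + D)
    as.numeric(solve(A, (1 - d) * prior))
}

# K-step Markov by explicit dense matrix application
oracleKStep <- function(adj, start, k) {
    n <- nrow(adj)
    colsum <- colSums(adj)
    dang <- colsum == 0
    W <- adj
    W[, !dang] <- sweep(adj[, !dang, drop = FALSE], 2, colsum[!dang], "/")
    x <- start
    acc <- numeric(n)
    for (s in seq_len(k)) {
        x <- as.numeric(W %*% x) + sum(x[dang]) * start
        acc <- acc + x
    }
    acc / k
}

# betweenness by exhaustive BFS path counting over all ordered pairs
oracleBetweenness <- function(adj) {
    n <- nrow(adj)
    btw <- numeric(n)
    for (s in seq_len(n)) for (t in seq_len(n)) {
        if (s >= t) next
        # enumerate all shortest paths s -> t by BFS layers
        dist <- rep(Inf, n); dist[s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (w in which(adj[v, ] > 0))
                if (dist[w] > dist[v] + 1) {
                    dist[w] <- dist[v] + 1
                    queue <- c(queue, w)
                }
        }
        if (!is.finite(dist[t])) next
        paths <- list(s)
        for (step in seq_len(dist[t])) {
            paths <- unlist(lapply(paths, function(p) {
                v <- p[length(p)]
                nxt <- which(adj[v, ] > 0 & dist == dist[v] + 1 &
                             dist <= dist[t])
                lapply(nxt, function(w) c(p, w))
            }), recursive = FALSE)
        }
        paths <- Filter(function(p) p[length(p)] == t, paths)
        if (!length(paths)) next
        inner <- unlist(lapply(paths, function(p)
            p[-c(1, length(p))]))
        if (length(inner)) {
            tab <- table(inner)
            idx <- as.integer(names(tab))
            btw[idx] <- btw[idx] + as.numeric(tab) / length(paths)
        }
    }
    btw
}

# random small undirected adjacency matrix (possibly with isolated
# nodes), for network oracle comparisons
randomAdjacency <- function(n, pEdge = 0.35) {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (stats::runif(1) < pEdge) adj[i, j] <- adj[j, i] <- 1
    adj
}

# PPINetwork from a 0/1 adjacency matrix with letter node names
networkFromAdjacency <- function(adj) {
    n <- nrow(adj)
    nm <- sprintf("N%02d", seq_len(n))
    idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    edf <- data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]],
                      weight = rep(1, nrow(idx)),
                      stringsAsFactors = FALSE)
    PPINetwork(edf, nodes = nm)
}

# default synthetic partition helper used across tests
bundlePartition <- function(bundle) {
    inter <- intersect(geneIds(bundle$aging), geneIds(bundle$exercise))
    list(training = GeneSet("training",
                            setdiff(geneIds(bundle$aging), inter)),
         test = GeneSet("test", inter))
}
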