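pathGraph <- function() PPINetwork(data.frame(
    from = c("A", "B"), to = c("B", "C")))

test_that("PageRank limits: symmetry, teleport-only, prior recovery", {
    two <- PPINetwork(data.frame(from = "A", to = "B"))
    pr <- pagerankWithPriors(two, GeneSet("s", c("A", "B")), d = 0.85)
    expect_equal(unname(pr), c(0.5, 0.5))

    seeds <- GeneSet("s", "A")
    pr0 <- pagerankWithPriors(pathGraph(), seeds, d = 0)
    expect_equal(unname(pr0), c(1, 0, 0))

    prior <- c(0.2, 0.5, 0.3)
    pr0b <- pagerankWithPriors(pathGraph(), prior = prior, d = 0)
    expect_equal(unname(pr0b), prior)
})

test_that("PageRank matches the dense linear-system oracle on small graphs", {
    set.seed(31)
    for (rep in 1:20) {
        n <- sample(4:10, 1)
        adj <- randomAdjacency(n)
        net <- networkFromAdjacency(adj)
        nSeeds <- sample(seq_len(n - 1), 1)
        seedIdx <- sample(n, nSeeds)
        prior <- numeric(n); prior[seedIdx] <- 1 / nSeeds
        pr <- pagerankWithPriors(net, prior = prior, d = 0.85,
                                 tol = 1e-14)
        expect_equal(unname(pr), oraclePagerank(adj, prior, 0.85),
                     tolerance = 1e-10)
        expect_equal(sum(pr), 1, tolerance = 1e-10)
    }
})

test_that("PageRank agrees with igraph's personalized variant", {
    set.seed(37)
    adj <- randomAdjacency(8, 0.5)
    net <- networkFromAdjacency(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    # compare on the largest connected component to avoid
    # dangling-node policy differences between implementations
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    adj2 <- adj[keep, keep]
    net2 <- networkFromAdjacency(adj2)
    prior <- numeric(nrow(adj2)); prior[1:2] <- 0.5
    pr <- pagerankWithPriors(net2, prior = prior, d = 0.85, tol = 1e-14)
    g2 <- igraph::graph_from_adjacency_matrix(adj2, mode = "undirected")
    ig <- igraph::page_rank(g2, personalized = prior, damping = 0.85)
    expect_equal(unname(pr), ig$vector, tolerance = 1e-6)
})

test_that("PageRank is invariant under node relabeling", {
    set.seed(41)
    adj <- randomAdjacency(7, 0.4)
    net <- networkFromAdjacency(adj)
    prior <- rep(1 / 7, 7)
    pr <- pagerankWithPriors(net, prior = prior)
    perm <- sample(7)
    adjP <- adj[perm, perm]
    netP <- networkFromAdjacency(adjP)
    prP <- pagerankWithPriors(netP, prior = prior[perm])
    expect_equal(unname(prP), unname(pr)[perm], tolerance = 1e-9)
})

test_that("missing seeds raise a named error", {
    expect_error(pagerankWithPriors(pathGraph(), GeneSet("s", "ZZZ")),
                 "ZZZ")
})

test_that("K-step Markov distributes star-graph mass exactly", {
    leaves <- paste0("L", 1:5)
    star <- PPINetwork(data.frame(from = "HUB", to = leaves))
    seeds <- GeneSet("s", "HUB")
    m1 <- kStepMarkov(star, seeds, kSteps = 1)
    expect_equal(unname(m1[leaves]), rep(1 / 5, 5))
    expect_equal(m1[["HUB"]], 0)
    # step 2 returns all mass to the hub; average over steps = 1/2
    m2 <- kStepMarkov(star, seeds, kSteps = 2)
    expect_equal(m2[["HUB"]], 0.5)
    expect_equal(sum(m2), 1)
})

test_that("K-step Markov equals the dense matrix-power oracle", {
    set.seed(43)
    for (rep in 1:10) {
        adj <- randomAdjacency(6, 0.5)
        net <- networkFromAdjacency(adj)
        start <- numeric(6); start[c(1, 4)] <- 0.5
        got <- kStepMarkov(net, GeneSet("s", c("N01", "N04")),
                           kSteps = 3)
        expect_equal(unname(got), oracleKStep(adj, start, 3),
                     tolerance = 1e-12)
    }
})

test_that("centralities match hand counts and the brute-force oracle", {
    cen <- networkCentralities(pathGraph())
    expect_equal(cen$betweenness[cen$gene == "B"], 1)
    expect_equal(cen$betweenness[cen$gene == "A"], 0)
    expect_equal(cen$degree, c(1L, 2L, 1L))

    k4 <- PPINetwork(data.frame(
        from = c("A", "A", "A", "B", "B", "C"),
        to   = c("B", "C", "D", "C", "D", "D")))
    expect_equal(networkCentralities(k4)$betweenness, rep(0, 4))

    set.seed(47)
    # random tree on 7 nodes: igraph result vs exhaustive enumeration
    parents <- c(NA, sample(1, 1), sample(2, 1), sample(3, 1),
                 sample(4, 1), sample(5, 1), sample(6, 1))
    adj <- matrix(0, 7, 7)
    for (i in 2:7) { adj[i, parents[i]] <- 1; adj[parents[i], i] <- 1 }
    net <- networkFromAdjacency(adj)
    cen <- networkCentralities(net)
    expect_equal(cen$betweenness, oracleBetweenness(adj),
                 tolerance = 1e-9)
})

test_that("seed-wired candidates beat degree-matched unwired ones", {
    # two leaves of identical degree hang off a 4-cycle; S1/S2 are the
    # seeds; CAND_W attaches to both seeds, CAND_U to the non-seeds
    edf <- data.frame(
        from = c("S1", "X1", "S2", "X2", "CAND_W", "CAND_W",
                 "CAND_U", "CAND_U"),
        to   = c("X1", "S2", "X2", "S1", "S1", "S2", "X1", "X2"))
    net <- PPINetwork(edf)
    seeds <- GeneSet("s", c("S1", "S2"))
    for (rep in 1:5) {
        pr <- pagerankWithPriors(net, seeds)
        expect_gt(pr[["CAND_W"]], pr[["CAND_U"]])
    }
})

test_that("networkScores assembles all statistics for the candidates", {
    set.seed(53)
    cfg <- syntheticConfig(universeSize = 300, agingSize = 40,
        exerciseSize = 60, overlapSize = 10, networkNodes = 150,
        rngSeed = 5)
    b <- generateBundle(cfg)
    part <- bundlePartition(b)
    ns <- networkScores(part$test, part$training, b$network)
    expect_identical(nrow(ns), 10L)
    expect_identical(ns$net_score, ns$pagerank_prior)
    expect_true(all(ns$pagerank_prior > 0))
    expect_true(all(ns$degree >= 1L))
    nsr <- networkScores(part$test, part$training, b$network,
                         netScore = "rank_average")
    expect_false(identical(nsr$net_score, nsr$pagerank_prior))
    # a candidate missing from the network scores zero, with a warning
    cand2 <- GeneSet("te", c(geneIds(part$test), "NOTINNET"))
    expect_warning(ns2 <- networkScores(cand2, part$training,
                                        b$network), "NOTINNET")
    expect_equal(ns2$net_score[ns2$gene == "NOTINNET"], 0)
})
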