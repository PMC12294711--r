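mkCategorical <- function(ann, name = "GO") {
    AnnotationCategory(name, "categorical", terms = ann)
}

test_that("training profile holds term frequencies and mean vectors", {
    training <- GeneSet("tr", c("T1", "T2", "T3", "T4"))
    cat1 <- mkCategorical(list(T1 = c("A", "B"), T2 = c("A"),
                               T3 = c("A"), T4 = c("A", "C")))
    prof <- buildTrainingProfile(training, list(cat1))
    expect_equal(prof$GO$weights[["A"]], 1.0)
    expect_equal(prof$GO$weights[["B"]], 0.25)
    expect_equal(prof$GO$weights[["C"]], 0.25)

    quant <- AnnotationCategory("EXPR", "quantitative",
        profiles = matrix(c(1, 2, 3, 4), 2, byrow = TRUE,
                          dimnames = list(c("T1", "T2"), NULL)))
    prof <- buildTrainingProfile(training, list(quant))
    expect_equal(unname(prof$EXPR$mean), c(2, 3))

    # category with no training annotation is dropped with a warning
    off <- mkCategorical(list(Z9 = "A"), name = "OFF")
    expect_warning(prof <- buildTrainingProfile(training,
                                                list(cat1, off)),
                   "no training gene")
    expect_named(prof, "GO")
})

test_that("categorical and quantitative similarities behave at the poles", {
    training <- GeneSet("tr", c("T1", "T2"))
    cat1 <- mkCategorical(list(T1 = c("A", "B"), T2 = c("A", "B"),
                               G1 = c("A", "B"), G2 = c("Z"),
                               G3 = character(0)))
    prof <- buildTrainingProfile(training, list(cat1))
    # gene carrying exactly the profile's weight-1 terms: cosine 1
    expect_equal(categorySimilarity("G1", prof, cat1), 1.0)
    # gene with only terms absent from the profile: orthogonal
    expect_equal(categorySimilarity("G2", prof, cat1), 0.0)
    # unannotated gene scores 0
    expect_equal(categorySimilarity("G9", prof, cat1), 0.0)
    # soft-Jaccard variant agrees at the poles too
    expect_equal(categorySimilarity("G1", prof, cat1,
                                    method = "jaccard"), 1.0)
    expect_equal(categorySimilarity("G2", prof, cat1,
                                    method = "jaccard"), 0.0)

    quant <- AnnotationCategory("EXPR", "quantitative",
        profiles = rbind(T1 = c(1, 2, 3), T2 = c(1, 2, 3),
                         G1 = c(1, 2, 3), G2 = c(5, 5, 5)))
    profQ <- buildTrainingProfile(training, list(quant))
    expect_equal(categorySimilarity("G1", profQ, quant), 1.0)
    expect_warning(s <- categorySimilarity("G2", profQ, quant),
                   "zero-variance")
    expect_equal(s, 0)
    # vectorized path agrees with the scalar one
    sims <- categorySimilarities(c("G1", "G2", "G9"), profQ, quant)
    expect_equal(unname(sims), c(1, 0, 0))
})

test_that("empirical p-values use the add-one rule and a fixed seed", {
    nulls <- seq(0, 0.5, length.out = 2000)
    set.seed(1)
    expect_equal(empiricalPValue(0.9, nulls, M = 999), 1 / 1000)
    set.seed(1)
    expect_equal(empiricalPValue(-1, nulls, M = 999), 1.0)
    set.seed(5); p1 <- empiricalPValue(0.25, nulls, M = 999)
    set.seed(5); p2 <- empiricalPValue(0.25, nulls, M = 999)
    expect_identical(p1, p2)
    expect_warning(empiricalPValue(0.2, nulls[1:100], M = 999),
                   "replacement")
    expect_error(empiricalPValue(0.2, nulls, M = 50), "99")
})

test_that("Fisher combination matches the closed form for even df", {
    one <- fisherCombine(0.05)
    expect_equal(one$sCombined, 0.95, tolerance = 1e-12)
    expect_equal(fisherCombine(c(1, 1, 1))$sCombined, 0)
    two <- fisherCombine(c(0.1, 0.1))
    X <- -2 * sum(log(c(0.1, 0.1)))
    expect_equal(two$statistic, X, tolerance = 1e-12)
    expect_equal(two$pFisher, exp(-X / 2) * (1 + X / 2),
                 tolerance = 1e-12)
    expect_equal(two$sCombined, 1 - exp(-X / 2) * (1 + X / 2),
                 tolerance = 1e-12)
    expect_warning(z <- fisherCombine(c(0.5, 0)), "clamped")
    expect_lt(z$pFisher, 1e-100)
})

test_that("the combined score never decreases when a p-value improves", {
    set.seed(23)
    for (i in 1:25) {
        p <- runif(4, 0.01, 1)
        j <- sample(4, 1)
        p2 <- p
        p2[j] <- p[j] * runif(1)
        expect_gte(fisherCombine(p2)$sCombined,
                   fisherCombine(p)$sCombined)
    }
})

test_that("planted effectors out-score background candidates", {
    wins <- 0L
    nRep <- 20L
    for (rep in seq_len(nRep)) {
        cfg <- syntheticConfig(universeSize = 300, agingSize = 40,
            exerciseSize = 60, overlapSize = 10, nCategories = 3,
            plantedEffectors = 3, networkNodes = 150, rngSeed = rep)
        b <- generateBundle(cfg)
        part <- bundlePartition(b)
        set.seed(rep)
        fun <- suppressWarnings(functionalScores(part$test,
            part$training, b$categories, b$universe, M = 199))
        planted <- fun$s_combined[fun$gene %in% b$truth$effectors]
        others <- fun$s_combined[!fun$gene %in% b$truth$effectors]
        wins <- wins + (median(planted) > median(others))
    }
    expect_gte(wins, ceiling(0.95 * nRep))
})

test_that("candidates missing from a category stay comparable (p = 1)", {
    training <- GeneSet("tr", c("T1", "T2"))
    cat1 <- mkCategorical(list(T1 = "A", T2 = "A", C1 = "A"))
    cands <- GeneSet("te", c("C1", "C2"))   # C2 unannotated
    set.seed(3)
    fun <- suppressWarnings(functionalScores(cands, training,
        list(cat1), sprintf("U%02d", 1:50), M = 99))
    expect_equal(fun$p_GO[fun$gene == "C2"], 1)
    expect_equal(fun$sim_GO[fun$gene == "C2"], 0)
    expect_identical(nrow(fun), 2L)
    expect_identical(fun$gene[1], "C1")
})
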