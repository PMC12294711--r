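miniConfig <- function(seed = 1, ...) syntheticConfig(
    universeSize = 300, agingSize = 40, exerciseSize = 60,
    overlapSize = 10, nCategories = 3, plantedEffectors = 2,
    networkNodes = 150, rngSeed = seed, ...)

test_that("overlapping sets hit the configured sizes exactly", {
    sets <- generateOverlappingSets(syntheticConfig(rngSeed = 9))
    expect_identical(length(sets$aging), 243L)
    expect_identical(length(sets$exercise), 634L)
    expect_identical(length(intersect(geneIds(sets$aging),
                                      geneIds(sets$exercise))), 37L)
    # boundary: overlap equal to the smaller set forces containment
    cfg <- syntheticConfig(universeSize = 300, agingSize = 20,
        exerciseSize = 60, overlapSize = 20, plantedEffectors = 2,
        networkNodes = 100, rngSeed = 2)
    s2 <- generateOverlappingSets(cfg)
    expect_true(all(geneIds(s2$aging) %in% geneIds(s2$exercise)))
    # determinism
    a1 <- generateOverlappingSets(syntheticConfig(rngSeed = 4))
    a2 <- generateOverlappingSets(syntheticConfig(rngSeed = 4))
    expect_identical(geneIds(a1$aging), geneIds(a2$aging))
    expect_identical(geneIds(a1$exercise), geneIds(a2$exercise))
})

test_that("infeasible configurations are rejected with the inequality", {
    expect_error(syntheticConfig(agingSize = 10, overlapSize = 20),
                 "overlapSize")
    expect_error(syntheticConfig(universeSize = 100, agingSize = 80,
                                 exerciseSize = 80, overlapSize = 10),
                 "universeSize")
    expect_error(syntheticConfig(plantedEffectors = 50),
                 "plantedEffectors")
})

test_that("annotation planting follows the configured probabilities", {
    cfg <- miniConfig(seed = 3, enrichmentStrength = 1)
    b <- generateBundle(cfg)
    catCats <- Filter(function(x) categoryKind(x) == "categorical",
                      b$categories)
    for (cat in catCats)
        for (g in b$truth$effectors)
            expect_true(any(grepl("\\.PROF", cat@terms[[g]])))

    # background rate 0: non-planted candidates carry no annotation at
    # all in categorical categories
    cfg0 <- miniConfig(seed = 4, backgroundAnnotationRate = 0)
    b0 <- generateBundle(cfg0)
    inter <- intersect(geneIds(b0$aging), geneIds(b0$exercise))
    nonPlanted <- setdiff(inter, b0$truth$effectors)
    cat1 <- Filter(function(x) categoryKind(x) == "categorical",
                   b0$categories)[[1]]
    for (g in nonPlanted)
        expect_true(is.null(cat1@terms[[g]]) ||
                    length(cat1@terms[[g]]) == 0L)

    expect_length(b$categories, 3L)
    kinds <- vapply(b$categories, categoryKind, character(1))
    expect_identical(sum(kinds == "quantitative"), 1L)
})

test_that("the generated network is scale-free-ish and seed-wired", {
    b <- generateBundle(miniConfig(seed = 5))
    expect_identical(length(b$network), 150L)
    training <- setdiff(geneIds(b$aging),
                        geneIds(b$exercise))
    e <- edges(b$network)
    for (p in b$truth$effectors) {
        nb <- unique(c(e$to[e$from == p], e$from[e$to == p]))
        expect_gte(length(intersect(nb, training)), 4L)
    }
    # heavy-tailed degrees across seeded replicates
    heavy <- vapply(1:20, function(s) {
        bb <- generateBundle(miniConfig(seed = s))
        deg <- table(c(edges(bb$network)$from, edges(bb$network)$to))
        max(deg) > 3 * stats::median(deg)
    }, logical(1))
    expect_true(all(heavy))
})

test_that("bundles are reproducible and their truth lies in the overlap", {
    b1 <- generateBundle(miniConfig(seed = 6))
    b2 <- generateBundle(miniConfig(seed = 6))
    expect_identical(geneIds(b1$aging), geneIds(b2$aging))
    expect_identical(edges(b1$network), edges(b2$network))
    expect_identical(b1$truth, b2$truth)
    inter <- intersect(geneIds(b1$aging), geneIds(b1$exercise))
    expect_true(all(b1$truth$effectors %in% inter))
    expect_identical(length(b1$truth$effectors), 2L)

    # byte-identical files from the same seed
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeBundle(b1, d1); writeBundle(b2, d2)
    for (f in list.files(d1)) {
        expect_identical(readBin(file.path(d1, f), "raw",
                                 file.size(file.path(d1, f))),
                         readBin(file.path(d2, f), "raw",
                                 file.size(file.path(d2, f))),
                         info = f)
    }
})

test_that("every generated file parses back without warnings", {
    b <- generateBundle(miniConfig(seed = 7))
    d <- withr::local_tempdir()
    writeBundle(b, d)
    expect_no_warning({
        suppressMessages({
            readGeneList(file.path(d, "aging_down.txt"))
            readGeneList(file.path(d, "exercise_consensus.txt"))
            readGeneList(file.path(d, "universe.txt"))
        })
        for (f in list.files(d, pattern = "^category_.*\\.gmt$"))
            readAnnotationCategory(file.path(d, f), "categorical")
        for (f in list.files(d, pattern = "^category_.*\\.tsv$"))
            readAnnotationCategory(file.path(d, f), "quantitative")
        for (f in list.files(d, pattern = "^regulators_"))
            readGMT(file.path(d, f), asRegulator = TRUE)
        readEdgeList(file.path(d, "network.tsv"))
        readRunConfig(file.path(d, "run_config.json"))
    })
})
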