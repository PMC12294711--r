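#' Configuration for the synthetic benchmark generator
#'
#' The defaults emulate the study conditions the pipeline was designed
#' for: two gene sets of 243 (aging-downregulated) and 634
#' (exercise-responsive) genes over a shared universe with a forced
#' 37-gene intersection, annotation categories whose profile terms are
#' carried by a majority of training genes, regulator libraries with one
#' planted regulator per source, and a scale-free interaction network in
#' which planted effector genes are preferentially wired to training
#' genes. The universe defaults to 2,000 abstract symbols so a full
#' bundle generates in milliseconds; enrichment uses this universe size
#' as `N`.
#'
#' @param universeSize Number of genes in the universe (default 2000).
#' @param agingSize,exerciseSize,overlapSize Set sizes (defaults 243,
#'   634, 37).
#' @param nCategories Annotation categories; the last one is
#'   quantitative, the rest categorical (default 5).
#' @param plantedEffectors Number of planted effector genes inside the
#'   intersection (default 3).
#' @param enrichmentStrength Probability that a planted effector carries
#'   each profile term / tracks the quantitative profile (default 0.9).
#' @param backgroundAnnotationRate Annotation probability for
#'   non-planted genes (default 0.1).
#' @param networkNodes Nodes in the interaction network (default 1500).
#' @param attachmentEdges Edges added per node during
#'   preferential-attachment growth (default 3).
#' @param seedWiring Extra edges from each planted effector to distinct
#'   training genes (default 4; 0 disables planting in the network).
#' @param nRegulatorSources Regulator evidence libraries (default 2).
#' @param rngSeed Integer seed; every random choice in the bundle flows
#'   from it.
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(universeSize = 2000L, agingSize = 243L,
                            exerciseSize = 634L, overlapSize = 37L,
                            nCategories = 5L, plantedEffectors = 3L,
                            enrichmentStrength = 0.9,
                            backgroundAnnotationRate = 0.1,
                            networkNodes = 1500L, attachmentEdges = 3L,
                            seedWiring = 4L, nRegulatorSources = 2L,
                            rngSeed = 1L) {
    cfg <- list(universeSize = as.integer(universeSize),
                agingSize = as.integer(agingSize),
                exerciseSize = as.integer(exerciseSize),
                overlapSize = as.integer(overlapSize),
                nCategories = as.integer(nCategories),
                plantedEffectors = as.integer(plantedEffectors),
                enrichmentStrength = enrichmentStrength,
                backgroundAnnotationRate = backgroundAnnotationRate,
                networkNodes = as.integer(networkNodes),
                attachmentEdges = as.integer(attachmentEdges),
                seedWiring = as.integer(seedWiring),
                nRegulatorSources = as.integer(nRegulatorSources),
                rngSeed = as.integer(rngSeed))
    if (cfg$overlapSize > min(cfg$agingSize, cfg$exerciseSize))
        stop("infeasible sizes: overlapSize must be <= ",
             "min(agingSize, exerciseSize)")
    if (cfg$agingSize + cfg$exerciseSize - cfg$overlapSize >
        cfg$universeSize)
        stop("infeasible sizes: agingSize + exerciseSize - overlapSize ",
             "must be <= universeSize")
    if (cfg$plantedEffectors > cfg$overlapSize)
        stop("infeasible sizes: plantedEffectors must be <= overlapSize")
    if (cfg$enrichmentStrength <= 0 || cfg$enrichmentStrength > 1)
        stop("enrichmentStrength must lie in (0, 1]")
    if (cfg$backgroundAnnotationRate < 0 ||
        cfg$backgroundAnnotationRate >= 1)
        stop("backgroundAnnotationRate must lie in [0, 1)")
    if (cfg$nCategories < 1L || cfg$plantedEffectors < 0L)
        stop("nCategories must be >= 1 and plantedEffectors >= 0")
    class(cfg) <- "syntheticConfig"
    cfg
}

## internal: the abstract gene universe G000001..G<n>
.universeSymbols <- function(n) sprintf("G%06d", seq_len(n))

#' Generate two overlapping gene sets
#'
#' Samples, uniformly without replacement from the universe, an
#' intersection of exactly `overlapSize` genes plus disjoint unique
#' parts, so the two sets have exactly the configured sizes and
#' overlap. Deterministic given `cfg$rngSeed`.
#'
#' @param cfg A [syntheticConfig()].
#' @return List with `aging` and `exercise` [GeneSet-class] objects and
#'   the `universe` symbol vector.
#' @export
generateOverlappingSets <- function(cfg) {
    stopifnot(inherits(cfg, "syntheticConfig"))
    set.seed(cfg$rngSeed)
    universe <- .universeSymbols(cfg$universeSize)
    need <- cfg$agingSize + cfg$exerciseSize - cfg$overlapSize
    picked <- sample(universe, need)
    shared <- picked[seq_len(cfg$overlapSize)]
    agingOnly <- picked[cfg$overlapSize +
                        seq_len(cfg$agingSize - cfg$overlapSize)]
    exerciseOnly <- picked[cfg$agingSize +
                           seq_len(cfg$exerciseSize - cfg$overlapSize)]
    list(aging = GeneSet("aging_down", c(shared, agingOnly)),
         exercise = GeneSet("exercise_consensus",
                            c(shared, exerciseOnly)),
         universe = universe)
}

## internal: one categorical category with planted structure.
## profile terms annotate a majority of training genes; planted
## effectors carry each profile term with probability `strength`;
## every other gene carries each term with the background rate.
.generateCategoricalCategory <- function(name, universe, training,
                                         planted, strength, bgRate,
                                         nProfileTerms = 8L,
                                         nDecoyTerms = 12L,
                                         trainingCoverage = 0.7) {
    termIds <- c(sprintf("%s.PROF%02d", name, seq_len(nProfileTerms)),
                 sprintf("%s.BG%02d", name, seq_len(nDecoyTerms)))
    nT <- length(termIds)
    ann <- list()
    add <- function(gene, terms) {
        if (length(terms)) ann[[gene]] <<- terms
    }
    rest <- setdiff(universe, c(training, planted))
    for (g in training) {
        prof <- termIds[seq_len(nProfileTerms)][
            stats::runif(nProfileTerms) < trainingCoverage]
        bg <- termIds[nProfileTerms + seq_len(nDecoyTerms)][
            stats::runif(nDecoyTerms) < bgRate]
        add(g, c(prof, bg))
    }
    for (g in planted) {
        hit <- termIds[seq_len(nProfileTerms)][
            stats::runif(nProfileTerms) < strength]
        bg <- termIds[nProfileTerms + seq_len(nDecoyTerms)][
            stats::runif(nDecoyTerms) < bgRate]
        add(g, c(hit, bg))
    }
    for (g in rest) {
        got <- termIds[stats::runif(nT) < bgRate]
        add(g, got)
    }
    AnnotationCategory(name, "categorical", terms = ann)
}

## internal: the quantitative category. Training genes track a latent
## profile vector mu; planted effectors track it with probability
## `strength`, all other genes with probability `bgRate`; non-tracking
## genes get independent noise. Null configurations (strength == bgRate)
## therefore make planted and background genes exchangeable.
.generateQuantitativeCategory <- function(name, universe, training,
                                          planted, strength, bgRate,
                                          dim = 10L, noiseSd = 0.5) {
    mu <- stats::rnorm(dim)
    mat <- matrix(NA_real_, length(universe), dim,
                  dimnames = list(universe, NULL))
    rest <- setdiff(universe, c(training, planted))
    tracks <- stats::setNames(logical(length(universe)), universe)
    tracks[training] <- TRUE
    tracks[planted] <- stats::runif(length(planted)) < strength
    tracks[rest] <- stats::runif(length(rest)) < bgRate
    nTrack <- sum(tracks)
    mat[tracks, ] <- matrix(rep(mu, each = nTrack), nTrack, dim) +
        stats::rnorm(nTrack * dim, sd = noiseSd)
    mat[!tracks, ] <- stats::rnorm(sum(!tracks) * dim)
    AnnotationCategory(name, "quantitative", profiles = mat)
}

#' Generate annotation categories with planted structure
#'
#' Produces `cfg$nCategories` categories: all but the last categorical
#' (profile terms carried by ~70% of training genes, planted effectors
#' annotated at `enrichmentStrength`, everything else at the background
#' rate), the last one quantitative (latent profile vector plus noise).
#' Callers must have seeded the RNG; [generateBundle()] handles this.
#'
#' @param cfg A [syntheticConfig()].
#' @param universe Character vector of universe symbols.
#' @param training,planted Character vectors of training genes and
#'   planted effectors.
#' @return List of [AnnotationCategory-class] objects.
#' @export
generateAnnotationCategories <- function(cfg, universe, training,
                                         planted) {
    ncat <- cfg$nCategories
    cats <- vector("list", ncat)
    for (i in seq_len(ncat)) {
        nm <- sprintf("CAT%02d", i)
        cats[[i]] <- if (i < ncat || ncat == 1L)
            .generateCategoricalCategory(nm, universe, training, planted,
                cfg$enrichmentStrength, cfg$backgroundAnnotationRate)
        else
            .generateQuantitativeCategory(nm, universe, training, planted,
                cfg$enrichmentStrength, cfg$backgroundAnnotationRate)
    }
    cats
}

#' Generate regulator evidence libraries with planted regulators
#'
#' Each source contains one planted regulator whose targets cover 60%
#' of the aging input set (plus random padding) and nine decoy
#' regulators targeting random universe genes of comparable set sizes.
#'
#' @param cfg A [syntheticConfig()].
#' @param universe Universe symbols.
#' @param aging Character vector, the aging input set (the query the
#'   planted regulator should light up for).
#' @return List with `libraries` (list of [RegulatorLibrary-class]) and
#'   `plantedRegulators` (character vector).
#' @export
generateRegulatorLibraries <- function(cfg, universe, aging) {
    libs <- vector("list", cfg$nRegulatorSources)
    plantedRegs <- character(cfg$nRegulatorSources)
    for (s in seq_len(cfg$nRegulatorSources)) {
        regName <- sprintf("REG.PLANTED.S%d", s)
        plantedRegs[s] <- regName
        core <- sample(aging, ceiling(0.6 * length(aging)))
        pad <- sample(setdiff(universe, core), length(core) %/% 4L)
        sets <- list(c(core, pad))
        names(sets) <- regName
        for (dcy in seq_len(9L)) {
            sz <- length(core) + length(pad)
            sets[[sprintf("REG.DECOY.S%d.%02d", s, dcy)]] <-
                sample(universe, sz)
        }
        libs[[s]] <- RegulatorLibrary(sprintf("source%d", s), sets,
                                      universeSize = cfg$universeSize)
    }
    list(libraries = libs, plantedRegulators = plantedRegs)
}

#' Generate a scale-free PPI network wired to the seeds
#'
#' Grows a preferential-attachment (Barabasi-Albert) graph with
#' `attachmentEdges` edges per new node — giving the heavy-tailed
#' degree distribution of real interactomes — and assigns gene symbols
#' so that all aging/exercise genes are in the network. The candidate
#' (intersection) genes are assigned to the newest nodes of the growth
#' process, so all candidates enter the network degree-matched (around
#' `attachmentEdges` interactions each, as tissue-specific genes
#' typically are — interactome mega-hubs are essentially never members
#' of a small differential-expression set); each planted effector is
#' then connected to `seedWiring` distinct training genes, making seed
#' proximity the only systematic network difference between planted
#' and non-planted candidates. The result is simple (no loops or
#' duplicate edges) and connected by construction.
#'
#' @param cfg A [syntheticConfig()].
#' @param universe Universe symbols.
#' @param members Character vector of genes that must be nodes (the two
#'   input sets).
#' @param training,planted Training genes and planted effectors.
#' @param candidates Character vector of candidate genes (assigned to
#'   the newest, degree-matched nodes); defaults to `planted`.
#' @return A [PPINetwork-class].
#' @export
generatePPINetwork <- function(cfg, universe, members, training,
                               planted, candidates = planted) {
    if (cfg$networkNodes < length(members))
        stop("networkNodes must be >= the number of input-set genes")
    if (cfg$seedWiring > length(training))
        stop("seedWiring must be <= the number of training genes")
    g <- igraph::sample_pa(cfg$networkNodes, power = 1,
                           m = cfg$attachmentEdges, directed = FALSE)
    g <- igraph::simplify(g)
    candidates <- unique(c(candidates, planted))
    others <- setdiff(members, candidates)
    extra <- sample(setdiff(universe, members),
                    cfg$networkNodes - length(members))
    # nodes are created in growth order: the last ones are the newest
    labels <- character(cfg$networkNodes)
    nCand <- length(candidates)
    labels[seq_len(cfg$networkNodes - nCand)] <- sample(c(others, extra))
    labels[cfg$networkNodes - nCand + seq_len(nCand)] <-
        sample(candidates)
    el <- igraph::as_edgelist(g, names = FALSE)
    edf <- data.frame(from = labels[el[, 1L]], to = labels[el[, 2L]],
                      weight = 1, stringsAsFactors = FALSE)
    if (cfg$seedWiring > 0L) {
        for (p in planted) {
            partners <- sample(training, cfg$seedWiring)
            edf <- rbind(edf, data.frame(from = p, to = partners,
                                         weight = 1,
                                         stringsAsFactors = FALSE))
        }
    }
    key <- paste(pmin(edf$from, edf$to), pmax(edf$from, edf$to))
    edf <- edf[!duplicated(key) & edf$from != edf$to, , drop = FALSE]
    PPINetwork(edf, nodes = labels)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Composes [generateOverlappingSets()],
#' [generateAnnotationCategories()], [generateRegulatorLibraries()] and
#' [generatePPINetwork()] under a single RNG stream seeded from
#' `cfg$rngSeed`, so the bundle is bit-reproducible. The planted
#' effectors are drawn from the intersection of the two sets; the truth
#' manifest records them together with the planted regulators and the
#' planted profile terms.
#'
#' @param cfg A [syntheticConfig()].
#' @return List of class `syntheticBundle` with components `config`,
#'   `aging`, `exercise`, `universe`, `categories`, `regulatorLibraries`,
#'   `network` and `truth` (list: `effectors`, `regulators`, `terms`).
#' @export
generateBundle <- function(cfg = syntheticConfig()) {
    stopifnot(inherits(cfg, "syntheticConfig"))
    sets <- generateOverlappingSets(cfg)  # seeds the RNG
    inter <- intersect(geneIds(sets$aging), geneIds(sets$exercise))
    training <- setdiff(geneIds(sets$aging), inter)
    planted <- if (cfg$plantedEffectors > 0L)
        sample(inter, cfg$plantedEffectors) else character()
    cats <- generateAnnotationCategories(cfg, sets$universe, training,
                                         planted)
    regs <- generateRegulatorLibraries(cfg, sets$universe,
                                       geneIds(sets$aging))
    members <- union(geneIds(sets$aging), geneIds(sets$exercise))
    net <- generatePPINetwork(cfg, sets$universe, members, training,
                              planted, candidates = inter)
    profTerms <- unlist(lapply(cats, function(cat)
        if (categoryKind(cat) == "categorical")
            grep("\\.PROF", unique(unlist(cat@terms, use.names = FALSE)),
                 value = TRUE)
        else character()), use.names = FALSE)
    bundle <- list(config = cfg, aging = sets$aging,
                   exercise = sets$exercise, universe = sets$universe,
                   categories = cats,
                   regulatorLibraries = regs$libraries,
                   network = net,
                   truth = list(effectors = planted,
                                regulators = regs$plantedRegulators,
                                terms = sort(unique(profTerms))))
    class(bundle) <- "syntheticBundle"
    bundle
}

#' Write a synthetic bundle in the pipeline's input formats
#'
#' Writes gene lists for the two input sets, one GMT per categorical
#' annotation category, a TSV matrix for the quantitative category, one
#' GMT per regulator source, the network edge list, the truth manifest
#' (JSON) and a ready-to-run pipeline configuration (JSON) into `dir`.
#'
#' @param bundle Output of [generateBundle()].
#' @param dir Target directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    stopifnot(inherits(bundle, "syntheticBundle"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(aging = file.path(dir, "aging_down.txt"),
               exercise = file.path(dir, "exercise_consensus.txt"))
    writeGeneList(bundle$aging, paths["aging"])
    writeGeneList(bundle$exercise, paths["exercise"])
    catPaths <- character(); catKinds <- character()
    for (cat in bundle$categories) {
        nm <- categoryName(cat)
        if (categoryKind(cat) == "categorical") {
            p <- file.path(dir, paste0("category_", nm, ".gmt"))
            # invert gene -> terms into term -> genes for GMT
            genes <- rep(names(cat@terms), lengths(cat@terms))
            terms <- unlist(cat@terms, use.names = FALSE)
            sets <- split(genes, terms)
            writeGMT(GeneSetLibrary(nm, sets,
                universeSize = length(bundle$universe)), p)
        } else {
            p <- file.path(dir, paste0("category_", nm, ".tsv"))
            df <- data.frame(gene = rownames(cat@profiles),
                             cat@profiles, stringsAsFactors = FALSE)
            utils::write.table(df, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        }
        catPaths <- c(catPaths, p)
        catKinds <- c(catKinds, categoryKind(cat))
    }
    regPaths <- vapply(bundle$regulatorLibraries, function(lib) {
        p <- file.path(dir, paste0("regulators_", libraryName(lib),
                                   ".gmt"))
        writeGMT(lib, p)
        p
    }, character(1L))
    netPath <- file.path(dir, "network.tsv")
    writeEdgeList(bundle$network, netPath)
    univPath <- file.path(dir, "universe.txt")
    writeGeneList(GeneSet("universe", bundle$universe), univPath)
    truthPath <- file.path(dir, "truth.json")
    jsonlite::write_json(bundle$truth, truthPath, auto_unbox = FALSE,
                         pretty = TRUE)
    cfgPath <- file.path(dir, "run_config.json")
    runCfg <- list(
        aging = "aging_down.txt",
        exercise = "exercise_consensus.txt",
        universe = "universe.txt",
        categories = data.frame(path = basename(catPaths),
                                kind = catKinds,
                                stringsAsFactors = FALSE),
        regulator_libraries = basename(regPaths),
        network = "network.tsv",
        universe_size = bundle$config$universeSize,
        alpha = 0.5, beta = 0.5, top_fraction = 0.05,
        beta_sign = "bonus", training_rule = "aging_unique",
        damping = 0.85, tol = 1e-10, max_iter = 1000, k_steps = 3,
        sampling_m = 999, rng_seed = bundle$config$rngSeed)
    jsonlite::write_json(runCfg, cfgPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(paths, categories = catPaths, regulators = regPaths,
                network = netPath, universe = univPath,
                truth = truthPath, config = cfgPath))
}
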