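#' Read an annotation category from disk
#'
#' Categorical categories are GMT libraries (term -> member genes),
#' inverted here into the gene -> term map used by scoring.
#' Quantitative categories are TSV matrices with a `gene` column
#' followed by numeric coordinates.
#'
#' @param path File path.
#' @param kind `"categorical"` or `"quantitative"`.
#' @param categoryName Label; defaults to the file name without
#'   extension.
#' @return An [AnnotationCategory-class].
#' @export
readAnnotationCategory <- function(path,
        kind = c("categorical", "quantitative"), categoryName = NULL) {
    kind <- match.arg(kind)
    if (is.null(categoryName))
        categoryName <- sub("\\.[^.]*$", "",
                            sub("^category_", "", basename(path)))
    if (kind == "categorical") {
        lib <- readGMT(path)
        genes <- unlist(geneSets(lib), use.names = FALSE)
        terms <- rep(names(lib), lengths(geneSets(lib)))
        AnnotationCategory(categoryName, "categorical",
                           terms = split(terms, genes))
    } else {
        df <- utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
        mat <- as.matrix(df[, -1L, drop = FALSE])
        rownames(mat) <- df[[1L]]
        AnnotationCategory(categoryName, "quantitative", profiles = mat)
    }
}

#' Read a pipeline run configuration
#'
#' JSON with the input paths (relative paths resolved against the
#' config's directory) and the tunable parameters; unknown fields are
#' rejected so typos surface early. See [runPipeline()] for the fields.
#'
#' @param path Path to the JSON configuration.
#' @return A named list of class `runConfig`.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop(sprintf("config '%s' does not exist", path))
    cfg <- jsonlite::fromJSON(path)
    known <- c("aging", "exercise", "universe", "categories",
               "regulator_libraries", "network", "universe_size",
               "alpha", "beta", "top_fraction", "beta_sign",
               "training_rule", "similarity_method", "net_score",
               "damping", "tol", "max_iter", "k_steps", "sampling_m",
               "rng_seed")
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    base <- dirname(normalizePath(path))
    resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
    for (f in c("aging", "exercise", "universe", "network"))
        if (!is.null(cfg[[f]])) cfg[[f]] <- resolve(cfg[[f]])
    if (!is.null(cfg$categories))
        cfg$categories$path <- resolve(cfg$categories$path)
    if (!is.null(cfg$regulator_libraries))
        cfg$regulator_libraries <- resolve(cfg$regulator_libraries)
    for (f in c("aging", "exercise", "network"))
        if (!file.exists(cfg[[f]]))
            stop(sprintf("config input '%s' does not exist: %s", f,
                         cfg[[f]]))
    class(cfg) <- c("runConfig", "list")
    cfg
}

## defaults for optional config fields
.configDefaults <- list(alpha = 0.5, beta = 0.5, top_fraction = 0.05,
    beta_sign = "bonus", training_rule = "aging_unique",
    similarity_method = "cosine", net_score = "pagerank",
    damping = 0.85, tol = 1e-10, max_iter = 1000L, k_steps = 3L,
    sampling_m = 999L, universe_size = 20000L, rng_seed = 1L)

.withDefaults <- function(cfg) {
    for (f in names(.configDefaults))
        if (is.null(cfg[[f]])) cfg[[f]] <- .configDefaults[[f]]
    cfg
}

.writeTSV <- function(df, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
}

#' Run the whole prioritization pipeline
#'
#' Executes the stages in order — overlap/partition, library
#' enrichment, regulator rank aggregation, functional prioritization,
#' network prioritization, linear integration — writing each stage's
#' TSV before the next starts, then a JSON run manifest. Progress is
#' logged to stderr with stage-tagged lines; re-running with the same
#' configuration and seed reproduces every output byte-identically.
#'
#' @param config A `runConfig` from [readRunConfig()], or a path to the
#'   JSON file.
#' @param outDir Output directory (created if missing).
#' @return The manifest, invisibly: config echo, package version,
#'   per-stage output row counts, accumulated warnings and the stage
#'   order.
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config))
        config <- readRunConfig(config)
    cfg <- .withDefaults(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    warningsSeen <- character()
    noteWarnings <- function(expr) withCallingHandlers(expr,
        warning = function(w) {
            warningsSeen <<- c(warningsSeen, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    stage <- function(name) message(sprintf("[pipeline] stage: %s", name))
    counts <- list(); stages <- character()

    stage("overlap")
    aging <- suppressMessages(readGeneList(cfg$aging))
    exercise <- suppressMessages(readGeneList(cfg$exercise))
    ov <- noteWarnings(intersectAndPartition(aging, exercise,
        trainingRule = cfg$training_rule))
    regions <- ov$overlap$upsetCounts
    regionGenes <- c(
        paste(geneIds(ov$overlap$uniqueToEach[[1L]]), collapse = ","),
        paste(geneIds(ov$overlap$uniqueToEach[[2L]]), collapse = ","),
        paste(geneIds(ov$overlap$intersection), collapse = ","))
    .writeTSV(data.frame(region = names(regions),
                         count = as.integer(regions),
                         genes = regionGenes,
                         stringsAsFactors = FALSE),
              file.path(outDir, "01_overlap_regions.tsv"))
    jac <- ov$overlap$jaccard
    .writeTSV(data.frame(set = rownames(jac), jac, check.names = FALSE),
              file.path(outDir, "01_jaccard.tsv"))
    writeGeneList(ov$partition$training,
                  file.path(outDir, "01_training.txt"))
    writeGeneList(ov$partition$test, file.path(outDir, "01_test.txt"))
    counts$overlap <- length(regions)
    stages <- c(stages, "overlap")
    if (length(ov$partition$test) == 0L)
        stop("pipeline stopped after overlap: the input sets are ",
             "disjoint, so there are no candidate genes to prioritize")

    universe <- if (!is.null(cfg$universe))
        geneIds(suppressMessages(readGeneList(cfg$universe)))
    else .universeSymbols(cfg$universe_size)

    stage("enrichment")
    enrichRows <- 0L
    if (!is.null(cfg$categories)) {
        catLibs <- cfg$categories[cfg$categories$kind == "categorical", ,
                                  drop = FALSE]
        for (i in seq_len(nrow(catLibs))) {
            lib <- readGMT(catLibs$path[i],
                           universeSize = length(universe))
            for (qry in list(aging, exercise)) {
                res <- noteWarnings(enrichLibrary(qry, lib))
                .writeTSV(res, file.path(outDir, sprintf(
                    "02_enrichment_%s_%s.tsv", setName(qry),
                    libraryName(lib))))
                enrichRows <- enrichRows + nrow(res)
            }
        }
    }
    counts$enrichment <- enrichRows
    stages <- c(stages, "enrichment")

    stage("regulators")
    if (length(cfg$regulator_libraries)) {
        perSource <- list()
        for (p in cfg$regulator_libraries) {
            lib <- readGMT(p, universeSize = length(universe),
                           asRegulator = TRUE)
            perSource[[libraryName(lib)]] <-
                noteWarnings(regulatorEnrichment(aging, lib,
                    universeSize = length(universe)))
        }
        agg <- aggregateMeanRank(perSource)
        .writeTSV(agg, file.path(outDir, "03_regulators.tsv"))
        counts$regulators <- nrow(agg)
    } else counts$regulators <- 0L
    stages <- c(stages, "regulators")

    stage("functional")
    categories <- list()
    if (!is.null(cfg$categories))
        categories <- lapply(seq_len(nrow(cfg$categories)), function(i)
            readAnnotationCategory(cfg$categories$path[i],
                                   cfg$categories$kind[i]))
    if (!length(categories))
        stop("pipeline requires at least one annotation category")
    set.seed(cfg$rng_seed)
    fun <- noteWarnings(functionalScores(ov$partition$test,
        ov$partition$training, categories, universe,
        M = cfg$sampling_m, method = cfg$similarity_method))
    .writeTSV(fun, file.path(outDir, "04_functional.tsv"))
    counts$functional <- nrow(fun)
    stages <- c(stages, "functional")

    stage("network")
    net <- readEdgeList(cfg$network)
    nw <- noteWarnings(networkScores(ov$partition$test,
        ov$partition$training, net, d = cfg$damping, tol = cfg$tol,
        maxIter = cfg$max_iter, kSteps = cfg$k_steps,
        netScore = cfg$net_score))
    .writeTSV(nw, file.path(outDir, "05_network.tsv"))
    counts$network <- nrow(nw)
    stages <- c(stages, "network")

    stage("integration")
    ranking <- noteWarnings(rankCandidates(fun, nw, alpha = cfg$alpha,
        beta = cfg$beta, topFraction = cfg$top_fraction,
        betaSign = cfg$beta_sign))
    .writeTSV(ranking, file.path(outDir, "06_integrated.tsv"))
    counts$integration <- nrow(ranking)
    stages <- c(stages, "integration")

    manifest <- list(
        config = unclass(cfg),
        package_version = as.character(utils::packageVersion("priorank")),
        stage_order = stages,
        row_counts = counts,
        warnings = warningsSeen)
    manifestPath <- file.path(outDir, "run_manifest.json")
    tmp <- paste0(manifestPath, ".tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, manifestPath)
    message("[pipeline] done")
    invisible(manifest)
}
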