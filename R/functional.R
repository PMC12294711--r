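#' Build the training feature profile
#'
#' Summarizes the training (seed) genes in every annotation category:
#' for a categorical category the profile is the term-frequency vector
#' (fraction of training genes carrying each term, in (0, 1]); for a
#' quantitative category it is the coordinate-wise mean vector over the
#' annotated training genes. Categories annotating no training gene are
#' dropped with a warning.
#'
#' @param training A [GeneSet-class] of seed genes.
#' @param categories List of [AnnotationCategory-class] objects.
#' @return Named list (by category) with elements `kind` and either
#'   `weights` (named numeric, categorical) or `mean` (numeric vector,
#'   quantitative).
#' @export
buildTrainingProfile <- function(training, categories) {
    stopifnot(is(training, "GeneSet"), length(training) > 0L)
    tr <- geneIds(training)
    profile <- list()
    for (cat in categories) {
        stopifnot(is(cat, "AnnotationCategory"))
        if (categoryKind(cat) == "categorical") {
            ann <- cat@terms[intersect(tr, names(cat@terms))]
            ann <- ann[lengths(ann) > 0L]
            if (!length(ann)) {
                warning(sprintf(
                    "category '%s' annotates no training gene; dropped",
                    categoryName(cat)))
                next
            }
            tab <- table(unlist(ann, use.names = FALSE))
            w <- as.numeric(tab) / length(ann)
            names(w) <- names(tab)
            profile[[categoryName(cat)]] <-
                list(kind = "categorical", weights = w)
        } else {
            rows <- intersect(tr, rownames(cat@profiles))
            if (!length(rows)) {
                warning(sprintf(
                    "category '%s' annotates no training gene; dropped",
                    categoryName(cat)))
                next
            }
            profile[[categoryName(cat)]] <- list(
                kind = "quantitative",
                mean = colMeans(cat@profiles[rows, , drop = FALSE]))
        }
    }
    profile
}

#' Similarity of one gene to the training profile in one category
#'
#' Categorical categories use a fuzzy match of the gene's binary
#' term-membership vector against the profile's term-frequency weights:
#' either the cosine between the two vectors (default) or the best
#' term-set Jaccard against any single training gene's implied term set
#' (`method = "jaccard"`, using the profile weights as soft membership).
#' Quantitative categories use the Pearson correlation between the
#' gene's vector and the profile mean. Genes not annotated in a
#' category score 0.
#'
#' @param gene A gene symbol.
#' @param profile Output of [buildTrainingProfile()].
#' @param category An [AnnotationCategory-class] present in `profile`.
#' @param method Fuzzy similarity for categorical categories:
#'   `"cosine"` (default) or `"jaccard"`.
#' @return Similarity in \[-1, 1\].
#' @export
categorySimilarity <- function(gene, profile, category,
                               method = c("cosine", "jaccard")) {
    method <- match.arg(method)
    entry <- profile[[categoryName(category)]]
    if (is.null(entry))
        stop(sprintf("category '%s' not in the training profile",
                     categoryName(category)))
    gene <- normalizeSymbols(gene)
    if (categoryKind(category) == "categorical") {
        terms <- category@terms[[gene]]
        .categoricalSimilarity(terms, entry$weights, method)
    } else {
        if (!gene %in% rownames(category@profiles)) return(0)
        .pearsonSimilarity(category@profiles[gene, ], entry$mean)
    }
}

.categoricalSimilarity <- function(terms, weights, method) {
    if (is.null(terms) || !length(terms)) return(0)
    if (method == "cosine") {
        # vector space: union of profile terms and the gene's terms;
        # gene vector binary, profile vector the frequency weights
        space <- union(names(weights), terms)
        g <- as.numeric(space %in% terms)
        w <- weights[space]
        w[is.na(w)] <- 0
        denom <- sqrt(sum(g^2)) * sqrt(sum(w^2))
        if (denom == 0) return(0)
        sum(g * w) / denom
    } else {
        # soft Jaccard: sum of min/ max over the union, with the gene
        # binary and the profile graded by term frequency
        space <- union(names(weights), terms)
        g <- as.numeric(space %in% terms)
        w <- weights[space]
        w[is.na(w)] <- 0
        denom <- sum(pmax(g, w))
        if (denom == 0) return(0)
        sum(pmin(g, w)) / denom
    }
}

.pearsonSimilarity <- function(x, m) {
    if (stats::sd(x) == 0 || stats::sd(m) == 0) {
        warning("zero-variance quantitative vector: similarity set to 0")
        return(0)
    }
    stats::cor(x, m)
}

#' Similarity of every universe gene to the profile in one category
#'
#' Vectorized version of [categorySimilarity()] used for the empirical
#' null and for scoring many candidates at once.
#'
#' @inheritParams categorySimilarity
#' @param genes Character vector of gene symbols.
#' @return Named numeric vector of similarities.
#' @export
categorySimilarities <- function(genes, profile, category,
                                 method = c("cosine", "jaccard")) {
    method <- match.arg(method)
    entry <- profile[[categoryName(category)]]
    if (is.null(entry))
        stop(sprintf("category '%s' not in the training profile",
                     categoryName(category)))
    genes <- normalizeSymbols(genes)
    if (categoryKind(category) == "categorical") {
        sims <- vapply(genes, function(g)
            .categoricalSimilarity(category@terms[[g]], entry$weights,
                                   method), numeric(1L))
    } else {
        sims <- numeric(length(genes))
        names(sims) <- genes
        present <- genes %in% rownames(category@profiles)
        if (any(present)) {
            mat <- category@profiles[genes[present], , drop = FALSE]
            sds <- apply(mat, 1L, stats::sd)
            ok <- sds > 0 & stats::sd(entry$mean) > 0
            if (any(ok))
                sims[genes[present][ok]] <-
                    as.numeric(stats::cor(t(mat[ok, , drop = FALSE]),
                                          entry$mean))
        }
        return(sims)
    }
    names(sims) <- genes
    sims
}

#' Empirical p-value by genome-wide random sampling
#'
#' Corrects a similarity score for annotation-coverage bias: `M` genes
#' are sampled from the universe (training genes excluded), scored in
#' the same category, and the add-one estimator
#' \deqn{p = (1 + \#\{null \ge observed\}) / (M + 1)}
#' is returned, so p is never 0 and is deterministic for a given seed.
#' If the eligible universe is smaller than `M`, sampling is with
#' replacement (with a warning).
#'
#' @param observed Observed similarity of the candidate.
#' @param nullSimilarities Numeric vector of similarities of all
#'   eligible universe genes (null pool) in the same category, as
#'   computed by [categorySimilarities()]; `M` draws are taken from it.
#' @param M Number of random samples (default 999; must be >= 99).
#' @return Empirical p-value in (0, 1].
#' @export
empiricalPValue <- function(observed, nullSimilarities, M = 999L) {
    if (M < 99L)
        stop("M must be at least 99 for a usable empirical p-value")
    pool <- length(nullSimilarities)
    if (pool < 1L)
        stop("empty null pool")
    replace <- pool < M
    if (replace)
        warning("null pool smaller than M: sampling with replacement")
    draws <- nullSimilarities[sample.int(pool, M, replace = replace)]
    (1 + sum(draws >= observed)) / (M + 1)
}

#' Combine per-category p-values with Fisher's inverse chi-square method
#'
#' The statistic \eqn{X = -2 \sum_i \ln p_i} is referred to the upper
#' tail of a chi-square distribution with `2n` degrees of freedom, and
#' the combined score is \eqn{S = 1 - P_{fisher}}: larger for more
#' consistently significant categories. Zero p-values are clamped to
#' the smallest positive double with a warning.
#'
#' @param p Numeric vector of per-category p-values in (0, 1].
#' @return List with `statistic` (X), `pFisher` and `sCombined`.
#' @examples
#' fisherCombine(0.05)$sCombined  # 0.95 exactly
#' @export
fisherCombine <- function(p) {
    if (!length(p))
        stop("need at least one p-value")
    if (any(p < 0 | p > 1 | !is.finite(p)))
        stop("p-values must lie in (0, 1]")
    if (any(p == 0)) {
        warning("p-value of 0 clamped to the smallest positive double")
        p[p == 0] <- .Machine$double.xmin
    }
    X <- -2 * sum(log(p))
    pf <- stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
    list(statistic = X, pFisher = pf, sCombined = 1 - pf)
}

#' Score candidate genes against the training profile
#'
#' The full annotation-based prioritization: builds the training
#' profile, scores each candidate's similarity in every category,
#' converts each similarity to an empirical p-value by random sampling
#' from the universe (per candidate, per category, training genes
#' excluded), and combines the per-category p-values into a single
#' `s_combined` with [fisherCombine()]. Candidates missing from a
#' category get similarity 0 and p = 1 (uninformative) so the number of
#' combined categories is constant across candidates.
#'
#' @param candidates A [GeneSet-class] of test genes.
#' @param training A [GeneSet-class] of seed genes.
#' @param categories List of [AnnotationCategory-class] objects.
#' @param universe Character vector of all genes eligible as random
#'   controls; training genes are removed internally.
#' @param M Random samples per empirical p-value (default 999).
#' @param method Fuzzy similarity method, see [categorySimilarity()].
#' @return data.frame with one row per candidate: `gene`, one
#'   `sim_<category>` and one `p_<category>` column per category,
#'   `fisher_statistic`, `p_fisher`, `s_combined`; sorted descending by
#'   `s_combined` (ties by gene).
#' @export
functionalScores <- function(candidates, training, categories, universe,
                             M = 999L, method = c("cosine", "jaccard")) {
    stopifnot(is(candidates, "GeneSet"), length(candidates) > 0L)
    method <- match.arg(method)
    profile <- buildTrainingProfile(training, categories)
    kept <- Filter(function(cat) categoryName(cat) %in% names(profile),
                   categories)
    if (!length(kept))
        stop("no category annotates any training gene")
    cand <- geneIds(candidates)
    pool <- setdiff(normalizeSymbols(universe), geneIds(training))
    if (!length(pool))
        stop("universe contains no genes outside the training set")
    simCols <- list(); pCols <- list()
    for (cat in kept) {
        cn <- categoryName(cat)
        sims <- categorySimilarities(cand, profile, cat, method)
        nulls <- categorySimilarities(pool, profile, cat, method)
        annotated <- if (categoryKind(cat) == "categorical")
            cand %in% names(cat@terms) & lengths(cat@terms[cand]) > 0L
        else cand %in% rownames(cat@profiles)
        ps <- vapply(seq_along(cand), function(i) {
            if (!annotated[i]) return(1)
            empiricalPValue(sims[i], nulls, M)
        }, numeric(1L))
        simCols[[cn]] <- unname(sims)
        pCols[[cn]] <- ps
    }
    comb <- lapply(seq_along(cand), function(i)
        fisherCombine(vapply(pCols, `[[`, numeric(1L), i)))
    out <- data.frame(gene = cand, stringsAsFactors = FALSE)
    for (cn in names(simCols)) {
        out[[paste0("sim_", cn)]] <- simCols[[cn]]
        out[[paste0("p_", cn)]] <- pCols[[cn]]
    }
    out$fisher_statistic <- vapply(comb, `[[`, numeric(1L), "statistic")
    out$p_fisher <- vapply(comb, `[[`, numeric(1L), "pFisher")
    out$s_combined <- vapply(comb, `[[`, numeric(1L), "sCombined")
    out <- out[order(-out$s_combined, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
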