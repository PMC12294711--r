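#' Per-source regulator enrichment p-values
#'
#' For each regulator in one evidence library, tests whether the query
#' genes over-represent the regulator's targets with the one-sided
#' (enrichment) Fisher exact test on the 2x2 table (in query vs not) x
#' (target vs not). For fixed margins the one-sided exact test equals
#' the hypergeometric upper tail at the observed overlap, which is how
#' it is computed. P-values are Benjamini-Hochberg-corrected within the
#' source, and regulators receive dense integer ranks 1..R by ascending
#' raw p, ties broken by regulator symbol.
#'
#' @param query A [GeneSet-class].
#' @param library A [RegulatorLibrary-class] (or any
#'   [GeneSetLibrary-class] whose terms are regulators).
#' @param universeSize Universe `N` for the 2x2 table; default is the
#'   union of all targets in the source plus the query.
#' @return data.frame with columns `regulator`, `K`, `k`, `p`, `p_bh`,
#'   `rank`, sorted by rank.
#' @export
regulatorEnrichment <- function(query, library, universeSize = NULL) {
    stopifnot(is(query, "GeneSet"), is(library, "GeneSetLibrary"))
    if (!length(query))
        stop("query must be non-empty")
    targets <- geneSets(library)
    empty <- lengths(targets) == 0L
    if (any(empty)) {
        warning(sprintf("skipping regulator(s) with empty target sets: %s",
            paste(names(targets)[empty], collapse = ", ")))
        targets <- targets[!empty]
    }
    if (!length(targets))
        stop("no testable regulators in source '", libraryName(library), "'")
    q <- geneIds(query)
    if (is.null(universeSize))
        universeSize <- length(unique(c(unlist(targets, use.names = FALSE),
                                        q)))
    N <- as.integer(universeSize)
    n <- length(q)
    K <- pmin(lengths(targets), N)
    k <- lengths(lapply(targets, intersect, x = q))
    p <- hypergeomPValue(N, K, n, pmin(k, pmin(K, n)))
    ord <- order(p, names(targets))
    rank <- integer(length(p))
    rank[ord] <- seq_along(p)
    out <- data.frame(
        regulator = names(targets),
        K = as.integer(K), k = as.integer(k),
        p = p, p_bh = adjustPValues(p, "bh"),
        rank = rank,
        stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$rank), , drop = FALSE]
}

#' Aggregate regulator ranks across evidence sources
#'
#' Combines per-source integer ranks into a MeanRank score (arithmetic
#' mean of a regulator's ranks over the sources where it was testable;
#' lower is stronger) and a best scaled rank (minimum over sources of
#' rank divided by the number of regulators tested in that source).
#' Regulators absent from a source contribute nothing to their mean; a
#' fixed penalty rank for missing sources is available instead.
#'
#' @param perSource Named list of data.frames as returned by
#'   [regulatorEnrichment()], one per evidence source.
#' @param missingPenalty `NULL` (default: average only over sources where
#'   the regulator appears) or a numeric rank charged for each source
#'   missing the regulator.
#' @return data.frame with `regulator`, `mean_rank`, `best_scaled_rank`,
#'   `n_sources`, one `rank_<source>` and one `p_bh_<source>` column per
#'   source, sorted ascending by `mean_rank` (ties by regulator symbol).
#' @export
aggregateMeanRank <- function(perSource, missingPenalty = NULL) {
    stopifnot(is.list(perSource), length(perSource) >= 1L)
    if (is.null(names(perSource)) || any(!nzchar(names(perSource))))
        stop("'perSource' must be a named list (one name per source)")
    regs <- sort(unique(unlist(lapply(perSource, `[[`, "regulator"))))
    if (!length(regs))
        stop("no regulators ranked in any source")
    nsrc <- length(perSource)
    rankMat <- matrix(NA_real_, length(regs), nsrc,
                      dimnames = list(regs, names(perSource)))
    pMat <- rankMat
    sizes <- numeric(nsrc)
    for (j in seq_len(nsrc)) {
        df <- perSource[[j]]
        rankMat[df$regulator, j] <- df$rank
        pMat[df$regulator, j] <- df$p_bh
        sizes[j] <- nrow(df)
    }
    scaled <- sweep(rankMat, 2L, sizes, "/")
    bestScaled <- apply(scaled, 1L, min, na.rm = TRUE)
    if (is.null(missingPenalty)) {
        meanRank <- rowMeans(rankMat, na.rm = TRUE)
    } else {
        filled <- rankMat
        filled[is.na(filled)] <- as.numeric(missingPenalty)
        meanRank <- rowMeans(filled)
    }
    out <- data.frame(
        regulator = regs,
        mean_rank = meanRank,
        best_scaled_rank = bestScaled,
        n_sources = rowSums(!is.na(rankMat)),
        stringsAsFactors = FALSE, row.names = NULL)
    for (j in seq_len(nsrc)) {
        out[[paste0("rank_", names(perSource)[j])]] <- rankMat[, j]
        out[[paste0("p_bh_", names(perSource)[j])]] <- pMat[, j]
    }
    out[order(out$mean_rank, out$regulator), , drop = FALSE]
}
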