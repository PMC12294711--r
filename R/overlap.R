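#' Intersect two gene sets and build the training/test partition
#'
#' The candidate (test) genes are the intersection of the two inputs —
#' here, genes both downregulated with cardiac aging and responsive to
#' endurance training. The training (seed) genes default to the genes
#' unique to the aging set (`trainingRule = "aging_unique"`), matching
#' the partition used to seed prioritization; the symmetric difference
#' of both sets is available as an alternative rule.
#'
#' @param aging A [GeneSet-class] (first input, e.g. aging-downregulated).
#' @param exercise A [GeneSet-class] (second input, e.g. exercise-responsive).
#' @param trainingRule `"aging_unique"` (default: genes in `aging` only)
#'   or `"symmetric_difference"` (genes unique to either set).
#' @return A list with components:
#'   \describe{
#'     \item{overlap}{list with `setNames`, `intersection` (GeneSet),
#'       `uniqueToEach` (list of GeneSet), `upsetCounts`, `jaccard`.}
#'     \item{partition}{list with `training` and `test` GeneSets.}
#'   }
#' @examples
#' a <- GeneSet("A", c("G1", "G2", "G3"))
#' b <- GeneSet("B", c("G3", "G4"))
#' res <- intersectAndPartition(a, b)
#' geneIds(res$partition$test)  # "G3"
#' @export
intersectAndPartition <- function(aging, exercise,
        trainingRule = c("aging_unique", "symmetric_difference")) {
    stopifnot(is(aging, "GeneSet"), is(exercise, "GeneSet"))
    trainingRule <- match.arg(trainingRule)
    if (!length(aging) || !length(exercise))
        stop("both input sets must be non-empty")
    a <- geneIds(aging); b <- geneIds(exercise)
    inter <- intersect(a, b)
    if (!length(inter))
        warning("the two sets are disjoint: empty test set")
    if (setequal(a, b))
        warning("the two sets are identical: empty training set under ",
                "either rule")
    training <- switch(trainingRule,
        aging_unique = setdiff(a, inter),
        symmetric_difference = c(setdiff(a, inter), setdiff(b, inter)))
    sets <- list(aging, exercise)
    overlap <- list(
        setNames = c(setName(aging), setName(exercise)),
        intersection = GeneSet(
            paste0(setName(aging), "&", setName(exercise)), inter),
        uniqueToEach = list(
            GeneSet(paste0(setName(aging), ".only"), setdiff(a, b)),
            GeneSet(paste0(setName(exercise), ".only"), setdiff(b, a))),
        upsetCounts = upsetCounts(sets),
        jaccard = jaccardMatrix(sets)$matrix)
    partition <- list(
        training = GeneSet("training", training),
        test = GeneSet("test", inter))
    list(overlap = overlap, partition = partition)
}

#' Pairwise Jaccard similarity matrix
#'
#' Computes `J(i, j) = |Si ∩ Sj| / |Si ∪ Sj|` for every pair of sets and
#' an average-linkage hierarchical clustering order of the sets on the
#' distance `1 - J` (ties broken by input order, as `hclust` does).
#'
#' @param sets A list of two or more [GeneSet-class] objects.
#' @return List with `matrix` (symmetric, unit diagonal) and `order`
#'   (integer clustering order of the sets).
#' @export
jaccardMatrix <- function(sets) {
    stopifnot(length(sets) >= 2L, all(vapply(sets, is, TRUE, "GeneSet")))
    if (any(vapply(sets, length, 1L) == 0L))
        warning("empty set present: its Jaccard entries are 0")
    n <- length(sets)
    ids <- lapply(sets, geneIds)
    m <- diag(1, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        u <- length(union(ids[[i]], ids[[j]]))
        m[i, j] <- m[j, i] <-
            if (u == 0L) 0 else length(intersect(ids[[i]], ids[[j]])) / u
    }
    labs <- vapply(sets, setName, character(1L))
    dimnames(m) <- list(labs, labs)
    ord <- if (n > 2L)
        stats::hclust(stats::as.dist(1 - m), method = "average")$order
    else seq_len(n)
    list(matrix = m, order = ord)
}

#' Membership-pattern (UpSet) counts
#'
#' Counts the genes in every non-empty membership pattern over the input
#' sets. Region labels join set names with `&` for genes shared by those
#' sets only (e.g. `"A"`, `"B"`, `"A&B"`). Counts sum to the union size.
#'
#' @param sets A list of two or more [GeneSet-class] objects.
#' @return Named integer vector of region counts, covering all
#'   \eqn{2^k - 1} membership patterns (zero counts included).
#' @export
upsetCounts <- function(sets) {
    stopifnot(length(sets) >= 2L, all(vapply(sets, is, TRUE, "GeneSet")))
    labs <- vapply(sets, setName, character(1L))
    universe <- unique(unlist(lapply(sets, geneIds)))
    membership <- vapply(sets, function(s) universe %in% geneIds(s),
                         logical(length(universe)))
    if (length(universe) == 1L)
        membership <- matrix(membership, nrow = 1L)
    k <- length(sets)
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
    counts <- integer(nrow(patterns))
    names(counts) <- apply(patterns, 1L, function(p)
        paste(labs[as.logical(p)], collapse = "&"))
    if (length(universe)) {
        key <- apply(membership, 1L, function(p)
            paste(labs[p], collapse = "&"))
        tab <- table(key)
        counts[names(tab)] <- as.integer(tab)
    }
    counts
}
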