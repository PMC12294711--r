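#' Hypergeometric over-representation p-value
#'
#' Probability of observing `k` or more genes from a size-`n` query in a
#' pathway of `K` genes, when drawing without replacement from a
#' universe of `N` genes:
#' \deqn{p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n).}
#' Computed through the upper-tail survival function (never as
#' `1 - CDF`), so small p-values keep full relative precision.
#'
#' @param N Universe size (total genes considered).
#' @param K Pathway/term size.
#' @param n Query size.
#' @param k Overlap count.
#' @return The upper-tail probability, in (0, 1]. Vectorized over all
#'   arguments.
#' @examples
#' hypergeomPValue(10, 5, 5, 5)  # 1/choose(10,5) = 1/252
#' @export
hypergeomPValue <- function(N, K, n, k) {
    if (any(N < 0 | K < 0 | n < 0 | k < 0))
        stop("all arguments must be non-negative")
    if (any(K > N) || any(n > N))
        stop("K and n must not exceed the universe size N")
    if (any(k > pmin(K, n)))
        stop("k must not exceed min(K, n)")
    # P(X >= k) = P(X > k - 1); k = 0 gives 1 exactly
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Over-representation test of a query set against a library
#'
#' One hypergeometric record per term: overlap `k` is counted against
#' normalized symbols, the raw upper-tail p-value is Bonferroni- and
#' Benjamini-Hochberg-corrected across the library's terms, and records
#' are ranked by ascending p (descending `-log10(p)`), ties broken by
#' descending `k` then term identifier.
#'
#' @param query A [GeneSet-class].
#' @param library A [GeneSetLibrary-class].
#' @param universeSize Optional override of the library's universe `N`
#'   (configuration precedence: explicit argument > library field).
#' @return A data.frame with columns `term`, `N`, `K`, `n`, `k`, `p`,
#'   `p_bonferroni`, `p_bh`, `neglog10_p`, `member_genes` (comma-joined
#'   overlapping symbols), sorted by significance.
#' @export
enrichLibrary <- function(query, library, universeSize = NULL) {
    stopifnot(is(query, "GeneSet"), is(library, "GeneSetLibrary"))
    if (!length(query) || !length(library))
        stop("query and library must be non-empty")
    N <- if (is.null(universeSize)) universeSize(library)
         else as.integer(universeSize)
    q <- geneIds(query)
    n <- length(q)
    if (n > N)
        stop("query is larger than the universe N")
    terms <- names(library)
    K <- pmin(lengths(geneSets(library)), N)
    hits <- lapply(geneSets(library), intersect, x = q)
    k <- lengths(hits)
    if (all(k == 0L))
        warning("query shares no genes with any library term")
    p <- hypergeomPValue(N, K, n, k)
    out <- data.frame(
        term = terms,
        N = N, K = as.integer(K), n = n, k = as.integer(k),
        p = p,
        p_bonferroni = adjustPValues(p, "bonferroni"),
        p_bh = adjustPValues(p, "bh"),
        neglog10_p = -log10(p),
        member_genes = vapply(hits, paste, character(1L), collapse = ","),
        stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$p, -out$k, out$term), , drop = FALSE]
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()]: Bonferroni is `min(1, m * p)`;
#' Benjamini-Hochberg is the step-up adjustment (monotone in rank,
#' capped at 1, returned in input order).
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values in the input order.
#' @export
adjustPValues <- function(p, method = c("bh", "bonferroni")) {
    method <- match.arg(method)
    if (!length(p)) return(numeric())
    if (any(p <= 0 | p > 1 | !is.finite(p)))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}
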