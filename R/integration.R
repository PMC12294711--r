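#' Min-max scale a score vector over the candidate set
#'
#' `(x - min) / (max - min)`, mapping the candidates' scores onto
#' \[0, 1\]. Scaling is over the candidate set only, not the genome. A
#' constant input (including a single candidate) maps to all zeros with
#' a warning.
#'
#' @param x Numeric vector of scores.
#' @return Scaled scores in \[0, 1\].
#' @export
minmaxScale <- function(x) {
    if (!length(x))
        stop("cannot scale an empty score vector")
    rng <- range(x)
    if (rng[1] == rng[2]) {
        if (length(x) > 1L)
            warning("constant scores: scaled values all 0")
        return(rep(0, length(x)))
    }
    (x - rng[1]) / (rng[2] - rng[1])
}

#' Linear integration of scaled functional and network scores
#'
#' \deqn{FinalScore = \alpha\,Gene_{scaled} + (1-\alpha)\,Net_{scaled}
#'       + \beta\,IsTopNet}
#' with `alpha = 0.5` weighting the two evidence channels equally and
#' `beta = 0.5` the weight of the top-network-tier indicator. The
#' indicator term is added by default (as the formula states); setting
#' `betaSign = "penalty"` subtracts it instead, the alternative reading
#' of a hub-gene penalty.
#'
#' @param geneScaled Scaled functional score in \[0, 1\].
#' @param netScaled Scaled network score in \[0, 1\].
#' @param isTopNet Indicator in \{0, 1\}: does the gene fall in the top
#'   fraction of network scores?
#' @param alpha Weight of the functional channel, in \[0, 1\];
#'   default 0.5.
#' @param beta Weight of the indicator, >= 0; default 0.5.
#' @param betaSign `"bonus"` (default, add) or `"penalty"` (subtract).
#' @return The final score (vectorized).
#' @examples
#' finalScore(0.8, 0.4, 0)  # 0.6
#' @export
finalScore <- function(geneScaled, netScaled, isTopNet, alpha = 0.5,
                       beta = 0.5, betaSign = c("bonus", "penalty")) {
    betaSign <- match.arg(betaSign)
    stopifnot(alpha >= 0, alpha <= 1, beta >= 0)
    if (!all(isTopNet %in% c(0, 1)))
        stop("isTopNet must be 0 or 1")
    if (any(geneScaled < 0 | geneScaled > 1 | netScaled < 0 | netScaled > 1))
        stop("scaled scores must lie in [0, 1]")
    sgn <- if (betaSign == "bonus") 1 else -1
    alpha * geneScaled + (1 - alpha) * netScaled + sgn * beta * isTopNet
}

#' Rank candidates by integrated functional and network evidence
#'
#' Min-max-scales the functional (`s_combined`) and network
#' (`net_score`) scores over the candidate set, flags the
#' `ceiling(topFraction * m)` candidates with the highest raw network
#' scores (`is_top_net`, ties by descending network score then symbol),
#' computes [finalScore()] for each candidate, and ranks descending
#' (ties by `gene_scaled` then symbol; ranks are dense 1..m).
#'
#' @param functional data.frame from [functionalScores()] (columns
#'   `gene`, `s_combined`).
#' @param network data.frame from [networkScores()] (columns `gene`,
#'   `net_score`).
#' @param alpha,beta,betaSign See [finalScore()].
#' @param topFraction Fraction of candidates flagged `is_top_net`
#'   (default 0.05).
#' @return data.frame with columns `gene`, `gene_scaled`, `net_scaled`,
#'   `is_top_net`, `final_score`, `rank`, sorted by rank.
#' @export
rankCandidates <- function(functional, network, alpha = 0.5, beta = 0.5,
                           topFraction = 0.05,
                           betaSign = c("bonus", "penalty")) {
    betaSign <- match.arg(betaSign)
    stopifnot(topFraction > 0, topFraction <= 1)
    if (!setequal(functional$gene, network$gene)) {
        onlyF <- setdiff(functional$gene, network$gene)
        onlyN <- setdiff(network$gene, functional$gene)
        stop(sprintf(
            "candidate mismatch between inputs%s%s",
            if (length(onlyF)) paste0("; functional only: ",
                paste(onlyF, collapse = ", ")) else "",
            if (length(onlyN)) paste0("; network only: ",
                paste(onlyN, collapse = ", ")) else ""))
    }
    genes <- sort(functional$gene)
    fs <- functional$s_combined[match(genes, functional$gene)]
    ns <- network$net_score[match(genes, network$gene)]
    m <- length(genes)
    nTop <- ceiling(topFraction * m)
    topOrder <- order(-ns, genes)
    isTop <- integer(m)
    isTop[topOrder[seq_len(nTop)]] <- 1L
    geneScaled <- minmaxScale(fs)
    netScaled <- minmaxScale(ns)
    final <- finalScore(geneScaled, netScaled, isTop, alpha = alpha,
                        beta = beta, betaSign = betaSign)
    out <- data.frame(
        gene = genes,
        gene_scaled = geneScaled,
        net_scaled = netScaled,
        is_top_net = isTop,
        final_score = final,
        stringsAsFactors = FALSE, row.names = NULL)
    ord <- order(-out$final_score, -out$gene_scaled, out$gene)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(m)
    rownames(out) <- NULL
    out
}
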