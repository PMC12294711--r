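#' Normalize gene symbols
#'
#' Trims surrounding whitespace and uppercases each symbol so that set
#' operations on symbols from different sources agree. Normalization is
#' idempotent. Symbol-to-identifier mapping (Entrez, Ensembl) and
#' cross-species orthology are deliberately out of scope: inputs are
#' expected to already use one nomenclature.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalizeSymbols(c("smpx ", "Ryr2"))  # "SMPX" "RYR2"
#' @export
normalizeSymbols <- function(x) {
    if (!is.character(x))
        stop("gene symbols must be character")
    out <- toupper(trimws(x))
    bad <- which(is.na(out) | !nzchar(out))
    if (length(bad))
        stop(sprintf("empty or missing gene symbol at position(s): %s",
                     paste(utils::head(bad, 5L), collapse = ", ")))
    if (any(grepl("[\t\n]", out)))
        stop("gene symbols must not contain tabs or newlines")
    out
}

#' Read a plain gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are
#' skipped; duplicates (after normalization) are collapsed. The number
#' of usable input lines versus unique symbols kept is reported via
#' `message()`.
#'
#' @param path Path to the text file.
#' @param setName Label for the resulting set; defaults to the file name
#'   without extension.
#' @return A [GeneSet-class].
#' @export
readGeneList <- function(path, setName = NULL) {
    if (!file.exists(path))
        stop(sprintf("cannot read gene list: '%s' does not exist", path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        stop(sprintf("gene list '%s' contains no usable lines", path))
    if (is.null(setName))
        setName <- sub("\\.[^.]*$", "", basename(path))
    gs <- GeneSet(setName, lines)
    message(sprintf("[geneset_io] %s: %d line(s) -> %d unique symbol(s)",
                    basename(path), length(lines), length(gs)))
    gs
}

#' Write a plain gene list
#'
#' One symbol per line, UTF-8, Unix newlines.
#'
#' @param x A [GeneSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(x, path) {
    stopifnot(is(x, "GeneSet"))
    .writeUnixLines(geneIds(x), path)
    invisible(path)
}

## write UTF-8 text with Unix newlines regardless of platform
.writeUnixLines <- function(lines, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
}

#' Read a GMT gene-set library
#'
#' Parses the Broad/MSigDB tab-separated convention: one term per line,
#' fields `term`, `description`, then member symbols. The description
#' column is ignored. Members are normalized and de-duplicated.
#'
#' @param path Path to the GMT file.
#' @param libraryName Label; defaults to the file name without extension.
#' @param universeSize Universe size `N` attached to the library
#'   (default 20000).
#' @param asRegulator If `TRUE` return a [RegulatorLibrary-class]
#'   (terms read as regulators).
#' @return A [GeneSetLibrary-class] (or subclass).
#' @export
readGMT <- function(path, libraryName = NULL, universeSize = 20000L,
                    asRegulator = FALSE) {
    if (!file.exists(path))
        stop(sprintf("cannot read GMT: '%s' does not exist", path))
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        stop(sprintf("GMT '%s' is empty", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("GMT '%s': line %d has fewer than 3 fields",
                     path, short[1L]))
    terms <- vapply(fields, `[[`, character(1L), 1L)
    if (anyDuplicated(terms))
        stop(sprintf("GMT '%s': duplicate term identifier(s): %s", path,
             paste(unique(terms[duplicated(terms)]), collapse = ", ")))
    sets <- lapply(fields, function(f) f[-c(1L, 2L)])
    names(sets) <- terms
    if (is.null(libraryName))
        libraryName <- sub("\\.[^.]*$", "", basename(path))
    ctor <- if (asRegulator) RegulatorLibrary else GeneSetLibrary
    ctor(libraryName, sets, universeSize = universeSize)
}

#' Write a GMT gene-set library
#'
#' Emits the 3+-column GMT dialect with `na` in the description column,
#' UTF-8, Unix newlines. `readGMT(writeGMT(lib))` reproduces the library
#' (up to symbol normalization, already applied on construction).
#'
#' @param x A [GeneSetLibrary-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "GeneSetLibrary"))
    lines <- vapply(names(x), function(term) {
        paste(c(term, "na", x[[term]]), collapse = "\t")
    }, character(1L))
    .writeUnixLines(lines, path)
    invisible(path)
}

#' Read a PPI edge list
#'
#' Tab-separated columns: interactor A, interactor B and an optional
#' confidence weight in (0, 1]. Lines starting with `#` are skipped.
#'
#' @param path Path to the edge-list TSV.
#' @return A [PPINetwork-class].
#' @export
readEdgeList <- function(path) {
    if (!file.exists(path))
        stop(sprintf("cannot read edge list: '%s' does not exist", path))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    PPINetwork(df)
}

#' Write a PPI edge list
#'
#' @param x A [PPINetwork-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
    stopifnot(is(x, "PPINetwork"))
    e <- edges(x)
    lines <- sprintf("%s\t%s\t%s", e$from, e$to,
                     formatC(e$weight, format = "fg"))
    .writeUnixLines(lines, path)
    invisible(path)
}
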