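#' Read an omics value matrix from a delimited file
#'
#' Parses the pipeline's TSV/CSV dialect: the first column holds feature ids
#' (`"GENE"` or `"GENE|SITE"`), remaining column headers encode sample keys
#' as `CONDITION_T<hours>h_R<rep>`. Empty cells and `"NA"` are missing values
#' (never zero). Gene symbols are upper-cased on read.
#'
#' @param path file path.
#' @param layer omics layer tag; see [layerLevels()].
#' @param scale value scale tag (`LOG2_LFQ`, `LOG2_SILAC_RATIO`, `VST`).
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return An [OmicsMatrix-class]; duplicate feature ids, malformed header
#'   tokens and incomplete condition/time/replicate grids are hard errors.
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path, layer, scale, sep = "\t") {
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (ncol(df) < 2L) stop("matrix file must have a feature column and samples")
    ids <- toupper(sub("\\|", "\01", as.character(df[[1L]])))
    ids <- sub("\01", "|", ids, fixed = TRUE)
    if (anyDuplicated(ids))
        stop("duplicate feature id: ", ids[duplicated(ids)][1L])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    OmicsMatrix(vals, layer = layer, scale = scale)
}

#' Write an omics matrix in the delimited dialect
#'
#' Values are written with 17 significant digits so that a write/read round
#' trip reproduces present values bit-identically and preserves the
#' missingness pattern.
#'
#' @param m an [OmicsMatrix-class].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(m, path, sep = "\t") {
    vals <- omicsValues(m)
    txt <- matrix(vapply(vals, function(x)
        if (is.na(x)) "NA" else sprintf("%.17g", x), ""), nrow = nrow(vals))
    out <- cbind(feature = rownames(vals), txt)
    colnames(out) <- c("feature", colnames(vals))
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a scored interaction edge table
#'
#' Three-column TSV `(node_a, node_b, combined_score)` with scores in
#' \[0, 1\] (STRING-style combined scores). Self-edges are dropped.
#'
#' @param path file path.
#' @return `data.frame` with columns `node_a`, `node_b`, `combined_score`.
#' @export
readEdgeTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("node_a", "node_b", "combined_score")
    df$node_a <- toupper(df$node_a)
    df$node_b <- toupper(df$node_b)
    validateEdgeTable(df)
}

#' @rdname readEdgeTable
#' @param edges a candidate edge `data.frame`.
#' @export
validateEdgeTable <- function(edges) {
    if (any(edges$combined_score < 0 | edges$combined_score > 1))
        stop("combined_score outside [0,1]")
    edges[edges$node_a != edges$node_b, , drop = FALSE]
}

#' Read a gene-keyword annotation table
#'
#' Two-column TSV `(gene, keyword)` carrying Uniprot-style keywords and
#' GO cellular-component terms used by the receptor/ligand rules.
#'
#' @param path file path.
#' @return `data.frame` with columns `gene`, `keyword`.
#' @export
readKeywordTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene", "keyword")
    df$gene <- toupper(df$gene)
    df
}

#' Read a one-column gene registry (e.g. a cytokine registry)
#' @param path file path; one gene symbol per line, optional header `gene`.
#' @return character vector of upper-cased gene symbols.
#' @export
readGeneRegistry <- function(path) {
    x <- readLines(path)
    x <- trimws(x[nzchar(trimws(x))])
    x <- x[tolower(x) != "gene"]
    toupper(x)
}
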