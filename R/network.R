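#' Filter interaction edges by combined score
#'
#' Keeps edges with `combined_score` strictly above `minScore` (high
#' confidence defaults to 0.95) and collapses symmetric duplicates, keeping
#' the maximum score per unordered pair.
#'
#' @param edges edge `data.frame` (`node_a`, `node_b`, `combined_score`).
#' @param minScore strict lower bound on the score.
#' @return filtered edge `data.frame` (a subset of the input; idempotent).
#' @export
filterEdges <- function(edges, minScore = 0.95) {
    edges <- validateEdgeTable(edges)
    edges <- edges[edges$combined_score > minScore, , drop = FALSE]
    if (!nrow(edges)) return(edges)
    key <- ifelse(edges$node_a < edges$node_b,
                  paste(edges$node_a, edges$node_b),
                  paste(edges$node_b, edges$node_a))
    keep <- unlist(lapply(split(seq_len(nrow(edges)), key), function(i)
        i[which.max(edges$combined_score[i])]), use.names = FALSE)
    out <- edges[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## modal class with ties broken by the fixed class order
.modalClass <- function(cls) {
    tab <- table(factor(cls, levels = .FINAL_CLASSES))
    names(tab)[which.max(tab)]
}

#' Collapse feature-level classes to gene level
#'
#' One row per gene; per-layer classes are retained as separate columns
#' (`class_<layer>`) and a primary class is chosen by the fixed layer
#' priority transcript > protein > phospho > secretome. Multiple features of
#' one gene within a layer (e.g. phosphosites) are summarized by their modal
#' class.
#'
#' @param classes feature-level classification table from
#'   [classifyResponses()] (columns `gene`, `layer`, `final`).
#' @return gene-level `data.frame` with `gene`, `class_<layer>` columns and
#'   `primary_class`.
#' @export
collapseFeaturesToGenes <- function(classes) {
    priority <- c("transcript", "protein", "phospho", "secretome")
    genes <- unique(classes$gene)
    out <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (ly in priority)
        out[[paste0("class_", ly)]] <- vapply(genes, function(g) {
            cls <- classes$final[classes$gene == g & classes$layer == ly]
            if (!length(cls)) NA_character_ else .modalClass(cls)
        }, "")
    out$primary_class <- apply(out[, paste0("class_", priority),
                                   drop = FALSE], 1L, function(r) {
        r <- r[!is.na(r)]
        if (length(r)) r[[1L]] else NA_character_
    })
    rownames(out) <- NULL
    out
}

#' Per-hub response-class composition
#'
#' For each user-supplied interaction hub, the fraction of member genes in
#' each response class (the donut-plot summary). Fractions sum to 1 per hub;
#' hubs without any classified gene are skipped with a warning.
#'
#' @param geneClasses gene-level table from [collapseFeaturesToGenes()].
#' @param hubs `data.frame` with columns `gene`, `hub`.
#' @return long `data.frame` with `hub`, `class`, `n`, `fraction`.
#' @export
hubComposition <- function(geneClasses, hubs) {
    out <- list()
    for (h in unique(hubs$hub)) {
        members <- hubs$gene[hubs$hub == h]
        cls <- geneClasses$primary_class[geneClasses$gene %in% members]
        cls <- cls[!is.na(cls)]
        if (!length(cls)) {
            warning("hub without classified genes skipped: ", h)
            next
        }
        tab <- table(factor(cls, levels = .FINAL_CLASSES))
        out[[h]] <- data.frame(hub = h, class = names(tab),
                               n = as.integer(tab),
                               fraction = as.numeric(tab) / length(cls),
                               stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(hub = character(), class = character(),
                          n = integer(), fraction = numeric())
    rownames(res) <- NULL
    res
}

.RECEPTOR_KEYWORDS <- c("extracellular", "GPI-anchor")
.LIGAND_KEYWORDS <- c("secreted", "signal",
                      "extracellular space", "extracellular region")

#' Receptor and ligand flags from keyword annotations and interactions
#'
#' A gene is a receptor if it carries the "extracellular" keyword or the
#' "GPI-anchor" topology annotation. A gene is a ligand if it carries a
#' "secreted"/"signal" keyword or an "extracellular space"/"extracellular
#' region" term AND interacts with a receptor at combined score strictly
#' above `cfg@ligandScoreMin` (0.4 by default). Both flags may co-occur.
#'
#' @param keywords annotation `data.frame` (`gene`, `keyword`).
#' @param edges scored edge `data.frame`.
#' @param cfg a [ThresholdConfig-class].
#' @return `data.frame` with `gene`, `receptor`, `ligand`, `flag` in
#'   \{receptor, ligand, both, neither\}.
#' @export
classifyReceptorsLigands <- function(keywords, edges,
                                     cfg = thresholdConfig()) {
    edges <- validateEdgeTable(edges)
    genes <- sort(unique(c(keywords$gene, edges$node_a, edges$node_b)))
    hasKw <- function(g, kws) any(keywords$keyword[keywords$gene == g] %in% kws)
    receptor <- vapply(genes, hasKw, TRUE, kws = .RECEPTOR_KEYWORDS)
    recSet <- genes[receptor]
    strong <- edges[edges$combined_score > cfg@ligandScoreMin, , drop = FALSE]
    touchesReceptor <- function(g)
        any(strong$node_b[strong$node_a == g] %in% recSet) ||
        any(strong$node_a[strong$node_b == g] %in% recSet)
    ligand <- vapply(genes, hasKw, TRUE, kws = .LIGAND_KEYWORDS) &
        vapply(genes, touchesReceptor, TRUE)
    flag <- ifelse(receptor & ligand, "both",
            ifelse(receptor, "receptor",
            ifelse(ligand, "ligand", "neither")))
    data.frame(gene = genes, receptor = receptor, ligand = ligand,
               flag = flag, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlay a cytokine registry on secretome results
#'
#' Restricts the secretome differential table to registry genes and reports,
#' per gene, the set of stimuli with significant induction (positive log2FC)
#' at 24 h, plus a constitutive flag for genes detected but never
#' significant under any stimulus or timepoint.
#'
#' @param secretomeResults secretome `DifferentialResult` table.
#' @param registry character vector of registry gene symbols.
#' @return `data.frame` with `gene`, `pattern` (comma-separated stimuli),
#'   `constitutive`; empty with a warning when no registry gene is detected.
#' @export
cytokineOverlay <- function(secretomeResults, registry) {
    res <- secretomeResults
    res$gene <- toupper(sub("\\|.*$", "", res$feature))
    res <- res[res$gene %in% toupper(registry), , drop = FALSE]
    if (!nrow(res)) {
        warning("no registry gene detected in the secretome results")
        return(data.frame(gene = character(), pattern = character(),
                          constitutive = logical()))
    }
    genes <- sort(unique(res$gene))
    rows <- lapply(genes, function(g) {
        sub <- res[res$gene == g, , drop = FALSE]
        induced <- sort(unique(sub$condition[sub$time_h == 24 &
                                             sub$significant &
                                             sub$log2fc > 0]))
        data.frame(gene = g, pattern = paste(induced, collapse = ","),
                   constitutive = !any(sub$significant),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
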