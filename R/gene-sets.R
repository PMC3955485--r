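#' Construct a gene-set (pathway) collection
#'
#' A tibble-backed collection of pathways, each with an id (KEGG-style, e.g.
#' `"map00020"`), a display name, a classification string (e.g.
#' `"Metabolism; carbohydrate metabolism"`) and a set of member gene symbols.
#'
#' @param pathway_id Character vector of unique pathway ids.
#' @param name Character vector of pathway names.
#' @param classification Character vector of classification labels (may be
#'   empty strings).
#' @param genes List of character vectors of member gene symbols; duplicates
#'   within a set are removed.
#' @return A `gene_set_collection`, a tibble with columns `pathway_id`,
#'   `name`, `classification`, `genes` (list-column) and `n_genes`.
#' @export
#' @examples
#' gsc <- gene_set_collection(
#'   pathway_id = "map00020",
#'   name = "Citrate cycle (TCA cycle)",
#'   classification = "Metabolism",
#'   genes = list(c("IDH1", "IDH2", "FH")))
#' pathway_universe(gsc)
gene_set_collection <- function(pathway_id, name, classification, genes) {
  pathway_id <- as.character(pathway_id)
  if (anyDuplicated(pathway_id)) {
    dup <- unique(pathway_id[duplicated(pathway_id)])
    pcx_abort(paste0("Duplicate pathway id(s): ", paste(dup, collapse = ", ")),
              "pcx_duplicate_pathway")
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    pcx_abort(paste0("Empty gene set(s): ",
                     paste(pathway_id[empty], collapse = ", ")),
              "pcx_empty_gene_set")
  }
  out <- tibble::tibble(
    pathway_id = pathway_id,
    name = as.character(name),
    classification = as.character(classification),
    genes = genes,
    n_genes = lengths(genes)
  )
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Pathway-annotated gene universe
#'
#' The union of all member gene symbols across the collection — the universe
#' used to restrict datasets and as the enrichment background.
#'
#' @param gsc A [gene_set_collection()].
#' @return Sorted character vector of gene symbols.
#' @export
pathway_universe <- function(gsc) {
  sort(unique(unlist(gsc$genes, use.names = FALSE)))
}
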