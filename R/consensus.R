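#' Intersect cross-cohort pathway sets with the enrichment set
#'
#' A pathway is a consensus pathway iff it is significant with one direction
#' in every cohort's permutation analysis (member of `gsea_up` or
#' `gsea_down`), significantly enriched in the meta-analysis gene list, and
#' the two directions agree. Direction conflicts are logged and excluded.
#' Key genes are the pathway's overlapping meta-significant genes, sorted by
#' combined p ascending.
#'
#' @param gsea_up,gsea_down Character vectors from [common_pathways()].
#' @param enriched A directed `enrichment_result` tibble (after
#'   [assign_direction()] and [significant_enrichment()]).
#' @param gene_alpha Combined-p cutoff defining key genes (default 0.05,
#'   strict `<`).
#' @return A tibble of class `consensus_result`, ordered by `pathway_id`,
#'   with columns `pathway_id`, `name`, `classification`, `direction`,
#'   `p_enrich`, `n_key_genes`, `key_genes` (list-column of tibbles `gene`,
#'   `p_combined`). An empty consensus is a valid outcome.
#' @export
intersect_pathways <- function(gsea_up, gsea_down, enriched,
                               gene_alpha = 0.05) {
  gsea_dir <- c(stats::setNames(rep("UP", length(gsea_up)), gsea_up),
                stats::setNames(rep("DOWN", length(gsea_down)), gsea_down))
  in_both <- enriched$pathway_id %in% names(gsea_dir)
  agree <- in_both & enriched$direction == gsea_dir[enriched$pathway_id]
  conflict <- in_both & !agree
  if (any(conflict)) {
    rlang::inform(paste0("Direction conflict, pathway(s) excluded from consensus: ",
                         paste(enriched$pathway_id[conflict], collapse = ", ")))
  }
  hits <- enriched[agree, , drop = FALSE]
  key <- purrr::map(hits$member_genes, function(tb) {
    kept <- tb[!is.na(tb$p_combined) & tb$p_combined < gene_alpha,
               c("gene", "p_combined")]
    kept[order(kept$p_combined, kept$gene), ]
  })
  out <- tibble::tibble(
    pathway_id = hits$pathway_id,
    name = hits$name,
    classification = hits$classification,
    direction = hits$direction,
    p_enrich = hits$p_enrich,
    n_key_genes = vapply(key, nrow, 0L),
    key_genes = key
  )
  out <- dplyr::arrange(out, .data$pathway_id)
  class(out) <- c("consensus_result", class(out))
  out
}

#' Render the consensus report table
#'
#' One row per consensus pathway with the key genes rendered as a single
#' comma-joined cell of `GENE(p)` entries, e.g. `"FH(8.33E-05)"`.
#' [parse_report_genes()] inverts the cell rendering.
#'
#' @param consensus A `consensus_result` tibble from [intersect_pathways()].
#' @return A flat tibble (writable with [write_result_table()]) with columns
#'   `pathway_id`, `name`, `classification`, `direction`, `p_enrich`,
#'   `n_key_genes`, `key_genes`, ordered by `pathway_id`.
#' @export
build_report <- function(consensus) {
  cells <- vapply(consensus$key_genes, function(tb) {
    paste0(tb$gene, "(", format_pvalue(tb$p_combined), ")", collapse = ", ")
  }, "")
  tibble::tibble(
    pathway_id = consensus$pathway_id,
    name = consensus$name,
    classification = consensus$classification,
    direction = consensus$direction,
    p_enrich = consensus$p_enrich,
    n_key_genes = consensus$n_key_genes,
    key_genes = cells
  )
}

#' @rdname build_report
#' @param cell A `key_genes` cell written by `build_report()`.
#' @return `parse_report_genes()` returns a tibble with columns `gene`,
#'   `p_combined`.
#' @export
parse_report_genes <- function(cell) {
  if (!nzchar(cell)) {
    return(tibble::tibble(gene = character(), p_combined = numeric()))
  }
  parts <- strsplit(cell, ", ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*)\\(([^()]*)\\)$", parts))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    pcx_abort(sprintf("Malformed gene cell entry: %s", parts[bad][1]),
              "pcx_parse_error")
  }
  tibble::tibble(
    gene = vapply(m, `[[`, "", 2L),
    p_combined = parse_pvalue(vapply(m, `[[`, "", 3L))
  )
}
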