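#' Hypergeometric pathway over-representation
#'
#' One-sided (upper-tail) hypergeometric test of the overlap between a
#' significant-gene list and each pathway, against a background universe —
#' the standard over-representation model that web annotation tools derive
#' their scores from. Pathways with zero overlap are omitted (an empty
#' overlap carries no evidence). With `ease = TRUE` the overlap count is
#' reduced by one before the tail probability (the conservative EASE-style
#' variant); the plain test is the default.
#'
#' @param sig_genes Character vector of significant gene symbols; must be a
#'   subset of `background`.
#' @param gsc A [gene_set_collection()].
#' @param background Character vector: the pathway-annotated universe
#'   intersected with the genes actually tested.
#' @param ease Use the overlap-minus-one variant (default `FALSE`).
#' @return A tibble of class `enrichment_result`, sorted by `p_enrich` then
#'   `pathway_id`, with columns `pathway_id`, `name`, `classification`,
#'   `n_overlap`, `n_pathway`, `n_sig`, `n_background`, `p_enrich`,
#'   `member_genes` (list-column of overlapping gene symbols).
#' @export
hypergeometric_enrichment <- function(sig_genes, gsc, background,
                                      ease = FALSE) {
  sig_genes <- unique(as.character(sig_genes))
  background <- unique(as.character(background))
  outside <- setdiff(sig_genes, background)
  if (length(outside)) {
    pcx_abort(paste0("Significant gene(s) outside the background: ",
                     paste(head(outside, 5), collapse = ", ")),
              "pcx_bad_argument")
  }
  N <- length(background)
  n_sig <- length(sig_genes)

  rows <- purrr::map(seq_len(nrow(gsc)), function(i) {
    members_bg <- intersect(gsc$genes[[i]], background)
    overlap <- intersect(members_bg, sig_genes)
    k <- length(overlap)
    if (k == 0L) return(NULL)
    m <- length(members_bg)
    q <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(q - 1L, m, N - m, n_sig, lower.tail = FALSE)
    tibble::tibble(
      pathway_id = gsc$pathway_id[i],
      name = gsc$name[i],
      classification = gsc$classification[i],
      n_overlap = k, n_pathway = m, n_sig = n_sig, n_background = N,
      p_enrich = p,
      member_genes = list(sort(overlap))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(
      pathway_id = character(), name = character(), classification = character(),
      n_overlap = integer(), n_pathway = integer(), n_sig = integer(),
      n_background = integer(), p_enrich = numeric(), member_genes = list())
  }
  out <- dplyr::arrange(out, .data$p_enrich, .data$pathway_id)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Label enriched pathways up or down
#'
#' Direction by majority vote over the overlapping genes' meta-analysis
#' directions: UP if most overlapping genes have positive mean t, DOWN if
#' most are negative. An exact tie falls back to the sign of the summed mean
#' t statistics; a still-tied pathway is labelled UNDEFINED with a warning.
#'
#' @param records An `enrichment_result` tibble.
#' @param meta A `meta_gene_result` tibble from [run_meta()].
#' @return `records` with a `direction` column added, and `member_genes`
#'   upgraded to a list-column of tibbles (`gene`, `p_combined`, `mean_t`).
#' @export
assign_direction <- function(records, meta) {
  info <- purrr::map(records$member_genes, function(genes) {
    idx <- match(genes, meta$gene)
    tibble::tibble(gene = genes,
                   p_combined = meta$p_combined[idx],
                   mean_t = meta$mean_t[idx])
  })
  dir <- vapply(info, function(tb) {
    n_up <- sum(tb$mean_t > 0, na.rm = TRUE)
    n_down <- sum(tb$mean_t < 0, na.rm = TRUE)
    if (n_up > n_down) return("UP")
    if (n_down > n_up) return("DOWN")
    net <- sum(tb$mean_t, na.rm = TRUE)
    if (net > 0) "UP" else if (net < 0) "DOWN" else "UNDEFINED"
  }, "")
  if (any(dir == "UNDEFINED")) {
    rlang::warn(paste0("Direction undefined for pathway(s): ",
                       paste(records$pathway_id[dir == "UNDEFINED"], collapse = ", ")))
  }
  records$member_genes <- info
  records$direction <- dir
  records
}

#' Select significantly enriched pathways
#'
#' Pathways with enrichment p strictly below `alpha`.
#'
#' @param records An `enrichment_result` tibble (after [assign_direction()]
#'   if directions are wanted downstream).
#' @param alpha Significance level (default 0.05).
#' @return The filtered `enrichment_result` tibble.
#' @export
significant_enrichment <- function(records, alpha = 0.05) {
  out <- records[records$p_enrich < alpha, , drop = FALSE]
  class(out) <- class(records)
  out
}
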