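#' Restrict a dataset to pathway-annotated genes
#'
#' Keeps only probes whose gene symbol belongs to the pathway-annotated
#' universe of `gsc`; probes with an empty symbol are removed. Sample
#' metadata is unchanged.
#'
#' @param ds An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @return The restricted dataset. Errors with class `pcx_empty_dataset` if
#'   no probe survives.
#' @export
restrict_to_pathway_genes <- function(ds, gsc) {
  universe <- pathway_universe(gsc)
  keep <- ds$probes$gene_symbol != "" & ds$probes$gene_symbol %in% universe
  if (!any(keep)) {
    pcx_abort(sprintf("Dataset %s: no probe maps to a pathway gene.",
                      ds$dataset_id),
              "pcx_empty_dataset")
  }
  subset_probes(ds, which(keep))
}

#' Interquartile range with linear interpolation between order statistics
#'
#' Q3 - Q1 with quartiles interpolated at position `(n - 1) * q` of the
#' sorted values (the type-7 quantile convention).
#'
#' @param values Numeric vector of at least 2 values.
#' @return The interquartile range, a non-negative number.
#' @export
#' @examples
#' compute_iqr(c(1, 2, 3, 4)) # Q1 = 1.75, Q3 = 3.25 -> 1.5
compute_iqr <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    pcx_abort("IQR needs at least 2 numeric values.", "pcx_bad_argument")
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

# Per-probe IQR across all samples (both groups pooled).
probe_iqrs <- function(ds) {
  q <- t(apply(ds$values, 1, stats::quantile, probs = c(0.25, 0.75),
               type = 7, names = FALSE))
  unname(q[, 2] - q[, 1])
}

#' Remove probes with low variability
#'
#' Drops probes whose interquartile range across all samples is strictly
#' below `cutoff`; a probe at exactly the cutoff is kept.
#'
#' @param ds An [expression_dataset()].
#' @param cutoff IQR cutoff (default 0.5).
#' @return The filtered dataset. Errors with class `pcx_empty_dataset` if no
#'   probe survives.
#' @export
filter_by_iqr <- function(ds, cutoff = 0.5) {
  iqr <- probe_iqrs(ds)
  keep <- iqr >= cutoff
  if (!any(keep)) {
    pcx_abort(sprintf("Dataset %s: every probe has IQR below %g.",
                      ds$dataset_id, cutoff),
              "pcx_empty_dataset")
  }
  subset_probes(ds, which(keep))
}

#' Collapse multiple probes per gene to the most variable one
#'
#' For each gene, keeps the single probe with maximal IQR (ties broken by the
#' lexicographically smallest probe id). The retained row keeps its probe id;
#' output rows are sorted by gene symbol.
#'
#' @param ds An [expression_dataset()].
#' @return A dataset with one probe per gene.
#' @export
collapse_probes <- function(ds) {
  iqr <- probe_iqrs(ds)
  ord <- order(ds$probes$gene_symbol, -iqr, ds$probes$probe_id)
  first <- ord[!duplicated(ds$probes$gene_symbol[ord])]
  subset_probes(ds, sort_by_gene(ds, first))
}

sort_by_gene <- function(ds, idx) {
  idx[order(ds$probes$gene_symbol[idx])]
}

#' Preprocess one cohort: restrict, filter, collapse
#'
#' Applies the full reduction in order: restrict to pathway-annotated genes,
#' remove probes with IQR < `cutoff`, then collapse to the most variable
#' probe per gene. Also returns an audit trail recording the fate of every
#' input probe.
#'
#' @param ds An [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param iqr_cutoff Variability cutoff (default 0.5).
#' @return A list with `dataset` (the reduced [expression_dataset()], one row
#'   per gene) and `audit` (tibble: `probe_id`, `gene_symbol`, `iqr`,
#'   `kept`, `reason`).
#' @export
preprocess_dataset <- function(ds, gsc, iqr_cutoff = 0.5) {
  universe <- pathway_universe(gsc)
  audit <- tibble::tibble(
    probe_id = ds$probes$probe_id,
    gene_symbol = ds$probes$gene_symbol,
    iqr = probe_iqrs(ds),
    kept = FALSE,
    reason = NA_character_
  )
  unannotated <- audit$gene_symbol == ""
  off_pathway <- !unannotated & !audit$gene_symbol %in% universe
  audit$reason[unannotated] <- "unannotated"
  audit$reason[off_pathway] <- "not_in_pathway_universe"

  restricted <- restrict_to_pathway_genes(ds, gsc)
  low <- is.na(audit$reason) & audit$iqr < iqr_cutoff
  audit$reason[low] <- "low_iqr"
  filtered <- filter_by_iqr(restricted, iqr_cutoff)
  collapsed <- collapse_probes(filtered)

  kept <- audit$probe_id %in% collapsed$probes$probe_id
  audit$kept <- kept
  audit$reason[kept] <- "kept"
  audit$reason[is.na(audit$reason)] <- "not_max_iqr"

  list(dataset = collapsed, audit = audit)
}
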