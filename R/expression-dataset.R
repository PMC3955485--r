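#' Construct a per-cohort expression dataset
#'
#' The container for one cohort: a log2 intensity matrix (probes x samples)
#' plus probe and sample metadata. Probes with no known gene symbol carry an
#' empty string and are dropped later by [restrict_to_pathway_genes()].
#'
#' @param values Numeric matrix of log2 intensities with probe ids as row
#'   names and sample ids as column names. No missing values are allowed.
#' @param samples Data frame with columns `sample_id`, `group` (one of
#'   `"TUMOR"`/`"NORMAL"`, case-insensitive) and optionally `pair` (pair
#'   label for paired designs; stored but not used by the statistics).
#' @param probes Data frame with columns `probe_id`, `gene_symbol`. Probes in
#'   `values` absent from this map get an empty gene symbol. `NULL` means no
#'   annotation (all symbols empty).
#' @param dataset_id Character label for the cohort.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `values`, `probes` (tibble `probe_id`, `gene_symbol`) and
#'   `samples` (tibble `sample_id`, `group`, `pair`).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' ann <- data.frame(sample_id = paste0("s", 1:4),
#'                   group = c("TUMOR", "TUMOR", "NORMAL", "NORMAL"))
#' ds <- expression_dataset(m, ann, dataset_id = "toy")
#' n_probes(ds)
expression_dataset <- function(values, samples, probes = NULL,
                               dataset_id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    pcx_abort("`values` must be a numeric matrix.", "pcx_invalid_matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    pcx_abort("`values` must have probe row names and sample column names.",
              "pcx_invalid_matrix")
  }
  if (anyNA(values)) {
    pcx_abort("Expression matrix contains missing values.", "pcx_missing_values")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    pcx_abort(paste0("Duplicate probe ids: ", paste(head(dup, 5), collapse = ", ")),
              "pcx_duplicate_probes")
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    pcx_abort(paste0("Duplicate sample ids: ", paste(head(dup, 5), collapse = ", ")),
              "pcx_duplicate_samples")
  }

  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    pcx_abort("`samples` needs columns sample_id and group.", "pcx_bad_annotation")
  }
  if (!"pair" %in% names(samples)) samples$pair <- NA_character_
  samples <- samples[, c("sample_id", "group", "pair")]
  samples$sample_id <- as.character(samples$sample_id)
  samples$pair <- as.character(samples$pair)

  missing_ann <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_ann)) {
    pcx_abort(paste0("Samples missing from annotation: ",
                     paste(head(missing_ann, 5), collapse = ", ")),
              "pcx_missing_annotation")
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]

  grp <- toupper(as.character(samples$group))
  bad <- !grp %in% .groups
  if (any(bad)) {
    pcx_abort(paste0("Unknown group label for sample(s) ",
                     paste(head(samples$sample_id[bad], 5), collapse = ", "),
                     ": ", paste(unique(samples$group[bad]), collapse = ", "),
                     " (expected TUMOR or NORMAL)."),
              "pcx_unknown_group")
  }
  samples$group <- grp

  probe_tbl <- tibble::tibble(probe_id = rownames(values),
                              gene_symbol = "")
  if (!is.null(probes)) {
    probes <- tibble::as_tibble(probes)
    if (!all(c("probe_id", "gene_symbol") %in% names(probes))) {
      pcx_abort("`probes` needs columns probe_id and gene_symbol.",
                "pcx_bad_probe_map")
    }
    if (anyDuplicated(probes$probe_id)) {
      pcx_abort("Duplicate probe ids in probe map.", "pcx_bad_probe_map")
    }
    idx <- match(probe_tbl$probe_id, as.character(probes$probe_id))
    hit <- !is.na(idx)
    probe_tbl$gene_symbol[hit] <- as.character(probes$gene_symbol)[idx[hit]]
    probe_tbl$gene_symbol[is.na(probe_tbl$gene_symbol)] <- ""
  }

  structure(
    list(dataset_id = as.character(dataset_id),
         values = values,
         probes = probe_tbl,
         samples = samples),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %s: %d probes x %d samples (%d TUMOR / %d NORMAL)\n",
    x$dataset_id, n_probes(x), n_samples(x),
    sum(x$samples$group == "TUMOR"), sum(x$samples$group == "NORMAL")))
  n_gene <- length(unique(x$probes$gene_symbol[x$probes$gene_symbol != ""]))
  cat(sprintf("  annotated genes: %d; paired: %s\n", n_gene,
              if (all(is.na(x$samples$pair))) "no" else "yes"))
  invisible(x)
}

#' Dataset dimensions
#' @param ds An [expression_dataset()].
#' @return Integer count.
#' @export
n_probes <- function(ds) nrow(ds$values)

#' @rdname n_probes
#' @export
n_samples <- function(ds) ncol(ds$values)

# Column indices per group, in matrix order.
group_columns <- function(ds) {
  list(tumor = which(ds$samples$group == "TUMOR"),
       normal = which(ds$samples$group == "NORMAL"))
}

# Guard used by every statistical stage.
check_two_per_group <- function(ds) {
  g <- group_columns(ds)
  if (length(g$tumor) < 2L || length(g$normal) < 2L) {
    pcx_abort(sprintf("Dataset %s needs at least 2 samples per group.",
                      ds$dataset_id),
              "pcx_too_few_samples")
  }
  invisible(g)
}

# Subset probes by row index, preserving metadata alignment.
subset_probes <- function(ds, keep) {
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$probes <- ds$probes[keep, , drop = FALSE]
  ds
}
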