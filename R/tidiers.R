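## broom-style tidiers for the stage result classes. tidy() returns the
## plain per-row tibble; glance() a one-row summary.

#' @method tidy pathway_perm_result
#' @export
tidy.pathway_perm_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pathway_perm_result")
  out
}

#' @method glance pathway_perm_result
#' @export
glance.pathway_perm_result <- function(x, ...) {
  tibble::tibble(
    dataset_id = attr(x, "dataset_id") %||% NA_character_,
    n_pathways = nrow(x),
    n_permutations = if (nrow(x)) x$n_permutations[1] else NA_integer_,
    min_p_perm = if (nrow(x)) min(x$p_perm) else NA_real_
  )
}

#' @method tidy meta_gene_result
#' @export
tidy.meta_gene_result <- function(x, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -"per_dataset_p", -"per_dataset_t")
  out
}

#' @method glance meta_gene_result
#' @export
glance.meta_gene_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    max_k = if (nrow(x)) max(x$k) else NA_integer_,
    min_p_combined = if (nrow(x)) min(x$p_combined) else NA_real_
  )
}

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  flatten_enrichment(x)
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    n_background = if (nrow(x)) x$n_background[1] else NA_integer_,
    n_sig_genes = if (nrow(x)) x$n_sig[1] else NA_integer_,
    min_p_enrich = if (nrow(x)) min(x$p_enrich) else NA_real_
  )
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  build_report(x)
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x),
    n_up = sum(x$direction == "UP"),
    n_down = sum(x$direction == "DOWN"),
    n_key_genes = sum(x$n_key_genes)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
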