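## In-code fixture builders shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-probe-per-gene dataset from a named matrix; gene symbols default to
# the probe ids themselves.
toy_dataset <- function(values, groups, genes = rownames(values),
                        id = "toy") {
  expression_dataset(
    values,
    tibble::tibble(sample_id = colnames(values), group = groups),
    tibble::tibble(probe_id = rownames(values), gene_symbol = genes),
    dataset_id = id
  )
}

# Random valid dataset for round-trip / fuzz tests.
random_dataset <- function(n_probes = 6, n_per_group = 3, seed = 1,
                           id = "rand") {
  withr::with_seed(seed, {
    m <- matrix(round(stats::rnorm(n_probes * 2 * n_per_group, 8, 1), 4),
                nrow = n_probes,
                dimnames = list(
                  sprintf("p%02d", seq_len(n_probes)),
                  c(sprintf("t%02d", seq_len(n_per_group)),
                    sprintf("n%02d", seq_len(n_per_group)))))
    toy_dataset(m, rep(c("TUMOR", "NORMAL"), each = n_per_group),
                genes = sprintf("GENE%02d", seq_len(n_probes)), id = id)
  })
}

# Write a dataset to the three data_io files in a temp dir; returns paths.
write_fixture_files <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_expression(ds, dir)
}

# Small gene-set collection over a dataset's genes: consecutive blocks.
block_gsc <- function(genes, set_size = 2) {
  idx <- split(seq_along(genes),
               ceiling(seq_along(genes) / set_size))
  gene_set_collection(
    pathway_id = sprintf("map%05d", seq_along(idx)),
    name = sprintf("Block set %d", seq_along(idx)),
    classification = "Test",
    genes = lapply(idx, function(i) genes[i])
  )
}
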