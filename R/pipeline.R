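#' Pipeline configuration
#'
#' Bundles every stage parameter plus either a simulation config or the
#' input file paths for real cohorts.
#'
#' @param simulation A [sim_config()] to generate the study, or `NULL` when
#'   `inputs` is given.
#' @param inputs `NULL`, or a list with `gmt` (path) and `datasets` (list of
#'   lists with `matrix`, `annotation`, `probe_map` paths).
#' @param iqr_cutoff Probe variability cutoff (default 0.5).
#' @param n_permutations Permutations per cohort (default 1000).
#' @param gsea_alpha Per-cohort pathway significance level (default 0.05,
#'   boundary included).
#' @param meta_alpha Combined-p gene significance level (default 0.05,
#'   strict).
#' @param enrich_alpha Enrichment significance level (default 0.05, strict).
#' @param ease Use the EASE-style overlap-minus-one enrichment variant.
#' @param seed Master seed; per-cohort permutation seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            inputs = NULL,
                            iqr_cutoff = 0.5,
                            n_permutations = 1000,
                            gsea_alpha = 0.05,
                            meta_alpha = 0.05,
                            enrich_alpha = 0.05,
                            ease = FALSE,
                            seed = 1L) {
  if (is.null(simulation) && is.null(inputs)) {
    pcx_abort("Provide either a simulation config or input file paths.",
              "pcx_bad_config")
  }
  cfg <- list(simulation = simulation, inputs = inputs,
              iqr_cutoff = iqr_cutoff, n_permutations = as.integer(n_permutations),
              gsea_alpha = gsea_alpha, meta_alpha = meta_alpha,
              enrich_alpha = enrich_alpha, ease = isTRUE(ease),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain any [pipeline_config()] field; a `simulation` block
#' holds [sim_config()] fields, an `inputs` block holds file paths.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) sim <- do.call(sim_config, y$simulation)
  args <- y[setdiff(names(y), c("simulation", "inputs"))]
  do.call(pipeline_config,
          c(list(simulation = sim, inputs = y$inputs), args))
}

#' Run the full consensus pipeline
#'
#' Executes simulate (or load) -> preprocess -> per-cohort permutation GSEA
#' -> cross-cohort common pathways -> Fisher meta-analysis -> hypergeometric
#' enrichment -> consensus intersection, writing every intermediate table and
#' a parameter log under `out_dir`. Two runs with an identical config produce
#' bit-identical output trees.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed. `NULL` writes nothing.
#' @return Invisibly, a list with all stage objects: `datasets`, `gene_sets`,
#'   `truth` (simulated runs only), `preprocessed`, `gsea`, `per_dataset_sig`,
#'   `gsea_summary`, `common`, `meta`, `significant_genes`, `enrichment`,
#'   `enriched`, `consensus`, `report`.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   simulation = sim_config(n_genes = 120, n_pathways = 8,
#'     genes_per_pathway = 10, samples_per_group = c(5, 5), n_datasets = 2),
#'   n_permutations = 199)
#' res <- run_pipeline(cfg, out_dir = NULL)
#' res$report
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(tbl, file) {
    if (write_out) write_result_table(tbl, file.path(out_dir, file))
  }

  ## Stage 1: obtain the study.
  truth <- NULL
  if (!is.null(config$simulation)) {
    study <- simulate_study(config$simulation)
    datasets <- study$datasets
    gsc <- study$gene_sets
    truth <- study$truth
    if (write_out) {
      for (ds in datasets) write_expression(ds, file.path(out_dir, "input"))
      write_gmt(gsc, file.path(out_dir, "input", "gene_sets.gmt"))
      emit(tibble::tibble(
        pathway_id = gsc$pathway_id,
        truth = dplyr::case_when(
          gsc$pathway_id %in% truth$up_pathways ~ "UP",
          gsc$pathway_id %in% truth$down_pathways ~ "DOWN",
          TRUE ~ "NULL")), "ground_truth.tsv")
    }
  } else {
    gsc <- read_gmt(config$inputs$gmt)
    datasets <- purrr::map(config$inputs$datasets, function(d) {
      read_expression(d$matrix, d$annotation, d$probe_map,
                      dataset_id = d$dataset_id)
    })
  }

  ## Stage 2: preprocess each cohort.
  prep <- purrr::map(datasets, preprocess_dataset, gsc = gsc,
                     iqr_cutoff = config$iqr_cutoff)
  preprocessed <- purrr::map(prep, "dataset")
  for (i in seq_along(prep)) {
    emit(prep[[i]]$audit,
         sprintf("preprocess_audit_%s.tsv", datasets[[i]]$dataset_id))
    if (write_out) {
      write_expression(preprocessed[[i]], file.path(out_dir, "preprocessed"))
    }
  }

  ## Stage 3: per-cohort permutation GSEA.
  gsea <- purrr::map(seq_along(preprocessed), function(d) {
    permutation_test(preprocessed[[d]], gsc,
                     n_permutations = config$n_permutations,
                     seed = derive_seed(config$seed, d))
  })
  per_dataset_sig <- purrr::map(gsea, significant_pathways,
                                alpha = config$gsea_alpha)
  for (d in seq_along(gsea)) {
    emit(tibble::as_tibble(gsea[[d]]),
         sprintf("gsea_%s.tsv", preprocessed[[d]]$dataset_id))
  }
  gsea_summary <- purrr::map2(preprocessed, seq_along(preprocessed),
    function(ds, d) {
      st <- gene_t_statistics(ds)
      tibble::tibble(
        dataset_id = ds$dataset_id,
        n_tumor = sum(ds$samples$group == "TUMOR"),
        n_normal = sum(ds$samples$group == "NORMAL"),
        n_genes_tested = nrow(st),
        n_significant_genes = sum(st$p_two_sided <= config$gsea_alpha),
        n_up_pathways = length(per_dataset_sig[[d]]$up),
        n_down_pathways = length(per_dataset_sig[[d]]$down))
    }) |> dplyr::bind_rows()
  emit(gsea_summary, "gsea_summary.tsv")
  common <- common_pathways(per_dataset_sig)

  ## Stage 4: Fisher meta-analysis.
  meta <- run_meta(preprocessed)
  emit(flatten_meta(meta), "meta_genes.tsv")
  sig_genes <- select_significant_genes(meta, alpha = config$meta_alpha)
  emit(tibble::tibble(gene = sig_genes), "significant_genes.tsv")

  ## Stage 5: enrichment of the significant genes.
  background <- intersect(pathway_universe(gsc), meta$gene)
  enrichment <- hypergeometric_enrichment(sig_genes, gsc, background,
                                          ease = config$ease)
  enrichment <- assign_direction(enrichment, meta)
  enriched <- significant_enrichment(enrichment, alpha = config$enrich_alpha)
  emit(flatten_enrichment(enrichment), "enrichment.tsv")

  ## Stage 6: consensus.
  consensus <- intersect_pathways(common$up, common$down, enriched,
                                  gene_alpha = config$meta_alpha)
  report <- build_report(consensus)
  emit(report, "consensus_report.tsv")

  if (write_out) {
    writeLines(run_log_lines(config), file.path(out_dir, "run_log.txt"))
  }

  invisible(list(
    datasets = datasets, gene_sets = gsc, truth = truth,
    preprocessed = preprocessed, audits = purrr::map(prep, "audit"),
    gsea = gsea, per_dataset_sig = per_dataset_sig,
    gsea_summary = gsea_summary, common = common,
    meta = meta, significant_genes = sig_genes,
    enrichment = enrichment, enriched = enriched,
    consensus = consensus, report = report
  ))
}

# Flat, writable view of the meta result (per-cohort p-values widened).
flatten_meta <- function(meta) {
  wide <- purrr::map2(meta$gene, meta$per_dataset_p, function(g, p) {
    tibble::tibble(gene = g, dataset_id = names(p), p = unname(p))
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "p",
                       names_prefix = "p_")
  flat <- dplyr::select(tibble::as_tibble(meta), "gene", "k", "chi_square",
                        "df", "p_combined", "mean_t", "direction")
  dplyr::left_join(flat, wide, by = "gene")
}

flatten_enrichment <- function(records) {
  out <- dplyr::select(tibble::as_tibble(records), -"member_genes")
  out$member_genes <- vapply(records$member_genes, function(tb) {
    paste(tb$gene, collapse = ", ")
  }, "")
  out
}

run_log_lines <- function(config) {
  sim <- config$simulation
  c("pathconsensus run log",
    paste0("package_version: ", as.character(utils::packageVersion("pathconsensus"))),
    paste0("seed: ", config$seed),
    paste0("iqr_cutoff: ", config$iqr_cutoff),
    paste0("n_permutations: ", config$n_permutations),
    paste0("gsea_alpha: ", config$gsea_alpha),
    paste0("meta_alpha: ", config$meta_alpha),
    paste0("enrich_alpha: ", config$enrich_alpha),
    paste0("ease: ", config$ease),
    if (!is.null(sim)) {
      paste0("simulation_", names(unclass(sim)), ": ",
             vapply(unclass(sim), function(v) paste(v, collapse = ","), ""))
    } else {
      paste0("input_gmt: ", config$inputs$gmt)
    })
}
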