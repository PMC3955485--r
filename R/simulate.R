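#' Configuration for the synthetic multi-cohort study generator
#'
#' Defaults emulate a three-cohort paired tumor/normal design with 7/7, 10/10
#' and 23/23 samples per group, pathway-structured mean shifts of one log2
#' unit, and unit-variance Gaussian noise on the log2 scale.
#'
#' @param n_datasets Number of cohorts.
#' @param samples_per_group Integer vector, one per cohort: samples in each of
#'   the TUMOR and NORMAL groups.
#' @param n_genes Total genes in the shared universe.
#' @param n_pathways Number of gene sets; membership blocks are disjoint.
#' @param genes_per_pathway Member genes per pathway.
#' @param probes_per_gene Length-2 integer range; each gene's probe count is
#'   drawn uniformly from it.
#' @param frac_up_pathways,frac_down_pathways Fractions of pathways planted
#'   up-/down-regulated in TUMOR; their sum must be at most 1.
#' @param effect_size Mean log2 shift applied to TUMOR samples of genes in
#'   affected pathways (positive; the down direction negates it).
#' @param noise_sd Per-observation Gaussian standard deviation (log2 scale).
#' @param baseline_mean Log2 baseline intensity.
#' @param iqr_decoy_frac Fraction of unaffected genes given near-constant
#'   expression (`decoy_sd`) so that the IQR >= 0.5 variability filter has
#'   something to remove.
#' @param decoy_sd Standard deviation of decoy genes; the default 0.05 gives
#'   an expected IQR of about 0.07, far below the 0.5 cutoff.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_datasets = 3,
                       samples_per_group = c(7, 10, 23),
                       n_genes = 800,
                       n_pathways = 50,
                       genes_per_pathway = 15,
                       probes_per_gene = c(1, 3),
                       frac_up_pathways = 0.2,
                       frac_down_pathways = 0.2,
                       effect_size = 1,
                       noise_sd = 1,
                       baseline_mean = 8,
                       iqr_decoy_frac = 0.05,
                       decoy_sd = 0.05,
                       seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              samples_per_group = as.integer(samples_per_group),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              genes_per_pathway = as.integer(genes_per_pathway),
              probes_per_gene = as.integer(probes_per_gene),
              frac_up_pathways = frac_up_pathways,
              frac_down_pathways = frac_down_pathways,
              effect_size = effect_size,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              iqr_decoy_frac = iqr_decoy_frac,
              decoy_sd = decoy_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) pcx_abort(msg, "pcx_bad_config")
  chk(cfg$n_datasets >= 1, "n_datasets must be positive.")
  chk(length(cfg$samples_per_group) == cfg$n_datasets,
      "samples_per_group needs one entry per dataset.")
  chk(all(cfg$samples_per_group >= 2), "Need >=2 samples per group.")
  chk(cfg$n_genes >= 1 && cfg$n_pathways >= 1 && cfg$genes_per_pathway >= 1,
      "Counts must be positive.")
  chk(cfg$n_pathways * cfg$genes_per_pathway <= cfg$n_genes,
      "n_genes must cover n_pathways disjoint membership blocks.")
  chk(length(cfg$probes_per_gene) == 2 && all(cfg$probes_per_gene >= 1) &&
        cfg$probes_per_gene[1] <= cfg$probes_per_gene[2],
      "probes_per_gene must be an increasing range of counts >= 1.")
  chk(cfg$frac_up_pathways >= 0 && cfg$frac_down_pathways >= 0 &&
        cfg$frac_up_pathways + cfg$frac_down_pathways <= 1,
      "frac_up_pathways + frac_down_pathways must lie in [0, 1].")
  chk(cfg$noise_sd > 0, "noise_sd must be positive.")
  chk(cfg$iqr_decoy_frac >= 0 && cfg$iqr_decoy_frac <= 1,
      "iqr_decoy_frac must lie in [0, 1].")
  invisible(cfg)
}

#' Simulate a multi-cohort tumor/normal expression study
#'
#' Generates `n_datasets` cohorts sharing one gene universe, one probe map and
#' one pathway collection. Pathways partition disjoint gene blocks; a subset
#' are planted up- or down-regulated, meaning every member gene's TUMOR mean
#' is shifted by +/- `effect_size`, identically in every cohort. Each gene is
#' measured by one or more probes (independent noisy replicates of the same
#' gene signal). Decoy genes, drawn from unaffected genes, get near-constant
#' expression to exercise the variability filter. Samples are independent;
#' the paired design is emulated only through pair labels.
#'
#' @param config A [sim_config()].
#' @return A list with elements `datasets` (list of [expression_dataset()]),
#'   `gene_sets` (a [gene_set_collection()]) and `truth` (list with
#'   `up_pathways`, `down_pathways`, `null_pathways`, `affected_genes` tibble
#'   (`gene`, `effect`), and `decoy_genes`).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_datasets = 1, samples_per_group = 3,
#'   n_genes = 40, n_pathways = 4, genes_per_pathway = 5, seed = 7))
#' study$datasets[[1]]
simulate_study <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  ## Pathways own disjoint, consecutive gene blocks; remaining genes are
  ## unannotated (outside the pathway universe).
  member_idx <- split(seq_len(cfg$n_pathways * cfg$genes_per_pathway),
                      rep(seq_len(cfg$n_pathways), each = cfg$genes_per_pathway))
  classes <- c("Metabolism", "Organismal systems", "Cellular processes",
               "Environmental information processing", "Human diseases")
  gsc <- gene_set_collection(
    pathway_id = sprintf("map%05d", seq_len(cfg$n_pathways)),
    name = sprintf("Synthetic pathway %d", seq_len(cfg$n_pathways)),
    classification = classes[(seq_len(cfg$n_pathways) - 1L) %% length(classes) + 1L],
    genes = lapply(member_idx, function(i) genes[i])
  )

  n_up <- round(cfg$frac_up_pathways * cfg$n_pathways)
  n_down <- round(cfg$frac_down_pathways * cfg$n_pathways)
  affected_pw <- sample(cfg$n_pathways, n_up + n_down)
  up_pw <- sort(affected_pw[seq_len(n_up)])
  down_pw <- sort(affected_pw[seq_len(n_down) + n_up])
  null_pw <- setdiff(seq_len(cfg$n_pathways), c(up_pw, down_pw))

  effect <- stats::setNames(numeric(cfg$n_genes), genes)
  for (i in up_pw) effect[member_idx[[i]]] <- cfg$effect_size
  for (i in down_pw) effect[member_idx[[i]]] <- -cfg$effect_size

  ## Decoys come only from unaffected genes so ground truth stays clean.
  unaffected <- which(effect == 0)
  n_decoy <- min(round(cfg$iqr_decoy_frac * cfg$n_genes), length(unaffected))
  decoy_idx <- if (n_decoy > 0) sort(sample(unaffected, n_decoy)) else integer()
  gene_sd <- rep(cfg$noise_sd, cfg$n_genes)
  gene_sd[decoy_idx] <- cfg$decoy_sd

  ## Shared probe map across cohorts.
  probe_counts <- seq(cfg$probes_per_gene[1], cfg$probes_per_gene[2])
  n_probes_of_gene <- if (length(probe_counts) == 1L) {
    rep(probe_counts, cfg$n_genes)
  } else {
    sample(probe_counts, cfg$n_genes, replace = TRUE)
  }
  probe_gene_idx <- rep(seq_len(cfg$n_genes), n_probes_of_gene)
  probe_ids <- paste0(genes[probe_gene_idx], "_at",
                      unlist(lapply(n_probes_of_gene, seq_len), use.names = FALSE))
  probe_map <- tibble::tibble(probe_id = probe_ids,
                              gene_symbol = genes[probe_gene_idx])

  datasets <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    n <- cfg$samples_per_group[d]
    ds_id <- sprintf("cohort%d", d)
    sample_ids <- c(sprintf("%s_T%02d", ds_id, seq_len(n)),
                    sprintf("%s_N%02d", ds_id, seq_len(n)))
    groups <- rep(c("TUMOR", "NORMAL"), each = n)
    pairs <- rep(sprintf("pair%02d", seq_len(n)), 2)

    mu <- cfg$baseline_mean +
      outer(effect[probe_gene_idx], as.numeric(groups == "TUMOR"))
    noise <- matrix(stats::rnorm(length(probe_ids) * 2 * n,
                                 sd = gene_sd[probe_gene_idx]),
                    nrow = length(probe_ids))
    values <- mu + noise
    dimnames(values) <- list(probe_ids, sample_ids)

    datasets[[d]] <- expression_dataset(
      values,
      tibble::tibble(sample_id = sample_ids, group = groups, pair = pairs),
      probe_map, dataset_id = ds_id)
  }

  truth <- list(
    up_pathways = gsc$pathway_id[up_pw],
    down_pathways = gsc$pathway_id[down_pw],
    null_pathways = gsc$pathway_id[null_pw],
    affected_genes = tibble::tibble(gene = genes[effect != 0],
                                    effect = unname(effect[effect != 0])),
    decoy_genes = genes[decoy_idx]
  )

  list(datasets = datasets, gene_sets = gsc, truth = truth)
}

#' Monte-Carlo power of a single-gene test in the smallest cohort
#'
#' Estimates, independently of the pipeline code paths, the probability that
#' one affected gene reaches two-sided p < `alpha` in an equal-variance
#' two-sample t test on the smallest cohort of the design. Used to set
#' expectations in validation, not part of the analysis itself.
#'
#' @param config A [sim_config()].
#' @param n_sim Monte-Carlo replicates.
#' @param alpha Significance level.
#' @return Estimated power (fraction in \[0, 1\]).
#' @export
expected_detectable_power <- function(config, n_sim = 2000, alpha = 0.05) {
  validate_sim_config(config)
  n <- min(config$samples_per_group)
  withr::with_seed(derive_seed(config$seed, 77L), {
    hits <- vapply(seq_len(n_sim), function(i) {
      x <- stats::rnorm(n, mean = config$effect_size, sd = config$noise_sd)
      y <- stats::rnorm(n, mean = 0, sd = config$noise_sd)
      stats::t.test(x, y, var.equal = TRUE)$p.value < alpha
    }, TRUE)
    mean(hits)
  })
}
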