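#' Gene-level pooled-variance t statistics
#'
#' Classical equal-variance two-sample Student's t per gene, oriented TUMOR
#' mean minus NORMAL mean, with `df = n_T + n_N - 2` and a two-sided p-value
#' from the t distribution. Genes with zero pooled variance and a nonzero
#' mean difference cannot be scored; they are excluded with a warning. Zero
#' pooled variance with zero difference yields `t = 0`, `p = 1`.
#'
#' @param ds A preprocessed [expression_dataset()] (one row per gene).
#' @return A tibble of class `gene_tstat` with columns `gene`, `t`, `df`,
#'   `p_two_sided`.
#' @export
gene_t_statistics <- function(ds) {
  g <- check_two_per_group(ds)
  st <- pooled_t(ds$values, g$tumor, g$normal)
  gene <- ds$probes$gene_symbol
  gene[gene == ""] <- ds$probes$probe_id[gene == ""]

  degenerate <- !is.finite(st$t)
  if (any(degenerate)) {
    rlang::warn(sprintf(
      "Dataset %s: excluding %d degenerate gene(s) with zero pooled variance and nonzero mean difference: %s",
      ds$dataset_id, sum(degenerate),
      paste(head(gene[degenerate], 5), collapse = ", ")))
  }
  out <- tibble::tibble(
    gene = gene[!degenerate],
    t = st$t[!degenerate],
    df = st$df,
    p_two_sided = 2 * stats::pt(abs(st$t[!degenerate]), df = st$df,
                                lower.tail = FALSE)
  )
  class(out) <- c("gene_tstat", class(out))
  out
}

# Pooled two-sample t for every row of X. Returns +/-Inf where the pooled
# variance is zero but the mean difference is not; 0 where both are zero.
pooled_t <- function(X, tumor_idx, normal_idx) {
  n1 <- length(tumor_idx); n2 <- length(normal_idx)
  df <- n1 + n2 - 2L
  m1 <- rowMeans(X[, tumor_idx, drop = FALSE])
  m2 <- rowMeans(X[, normal_idx, drop = FALSE])
  ss1 <- rowSums((X[, tumor_idx, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, normal_idx, drop = FALSE] - m2)^2)
  se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  list(t = unname(t), df = df)
}

# t statistics for many label assignments at once. `assign` is an
# n_samples x B 0/1 matrix marking the permuted TUMOR columns (each column
# sums to n1). Returns genes x B. Zero pooled variance under a permutation
# yields t = 0 (preprocessed data make this vanishingly rare).
perm_t_matrix <- function(X, assign, n1, n2) {
  df <- n1 + n2 - 2L
  tot <- rowSums(X)
  tot2 <- rowSums(X^2)
  S <- X %*% assign
  S2 <- (X^2) %*% assign
  m1 <- S / n1
  m2 <- (tot - S) / n2
  ss <- pmax(S2 - n1 * m1^2, 0) + pmax((tot2 - S2) - n2 * m2^2, 0)
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Mean-t pathway score
#'
#' The pathway statistic: the arithmetic mean of member-gene t statistics.
#'
#' @param tstats A `gene_tstat` tibble from [gene_t_statistics()].
#' @param genes Character vector of member gene symbols.
#' @return The mean t of members present in `tstats`, or `NA` (with a
#'   warning) if no member is present.
#' @export
pathway_score <- function(tstats, genes) {
  t <- tstats$t[tstats$gene %in% genes]
  if (!length(t)) {
    rlang::warn("No member gene present in the dataset; pathway skipped.")
    return(NA_real_)
  }
  mean(t)
}

#' Per-pathway permutation test for one cohort
#'
#' Scores every pathway by the mean of its member-gene t statistics, then
#' tests it against a sample-label permutation null: group labels are
#' shuffled preserving group sizes, gene t statistics are recomputed, and
#' every pathway is rescored. One shared shuffle stream scores all pathways.
#' One-sided p-values use the plus-one estimator,
#' `p_up = (1 + #(permuted score >= observed)) / (B + 1)` (and `<=` for
#' `p_down`), so p-values are floored at `1 / (B + 1)`. With
#' `exhaustive = TRUE` all distinct group-size-preserving label assignments
#' (the observed one included) replace the random stream and p-values are
#' exact proportions.
#'
#' @param ds A preprocessed [expression_dataset()].
#' @param gsc A [gene_set_collection()].
#' @param n_permutations Number of random shuffles (default 1000).
#' @param seed Integer seed for the shuffle stream.
#' @param exhaustive Enumerate all assignments instead of sampling (small
#'   designs only; refuses above `choose(n, n_T)` = 50000 assignments).
#' @return A tibble of class `pathway_perm_result` with columns `pathway_id`,
#'   `n_genes_tested`, `score`, `p_up`, `p_down`, `direction`, `p_perm`,
#'   `n_permutations`, `seed`, plus attribute `dataset_id`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_datasets = 1, samples_per_group = 5,
#'   n_genes = 60, n_pathways = 4, genes_per_pathway = 10, seed = 3))
#' ds <- preprocess_dataset(study$datasets[[1]], study$gene_sets)$dataset
#' permutation_test(ds, study$gene_sets, n_permutations = 99, seed = 1)
permutation_test <- function(ds, gsc, n_permutations = 1000, seed = 1L,
                             exhaustive = FALSE) {
  if (!exhaustive && n_permutations < 1) {
    pcx_abort("n_permutations must be at least 1.", "pcx_bad_argument")
  }
  grp <- check_two_per_group(ds)
  n1 <- length(grp$tumor); n2 <- length(grp$normal); n <- n1 + n2

  tstats <- gene_t_statistics(ds)
  X <- ds$values[match_rows(ds, tstats$gene), , drop = FALSE]

  present <- lapply(gsc$genes, function(g) which(tstats$gene %in% g))
  n_present <- lengths(present)
  skipped <- n_present == 0L
  if (any(skipped)) {
    rlang::inform(sprintf("Skipping %d pathway(s) with no member gene in %s: %s",
                          sum(skipped), ds$dataset_id,
                          paste(head(gsc$pathway_id[skipped], 5), collapse = ", ")))
  }
  keep_pw <- which(!skipped)
  M <- matrix(0, nrow = length(keep_pw), ncol = nrow(tstats))
  for (i in seq_along(keep_pw)) {
    M[i, present[[keep_pw[i]]]] <- 1 / n_present[keep_pw[i]]
  }
  obs <- as.vector(M %*% tstats$t)
  ## The observed and permuted scores travel different (algebraically equal)
  ## arithmetic paths; compare with a tiny relative tolerance so the identity
  ## relabelling always counts as an exceedance.
  tol <- 1e-9 * (1 + abs(obs))

  if (exhaustive) {
    n_assign <- choose(n, n1)
    if (n_assign > 50000) {
      pcx_abort("Design too large for exhaustive enumeration.",
                "pcx_bad_argument")
    }
    ## Enumerate which n1 matrix columns carry the TUMOR label; the observed
    ## labelling is one of the combinations.
    picks <- combn(n, n1)
    assign <- matrix(0, nrow = n, ncol = ncol(picks))
    assign[cbind(as.vector(picks), rep(seq_len(ncol(picks)), each = n1))] <- 1
    perm_scores <- M %*% perm_t_matrix(X, assign, n1, n2)
    p_up <- rowMeans(perm_scores >= obs - tol)
    p_down <- rowMeans(perm_scores <= obs + tol)
    n_used <- ncol(picks)
  } else {
    assign <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(b) {
        a <- numeric(n)
        a[sample.int(n, n1)] <- 1
        a
      }, numeric(n))
    })
    perm_scores <- M %*% perm_t_matrix(X, assign, n1, n2)
    p_up <- (1 + rowSums(perm_scores >= obs - tol)) / (n_permutations + 1)
    p_down <- (1 + rowSums(perm_scores <= obs + tol)) / (n_permutations + 1)
    n_used <- n_permutations
  }

  out <- tibble::tibble(
    pathway_id = gsc$pathway_id[keep_pw],
    n_genes_tested = n_present[keep_pw],
    score = obs,
    p_up = p_up,
    p_down = p_down,
    direction = ifelse(p_up <= p_down, "UP", "DOWN"),
    p_perm = pmin(p_up, p_down),
    n_permutations = n_used,
    seed = as.integer(seed)
  )
  class(out) <- c("pathway_perm_result", class(out))
  attr(out, "dataset_id") <- ds$dataset_id
  out
}

# Row indices of ds$values for a vector of (unique) gene symbols, falling
# back to probe ids for unannotated rows.
match_rows <- function(ds, genes) {
  lab <- ds$probes$gene_symbol
  lab[lab == ""] <- ds$probes$probe_id[lab == ""]
  match(genes, lab)
}

#' Select significantly shifted pathways in one cohort
#'
#' A pathway enters the up set if `p_up <= alpha` and the down set if
#' `p_down <= alpha`. A pathway passing both enters only the set with the
#' smaller p-value; an exact tie excludes it with a warning.
#'
#' @param results A `pathway_perm_result` tibble.
#' @param alpha Significance level (default 0.05; the boundary is included).
#' @return A list with character vectors `up` and `down`.
#' @export
significant_pathways <- function(results, alpha = 0.05) {
  up <- results$p_up <= alpha
  down <- results$p_down <= alpha
  both <- up & down
  if (any(both)) {
    tie <- both & results$p_up == results$p_down
    if (any(tie)) {
      rlang::warn(paste0("Pathway(s) tied between directions excluded: ",
                         paste(results$pathway_id[tie], collapse = ", ")))
    }
    up[both] <- !tie[both] & results$p_up[both] < results$p_down[both]
    down[both] <- !tie[both] & results$p_down[both] < results$p_up[both]
  }
  list(up = results$pathway_id[up], down = results$pathway_id[down])
}

#' Cross-cohort common pathways
#'
#' Intersects the per-cohort up sets and, separately, the per-cohort down
#' sets. Direction concordance is required: a pathway significant up in some
#' cohorts and down in others belongs to neither intersection.
#'
#' @param per_dataset A list of `list(up =, down =)` as returned by
#'   [significant_pathways()], one per cohort.
#' @return A list with character vectors `up` and `down`.
#' @export
common_pathways <- function(per_dataset) {
  up <- Reduce(intersect, lapply(per_dataset, `[[`, "up"))
  down <- Reduce(intersect, lapply(per_dataset, `[[`, "down"))
  conflicted <- intersect(up, down)
  list(up = sort(setdiff(up, conflicted)), down = sort(setdiff(down, conflicted)))
}
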