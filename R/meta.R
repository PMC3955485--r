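#' Unpaired per-gene t test in one cohort
#'
#' Identical computation to [gene_t_statistics()] (shared implementation),
#' returned for a single gene. The unpaired test is used even for paired
#' designs; pair labels are deliberately ignored.
#'
#' @param ds A preprocessed [expression_dataset()].
#' @param gene Gene symbol.
#' @return A list with elements `t` and `p`.
#' @export
unpaired_gene_p <- function(ds, gene) {
  st <- gene_t_statistics(ds)
  i <- match(gene, st$gene)
  if (is.na(i)) {
    pcx_abort(sprintf("Gene %s not present in dataset %s.", gene, ds$dataset_id),
              "pcx_bad_argument")
  }
  list(t = st$t[i], p = st$p_two_sided[i])
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values as `X^2 = -2 * sum(ln p_i)`, referred to a
#' chi-square distribution with `2k` degrees of freedom (natural logarithm).
#' For k = 1 the combined p equals the input p analytically.
#'
#' @param pvalues Non-empty numeric vector of probabilities in (0, 1]. Exact
#'   zeros are a domain error: callers must floor p-values at their test's
#'   attainable minimum first.
#' @return A list with `chi_square`, `df` (= 2k) and `p_combined`.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05, 0.05))
fisher_combine <- function(pvalues) {
  if (!is.numeric(pvalues) || !length(pvalues)) {
    pcx_abort("Need a non-empty numeric vector of p-values.", "pcx_bad_argument")
  }
  if (any(is.na(pvalues)) || any(pvalues > 1) || any(pvalues < 0)) {
    pcx_abort("p-values must lie in (0, 1].", "pcx_bad_argument")
  }
  if (any(pvalues == 0)) {
    pcx_abort("p = 0 is outside the domain of Fisher's method; floor at the test's minimum attainable p.",
              "pcx_domain_error")
  }
  x2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi_square = x2, df = df,
       p_combined = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Gene-level meta-analysis across cohorts
#'
#' Runs the per-gene unpaired t test in every cohort and combines the
#' two-sided p-values with Fisher's method. A gene missing from some cohorts
#' contributes a reduced k (only the cohorts where it survived
#' preprocessing). Underflowed per-cohort p-values are floored at the
#' smallest positive double before combining. The mean direction is the sign
#' of the average contributing t statistic.
#'
#' @param datasets List of preprocessed [expression_dataset()]s.
#' @return A tibble of class `meta_gene_result` with columns `gene`, `k`,
#'   `per_dataset_p` (list-column of named per-cohort p-values),
#'   `per_dataset_t` (list-column), `chi_square`, `df`, `p_combined`,
#'   `mean_t`, `direction` (`"UP"`, `"DOWN"` or `"UNDEFINED"`).
#' @export
run_meta <- function(datasets) {
  if (!length(datasets)) {
    pcx_abort("Need at least one dataset.", "pcx_bad_argument")
  }
  per <- purrr::map(datasets, function(ds) {
    st <- gene_t_statistics(ds)
    tibble::tibble(dataset_id = ds$dataset_id, gene = st$gene,
                   t = st$t, p = pmax(st$p_two_sided, .Machine$double.xmin))
  })
  long <- dplyr::bind_rows(per)

  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      k = dplyr::n(),
      per_dataset_p = list(stats::setNames(.data$p, .data$dataset_id)),
      per_dataset_t = list(stats::setNames(.data$t, .data$dataset_id)),
      chi_square = -2 * sum(log(.data$p)),
      mean_t = mean(.data$t),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      df = 2L * .data$k,
      p_combined = stats::pchisq(.data$chi_square, df = .data$df,
                                 lower.tail = FALSE),
      direction = dplyr::case_when(
        .data$mean_t > 0 ~ "UP",
        .data$mean_t < 0 ~ "DOWN",
        TRUE ~ "UNDEFINED"
      )
    ) |>
    dplyr::select("gene", "k", "per_dataset_p", "per_dataset_t",
                  "chi_square", "df", "p_combined", "mean_t", "direction") |>
    dplyr::arrange(.data$gene)

  undef <- out$direction == "UNDEFINED"
  if (any(undef)) {
    rlang::inform(sprintf("%d gene(s) with exactly zero mean t: direction UNDEFINED.",
                          sum(undef)))
  }
  class(out) <- c("meta_gene_result", class(out))
  out
}

#' Select meta-significant genes
#'
#' Genes with combined p strictly below `alpha` (this stage uses `<`, unlike
#' the permutation stage's `<=`).
#'
#' @param results A `meta_gene_result` tibble from [run_meta()].
#' @param alpha Significance level (default 0.05).
#' @return Character vector of gene symbols.
#' @export
select_significant_genes <- function(results, alpha = 0.05) {
  results$gene[results$p_combined < alpha]
}
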