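## Brute-force oracles, implemented independently of the package's own
## statistical code paths (stats::t.test, explicit series, combinatorics).

# Upper-tail chi-square probability for even df via the closed-form series
# exp(-x/2) * sum_{j<k} (x/2)^j / j!.
oracle_chisq_upper_tail_even_df <- function(x, df) {
  stopifnot(x >= 0, df > 0)
  if (df %% 2 != 0) stop("oracle only supports even df")
  j <- 0:(df / 2 - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Exact permutation p for the mean member-gene t statistic, by enumerating
# every group-size-preserving label assignment (observed included). Member
# gene t statistics come from stats::t.test.
oracle_exhaustive_permutation_p <- function(values, groups, member_rows) {
  n <- ncol(values)
  n1 <- sum(groups == "TUMOR")
  if (n > 12) stop("oracle refuses designs with more than 12 samples")
  score <- function(tumor_cols) {
    mean(vapply(member_rows, function(r) {
      v <- values[r, ]
      unname(stats::t.test(v[tumor_cols], v[-tumor_cols],
                           var.equal = TRUE)$statistic)
    }, 0))
  }
  obs <- score(which(groups == "TUMOR"))
  picks <- utils::combn(n, n1)
  all_scores <- apply(picks, 2, score)
  list(p_up = mean(all_scores >= obs),
       p_down = mean(all_scores <= obs),
       n_assignments = ncol(picks))
}

# Hypergeometric upper tail P(X >= k) by direct combinatorial summation.
oracle_hypergeom_upper <- function(k, n_background, n_pathway, n_sig) {
  j <- k:min(n_pathway, n_sig)
  sum(choose(n_pathway, j) * choose(n_background - n_pathway, n_sig - j)) /
    choose(n_background, n_sig)
}

# Closed-form power of the two-sided equal-variance two-sample t test with
# noncentrality delta * sqrt(n / 2).
oracle_t_power <- function(delta, sd, n, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- (delta / sd) * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp = ncp) + stats::pt(crit, df, ncp = ncp,
                                              lower.tail = FALSE)
}
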