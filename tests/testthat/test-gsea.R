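test_that("gene t statistics match the pooled-t closed form", {
  m <- rbind(g1 = c(4, 5, 6, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  ds <- toy_dataset(m, rep(c("TUMOR", "NORMAL"), each = 3), genes = "G1")
  st <- gene_t_statistics(ds)
  expect_equal(round(st$t, 3), 3.674)
  expect_equal(st$df, 4)
  expect_equal(st$p_two_sided, 0.0213, tolerance = 0.02)

  # against the independent implementation
  tt <- stats::t.test(m[1, 1:3], m[1, 4:6], var.equal = TRUE)
  expect_equal(st$t, unname(tt$statistic))
  expect_equal(st$p_two_sided, tt$p.value)
})

test_that("t statistics are antisymmetric in the group labels", {
  ds <- random_dataset(n_probes = 8, n_per_group = 4, seed = 5)
  st <- gene_t_statistics(ds)
  flipped <- ds
  flipped$samples$group <- ifelse(ds$samples$group == "TUMOR", "NORMAL", "TUMOR")
  st2 <- gene_t_statistics(flipped)
  expect_equal(st2$t, -st$t)
  expect_equal(st2$p_two_sided, st$p_two_sided)
})

test_that("degenerate genes are handled per their mean difference", {
  m <- rbind(flat = rep(1, 6),             # zero variance, zero difference
             jump = rep(c(2, 5), each = 3), # zero variance, nonzero difference
             ok = c(1.2, 0.8, 1.1, 2.2, 1.8, 2.4))
  colnames(m) <- paste0("s", 1:6)
  ds <- toy_dataset(m, rep(c("TUMOR", "NORMAL"), each = 3),
                    genes = c("FLAT", "JUMP", "OK"))
  expect_warning(st <- gene_t_statistics(ds), "JUMP")
  expect_setequal(st$gene, c("FLAT", "OK"))
  expect_equal(st$t[st$gene == "FLAT"], 0)
  expect_equal(st$p_two_sided[st$gene == "FLAT"], 1)
})

test_that("the pathway score is the mean member t", {
  tstats <- tibble::tibble(gene = c("A", "B", "C"), t = c(2, -1, 10),
                           df = 4, p_two_sided = c(0.1, 0.5, 0.001))
  expect_equal(pathway_score(tstats, c("A", "B")), 0.5)
  expect_equal(pathway_score(tstats, "C"), 10)
  expect_warning(out <- pathway_score(tstats, "ZZZ"), "skipped")
  expect_true(is.na(out))
})

test_that("exhaustive enumeration gives exact small-design p-values", {
  # one strongly up pathway on a 3v3 design: its score is the unique maximum
  m <- rbind(g1 = c(9.8, 10.1, 10.3, 6.9, 7.2, 7.0),
             g2 = c(9.9, 10.2, 10.0, 7.1, 6.8, 7.3))
  colnames(m) <- paste0("s", 1:6)
  ds <- toy_dataset(m, rep(c("TUMOR", "NORMAL"), each = 3),
                    genes = c("G1", "G2"))
  gsc <- gene_set_collection("mapX", "both genes", "", list(c("G1", "G2")))
  res <- permutation_test(ds, gsc, exhaustive = TRUE)
  expect_equal(res$n_permutations, 20)  # C(6,3) assignments
  expect_equal(res$p_up, 1 / 20)
  expect_equal(res$direction, "UP")

  # matches the independent enumeration oracle
  oracle <- oracle_exhaustive_permutation_p(m, ds$samples$group, 1:2)
  expect_equal(res$p_up, oracle$p_up)
  expect_equal(res$p_down, oracle$p_down)
})

test_that("Monte-Carlo permutation p agrees with enumeration within 3 binomial SE", {
  for (n_per_group in c(3, 4)) {
    ds <- random_dataset(n_probes = 6, n_per_group = n_per_group, seed = 60 + n_per_group)
    gsc <- block_gsc(sprintf("GENE%02d", 1:6), set_size = 3)
    exact <- permutation_test(ds, gsc, exhaustive = TRUE)
    mc <- permutation_test(ds, gsc, n_permutations = 1000, seed = 314)
    for (i in seq_len(nrow(exact))) {
      se <- sqrt(exact$p_up[i] * (1 - exact$p_up[i]) / 1000)
      expect_lt(abs(mc$p_up[i] - exact$p_up[i]), 3 * se + 2 / 1001)
      se_d <- sqrt(exact$p_down[i] * (1 - exact$p_down[i]) / 1000)
      expect_lt(abs(mc$p_down[i] - exact$p_down[i]), 3 * se_d + 2 / 1001)
    }
  }
})

test_that("permutation results are reproducible from the seed and floored", {
  ds <- random_dataset(n_probes = 6, n_per_group = 4, seed = 8)
  gsc <- block_gsc(sprintf("GENE%02d", 1:6), set_size = 2)
  a <- permutation_test(ds, gsc, n_permutations = 200, seed = 42)
  b <- permutation_test(ds, gsc, n_permutations = 200, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(a$p_up >= 1 / 201))
  expect_true(all(a$p_down >= 1 / 201))
  expect_equal(a$p_perm, pmin(a$p_up, a$p_down))
})

test_that("negating the matrix swaps the up and down sets exactly", {
  study <- simulate_study(sim_config(n_datasets = 1, samples_per_group = 7,
    n_genes = 150, n_pathways = 10, genes_per_pathway = 10,
    iqr_decoy_frac = 0, seed = 77))
  ds <- preprocess_dataset(study$datasets[[1]], study$gene_sets)$dataset
  res <- permutation_test(ds, study$gene_sets, n_permutations = 300, seed = 9)
  neg <- ds
  neg$values <- -neg$values
  res_neg <- permutation_test(neg, study$gene_sets, n_permutations = 300, seed = 9)
  sig <- significant_pathways(res)
  sig_neg <- significant_pathways(res_neg)
  expect_setequal(sig$up, sig_neg$down)
  expect_setequal(sig$down, sig_neg$up)
})

test_that("significance selection includes the alpha boundary", {
  res <- tibble::tibble(
    pathway_id = c("A", "B", "C"),
    p_up = c(0.05, 0.051, 0.9),
    p_down = c(0.9, 0.9, 0.01))
  sets <- significant_pathways(res, alpha = 0.05)
  expect_equal(sets$up, "A")       # p = 0.05 exactly -> included
  expect_equal(sets$down, "C")     # B at 0.051 excluded

  # a pathway passing both directions goes to the smaller p; ties drop out
  res2 <- tibble::tibble(pathway_id = c("D", "E"),
                         p_up = c(0.01, 0.02), p_down = c(0.03, 0.02))
  expect_warning(sets2 <- significant_pathways(res2, alpha = 0.05), "tied")
  expect_equal(sets2$up, "D")
  expect_length(sets2$down, 0)
})

test_that("common pathways require presence in every cohort with one direction", {
  per_ds <- list(list(up = c("A", "B"), down = c("X")),
                 list(up = c("B", "C"), down = c("X", "Y")),
                 list(up = c("B"), down = c("X")))
  out <- common_pathways(per_ds)
  expect_equal(out$up, "B")
  expect_equal(out$down, "X")

  # discordant pathway (up in some cohorts, down in another) is excluded
  per_ds2 <- list(list(up = "A", down = character()),
                  list(up = "A", down = character()),
                  list(up = character(), down = "A"))
  out2 <- common_pathways(per_ds2)
  expect_length(out2$up, 0)
  expect_length(out2$down, 0)

  # single cohort returns its own sets
  one <- list(list(up = c("P", "Q"), down = "R"))
  expect_setequal(common_pathways(one)$up, c("P", "Q"))
  expect_equal(common_pathways(one)$down, "R")
})
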