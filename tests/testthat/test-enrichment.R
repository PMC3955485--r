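test_that("the hypergeometric tail matches exact enumeration", {
  background <- sprintf("B%02d", 1:20)
  gsc <- gene_set_collection("mapA", "five members", "",
                             list(background[1:5]))
  # all five significant genes are the five members: p = 1 / C(20, 5)
  rec <- hypergeometric_enrichment(background[1:5], gsc, background)
  expect_equal(rec$p_enrich, 1 / choose(20, 5))
  expect_equal(rec$n_overlap, 5)
  expect_equal(rec$n_background, 20)

  # random small configurations against the combinatorial oracle
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- sample(3:8, 1)
      n_sig <- sample(3:10, 1)
      gsc_i <- gene_set_collection("mapB", "set", "",
                                   list(sample(background, m)))
      sig <- sample(background, n_sig)
      rec_i <- hypergeometric_enrichment(sig, gsc_i, background)
      k <- length(intersect(sig, gsc_i$genes[[1]]))
      if (k == 0) {
        expect_equal(nrow(rec_i), 0)
      } else {
        expect_equal(rec_i$p_enrich,
                     oracle_hypergeom_upper(k, 20, m, n_sig),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("zero-overlap pathways are omitted and saturation gives p = 1", {
  background <- sprintf("B%02d", 1:12)
  gsc <- gene_set_collection(c("map1", "map2"), c("hit", "miss"), c("", ""),
                             list(background[1:4], background[9:12]))
  rec <- hypergeometric_enrichment(background[1:3], gsc, background)
  expect_equal(rec$pathway_id, "map1")

  # significant list = whole background -> every pathway at p = 1
  rec_all <- hypergeometric_enrichment(background, gsc, background)
  expect_equal(nrow(rec_all), 2)
  expect_true(all(rec_all$p_enrich == 1))
})

test_that("significant genes outside the background are named in the error", {
  gsc <- gene_set_collection("map1", "s", "", list(c("A", "B")))
  err <- expect_error(
    hypergeometric_enrichment(c("A", "ROGUE"), gsc, c("A", "B", "C")),
    class = "pcx_bad_argument")
  expect_match(conditionMessage(err), "ROGUE")
})

test_that("growing the significant list never shrinks enrichment evidence unfairly", {
  background <- sprintf("B%02d", 1:25)
  gsc <- gene_set_collection("map1", "s", "", list(background[1:6]))
  sig <- background[1:4]
  p_before <- hypergeometric_enrichment(sig, gsc, background)$p_enrich
  # adding a non-member gene enlarges n_sig with the same overlap
  p_after <- hypergeometric_enrichment(c(sig, background[20]), gsc,
                                       background)$p_enrich
  expect_gt(p_after, p_before)
})

test_that("direction labels follow the majority with a net-t tie-break", {
  meta <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    p_combined = c(0.001, 0.002, 0.003, 0.004),
    mean_t = c(2, 1.5, -1, 1))
  rec <- tibble::tibble(
    pathway_id = "mapZ", name = "z", classification = "",
    n_overlap = 3L, n_pathway = 4L, n_sig = 4L, n_background = 10L,
    p_enrich = 0.01, member_genes = list(c("A", "B", "C")))
  class(rec) <- c("enrichment_result", class(rec))
  out <- assign_direction(rec, meta)
  expect_equal(out$direction, "UP")  # 2 of 3 positive
  expect_equal(out$member_genes[[1]]$gene, c("A", "B", "C"))

  # all negative -> DOWN
  meta_dn <- dplyr::mutate(meta, mean_t = -abs(mean_t))
  expect_equal(assign_direction(rec, meta_dn)$direction, "DOWN")

  # 2 up / 2 down resolved by the sign of the summed mean t (+0.3 here)
  meta_tie <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    p_combined = rep(0.001, 4),
    mean_t = c(1.0, 0.8, -0.9, -0.6))
  rec4 <- rec
  rec4$member_genes <- list(c("A", "B", "C", "D"))
  expect_equal(assign_direction(rec4, meta_tie)$direction, "UP")

  # exact zero net t -> UNDEFINED with a warning
  meta_zero <- dplyr::mutate(meta_tie, mean_t = c(1, -1, 1, -1))
  expect_warning(out0 <- assign_direction(rec4, meta_zero), "undefined|UNDEFINED")
  expect_equal(out0$direction, "UNDEFINED")
})

test_that("enrichment significance is strict and matches reported magnitudes", {
  rec <- tibble::tibble(
    pathway_id = c("map04610", "map05322"),
    name = c("complement-like", "lupus-like"),
    classification = c("", ""),
    n_overlap = c(5L, 4L), n_pathway = c(8L, 8L), n_sig = c(10L, 10L),
    n_background = c(40L, 40L),
    p_enrich = c(0.00363, 0.09307),
    member_genes = list(character(), character()),
    direction = c("UP", "DOWN"))
  class(rec) <- c("enrichment_result", class(rec))
  keep <- significant_enrichment(rec, alpha = 0.05)
  expect_equal(keep$pathway_id, "map04610")
  expect_equal(nrow(significant_enrichment(rec, alpha = 1)), 2)
})

test_that("null enrichment p-values are not anti-conservative", {
  # a null study: significance assigned to a random gene subset
  background <- sprintf("G%03d", 1:200)
  gsc <- block_gsc(background, set_size = 10)
  withr::with_seed(404, {
    rates <- vapply(1:40, function(i) {
      sig <- sample(background, 10)
      rec <- hypergeometric_enrichment(sig, gsc, background)
      sum(rec$p_enrich < 0.05) / nrow(gsc)
    }, 0)
  })
  # empirical type-I rate across replicates stays at or below alpha + 3 SE
  se <- sqrt(0.05 * 0.95 / (40 * nrow(gsc)))
  expect_lt(mean(rates), 0.05 + 3 * se)
})
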