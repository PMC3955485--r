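test_that("a toy cohort loads with correct dimensions and metadata", {
  ds <- random_dataset(n_probes = 3, n_per_group = 2)
  paths <- write_fixture_files(ds)
  loaded <- read_expression(paths$matrix, paths$samples, paths$probes,
                            dataset_id = "rand")
  expect_s3_class(loaded, "expression_dataset")
  expect_equal(n_probes(loaded), 3)
  expect_equal(n_samples(loaded), 4)
  expect_equal(loaded$samples$group, c("TUMOR", "TUMOR", "NORMAL", "NORMAL"))
  expect_equal(loaded$probes$gene_symbol, sprintf("GENE%02d", 1:3))
})

test_that("group labels are read case-insensitively", {
  ds <- random_dataset()
  paths <- write_fixture_files(ds)
  ann <- read_result_table(paths$samples)
  ann$group <- c("Tumor", "tumor", "TUMOR", "Normal", "normal", "NORMAL")
  readr::write_tsv(ann, paths$samples)
  loaded <- read_expression(paths$matrix, paths$samples, paths$probes)
  expect_equal(loaded$samples$group, rep(c("TUMOR", "NORMAL"), each = 3))
})

test_that("write -> read round-trips a dataset exactly on all fields", {
  for (seed in 1:5) {
    ds <- random_dataset(n_probes = 4 + seed, n_per_group = 2 + seed %% 3,
                         seed = seed, id = paste0("rt", seed))
    paths <- write_fixture_files(ds)
    back <- read_expression(paths$matrix, paths$samples, paths$probes,
                            dataset_id = ds$dataset_id)
    expect_equal(back$values, ds$values)
    expect_equal(back$probes, ds$probes)
    expect_equal(back$samples$group, ds$samples$group)
    expect_equal(back$samples$sample_id, ds$samples$sample_id)
  }
})

test_that("the loader rejects each kind of invalid input with a named error", {
  ds <- random_dataset()
  base <- write_fixture_files(ds)

  corrupt <- function(file, fun) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    for (f in base) file.copy(f, dir)
    p <- lapply(base, function(f) file.path(dir, basename(f)))
    lines <- readLines(p[[file]])
    writeLines(fun(lines), p[[file]])
    p
  }

  # unknown group label, error names the offending sample
  p <- corrupt("samples", function(l) c(l[1], sub("TUMOR", "Tumour", l[2]), l[-(1:2)]))
  err <- expect_error(read_expression(p$matrix, p$samples, p$probes),
                      class = "pcx_unknown_group")
  expect_match(conditionMessage(err), "t01")

  # duplicate probe id
  p <- corrupt("matrix", function(l) c(l, l[2]))
  expect_error(read_expression(p$matrix, p$samples, p$probes),
               class = "pcx_duplicate_probes")

  # sample present in matrix but missing from annotation
  p <- corrupt("samples", function(l) l[-2])
  expect_error(read_expression(p$matrix, p$samples, p$probes),
               class = "pcx_missing_annotation")

  # non-numeric cell
  p <- corrupt("matrix", function(l) c(l[1], sub("^(p01\t)[0-9.\\-]+", "\\1abc", l[2]), l[-(1:2)]))
  expect_error(read_expression(p$matrix, p$samples, p$probes),
               class = "pcx_non_numeric")

  # missing cell
  p <- corrupt("matrix", function(l) c(l[1], sub("^(p01\t)[0-9.\\-]+", "\\1NA", l[2]), l[-(1:2)]))
  expect_error(read_expression(p$matrix, p$samples, p$probes),
               class = "pcx_missing_values")
})

test_that("GMT parsing handles names, classifications and dedup", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c(
    "map00020\tCitrate cycle (TCA cycle)|Metabolism\tIDH1\tIDH2\tFH",
    "map99999\tRepeats only\tA\tA\tB"
  ), gmt)
  gsc <- read_gmt(gmt)
  expect_equal(nrow(gsc), 2)
  expect_equal(gsc$name[1], "Citrate cycle (TCA cycle)")
  expect_equal(gsc$classification[1], "Metabolism")
  expect_setequal(gsc$genes[[1]], c("IDH1", "IDH2", "FH"))
  # duplicated gene counted once
  expect_equal(gsc$n_genes[2], 2)
  expect_equal(gsc$classification[2], "")

  # round trip
  out <- file.path(dir, "roundtrip.gmt")
  write_gmt(gsc, out)
  back <- read_gmt(out)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(gsc))
})

test_that("GMT errors carry line numbers; empty files give empty collections", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.gmt")
  writeLines(c("map00001\tok|x\tG1", "map00002\tonly-two-fields"), bad)
  err <- expect_error(read_gmt(bad), class = "pcx_gmt_parse")
  expect_match(conditionMessage(err), "line 2")

  dup <- file.path(dir, "dup.gmt")
  writeLines(c("map00001\ta|x\tG1", "map00001\tb|y\tG2"), dup)
  expect_error(read_gmt(dup), class = "pcx_duplicate_pathway")

  empty <- file.path(dir, "empty.gmt")
  writeLines(character(), empty)
  expect_equal(nrow(read_gmt(empty)), 0)
})

test_that("result tables round-trip values, order and scientific notation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.tsv")

  tbl <- tibble::tibble(gene = c("ALDH1B1", "FH", "ZZZ"),
                        p = c(1.21e-06, 8.33e-05, 0.98765432))
  write_result_table(tbl, path)
  back <- read_result_table(path)
  expect_equal(back$p, tbl$p)
  expect_equal(back$gene, tbl$gene)

  # empty table -> header-only file
  write_result_table(tbl[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(names(read_result_table(path)), c("gene", "p"))

  # invalid tables refused
  bad <- tbl
  names(bad) <- c("gene", "gene")
  expect_error(write_result_table(bad, path), class = "pcx_bad_table")
  expect_error(write_result_table(tibble::tibble(x = list(1)), path),
               class = "pcx_bad_table")
})
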