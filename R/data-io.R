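#' Read one cohort from tab-delimited files
#'
#' Loads an expression matrix, its sample annotation and a probe-to-gene map
#' into a validated [expression_dataset()].
#'
#' @param matrix_path Tab-delimited matrix: first column probe ids, header row
#'   of sample ids, cells log2 intensities.
#' @param annotation_path Tab-delimited table with columns `sample_id`,
#'   `group` (`TUMOR`/`NORMAL`, case-insensitive) and optionally `pair`.
#' @param probe_map_path Tab-delimited table with columns `probe_id`,
#'   `gene_symbol`. Probes absent from the map are retained with an empty
#'   symbol (they are dropped later by preprocessing). `NULL` to skip.
#' @param dataset_id Cohort label; defaults to the matrix file name.
#'
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, annotation_path, probe_map_path = NULL,
                            dataset_id = NULL) {
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = "c"),
                         name_repair = "minimal", progress = FALSE)
  if (ncol(raw) < 2L) {
    pcx_abort("Expression matrix needs a probe column plus >=1 sample column.",
              "pcx_invalid_matrix")
  }
  sample_ids <- names(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    pcx_abort(paste0("Duplicate sample ids in matrix header: ",
                     paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
              "pcx_duplicate_samples")
  }
  probe_ids <- as.character(raw[[1]])
  if (anyDuplicated(probe_ids)) {
    pcx_abort(paste0("Duplicate probe ids in matrix: ",
                     paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")),
              "pcx_duplicate_probes")
  }
  cells <- as.matrix(raw[-1])
  missing <- is.na(cells) | cells == "" | cells == "NA"
  if (any(missing)) {
    w <- which(missing, arr.ind = TRUE)[1, ]
    pcx_abort(sprintf("Missing value at probe %s, sample %s.",
                      probe_ids[w[1]], sample_ids[w[2]]),
              "pcx_missing_values")
  }
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- is.na(values)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    pcx_abort(sprintf("Non-numeric cell '%s' at probe %s, sample %s.",
                      cells[w[1], w[2]], probe_ids[w[1]], sample_ids[w[2]]),
              "pcx_non_numeric")
  }
  dimnames(values) <- list(probe_ids, sample_ids)

  ann <- readr::read_tsv(annotation_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(ann))) {
    pcx_abort("Annotation needs columns sample_id and group.",
              "pcx_bad_annotation")
  }
  if (anyDuplicated(ann$sample_id)) {
    pcx_abort("Duplicate sample ids in annotation.", "pcx_duplicate_samples")
  }

  probes <- NULL
  if (!is.null(probe_map_path)) {
    probes <- readr::read_tsv(probe_map_path,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
    if (!all(c("probe_id", "gene_symbol") %in% names(probes))) {
      pcx_abort("Probe map needs columns probe_id and gene_symbol.",
                "pcx_bad_probe_map")
    }
  }

  expression_dataset(values, ann, probes, dataset_id = dataset_id)
}

#' Write one cohort to tab-delimited files
#'
#' Inverse of [read_expression()]: writes `<id>_matrix.tsv`,
#' `<id>_samples.tsv` and `<id>_probes.tsv` under `dir`.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_expression <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, paste0(ds$dataset_id, "_matrix.tsv")),
    samples = file.path(dir, paste0(ds$dataset_id, "_samples.tsv")),
    probes = file.path(dir, paste0(ds$dataset_id, "_probes.tsv"))
  )
  mat_tbl <- tibble::as_tibble(ds$values, rownames = "probe_id")
  readr::write_tsv(mat_tbl, paths$matrix, progress = FALSE)
  readr::write_tsv(ds$samples, paths$samples, na = "", progress = FALSE)
  readr::write_tsv(ds$probes, paths$probes, progress = FALSE)
  invisible(paths)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated: set id, description, then
#' member gene symbols. The description field is overloaded as
#' `"name|classification"` so that KEGG-style classification labels survive
#' the format (plain descriptions without a pipe are taken as the name with
#' empty classification).
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()]; empty files yield an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(gene_set_collection(character(), character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    pcx_abort(sprintf("GMT line %d has fewer than 3 fields.", which(short)[1]),
              "pcx_gmt_parse")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  pipe <- regexpr("|", desc, fixed = TRUE)
  nm <- ifelse(pipe > 0, substr(desc, 1, pipe - 1), desc)
  cls <- ifelse(pipe > 0, substr(desc, pipe + 1, nchar(desc)), "")
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  gene_set_collection(ids, nm, cls, genes)
}

#' @rdname read_gmt
#' @param gsc A [gene_set_collection()] to write.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(seq_len(nrow(gsc)), function(i) {
    paste(c(gsc$pathway_id[i],
            paste0(gsc$name[i], "|", gsc$classification[i]),
            gsc$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a result table
#'
#' Deterministic tab-delimited output for every stage result. Floats are
#' written at full (round-trip) precision; read-back restores values and row
#' order exactly.
#'
#' @param table A data frame without list columns; column names must be
#'   non-empty and unique.
#' @param path Output file path.
#' @return `write_result_table()` returns `path` invisibly;
#'   `read_result_table()` returns a tibble.
#' @export
write_result_table <- function(table, path) {
  nm <- names(table)
  if (any(!nzchar(nm)) || anyDuplicated(nm)) {
    pcx_abort("Result table column names must be non-empty and unique.",
              "pcx_bad_table")
  }
  if (any(vapply(table, is.list, TRUE))) {
    pcx_abort("Result table may not contain list columns; flatten first.",
              "pcx_bad_table")
  }
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
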