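# Plain-text I/O: TSV expression matrices, sample metadata, annotation,
# result JSON. All writers produce files the package's own readers ingest.

parse_error <- function(path, line, msg) {
  stop2(sprintf("%s: line %d: %s", path, line, msg), "dnbscreen_parse_error")
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a UTF-8 TSV whose first column is `gene_id` followed by one column
#' per sample. Duplicate gene ids, ragged rows and non-numeric cells raise a
#' parse error naming the offending line.
#'
#' @param path File path.
#' @param stage_label Stage label for the result; defaults to the file name
#'   without extension.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path,
                                stage_label = sub("\\.[^.]*$", "",
                                                  basename(path))) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) parse_error(path, 1L, "empty file")
  rows <- strsplit(lines, "\t", fixed = TRUE)
  header <- rows[[1L]]
  if (header[1L] != "gene_id") {
    parse_error(path, 1L, "first column must be 'gene_id'")
  }
  nc <- length(header)
  if (nc < 2L) parse_error(path, 1L, "no sample columns")
  n <- length(rows) - 1L
  ids <- character(n)
  vals <- matrix(NA_real_, n, nc - 1L)
  for (i in seq_len(n)) {
    r <- rows[[i + 1L]]
    if (length(r) != nc) {
      parse_error(path, i + 1L,
                  sprintf("expected %d fields, found %d", nc, length(r)))
    }
    ids[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) parse_error(path, i + 1L, "non-numeric expression value")
    vals[i, ] <- v
  }
  dup <- which(duplicated(ids))
  if (length(dup)) {
    parse_error(path, dup[1L] + 1L,
                sprintf("duplicated gene id '%s'", ids[dup[1L]]))
  }
  expression_matrix(vals, ids, header[-1L], stage_label)
}

#' Write a genes-by-samples expression TSV
#'
#' Values are written with 12 significant digits, so
#' `read_expression_tsv(write_expression_tsv(x))` round-trips exactly for
#' values representable at that precision.
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", x$sample_ids), collapse = "\t"), con)
  body <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i], sprintf("%.12g", x$values[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write a stage series as TSV stage files plus metadata
#'
#' Creates `dir/stages/<label>.tsv` for every stage, a sample-metadata table
#' `dir/metadata.tsv` (`sample_id`, `stage`, `stage_order`) and, when the
#' provenance carries ground truth (synthetic data), `dir/ground_truth.json`.
#'
#' @param series A [stage_series()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stage_series <- function(series, dir) {
  stopifnot(inherits(series, "stage_series"))
  stage_dir <- file.path(dir, "stages")
  dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in series$stages) {
    write_expression_tsv(s, file.path(stage_dir,
                                      paste0(s$stage_label, ".tsv")))
  }
  meta <- do.call(rbind, lapply(seq_along(series$stages), function(i) {
    s <- series$stages[[i]]
    data.frame(sample_id = s$sample_ids, stage = s$stage_label,
               stage_order = i)
  }))
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(series$provenance)) {
    jsonlite::write_json(series$provenance,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a stage series written by [write_stage_series()]
#'
#' Reads the metadata table, loads each stage TSV, and cross-validates the
#' sample ids: a metadata sample absent from its stage matrix (or vice versa)
#' raises an error listing the orphan ids.
#'
#' @param dir Directory containing `stages/` and `metadata.tsv`.
#' @return A [stage_series()].
#' @export
read_stage_series <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) {
    stop2(paste("metadata.tsv not found in", dir), "dnbscreen_parse_error")
  }
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "stage_order")
  if (!all(need %in% names(meta))) {
    stop2("metadata.tsv must have columns sample_id, stage, stage_order",
          "dnbscreen_parse_error")
  }
  ord <- unique(meta[order(meta$stage_order), "stage"])
  stages <- lapply(ord, function(lab) {
    x <- read_expression_tsv(file.path(dir, "stages", paste0(lab, ".tsv")),
                             stage_label = lab)
    want <- meta$sample_id[meta$stage == lab]
    orphan_meta <- setdiff(want, x$sample_ids)
    orphan_mat <- setdiff(x$sample_ids, want)
    if (length(orphan_meta) || length(orphan_mat)) {
      stop2(sprintf(
        "stage '%s': samples in metadata but not matrix [%s]; in matrix but not metadata [%s]",
        lab, paste(orphan_meta, collapse = ", "),
        paste(orphan_mat, collapse = ", ")),
        "dnbscreen_cross_validation")
    }
    x
  })
  truth_path <- file.path(dir, "ground_truth.json")
  prov <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    list()
  }
  stage_series(stages, stage_order = ord, provenance = prov)
}

#' Read a gene-annotation TSV
#'
#' Expects columns `gene_id` and `biotype` (header required). Duplicated gene
#' ids are resolved last-wins with a warning.
#'
#' @param path File path.
#' @return Data frame with columns `gene_id`, `biotype`.
#' @export
read_annotation_tsv <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop2(paste0(path, ": ", conditionMessage(e)),
                         "dnbscreen_parse_error")
                 })
  if (!all(c("gene_id", "biotype") %in% names(df))) {
    stop2(paste(path, "must have columns gene_id and biotype"),
          "dnbscreen_parse_error")
  }
  if (anyDuplicated(df$gene_id)) {
    warn2("duplicated gene_id in annotation: last entry wins",
          "dnbscreen_duplicate_annotation")
    df <- df[!duplicated(df$gene_id, fromLast = TRUE), , drop = FALSE]
  }
  df[, c("gene_id", "biotype")]
}

#' Write a detection result as JSON plus a per-stage index TSV
#'
#' @param result A [detect_predisease()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dnb_result <- function(result, dir) {
  stopifnot(inherits(result, "dnb_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comp <- result$components_by_stage
  jsonlite::write_json(list(
    predisease_stage = result$predisease_stage,
    is_significant = result$is_significant,
    members = result$members,
    candidate_pool_size = length(result$candidate_pool),
    composite_index_by_stage = as.list(result$composite_index_by_stage),
    components_by_stage = lapply(rownames(comp), function(r) {
      as.list(comp[r, ])
    }),
    config = unclass(result$config)
  ), file.path(dir, "dnb_result.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  idx <- data.frame(stage = names(result$composite_index_by_stage),
                    composite_index = unname(result$composite_index_by_stage),
                    sd_in = comp[, "sd_in"], r_in = comp[, "r_in"],
                    r_out = comp[, "r_out"])
  utils::write.table(idx, file.path(dir, "composite_index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write an intervention ranking as TSV
#'
#' One row per gene in rank order: `gene_id`, `index`, `rank`, `selected`.
#'
#' @param ranking An [intervention_index()] result (optionally after
#'   [select_top()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  stopifnot(inherits(ranking, "intervention_ranking"))
  df <- data.frame(gene_id = ranking$ranking,
                   index = sprintf("%.12g",
                                   unname(ranking$index[ranking$ranking])),
                   rank = seq_along(ranking$ranking),
                   selected = ranking$ranking %in% ranking$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
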