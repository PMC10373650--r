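#' Read a gene expression matrix from tab-separated text
#'
#' The expected layout is genes as rows: the first column holds gene
#' identifiers and the header row holds sample identifiers. Values must be
#' finite and nonnegative (expression units such as FPKM or TPM are not
#' constrained). Duplicate gene rows are collapsed by their mean with a
#' warning; duplicate sample identifiers are an error.
#'
#' @param path Path to a TSV file.
#' @param transpose If `TRUE`, the file is samples-as-rows and is transposed
#'   on read.
#' @return A tibble whose first column `gene` holds gene identifiers and whose
#'   remaining columns are samples, in file order.
#' @export
read_expression <- function(path, transpose = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort("expression file must contain at least 1 gene and 1 sample")
  }
  ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- ids
  if (transpose) {
    mat <- t(mat)
  }
  if (anyDuplicated(colnames(mat))) {
    dup <- unique(colnames(mat)[duplicated(colnames(mat))])
    abort(paste0("duplicate sample identifier(s): ", toString(head(dup, 5L))))
  }
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]
    ))
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- unique(rownames(mat)[duplicated(rownames(mat))])
    warn(paste0(
      "collapsing duplicate gene row(s) by mean: ", toString(head(dup, 5L))
    ))
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE) /
      as.vector(table(factor(rownames(mat), levels = unique(rownames(mat)))))
  }
  expr_to_tibble(mat)
}

#' Read a STRING-style scored edge list
#'
#' Three columns: two node identifiers and a numeric interaction confidence.
#' Scores are returned on a \[0, 1\] scale; when the maximum observed score
#' exceeds 1 the whole column is divided by 1000 (the STRING `combined_score`
#' 0--1000 dialect), with a message.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `node_a`, `node_b`, `score`.
#' @export
read_scored_edges <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warn("edge file contains no edges")
    return(tibble(node_a = character(), node_b = character(), score = double()))
  }
  if (ncol(raw) < 3L) abort("scored edge list needs 3 columns (node_a, node_b, score)")
  score <- suppressWarnings(as.numeric(raw[[3L]]))
  if (anyNA(score)) {
    abort(sprintf("non-numeric score '%s' at row %d", raw[[3L]][which(is.na(score))[1L]],
                  which(is.na(score))[1L]))
  }
  if (max(score) > 1) {
    inform("scores exceed 1; assuming STRING 0-1000 combined_score, dividing by 1000")
    score <- score / 1000
  }
  tibble(node_a = as.character(raw[[1L]]), node_b = as.character(raw[[2L]]),
         score = score)
}

#' Read a sample-to-stage annotation table
#'
#' Two or three tab-separated columns: `sample_id`, `stage_label`, and an
#' optional integer `stage_order`. When `stage_order` is absent the rank is
#' taken from first appearance of each label in the file.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `sample_id`, `stage_label`, `stage_order`.
#' @export
read_stage_annotation <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort("stage annotation table is empty")
  out <- tibble(sample_id = as.character(raw[[1L]]),
                stage_label = as.character(raw[[2L]]))
  if (ncol(raw) >= 3L) {
    ord <- suppressWarnings(as.integer(raw[[3L]]))
    if (anyNA(ord)) abort("stage_order column must be integer")
    out$stage_order <- ord
  } else {
    out$stage_order <- match(out$stage_label, unique(out$stage_label))
  }
  validate_stage_annotation(out)
}

validate_stage_annotation <- function(ann) {
  ann <- as_tibble(ann)
  stopifnot(all(c("sample_id", "stage_label", "stage_order") %in% names(ann)))
  if (anyDuplicated(ann$sample_id)) {
    dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
    abort(paste0("sample annotated more than once: ", toString(head(dup, 5L))))
  }
  per_label <- unique(ann[, c("stage_label", "stage_order")])
  if (anyDuplicated(per_label$stage_label)) {
    abort("each stage_label must map to a single stage_order")
  }
  ann
}

#' Read a survival table
#'
#' Three tab-separated columns: `sample_id`, `time` (nonnegative, in the
#' unit declared by the study -- days or months; no conversion is performed),
#' and `event` (1 = death, 0 = censored).
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) abort("survival table has no records")
  if (ncol(raw) < 3L) abort("survival table needs 3 columns (sample_id, time, event)")
  out <- tibble(sample_id = as.character(raw[[1L]]),
                time = suppressWarnings(as.numeric(raw[[2L]])),
                event = suppressWarnings(as.integer(raw[[3L]])))
  validate_survival(out)
}

validate_survival <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("sample_id", "time", "event") %in% names(records)))
  if (nrow(records) == 0L) abort("survival table has no records")
  if (anyDuplicated(records$sample_id)) abort("duplicate sample_id in survival table")
  if (anyNA(records$time) || any(!is.finite(records$time)) || any(records$time < 0)) {
    abort("survival time must be finite and >= 0")
  }
  if (anyNA(records$event) || !all(records$event %in% c(0L, 1L))) {
    bad <- records$sample_id[is.na(records$event) | !(records$event %in% c(0L, 1L))][1L]
    abort(sprintf("event must be 0 (censored) or 1 (death); offending sample '%s'", bad))
  }
  records
}

#' Write per-sample sMFE scores, or a biomarker table, to TSV
#'
#' `write_scores()` emits one row per sample with the global score and the
#' comma-joined signaling gene set; local per-gene scores can be written with
#' `tidy()` + `readr::write_tsv()`. Writing then reading back is the identity
#' on the data model.
#'
#' @param scores An [score_samples()] result.
#' @param results A biomarker tibble from [find_biomarkers()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "smfe_scores"))
  out <- glance(scores)
  out$signaling_genes <- vapply(scores$signaling[out$sample_id],
                                paste, character(1L), collapse = ",")
  readr::write_tsv(out, path)
  invisible(scores)
}

#' @rdname write_scores
#' @export
write_biomarkers <- function(results, path) {
  readr::write_tsv(as_tibble(results), path)
  invisible(results)
}

#' @rdname read_survival
#' @param records A survival tibble to write.
#' @param path Output file path.
#' @export
write_survival <- function(records, path) {
  readr::write_tsv(validate_survival(records), path)
  invisible(records)
}

# internal: tibble (gene + sample columns) or matrix -> validated matrix
as_expr_matrix <- function(x, arg = "expression") {
  if (is.matrix(x)) {
    mat <- x
    if (is.null(rownames(mat)) || is.null(colnames(mat))) {
      abort(sprintf("%s matrix needs gene rownames and sample colnames", arg))
    }
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) abort(sprintf("%s needs a gene column plus >= 1 sample column", arg))
    mat <- as.matrix(x[, -1L, drop = FALSE])
    rownames(mat) <- as.character(x[[1L]])
  } else {
    abort(sprintf("%s must be a data frame or a matrix", arg))
  }
  storage.mode(mat) <- "double"
  if (anyDuplicated(rownames(mat))) abort(sprintf("duplicate gene ids in %s", arg))
  if (anyDuplicated(colnames(mat))) abort(sprintf("duplicate sample ids in %s", arg))
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("%s has a non-finite or negative value at gene '%s', sample '%s'",
                  arg, rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  mat
}

expr_to_tibble <- function(mat) {
  out <- as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- tibble(gene = rownames(mat), !!!out)
  out
}

#' Write an expression tibble to TSV (genes as rows)
#'
#' @param expr Expression tibble (first column gene ids) or matrix.
#' @param path Output file path.
#' @export
write_expression <- function(expr, path) {
  mat <- as_expr_matrix(expr)
  readr::write_tsv(expr_to_tibble(mat), path)
  invisible(expr)
}
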