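# Tab-delimited readers/writers for the pipeline's standard tables.

#' Read a count table
#'
#' Expects a TSV with a `gene_id` column followed by one integer column per
#' sample.
#'
#' @param path Path to the TSV.
#' @return Count tibble.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  expr_matrix(counts, "count table")  # validates layout
  counts
}

#' Read a gene annotation table
#'
#' Expects `gene_id`, optional `gene_name` (`.` for missing), `length_bp`.
#'
#' @param path Path to the TSV.
#' @return Annotation tibble with `.` converted to `NA` gene names.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(ann))) {
    abort("annotation must have gene_id and length_bp columns")
  }
  if ("gene_name" %in% names(ann)) {
    ann$gene_name <- ifelse(ann$gene_name == ".", NA_character_,
                            ann$gene_name)
  } else {
    ann$gene_name <- NA_character_
  }
  ann[c("gene_id", "gene_name", "length_bp")]
}

#' Read a sample sheet
#'
#' Expects `sample_id`, `group`, `stage`, and optional `replicate`, `lineage`.
#'
#' @param path Path to the TSV.
#' @return Sample-sheet tibble.
#' @export
read_samples <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("sample_id", "group", "stage")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"replicate" %in% names(sheet)) sheet$replicate <- 1L
  if (!"lineage" %in% names(sheet)) sheet$lineage <- "none"
  if (anyDuplicated(sheet$sample_id)) {
    abort("sample sheet has duplicated sample_id values")
  }
  as_tibble(sheet)
}

#' Read gene sets in GMT format
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep(".", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
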