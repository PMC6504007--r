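# ICM-marker identification from bisected blastocysts and gene-panel
# trajectory extraction.

#' Identify ICM-specific transcripts from bisected blastocysts
#'
#' Blastocysts are bisected so that one half contains ICM and TE ("IT") and
#' the other only TE. A gene is an ICM marker when its mean FPKM is strictly
#' below `te_max` in TE halves and strictly above `it_min` in IT halves.
#'
#' @param fpkm FPKM table.
#' @param sample_sheet Sample sheet with `lineage` tags `IT`/`TE`.
#' @param te_max Strict upper bound on TE FPKM (default 1).
#' @param it_min Strict lower bound on IT FPKM (default 10).
#' @param group Optional group filter (e.g. `"IV-D"`).
#' @param rho Optional ICM mixture fraction: adds a model-based
#'   `icm_estimate = (IT - (1 - rho) * TE) / rho` column back-estimating the
#'   pure-ICM level from the IT/TE mixture.
#' @return Tibble sorted by `fpkm_it` descending: `gene_id`, `fpkm_it`,
#'   `fpkm_te`, `marker` (and `icm_estimate` when `rho` is given).
#' @export
icm_markers <- function(fpkm, sample_sheet, te_max = 1, it_min = 10,
                        group = NULL, rho = NULL) {
  m <- expr_matrix(fpkm, "FPKM table")
  sheet <- sample_sheet
  if (!is.null(group)) sheet <- sheet[sheet$group %in% group, , drop = FALSE]
  it_ids <- intersect(sheet$sample_id[sheet$lineage == "IT"], colnames(m))
  te_ids <- intersect(sheet$sample_id[sheet$lineage == "TE"], colnames(m))
  if (length(it_ids) == 0 || length(te_ids) == 0) {
    abort("need at least one IT and one TE sample (check lineage tags)")
  }
  fpkm_it <- rowMeans(m[, it_ids, drop = FALSE])
  fpkm_te <- rowMeans(m[, te_ids, drop = FALSE])
  out <- tibble(gene_id = rownames(m), fpkm_it = unname(fpkm_it),
                fpkm_te = unname(fpkm_te),
                marker = fpkm_te < te_max & fpkm_it > it_min)
  if (!is.null(rho)) {
    if (rho <= 0 || rho > 1) abort("rho must lie in (0, 1]")
    out$icm_estimate <- (out$fpkm_it - (1 - rho) * out$fpkm_te) / rho
  }
  arrange(out, dplyr::desc(.data$fpkm_it))
}

#' Built-in gene panels
#'
#' Editable GMT shipped with the package: `pluripotency` (KLF17, MYC, NANOG,
#' KLF4, MBD3, SOX2, BMP4, POU5F1), `kmt` (H3K4/H3K9/H3K27 lysine
#' methyltransferases) and `kdm` (lysine demethylases).
#'
#' @param path Optional path to an alternative GMT file.
#' @return Named list of character vectors of gene names.
#' @export
builtin_panels <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "panels.gmt", package = "embryodyn")
  }
  read_gmt(path)
}

#' Extract gene-panel expression trajectories
#'
#' Resolves panel members against annotation gene names (case-insensitive
#' exact match) and returns, for every gene x group x stage x replicate, the
#' FPKM together with the replicate mean of that gene x group x stage cell.
#' Unmatched panel genes are reported via the `unmatched` attribute and a
#' message, never silently dropped.
#'
#' @param fpkm FPKM table.
#' @param panel Character vector of gene names, or the name of a built-in
#'   panel (`"pluripotency"`, `"kmt"`, `"kdm"`).
#' @param sample_sheet Sample sheet.
#' @param annotation Annotation with `gene_id` and `gene_name`.
#' @param ordering Ordered stage labels (used to order the output).
#' @param groups Optional group filter; defaults to all embryo groups.
#' @return Long tibble: `gene_name`, `gene_id`, `group`, `stage`,
#'   `replicate`, `fpkm`, `mean_fpkm`.
#' @export
panel_trajectories <- function(fpkm, panel, sample_sheet, annotation,
                               ordering = DEFAULT_STAGES, groups = NULL) {
  if (length(panel) == 1 && panel %in% names(builtin_panels())) {
    panel <- builtin_panels()[[panel]]
  }
  panel <- unique(panel)
  m <- expr_matrix(fpkm, "FPKM table")
  idx <- match(toupper(panel), toupper(annotation$gene_name))
  unmatched <- panel[is.na(idx)]
  if (length(unmatched) > 0) {
    inform(sprintf("panel gene(s) not found in annotation: %s",
                   paste(unmatched, collapse = ", ")))
  }
  matched <- tibble(gene_name = panel[!is.na(idx)],
                    gene_id = annotation$gene_id[idx[!is.na(idx)]])
  sheet <- sample_sheet[sample_sheet$lineage == "none" &
                          sample_sheet$stage %in% ordering, , drop = FALSE]
  if (!is.null(groups)) sheet <- sheet[sheet$group %in% groups, , drop = FALSE]

  long <- matched |>
    dplyr::inner_join(
      as_tibble(m[matched$gene_id, sheet$sample_id, drop = FALSE],
                rownames = "gene_id") |>
        tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                            values_to = "fpkm"),
      by = "gene_id") |>
    dplyr::inner_join(sheet, by = "sample_id") |>
    group_by(.data$gene_name, .data$gene_id, .data$group, .data$stage) |>
    mutate(mean_fpkm = mean(.data$fpkm)) |>
    ungroup() |>
    arrange(.data$gene_name, .data$group, match(.data$stage, ordering),
            .data$replicate) |>
    select("gene_name", "gene_id", "group", "stage", "replicate", "fpkm",
           "mean_fpkm")
  attr(long, "unmatched") <- unmatched
  long
}
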