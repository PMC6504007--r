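# Staging analyses: successive-stage DEG profiles, stage-specific and
# first-expressed gene classification, set overlaps, over-representation.

# Stages of `ordering` present for `group` in the sheet, in order.
stage_series <- function(sample_sheet, group, ordering) {
  present <- unique(sample_sheet$stage[sample_sheet$group == group])
  series <- ordering[ordering %in% present]
  if (length(series) < 2) {
    abort(sprintf("group '%s' has fewer than 2 stages in the ordering", group))
  }
  series
}

# Mean FPKM per gene x stage for one group (replicates collapsed by
# arithmetic mean). Returns genes x stages matrix.
collapse_fpkm <- function(fpkm, sample_sheet, group, series) {
  m <- expr_matrix(fpkm, "FPKM table")
  out <- matrix(NA_real_, nrow = nrow(m), ncol = length(series),
                dimnames = list(rownames(m), series))
  for (s in series) {
    ids <- sample_sheet$sample_id[sample_sheet$group == group &
                                    sample_sheet$stage == s &
                                    sample_sheet$lineage == "none"]
    ids <- intersect(ids, colnames(m))
    if (length(ids) == 0) {
      abort(sprintf("no sample for group '%s' at stage '%s'", group, s))
    }
    out[, s] <- rowMeans(m[, ids, drop = FALSE])
  }
  out
}

#' Differential expression across successive stages
#'
#' Runs one contrast per consecutive stage pair of a group's stage series,
#' oriented later stage over earlier stage.
#'
#' @param counts Count table.
#' @param sample_sheet Sample sheet.
#' @param group Group label to analyse.
#' @param ordering Ordered stage labels.
#' @param mode Passed to [run_contrast()].
#' @param annotation Optional annotation for gene names.
#' @param thresholds A [de_thresholds()].
#' @return A tibble of stacked DE results with `group`, `stage_from`
#'   (earlier) and `stage_to` (later) columns.
#' @export
run_successive_de <- function(counts, sample_sheet, group,
                              ordering = DEFAULT_STAGES, mode = "auto",
                              annotation = NULL,
                              thresholds = de_thresholds()) {
  series <- stage_series(sample_sheet, group, ordering)
  purrr::map_dfr(seq_len(length(series) - 1), function(i) {
    from <- series[i]
    to <- series[i + 1]
    ids_to <- sample_sheet$sample_id[sample_sheet$group == group &
                                       sample_sheet$stage == to &
                                       sample_sheet$lineage == "none"]
    ids_from <- sample_sheet$sample_id[sample_sheet$group == group &
                                         sample_sheet$stage == from &
                                         sample_sheet$lineage == "none"]
    run_contrast(counts, ids_to, ids_from, annotation = annotation,
                 mode = mode, thresholds = thresholds,
                 contrast = sprintf("%s_%s_vs_%s_%s", group, to,
                                    group, from)) |>
      mutate(group = group, stage_from = from, stage_to = to)
  })
}

#' Count DEGs per successive stage transition
#'
#' Tabulates flagged genes by direction for every consecutive stage pair,
#' oriented later stage over earlier stage (so `n_up` counts genes higher at
#' the later stage).
#'
#' @param de Stacked DE results from [run_successive_de()] (must carry
#'   `group`, `stage_from`, `stage_to`, `significant`, `direction`). The
#'   significance flags must already reflect the desired thresholds; pass
#'   `thresholds` to re-flag.
#' @param thresholds Optional [de_thresholds()] to re-apply before counting.
#' @param ordering Stage ordering used to verify that every consecutive pair
#'   of each group's series is present.
#' @return Tibble: `group`, `stage_from`, `stage_to`, `n_up`, `n_down`,
#'   `n_total`.
#' @export
successive_stage_degs <- function(de, thresholds = NULL,
                                  ordering = DEFAULT_STAGES) {
  required <- c("group", "stage_from", "stage_to")
  if (!all(required %in% names(de))) {
    abort("DE results must carry group, stage_from and stage_to columns")
  }
  if (!is.null(thresholds)) de <- call_degs(de, thresholds)
  for (g in unique(de$group)) {
    stages_seen <- unique(c(de$stage_from[de$group == g],
                            de$stage_to[de$group == g]))
    series <- ordering[ordering %in% stages_seen]
    pairs <- paste(series[-length(series)], series[-1])
    have <- paste(de$stage_from[de$group == g], de$stage_to[de$group == g])
    gap <- setdiff(pairs, have)
    if (length(gap) > 0) {
      abort(sprintf("missing transition(s) for group '%s': %s", g,
                    paste(gap, collapse = "; ")))
    }
  }
  de |>
    group_by(.data$group, .data$stage_from, .data$stage_to) |>
    summarise(
      n_up = sum(.data$significant & .data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$significant & .data$direction == "down",
                   na.rm = TRUE),
      .groups = "drop") |>
    mutate(n_total = .data$n_up + .data$n_down) |>
    arrange(match(.data$stage_from, ordering))
}

#' Classify stage-specific genes
#'
#' A gene is stage-specific at stage `s` of a group's stage series when its
#' mean FPKM is strictly above `hi` at `s` and strictly below `lo` at every
#' other stage of that series. With `named_only = TRUE` (the default, and the
#' published filter), genes without a gene name in the annotation are
#' excluded. Genes with a missing FPKM at any stage are excluded and counted
#' in the `n_excluded` attribute.
#'
#' @param fpkm FPKM table.
#' @param sample_sheet Sample sheet.
#' @param group Group label.
#' @param ordering Ordered stage labels.
#' @param hi Strict lower bound for the called stage (default 5).
#' @param lo Strict upper bound for all other stages (default 1).
#' @param named_only Exclude genes without a `gene_name`.
#' @param annotation Annotation tibble (required when `named_only`).
#' @return Tibble: `gene_id`, `gene_name`, `group`, `stage`, `fpkm_stage`,
#'   `fpkm_other_max`.
#' @export
classify_stage_specific <- function(fpkm, sample_sheet, group,
                                    ordering = DEFAULT_STAGES,
                                    hi = 5, lo = 1, named_only = TRUE,
                                    annotation = NULL) {
  series <- stage_series(sample_sheet, group, ordering)
  M <- collapse_fpkm(fpkm, sample_sheet, group, series)

  complete <- rowSums(is.na(M)) == 0
  n_excluded <- sum(!complete)
  M <- M[complete, , drop = FALSE]

  gene_name <- rep(NA_character_, nrow(M))
  if (!is.null(annotation)) {
    gene_name <- annotation$gene_name[match(rownames(M), annotation$gene_id)]
  }
  if (isTRUE(named_only)) {
    if (is.null(annotation)) {
      abort("named_only = TRUE requires an annotation with gene_name")
    }
    keep <- !is.na(gene_name)
    M <- M[keep, , drop = FALSE]
    gene_name <- gene_name[keep]
  }

  imax <- max.col(M, ties.method = "first")
  vmax <- M[cbind(seq_len(nrow(M)), imax)]
  other_max <- vapply(seq_len(nrow(M)), function(i) {
    if (ncol(M) == 1) return(-Inf)
    max(M[i, -imax[i]])
  }, numeric(1))
  hit <- vmax > hi & other_max < lo

  out <- tibble(gene_id = rownames(M)[hit], gene_name = gene_name[hit],
                group = group, stage = series[imax[hit]],
                fpkm_stage = unname(vmax[hit]),
                fpkm_other_max = unname(other_max[hit]))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Detect first-expressed genes
#'
#' A gene is first expressed at stage `s` of a group's stage series when its
#' mean FPKM is strictly above `expr` at `s`, strictly below `expr` at every
#' earlier stage of the series (including the oocyte when present), and the
#' contrast of `s` against its immediate predecessor is significant
#' (`padj < q_cut`, strict) with the gene higher at `s`. The earliest
#' qualifying stage is reported; the first stage of the series can never be
#' called.
#'
#' @param fpkm FPKM table.
#' @param de Stacked successive-stage DE results from [run_successive_de()]
#'   for this group.
#' @param sample_sheet Sample sheet.
#' @param group Group label.
#' @param ordering Ordered stage labels.
#' @param expr Expression threshold (strict on both sides; default 1).
#' @param q_cut Strict adjusted-p cutoff for the predecessor contrast.
#' @return Tibble: `gene_id`, `group`, `stage`, `fpkm_stage`,
#'   `fpkm_prev_max`, `padj_vs_prev`.
#' @export
detect_first_expressed <- function(fpkm, de, sample_sheet, group,
                                   ordering = DEFAULT_STAGES,
                                   expr = 1, q_cut = 0.05) {
  series <- stage_series(sample_sheet, group, ordering)
  M <- collapse_fpkm(fpkm, sample_sheet, group, series)
  complete <- rowSums(is.na(M)) == 0
  n_excluded <- sum(!complete)
  M <- M[complete, , drop = FALSE]

  de <- de[de$group == group, , drop = FALSE]
  qmat <- matrix(NA_real_, nrow = nrow(M), ncol = length(series),
                 dimnames = list(rownames(M), series))
  upmat <- matrix(FALSE, nrow = nrow(M), ncol = length(series),
                  dimnames = list(rownames(M), series))
  for (i in 2:length(series)) {
    sub <- de[de$stage_to == series[i] & de$stage_from == series[i - 1], ]
    if (nrow(sub) == 0) {
      abort(sprintf(
        "missing predecessor contrast %s vs %s for group '%s'",
        series[i], series[i - 1], group))
    }
    idx <- match(rownames(M), sub$gene_id)
    qmat[, i] <- sub$padj[idx]
    upmat[, i] <- sub$log2_fc[idx] > 0
  }

  below_before <- cbind(TRUE, t(apply(M < expr, 1, cumprod))[,
                        -ncol(M), drop = FALSE] > 0)
  eligible <- M > expr & below_before & qmat < q_cut & upmat
  eligible[, 1] <- FALSE
  first_idx <- apply(eligible, 1, function(r) {
    w <- which(r)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  hit <- which(!is.na(first_idx))

  prev_max <- vapply(hit, function(i) {
    max(M[i, seq_len(first_idx[i] - 1)])
  }, numeric(1))

  out <- tibble(gene_id = rownames(M)[hit], group = group,
                stage = series[first_idx[hit]],
                fpkm_stage = M[cbind(hit, first_idx[hit])],
                fpkm_prev_max = prev_max,
                padj_vs_prev = qmat[cbind(hit, first_idx[hit])])
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Venn-region counts for 2 or 3 gene sets
#'
#' Counts every region of the 2- or 3-set Venn partition; region labels join
#' the member set names with `&`, and the counts sum to the union size.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Tibble: `region`, `n`.
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("sets must be a named list")
  }
  if (length(sets) < 2 || length(sets) > 3) {
    abort("overlap_sets() supports 2 or 3 sets")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), ncol = length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    mask <- unlist(combos[i, ])
    inside <- if (length(universe) == 0) logical(0) else {
      apply(member, 1, function(r) all(r == mask))
    }
    tibble(region = paste(names(sets)[mask], collapse = "&"),
           n = sum(inside))
  }) |>
    arrange(.data$region)
}

#' One-sided Fisher over-representation test
#'
#' Per gene set, tests enrichment of the gene list within the universe via
#' the hypergeometric upper tail (equivalent to Fisher's exact test,
#' alternative = greater), reports the sample odds ratio, and adjusts across
#' sets with Benjamini-Hochberg.
#'
#' @param gene_list Character vector of genes of interest (must be contained
#'   in `universe`).
#' @param universe Character vector of all assayed genes.
#' @param gene_sets Named list of gene sets (intersected with the universe).
#' @param q_cut Significance cutoff on adjusted p.
#' @return Tibble: `set`, `n_set`, `n_list`, `n_overlap`, `odds_ratio`,
#'   `pvalue`, `padj`, `significant`.
#' @export
ora_fisher <- function(gene_list, universe, gene_sets, q_cut = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("universe must be non-empty")
  gene_list <- unique(gene_list)
  stray <- setdiff(gene_list, universe)
  if (length(stray) > 0) {
    abort(sprintf("gene_list contains %d gene(s) outside the universe",
                  length(stray)))
  }
  N <- length(universe)
  k <- length(gene_list)
  res <- purrr::map_dfr(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    m <- length(set)
    x <- length(intersect(set, gene_list))
    p <- if (m == 0) 1 else phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    or <- (x * (N - m - k + x)) / ((m - x) * (k - x))
    tibble(set = nm, n_set = m, n_list = k, n_overlap = x,
           odds_ratio = or, pvalue = p)
  })
  res$padj <- adjust_bh(res$pvalue)
  res$significant <- res$padj < q_cut
  res
}
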