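# Counts -> FPKM, expressed-gene calling, and normalization factors.

#' Compute FPKM from a count table
#'
#' `FPKM_ij = k_ij * 1e9 / (N_j * L_i)` where `N_j` is the total counted
#' fragments of sample `j` within the matrix and `L_i` the annotation-supplied
#' transcript-union length in bp. Genes absent from the annotation are dropped
#' with a message; the per-sample identity
#' `sum_i FPKM_ij * L_i = 1e9` holds exactly up to float tolerance.
#'
#' @param counts Count table (tibble: `gene_id` + one numeric column per
#'   sample, non-negative).
#' @param annotation Tibble with `gene_id` and `length_bp > 0` (and optionally
#'   `gene_name`).
#' @return FPKM table in the same layout, with attributes `lib_sizes`,
#'   `lengths` and `n_dropped`.
#' @export
compute_fpkm <- function(counts, annotation) {
  k <- expr_matrix(counts, "count table")
  if (any(k < 0)) abort("count table has negative entries")

  idx <- match(rownames(k), annotation$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(sprintf("dropping %d gene(s) missing from the annotation", dropped))
    k <- k[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  L <- annotation$length_bp[idx]
  if (any(L <= 0)) {
    abort(sprintf("annotation has non-positive length_bp for %d gene(s)",
                  sum(L <= 0)))
  }
  N <- colSums(k)
  if (any(N == 0)) {
    abort(sprintf("degenerate sample(s) with zero total counts: %s",
                  paste(colnames(k)[N == 0], collapse = ", ")))
  }
  fpkm <- sweep(k * 1e9 / L, 2, N, "/")
  out <- expr_tibble(fpkm)
  attr(out, "lib_sizes") <- N
  attr(out, "lengths") <- setNames(L, rownames(k))
  attr(out, "n_dropped") <- dropped
  out
}

#' Call expressed genes per sample
#'
#' A gene is expressed in a sample when its FPKM is at or above the threshold
#' (inclusive bound: FPKM exactly 1 counts as expressed at the default).
#'
#' @param fpkm FPKM table.
#' @param threshold Expression threshold (> 0), default 1.
#' @return Tibble with `sample_id`, `n_expressed`, and a list-column `genes`
#'   of expressed gene ids.
#' @export
call_expressed <- function(fpkm, threshold = 1) {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be > 0")
  }
  m <- expr_matrix(fpkm, "FPKM table")
  expressed <- m >= threshold
  tibble(
    sample_id = colnames(m),
    n_expressed = unname(colSums(expressed)),
    genes = lapply(seq_len(ncol(m)), function(j) rownames(m)[expressed[, j]])
  )
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with strictly positive counts in every sample) of the ratio of the
#' gene's count to its geometric mean across samples.
#'
#' @param counts Count table.
#' @param rescale If `TRUE`, divide by the geometric mean so factors multiply
#'   to 1.
#' @return Tibble: `sample_id`, `size_factor`, `method = "median_ratio"`.
#' @export
size_factors_median_ratio <- function(counts, rescale = FALSE) {
  k <- expr_matrix(counts, "count table")
  if (any(k < 0)) abort("count table has negative entries")
  log_geo <- rowMeans(log(k))
  use <- is.finite(log_geo)
  if (!any(use)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider trimmed_mean_factors()"))
  }
  s <- apply(k[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo[use]))
  })
  if (isTRUE(rescale)) s <- s / exp(mean(log(s)))
  tibble(sample_id = colnames(k), size_factor = unname(s),
         method = "median_ratio")
}

#' Trimmed-mean (TMM) scaling factors
#'
#' Single scaling factor per library relative to a reference: the weighted
#' trimmed mean of per-gene log2 expression ratios
#' `M = log2((k_j/N_j)/(k_r/N_r))`, excluding genes with a zero count in
#' either library, trimming the most extreme `trim_m` of M-values and
#' `trim_a` of average log expression, and weighting by inverse asymptotic
#' (delta-method) variance. The effective library size is `N_j * f_j`.
#'
#' @param counts Count table.
#' @param ref_sample Reference sample id; by default the sample whose
#'   upper-quartile count fraction is closest to the mean upper quartile.
#' @param trim_m,trim_a Two-sided trim fractions for M and A values.
#' @return Tibble: `sample_id`, `scale_factor`, `eff_lib_size`, `method`;
#'   the reference sample id is attached as attribute `ref_sample`.
#' @export
trimmed_mean_factors <- function(counts, ref_sample = NULL,
                                 trim_m = 0.30, trim_a = 0.05) {
  k <- expr_matrix(counts, "count table")
  if (any(k < 0)) abort("count table has negative entries")
  N <- colSums(k)
  if (any(N == 0)) {
    abort(sprintf("degenerate sample(s) with zero total counts: %s",
                  paste(colnames(k)[N == 0], collapse = ", ")))
  }
  if (is.null(ref_sample)) {
    uq <- apply(sweep(k, 2, N, "/"), 2, quantile, probs = 0.75)
    ref_sample <- colnames(k)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(k)) {
    abort(sprintf("reference sample '%s' not in the count table", ref_sample))
  }
  kr <- k[, ref_sample]
  Nr <- N[ref_sample]

  f <- vapply(colnames(k), function(j) {
    kj <- k[, j]
    Nj <- N[j]
    use <- kj > 0 & kr > 0
    if (!any(use)) return(NA_real_)
    M <- log2((kj[use] / Nj) / (kr[use] / Nr))
    A <- 0.5 * log2((kj[use] / Nj) * (kr[use] / Nr))
    v <- (Nj - kj[use]) / (Nj * kj[use]) + (Nr - kr[use]) / (Nr * kr[use])
    n <- length(M)
    keep_m <- rank(M, ties.method = "first") > floor(n * trim_m) &
      rank(M, ties.method = "first") <= n - floor(n * trim_m)
    keep_a <- rank(A, ties.method = "first") > floor(n * trim_a) &
      rank(A, ties.method = "first") <= n - floor(n * trim_a)
    keep <- keep_m & keep_a
    if (sum(keep) < 10) {
      warn(sprintf(
        "fewer than 10 genes survive trimming for sample '%s'; using the untrimmed weighted mean",
        j))
      keep <- rep(TRUE, n)
    }
    w <- 1 / v[keep]
    2^(sum(M[keep] * w) / sum(w))
  }, numeric(1))

  out <- tibble(sample_id = colnames(k), scale_factor = unname(f),
                eff_lib_size = unname(N * f), method = "tmm")
  attr(out, "ref_sample") <- ref_sample
  out
}

#' Transcript-union gene lengths from a GTF file
#'
#' Merges each gene's exon intervals (1-based, inclusive GTF coordinates) and
#' sums the merged widths. Requires the `rtracklayer` and `GenomicRanges`
#' packages.
#'
#' @param path Path to a GTF file.
#' @return Tibble with `gene_id` and `length_bp`.
#' @export
gene_lengths_from_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("gene_lengths_from_gtf() requires rtracklayer and GenomicRanges")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  by_gene <- GenomicRanges::split(gr, gr$gene_id)
  merged <- GenomicRanges::reduce(by_gene)
  widths <- sum(GenomicRanges::width(merged))
  tibble(gene_id = names(widths), length_bp = as.integer(widths))
}
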