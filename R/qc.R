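# Sample-level structure checks: hierarchical clustering on correlation
# distance, PCA of expressed genes, and pairwise squared Pearson correlation.

#' Hierarchical clustering of samples
#'
#' Samples are clustered on `1 - Pearson r` distance computed on
#' `log10(FPKM + offset)`, by default restricted to a gene subset (typically
#' the union of differentially expressed genes) and using average linkage.
#'
#' @param fpkm FPKM table.
#' @param genes Optional character vector restricting the genes used.
#' @param offset Offset inside the log10 transform (keeps zeros finite).
#' @param linkage `"average"` (default), `"complete"` or `"ward.D2"`.
#' @return An object of classes `embryo_hclust` and `hclust`.
#' @export
hclust_samples <- function(fpkm, genes = NULL, offset = 1,
                           linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  m <- expr_matrix(fpkm, "FPKM table")
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(m))
    if (length(genes) == 0) abort("gene subset is empty")
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2) abort("need at least 2 samples")
  x <- log10(m + offset)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance sample(s) under the gene subset: %s",
                  paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  d <- as.dist(1 - cor(x))
  hc <- hclust(d, method = linkage)
  class(hc) <- c("embryo_hclust", "hclust")
  attr(hc, "offset") <- offset
  attr(hc, "n_genes") <- nrow(m)
  hc
}

#' @method tidy embryo_hclust
#' @export
tidy.embryo_hclust <- function(x, ...) {
  tibble(merge1 = x$merge[, 1], merge2 = x$merge[, 2], height = x$height)
}

#' Export a sample dendrogram as Newick
#'
#' @param hc An `embryo_hclust` (or any `hclust`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(hc, path) {
  class(hc) <- "hclust"
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Principal component analysis of samples
#'
#' Genes are filtered to mean FPKM at or above `min_mean_fpkm` across
#' samples, transformed to `log10(FPKM + 1)` and gene-centered; samples are
#' projected on the principal components.
#'
#' @param fpkm FPKM table.
#' @param min_mean_fpkm Mean-FPKM filter (inclusive), default 1.
#' @return Object of class `embryo_pca`: `scores` (tibble of sample
#'   coordinates), `var_explained` (fractions summing to 1), `n_genes`.
#' @export
pca_samples <- function(fpkm, min_mean_fpkm = 1) {
  m <- expr_matrix(fpkm, "FPKM table")
  if (ncol(m) < 2) abort("need at least 2 samples")
  keep <- rowMeans(m) >= min_mean_fpkm
  if (sum(keep) < 2) abort("fewer than 2 genes survive the mean-FPKM filter")
  x <- t(log10(m[keep, , drop = FALSE] + 1))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(pc$x)),
                             as_tibble(pc$x, .name_repair = "minimal"))
  structure(list(scores = scores, var_explained = ve, n_genes = sum(keep)),
            class = "embryo_pca")
}

#' @method tidy embryo_pca
#' @export
tidy.embryo_pca <- function(x, ...) x$scores

#' @method glance embryo_pca
#' @export
glance.embryo_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_genes = x$n_genes,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) >= 2) x$var_explained[2]
                   else NA_real_)
}

#' @export
print.embryo_pca <- function(x, ...) {
  cat(sprintf("<embryo_pca> %d samples, %d genes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), x$n_genes, 100 * x$var_explained[1],
              if (length(x$var_explained) >= 2)
                100 * x$var_explained[2] else NA))
  invisible(x)
}

#' Pairwise squared Pearson correlation of samples
#'
#' `R^2` on `log10(FPKM + offset)` for each pair of samples; the diagonal is
#' 1. Entries involving a zero-variance sample are reported as missing.
#'
#' @param fpkm FPKM table.
#' @param offset Offset inside the log10 transform.
#' @param genes Optional gene subset.
#' @return Symmetric numeric matrix of squared correlations.
#' @export
pairwise_r2 <- function(fpkm, offset = 1, genes = NULL) {
  m <- expr_matrix(fpkm, "FPKM table")
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 samples")
  x <- log10(m + offset)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    inform(sprintf("zero-variance sample(s), R^2 reported as missing: %s",
                   paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  r2 <- suppressWarnings(cor(x))^2
  diag(r2) <- 1
  r2
}
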