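# Pairwise differential expression for unreplicated and replicated designs.
#
# Unreplicated contrasts use the conditional exact test: under the null of
# equal relative expression, k1 given the total k1 + k2 = n is binomial with
# probability proportional to the effective library sizes. Replicated
# contrasts use a negative-binomial conditioned exact test on the condition
# count sums, with a pooled method-of-moments dispersion per gene.

#' Significance thresholds for DEG calling
#'
#' Unreplicated contrasts require adjusted p < 0.005 and |log2 fold change|
#' > 1 (both strict); replicated contrasts require adjusted p < 0.05.
#'
#' @param q_noreplicate Adjusted-p cutoff for the unreplicated rule.
#' @param lfc Absolute log2 fold-change cutoff for the unreplicated rule.
#' @param q_replicated Adjusted-p cutoff for the replicated rule.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(q_noreplicate = 0.005, lfc = 1.0,
                          q_replicated = 0.05) {
  if (q_noreplicate <= 0 || lfc <= 0 || q_replicated <= 0) {
    abort("all thresholds must be positive")
  }
  structure(list(q_noreplicate = q_noreplicate, lfc = lfc,
                 q_replicated = q_replicated),
            class = "de_thresholds")
}

#' Two-library conditional exact test
#'
#' Tests equality of relative expression between two unreplicated libraries.
#' Under the null, `k1 | (k1 + k2 = n) ~ Binomial(n, N1 / (N1 + N2))` with
#' `N1`, `N2` the effective library sizes. The default two-sided rule doubles
#' the smaller tail, `p = min(1, 2 min(P(X <= k1), P(X >= k1)))`; the
#' `"minlike"` rule sums all outcomes no more likely than the observed one.
#' `k1 = k2 = 0` gives p = 1. Vectorized over `k1`, `k2`.
#'
#' @param k1,k2 Non-negative counts in the two libraries.
#' @param n1,n2 Effective library sizes (> 0).
#' @param two_sided Two-sided rule: `"doubling"` (default) or `"minlike"`.
#' @return Raw p-values in \[0, 1\].
#' @export
two_library_exact_test <- function(k1, k2, n1, n2,
                                   two_sided = c("doubling", "minlike")) {
  two_sided <- match.arg(two_sided)
  if (any(k1 < 0) || any(k2 < 0)) abort("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) abort("library sizes must be positive")
  p0 <- n1 / (n1 + n2)
  n <- k1 + k2
  if (two_sided == "doubling") {
    lower <- pbinom(k1, n, p0)
    upper <- pbinom(k1 - 1, n, p0, lower.tail = FALSE)
    p <- pmin(1, 2 * pmin(lower, upper))
  } else {
    p <- mapply(function(ki, ni) {
      if (ni == 0) return(1)
      probs <- dbinom(0:ni, ni, p0)
      sum(probs[probs <= probs[ki + 1] * (1 + 1e-7)])
    }, k1, n)
    p <- pmin(1, p)
  }
  p[n == 0] <- 1
  p
}

#' Log2 fold change with pseudocount
#'
#' `log2((k1/s1 + c) / (k2/s2 + c))`; antisymmetric under swapping the two
#' conditions. The pseudocount bounds fold changes for zero counts, the
#' dominant case for first-expressed genes.
#'
#' @param k1,k2 Counts (or mean normalized counts).
#' @param s1,s2 Positive scale factors dividing the counts.
#' @param pseudocount Positive pseudocount added on the normalized scale.
#' @return Log2 fold changes (condition 1 over condition 2).
#' @export
log2_fold_change <- function(k1, k2, s1 = 1, s2 = 1, pseudocount = 1) {
  if (any(s1 <= 0) || any(s2 <= 0)) abort("scale factors must be positive")
  if (any(pseudocount <= 0)) abort("pseudocount must be positive")
  log2((k1 / s1 + pseudocount) / (k2 / s2 + pseudocount))
}

#' Pooled method-of-moments dispersion estimates
#'
#' Per gene, `alpha = max(0, (v - m) / m^2)` with `m` the grand mean of
#' normalized counts and `v` the within-condition variance pooled over
#' conditions with at least two replicates. Genes with zero mean get
#' dispersion 0. Small replicate numbers make this estimator noisy; it is a
#' moment floor, not a fitted mean-dispersion trend.
#'
#' @param counts Count table.
#' @param size_factors Tibble from [size_factors_median_ratio()] (or any with
#'   `sample_id` and `size_factor`).
#' @param condition Per-sample condition labels, aligned with the count
#'   table's sample columns (or named by sample id).
#' @return Tibble: `gene_id`, `dispersion`, `method`.
#' @export
estimate_dispersion <- function(counts, size_factors, condition) {
  k <- expr_matrix(counts, "count table")
  sf <- size_factors$size_factor[match(colnames(k), size_factors$sample_id)]
  if (anyNA(sf)) abort("size_factors must cover every sample")
  if (!is.null(names(condition))) condition <- condition[colnames(k)]
  if (length(condition) != ncol(k)) {
    abort("condition labels must align with the count table samples")
  }
  x <- sweep(k, 2, sf, "/")
  reps <- table(condition)
  rep_conds <- names(reps)[reps >= 2]
  if (length(rep_conds) == 0) {
    abort(paste("no condition has >= 2 replicates;",
                "use the unreplicated (exact two-library) mode"))
  }
  ss <- matrix(0, nrow = nrow(x), ncol = length(rep_conds))
  df <- 0
  for (i in seq_along(rep_conds)) {
    cols <- which(condition == rep_conds[i])
    xm <- x[, cols, drop = FALSE]
    ss[, i] <- rowSums((xm - rowMeans(xm))^2)
    df <- df + length(cols) - 1
  }
  v <- rowSums(ss) / df
  m <- rowMeans(x)
  alpha <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  tibble(gene_id = rownames(k), dispersion = unname(alpha),
         method = "pooled_mom")
}

# Conditioned NB exact test for one gene: enumerate all splits (a, b) of the
# total count sum across the two fitted condition-sum NB distributions and
# sum the probability of outcomes no more likely than the observed one.
nb_exact_test_one <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  if (any(counts_a < 0) || any(counts_b < 0)) {
    abort("counts must be non-negative")
  }
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  n <- ka + kb
  if (n == 0) return(1)
  sa <- sum(sf_a)
  sb <- sum(sf_b)
  q0 <- n / (sa + sb)
  mu_a <- sa * q0
  mu_b <- sb * q0
  a <- 0:n
  if (alpha == 0) {
    la <- dpois(a, mu_a, log = TRUE)
    lb <- dpois(n - a, mu_b, log = TRUE)
  } else {
    # sum of replicate NBs: variance mu + alpha * q0^2 * sum(sf^2)
    size_a <- sa^2 / (alpha * sum(sf_a^2))
    size_b <- sb^2 / (alpha * sum(sf_b^2))
    la <- dnbinom(a, size = size_a, mu = mu_a, log = TRUE)
    lb <- dnbinom(n - a, size = size_b, mu = mu_b, log = TRUE)
  }
  lp <- la + lb
  l_obs <- lp[ka + 1]
  keep <- lp <= l_obs + 1e-8
  p <- exp(logsumexp(lp[keep]) - logsumexp(lp))
  min(p, 1)
}

#' Negative-binomial conditioned exact test
#'
#' Replicated-mode test of equal expression between two conditions: the
#' condition count sums `K_A`, `K_B` are modelled as negative binomial around
#' a pooled mean (scaled by the summed size factors, with replicate-sum
#' variance `mu + alpha q^2 sum(s_j^2)`), and the p-value sums, over all
#' splits `(a, b)` of `K_A + K_B`, the probabilities of outcomes no more
#' likely than the observed split, normalized over all splits. `alpha = 0`
#' reduces to the Poisson/binomial conditional test.
#'
#' @param counts_a,counts_b Replicate count vectors for the two conditions
#'   (one gene), or matrices (genes x replicates) for many genes.
#' @param sf_a,sf_b Size factors for the replicates of each condition.
#' @param alpha Per-gene NB dispersion (scalar, or vector over genes for
#'   matrix input).
#' @return Raw p-value(s).
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  if (is.matrix(counts_a) || is.matrix(counts_b)) {
    counts_a <- as.matrix(counts_a)
    counts_b <- as.matrix(counts_b)
    stopifnot(nrow(counts_a) == nrow(counts_b))
    if (length(alpha) == 1) alpha <- rep(alpha, nrow(counts_a))
    vapply(seq_len(nrow(counts_a)), function(i) {
      nb_exact_test_one(counts_a[i, ], counts_b[i, ], sf_a, sf_b, alpha[i])
    }, numeric(1))
  } else {
    nb_exact_test_one(counts_a, counts_b, sf_a, sf_b, alpha)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: in ascending order of p,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in input order.
#'
#' @param pvals Raw p-values in \[0, 1\] (no missing values).
#' @return Adjusted p-values (q-values).
#' @export
adjust_bh <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(pvals, method = "BH")
}

#' Flag differentially expressed genes
#'
#' Applies the mode's threshold rule: unreplicated calls require
#' `padj < q_noreplicate` and `|log2_fc| > lfc` (both strict); replicated
#' calls require `padj < q_replicated` (strict). Direction is `"up"` for a
#' positive log2 fold change in the A-over-B orientation.
#'
#' @param de DE result tibble with columns `log2_fc`, `padj` and a `mode`
#'   column or attribute (`"noreplicate"` or `"replicated"`).
#' @param thresholds A [de_thresholds()].
#' @return The tibble with `significant` (logical) and `direction`
#'   (`"up"`/`"down"`, `NA` when not significant) columns.
#' @export
call_degs <- function(de, thresholds = de_thresholds()) {
  mode <- if ("mode" %in% names(de)) de$mode else attr(de, "mode")
  if (is.null(mode)) abort("DE result must carry a 'mode' column or attribute")
  sig <- ifelse(mode == "noreplicate",
                de$padj < thresholds$q_noreplicate &
                  abs(de$log2_fc) > thresholds$lfc,
                de$padj < thresholds$q_replicated)
  de$significant <- sig
  de$direction <- ifelse(sig, ifelse(de$log2_fc > 0, "up", "down"),
                         NA_character_)
  de
}

#' Run one pairwise contrast
#'
#' High-level per-contrast driver. In unreplicated mode (one sample per side)
#' the libraries are scaled by trimmed-mean (TMM) effective sizes and tested
#' with [two_library_exact_test()]; fold changes are computed on counts per
#' million with a pseudocount. In replicated mode, median-of-ratios size
#' factors are estimated across the contrast's samples, per-gene dispersions
#' come from [estimate_dispersion()] (unless supplied), and
#' [nb_exact_test()] is applied to the condition sums; fold changes compare
#' mean normalized counts with a pseudocount. P-values are BH-adjusted within
#' the contrast and DEGs flagged by the mode's rule.
#'
#' @param counts Count table.
#' @param samples_a,samples_b Sample ids of the two conditions (A over B
#'   orientation).
#' @param annotation Optional annotation supplying `gene_name`.
#' @param mode `"auto"` (replicated when both sides have >= 2 samples),
#'   `"noreplicate"` or `"replicated"`.
#' @param dispersion Optional dispersion tibble (or per-gene vector) to use
#'   instead of estimating.
#' @param thresholds A [de_thresholds()].
#' @param pseudocount Pseudocount for fold changes.
#' @param contrast Contrast label; by default `"A_vs_B"` built from sample
#'   ids.
#' @return Tibble: `gene_id`, `gene_name`, `base_mean_a`, `base_mean_b`,
#'   `log2_fc`, `pvalue`, `padj`, `significant`, `direction`, `mode`,
#'   `contrast`.
#' @export
run_contrast <- function(counts, samples_a, samples_b, annotation = NULL,
                         mode = c("auto", "noreplicate", "replicated"),
                         dispersion = NULL, thresholds = de_thresholds(),
                         pseudocount = 1, contrast = NULL) {
  mode <- match.arg(mode)
  k <- expr_matrix(counts, "count table")
  missing_samples <- setdiff(c(samples_a, samples_b), colnames(k))
  if (length(missing_samples) > 0) {
    abort(sprintf("samples not in the count table: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  if (mode == "auto") {
    mode <- if (length(samples_a) >= 2 && length(samples_b) >= 2)
      "replicated" else "noreplicate"
  }
  if (is.null(contrast)) {
    contrast <- sprintf("%s_vs_%s", paste(samples_a, collapse = "+"),
                        paste(samples_b, collapse = "+"))
  }

  if (mode == "noreplicate") {
    if (length(samples_a) != 1 || length(samples_b) != 1) {
      abort("noreplicate mode takes exactly one sample per condition")
    }
    sub <- expr_tibble(k[, c(samples_a, samples_b), drop = FALSE])
    tmm <- trimmed_mean_factors(sub)
    eff <- setNames(tmm$eff_lib_size, tmm$sample_id)
    k1 <- k[, samples_a]
    k2 <- k[, samples_b]
    pvalue <- two_library_exact_test(k1, k2, eff[samples_a], eff[samples_b])
    base_a <- k1 / (eff[samples_a] / 1e6)   # counts per million
    base_b <- k2 / (eff[samples_b] / 1e6)
    lfc <- log2((base_a + pseudocount) / (base_b + pseudocount))
  } else {
    cols <- c(samples_a, samples_b)
    sub <- expr_tibble(k[, cols, drop = FALSE])
    sf <- size_factors_median_ratio(sub)
    sfv <- setNames(sf$size_factor, sf$sample_id)
    if (is.null(dispersion)) {
      cond <- setNames(rep(c("A", "B"), c(length(samples_a),
                                          length(samples_b))), cols)
      dispersion <- estimate_dispersion(sub, sf, cond)
    }
    alpha <- if (is.data.frame(dispersion)) {
      dispersion$dispersion[match(rownames(k), dispersion$gene_id)]
    } else {
      rep_len(dispersion, nrow(k))
    }
    pvalue <- nb_exact_test(k[, samples_a, drop = FALSE],
                            k[, samples_b, drop = FALSE],
                            sfv[samples_a], sfv[samples_b], alpha)
    xa <- sweep(k[, samples_a, drop = FALSE], 2, sfv[samples_a], "/")
    xb <- sweep(k[, samples_b, drop = FALSE], 2, sfv[samples_b], "/")
    base_a <- rowMeans(xa)
    base_b <- rowMeans(xb)
    lfc <- log2((base_a + pseudocount) / (base_b + pseudocount))
  }

  gene_name <- if (!is.null(annotation)) {
    annotation$gene_name[match(rownames(k), annotation$gene_id)]
  } else {
    NA_character_
  }
  de <- tibble(gene_id = rownames(k), gene_name = gene_name,
               base_mean_a = unname(base_a), base_mean_b = unname(base_b),
               log2_fc = unname(lfc), pvalue = unname(pvalue),
               padj = adjust_bh(pvalue), mode = mode, contrast = contrast)
  call_degs(de, thresholds)
}
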