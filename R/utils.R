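# Shared internal helpers: expression-table <-> matrix conversion and
# labelled RNG streams.

# A "gene table" throughout the package is a data frame whose first column is
# `gene_id` and whose remaining columns are one numeric column per sample.

expr_matrix <- function(df, what = "expression table") {
  if (!is.data.frame(df)) {
    abort(sprintf("%s must be a data frame with a gene_id column", what))
  }
  if (!"gene_id" %in% names(df)) {
    abort(sprintf("%s must contain a 'gene_id' column", what))
  }
  if (anyDuplicated(df$gene_id)) {
    abort(sprintf("%s has duplicated gene_id values", what))
  }
  sample_cols <- setdiff(names(df), "gene_id")
  if (length(sample_cols) == 0) {
    abort(sprintf("%s has no sample columns", what))
  }
  m <- as.matrix(as.data.frame(df)[sample_cols])
  if (!is.numeric(m)) {
    abort(sprintf("%s sample columns must be numeric", what))
  }
  rownames(m) <- as.character(df$gene_id)
  m
}

expr_tibble <- function(m) {
  dplyr::bind_cols(
    tibble(gene_id = rownames(m)),
    as_tibble(m, .name_repair = "minimal")
  )
}

# Stable 31-bit hash of a character label, combined with a master seed.
# Each stochastic operation draws from its own stream so that, e.g., adding a
# sample does not reshuffle the draws of earlier samples.
hash_label <- function(label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  h
}

stream_seed <- function(seed, label) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + hash_label(label)) %% 2147483647)
}

# Evaluate `expr` under the RNG stream (seed, label), restoring the caller's
# RNG state afterwards.
with_stream <- function(seed, label, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, label))
  expr
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
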