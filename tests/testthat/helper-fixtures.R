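# Fixture builders shared across test files. Everything is generated in code;
# no binary or stored data.

# Gene table (counts or FPKM) from a plain matrix.
make_table <- function(m, gene_ids = NULL, sample_ids = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- rownames(m) %||% sprintf("g%03d", seq_len(nrow(m)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(m) %||% sprintf("s%02d", seq_len(ncol(m)))
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# One-sample-per-stage sheet for a single group.
make_stage_sheet <- function(stages, group = "IV-D") {
  tibble::tibble(sample_id = paste0(group, "_", stages), group = group,
                 stage = stages, replicate = 1L, lineage = "none")
}

# FPKM table for one group with one sample per stage, rows = gene profiles.
make_profile_fpkm <- function(profiles, stages) {
  m <- do.call(rbind, profiles)
  make_table(m, sample_ids = paste0("IV-D_", stages))
}

# Flat annotation: every gene named, constant length unless given.
make_annotation <- function(gene_ids, length_bp = 1000,
                            gene_name = toupper(gene_ids)) {
  tibble::tibble(gene_id = gene_ids, gene_name = gene_name,
                 length_bp = length_bp)
}

# Brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j, O(m^2).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Naive NB conditioned exact test: plain-space enumeration of all splits.
nb_exact_oracle <- function(ka, kb, sf_a, sf_b, alpha) {
  n <- ka + kb
  if (n == 0) return(1)
  sa <- sum(sf_a); sb <- sum(sf_b)
  q0 <- n / (sa + sb)
  mu_a <- sa * q0; mu_b <- sb * q0
  pa <- function(x) {
    if (alpha == 0) dpois(x, mu_a)
    else dnbinom(x, size = sa^2 / (alpha * sum(sf_a^2)), mu = mu_a)
  }
  pb <- function(x) {
    if (alpha == 0) dpois(x, mu_b)
    else dnbinom(x, size = sb^2 / (alpha * sum(sf_b^2)), mu = mu_b)
  }
  probs <- vapply(0:n, function(a) pa(a) * pb(n - a), numeric(1))
  obs <- probs[ka + 1]
  sum(probs[probs <= obs * (1 + 1e-10)]) / sum(probs)
}

# Brute-force stage-specific rule on a genes x stages mean-FPKM matrix.
stage_specific_oracle <- function(M, stages, hi = 5, lo = 1) {
  out <- list()
  for (i in seq_len(nrow(M))) {
    for (s in seq_along(stages)) {
      if (M[i, s] > hi && all(M[i, -s] < lo)) {
        out[[length(out) + 1]] <- c(rownames(M)[i], stages[s])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), stage = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(gene_id = m[, 1], stage = m[, 2])
}

# Brute-force first-expressed rule given mean FPKM, q and up matrices.
first_expressed_oracle <- function(M, qmat, upmat, stages, expr = 1,
                                   q_cut = 0.05) {
  out <- list()
  for (i in seq_len(nrow(M))) {
    for (s in 2:length(stages)) {
      if (M[i, s] > expr && all(M[i, seq_len(s - 1)] < expr) &&
          !is.na(qmat[i, s]) && qmat[i, s] < q_cut && upmat[i, s]) {
        out[[length(out) + 1]] <- c(rownames(M)[i], stages[s])
        break
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), stage = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(gene_id = m[, 1], stage = m[, 2])
}

# Naive UPGMA cophenetic matrix from a dissimilarity matrix.
upgma_cophenetic_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  d <- D
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        a <- active[i]; b <- active[j]
        dd <- mean(D[clusters[[a]], clusters[[b]]])
        if (dd < bestd) { bestd <- dd; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active <- setdiff(active, b)
  }
  dimnames(coph) <- dimnames(D)
  coph
}
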