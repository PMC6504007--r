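# Stage-specific and first-expressed classification, transition counting,
# set overlaps and over-representation.

stages7 <- c("oocyte", "1-cell", "2-cell", "4-cell", "8-cell", "morula",
             "blastocyst")

test_that("stage-specific rule is forced on canonical profiles", {
  profiles <- list(hit = c(0, 0, 6, 0, 0, 0, 0),
                   leak = c(0, 0, 6, 1.5, 0, 0, 0),
                   at_hi = c(0, 0, 5, 0, 0, 0, 0),
                   at_lo = c(1, 0, 6, 0, 0, 0, 0))
  fpkm <- make_profile_fpkm(profiles, stages7)
  sheet <- make_stage_sheet(stages7)
  ann <- make_annotation(names(profiles))
  res <- classify_stage_specific(fpkm, sheet, "IV-D", stages7,
                                 annotation = ann)
  # only the clean spike qualifies: 1.5 elsewhere blocks, 5 is not > 5,
  # 1 elsewhere is not < 1
  expect_equal(res$gene_id, "hit")
  expect_equal(res$stage, stages7[3])
  expect_equal(res$fpkm_stage, 6)
})

test_that("unnamed genes are excluded only when named_only is on", {
  fpkm <- make_profile_fpkm(list(a = c(0, 0, 9, 0, 0, 0, 0),
                                 b = c(0, 9, 0, 0, 0, 0, 0)), stages7)
  sheet <- make_stage_sheet(stages7)
  ann <- tibble::tibble(gene_id = c("a", "b"),
                        gene_name = c(NA, "B"), length_bp = 1000)
  on <- classify_stage_specific(fpkm, sheet, "IV-D", stages7,
                                annotation = ann)
  expect_equal(on$gene_id, "b")
  off <- classify_stage_specific(fpkm, sheet, "IV-D", stages7,
                                 named_only = FALSE, annotation = ann)
  expect_setequal(off$gene_id, c("a", "b"))
})

test_that("both classifiers agree with brute-force rule evaluation", {
  set.seed(11)
  sheet <- make_stage_sheet(stages7)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    # values concentrated around the decision boundaries, including exact
    # 1 and 5
    M <- matrix(sample(c(0, 0.5, 1, 1.0000001, 2, 5, 5.0000001, 8, 20),
                       n * 7, replace = TRUE), nrow = n,
                dimnames = list(sprintf("g%03d", 1:n), NULL))
    fpkm <- make_table(M, sample_ids = paste0("IV-D_", stages7))
    ann <- make_annotation(rownames(M))

    got <- classify_stage_specific(fpkm, sheet, "IV-D", stages7,
                                   annotation = ann)
    want <- stage_specific_oracle(M, stages7)
    expect_equal(got[order(got$gene_id), c("gene_id", "stage")],
                 want[order(want$gene_id), ], ignore_attr = TRUE)

    # random predecessor-contrast q-values and directions
    qv <- matrix(sample(c(0.001, 0.04, 0.05, 0.2), n * 7, replace = TRUE),
                 nrow = n)
    up <- matrix(sample(c(TRUE, FALSE), n * 7, replace = TRUE, prob = c(.8, .2)),
                 nrow = n)
    de <- purrr::map_dfr(2:7, function(s) {
      tibble::tibble(gene_id = rownames(M), group = "IV-D",
                     stage_from = stages7[s - 1], stage_to = stages7[s],
                     log2_fc = ifelse(up[, s], 1, -1), padj = qv[, s])
    })
    got_fe <- detect_first_expressed(fpkm, de, sheet, "IV-D", stages7)
    want_fe <- first_expressed_oracle(M, qv, up, stages7)
    expect_equal(got_fe[order(got_fe$gene_id), c("gene_id", "stage")],
                 want_fe[order(want_fe$gene_id), ], ignore_attr = TRUE)
  }
})

test_that("first-expressed rule follows its worked examples", {
  M <- rbind(ok = c(0.1, 0.2, 3.0, 5.0, 6, 6, 6),
             blocked = c(0.1, 0.2, 3.0, 5.0, 6, 6, 6))
  fpkm <- make_table(M, sample_ids = paste0("IV-D_", stages7))
  sheet <- make_stage_sheet(stages7)
  qv_ok <- c(NA, 0.5, 0.01, 0.5, 0.5, 0.5, 0.5)
  qv_blocked <- c(NA, 0.5, 0.2, 0.01, 0.01, 0.01, 0.01)
  de <- purrr::map_dfr(2:7, function(s) {
    tibble::tibble(gene_id = c("ok", "blocked"), group = "IV-D",
                   stage_from = stages7[s - 1], stage_to = stages7[s],
                   log2_fc = 2, padj = c(qv_ok[s], qv_blocked[s]))
  })
  res <- detect_first_expressed(fpkm, de, sheet, "IV-D", stages7)
  # "ok": >1 at 2-cell with q = 0.01 vs 1-cell -> first-expressed there.
  # "blocked": q fails at its crossing stage, and the 3.0 >= 1 at that stage
  # blocks every later call -> no call at all.
  expect_equal(res$gene_id, "ok")
  expect_equal(res$stage, stages7[3])

  # the first stage of a series can never be called
  M2 <- rbind(x = c(9, 9, 9, 9, 9, 9, 9))
  de2 <- purrr::map_dfr(2:7, function(s) {
    tibble::tibble(gene_id = "x", group = "IV-D",
                   stage_from = stages7[s - 1], stage_to = stages7[s],
                   log2_fc = 2, padj = 0.001)
  })
  res2 <- detect_first_expressed(make_table(M2, sample_ids =
                                              paste0("IV-D_", stages7)),
                                 de2, sheet, "IV-D", stages7)
  expect_equal(nrow(res2), 0)
})

test_that("tightening thresholds can only shrink the stage-specific set", {
  set.seed(12)
  M <- matrix(rexp(200 * 7, rate = 0.2), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  fpkm <- make_table(M, sample_ids = paste0("IV-D_", stages7))
  sheet <- make_stage_sheet(stages7)
  ann <- make_annotation(rownames(M))
  base <- classify_stage_specific(fpkm, sheet, "IV-D", stages7,
                                  annotation = ann)
  higher_hi <- classify_stage_specific(fpkm, sheet, "IV-D", stages7, hi = 10,
                                       annotation = ann)
  lower_lo <- classify_stage_specific(fpkm, sheet, "IV-D", stages7, lo = 0.5,
                                      annotation = ann)
  expect_true(all(higher_hi$gene_id %in% base$gene_id))
  expect_true(all(lower_lo$gene_id %in% base$gene_id))
})

test_that("transition counts are oriented later-over-earlier and complete", {
  sim <- simulate_experiment(sim_config(n_genes = 400, seed = 14),
                             "design27")
  de <- run_successive_de(sim$counts, sim$sample_sheet, "IV-D")
  tab <- successive_stage_degs(de)
  expect_equal(tab$n_total, tab$n_up + tab$n_down)
  expect_equal(nrow(tab), 3)  # oocyte->4-cell->8-cell->blastocyst

  # reversing the stage ordering swaps up and down counts
  de_rev <- run_successive_de(sim$counts, sim$sample_sheet, "IV-D",
                              ordering = rev(stages7))
  tab_rev <- successive_stage_degs(de_rev, ordering = rev(stages7))
  m <- match(paste(tab$stage_from, tab$stage_to),
             paste(tab_rev$stage_to, tab_rev$stage_from))
  expect_equal(tab$n_up, tab_rev$n_down[m])
  expect_equal(tab$n_down, tab_rev$n_up[m])

  # a missing transition is reported with the gap named
  expect_error(successive_stage_degs(de[de$stage_to != "8-cell", ]),
               "missing transition")
})

test_that("null adjacent stages produce almost no DEG calls", {
  # the unreplicated exact test's null model is Poisson sampling noise, so
  # the null simulation is run at dispersion 0 (single libraries cannot
  # separate biological overdispersion from signal; see the vignette)
  cfg <- sim_config(n_genes = 2000, class_fractions = c(housekeeping = 0.8),
                    dispersion = 0, seed = 15)
  sheet <- emulate_design(tibble::tibble(
    sample_id = c("a", "b"), group = "IV-D",
    stage = c("morula", "blastocyst")))
  truth <- simulate_truth(cfg, sheet)
  counts <- sample_counts(truth, simulate_annotation(cfg), cfg)
  de <- run_contrast(counts, "b", "a", mode = "noreplicate")
  expect_lte(sum(de$significant), 0.005 * 2000)
})

test_that("planted up/down genes at one transition are recovered", {
  set.seed(16)
  n <- 2000
  base <- rpois(n, 150) + 1
  mu_late <- base
  up_idx <- 1:100; down_idx <- 101:150
  mu_late[up_idx] <- base[up_idx] * 8
  mu_late[down_idx] <- base[down_idx] / 8
  k <- cbind(early = rpois(n, base), late = rpois(n, mu_late))
  de <- run_contrast(make_table(k), "late", "early")
  n_up <- sum(de$direction == "up" & de$significant, na.rm = TRUE)
  n_down <- sum(de$direction == "down" & de$significant, na.rm = TRUE)
  true_up <- sum(which(de$significant & de$direction == "up") %in% up_idx)
  true_down <- sum(which(de$significant & de$direction == "down") %in%
                     down_idx)
  expect_gte(true_up, 90)
  expect_gte(true_down, 45)
  expect_lte((n_up - true_up) + (n_down - true_down), 5)
})

test_that("Venn regions partition the union", {
  a <- sprintf("g%02d", 1:10)
  same <- overlap_sets(list(A = a, B = a, C = a))
  expect_equal(same$n[same$region == "A&B&C"], 10)
  expect_equal(sum(same$n), 10)

  disjoint <- overlap_sets(list(A = c("x", "y"), B = c("z")))
  expect_equal(disjoint$n[disjoint$region == "A"], 2)
  expect_equal(disjoint$n[disjoint$region == "A&B"], 0)

  set.seed(17)
  sets <- list(A = sample(letters, 12), B = sample(letters, 8),
               C = sample(letters, 15))
  res <- overlap_sets(sets)
  expect_equal(sum(res$n), length(unique(unlist(sets))))
  # brute-force membership tabulation
  for (g in unique(unlist(sets))) {
    reg <- paste(names(sets)[vapply(sets, function(s) g %in% s,
                                    logical(1))], collapse = "&")
    expect_true(res$n[res$region == reg] >= 1)
  }
  expect_error(overlap_sets(list(A = a, B = a, C = a, D = a)), "2 or 3")
})

test_that("over-representation p-values equal the hypergeometric tail", {
  universe <- sprintf("u%03d", 1:100)
  gene_set <- universe[1:10]
  gene_list <- c(universe[1:5], universe[50:54])
  res <- ora_fisher(gene_list, universe, list(S = gene_set))
  expect_equal(res$pvalue,
               sum(choose(10, 5:10) * choose(90, 10 - 5:10)) / choose(100, 10))

  # list = universe -> no enrichment possible
  res_all <- ora_fisher(universe, universe, list(S = gene_set))
  expect_equal(res_all$pvalue, 1)

  # set semantics: order never matters
  res_perm <- ora_fisher(rev(gene_list), universe, list(S = rev(gene_set)))
  expect_equal(res_perm$pvalue, res$pvalue)

  expect_error(ora_fisher(c("zz"), universe, list(S = gene_set)),
               "outside the universe")
  expect_error(ora_fisher("a", character(0), list(S = "a")), "non-empty")
})
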