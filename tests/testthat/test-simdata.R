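# Synthetic-data generator: configuration validation, ground-truth
# invariants, count noise model, designs and determinism.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(class_fractions = c(maternal = 0.8, zygotic = 0.5)),
               "class_fractions")
  expect_error(sim_config(maternal_decay = 1.2), "maternal_decay")
  expect_error(sim_config(it_mixture = 0), "it_mixture")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(stage_labels = c("a", "a")), "stage_labels")
  expect_error(
    sim_config(group_perturbations = list("NT-D" = list(delay_prob = 1.5,
                                                        damping = 1))),
    "delay_prob")
  expect_error(sim_config(degradation_stage = "16-cell"), "degradation_stage")
})

test_that("ground truth honours the class rules", {
  cfg <- sim_config(n_genes = 600, seed = 11)
  sheet <- emulate_design("design25", stage_labels = cfg$stage_labels)
  truth <- simulate_truth(cfg, sheet)
  genes <- truth$genes
  stages <- cfg$stage_labels
  ga <- truth$group_activation

  # zygotic genes: true FPKM 0 strictly before the realized activation stage
  for (g in c("IV-D", "NT-D")) {
    act <- ga[ga$group == g & !is.na(ga$activation_stage) &
                genes$class == "zygotic", ]
    for (i in sample(seq_len(nrow(act)), 40)) {
      a_idx <- match(act$activation_stage[i], stages)
      ids <- truth$samples$sample_id[truth$samples$group == g]
      stage_idx <- match(truth$samples$stage[match(ids,
                                                   truth$samples$sample_id)],
                         stages)
      mu <- truth$fpkm[act$gene_id[i], ids]
      expect_true(all(mu[stage_idx < a_idx] == 0))
      expect_true(all(mu[stage_idx >= a_idx] > 0))
    }
  }

  # maternal genes: 0 at and after the degradation stage, decaying before
  deg_idx <- match(cfg$degradation_stage, stages)
  mat_ids <- genes$gene_id[genes$class == "maternal"]
  ivd <- truth$samples[truth$samples$group == "IV-D", ]
  mu <- truth$fpkm[mat_ids, ivd$sample_id]
  t_idx <- match(ivd$stage, stages)
  expect_true(all(mu[, t_idx >= deg_idx] == 0))
  pre <- mu[, order(t_idx[t_idx < deg_idx]), drop = FALSE]
  expect_true(all(diff(t(log(pre[pre[, 1] > 0, ]))) < 0))

  # housekeeping: constant across stages within a group
  hk <- genes$gene_id[genes$class == "housekeeping"]
  expect_true(all(apply(truth$fpkm[hk, ivd$sample_id], 1,
                        function(x) max(x) - min(x)) == 0))
})

test_that("IT halves carry exactly rho times the ICM level and TE none", {
  cfg <- sim_config(n_genes = 400, it_mixture = 0.5, seed = 5)
  sheet <- emulate_design("design27", bisect = TRUE)
  truth <- simulate_truth(cfg, sheet)
  icm <- truth$genes$gene_id[truth$genes$class == "lineage_icm"]
  it_id <- sheet$sample_id[sheet$lineage == "IT"][1]
  te_id <- sheet$sample_id[sheet$lineage == "TE"][1]
  expect_equal(truth$fpkm[icm, it_id],
               0.5 * truth$genes$baseline_fpkm[match(icm,
                                                     truth$genes$gene_id)],
               ignore_attr = TRUE)
  expect_true(all(truth$fpkm[icm, te_id] == 0))
})

test_that("count sampling is deterministic and column-stable", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  sim1 <- simulate_experiment(cfg, "design27")
  sim2 <- simulate_experiment(cfg, "design27")
  expect_identical(sim1$counts, sim2$counts)

  # adding bisected samples must not reshuffle the original columns
  sim3 <- simulate_experiment(cfg, "design27", bisect = TRUE)
  shared <- setdiff(names(sim1$counts), "gene_id")
  expect_identical(as.matrix(sim1$counts[shared]),
                   as.matrix(sim3$counts[shared]))
})

test_that("zero mean gives zero counts and alpha = 0 is Poisson", {
  cfg <- sim_config(n_genes = 1000, dispersion = 0,
                    class_fractions = c(housekeeping = 1),
                    baseline_log_sd = 0, seed = 7)
  sheet <- emulate_design(tibble::tibble(
    sample_id = sprintf("s%03d", 1:100), group = "IV-D", stage = "oocyte"))
  truth <- simulate_truth(cfg, sheet)
  ann <- make_annotation(truth$genes$gene_id, length_bp = 2000)
  counts <- sample_counts(truth, ann, cfg,
                          depths = rep(1e6, 100))
  k <- as.matrix(counts[-1])
  m_true <- 20 * 2000 * 1e6 / 1e9   # baseline 20 FPKM, 2 kb, depth 1e6
  draws <- as.numeric(k)
  ratio <- var(draws) / mean(draws)
  se <- sqrt((1 / m_true + 2) / length(draws))
  expect_lt(abs(ratio - 1), 3 * se)

  # mu = 0 -> k = 0 exactly
  cfg0 <- sim_config(n_genes = 50, class_fractions = c(zygotic = 1),
                     activation_weights = c("blastocyst" = 1), seed = 1)
  sheet0 <- make_stage_sheet("oocyte")
  truth0 <- simulate_truth(cfg0, sheet0)
  counts0 <- sample_counts(truth0, make_annotation(truth0$genes$gene_id),
                           cfg0)
  expect_true(all(as.matrix(counts0[-1]) == 0))
})

test_that("the named designs have the published shapes", {
  d27 <- emulate_design("design27")
  expect_equal(nrow(d27), 27)
  expect_setequal(unique(d27$group), c("NT-D", "IV-D", "donor"))
  expect_setequal(unique(d27$stage[d27$group != "donor"]),
                  c("oocyte", "4-cell", "8-cell", "blastocyst"))
  expect_true(all(table(d27$group, d27$stage)[, "4-cell"][c("NT-D",
                                                            "IV-D")] == 3))

  d25 <- emulate_design("design25")
  expect_equal(nrow(d25), 25)
  embryo <- d25[!d25$group %in% c("donor", "MII"), ]
  expect_equal(nrow(embryo), 21)  # 3 groups x 7 consecutive stages
  expect_equal(dplyr::n_distinct(embryo$stage), 7)

  expect_error(emulate_design("design99"), "design25")
  expect_error(
    emulate_design(tibble::tibble(sample_id = c("a", "a"),
                                  group = "IV-D", stage = "oocyte")),
    "duplicated")
})

test_that("a larger delay probability delays more genes", {
  base <- function(delta) {
    cfg <- sim_config(n_genes = 1000, seed = 13,
                      group_perturbations = list(
                        "IV-D" = list(delay_prob = 0, damping = 1),
                        "NT-D" = list(delay_prob = delta, damping = 1)))
    truth <- simulate_truth(cfg, emulate_design("design27"))
    sum(truth$group_activation$delayed[truth$group_activation$group ==
                                         "NT-D"])
  }
  expect_gt(base(0.4), base(0.1))
  expect_equal(base(0), 0)
})

test_that("planted zygotic genes cross the expression threshold at activation", {
  cfg <- sim_config(n_genes = 2000, seed = 19)
  sim <- simulate_experiment(cfg, "design25")
  fpkm <- compute_fpkm(sim$counts, sim$annotation)
  m <- as.matrix(fpkm[-1]); rownames(m) <- fpkm$gene_id
  stages <- cfg$stage_labels
  ivd <- sim$sample_sheet[sim$sample_sheet$group == "IV-D", ]
  ord <- ivd$sample_id[match(stages, ivd$stage)]
  genes <- sim$truth$genes
  zyg <- genes[genes$class == "zygotic" & genes$baseline_fpkm >= 5, ]
  a_idx <- match(zyg$activation_stage, stages)
  prof <- m[zyg$gene_id, ord, drop = FALSE]
  ok <- vapply(seq_len(nrow(prof)), function(i) {
    all(prof[i, seq_len(ncol(prof)) >= a_idx[i]] > 1) &&
      all(prof[i, seq_len(ncol(prof)) < a_idx[i]] < 1)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
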