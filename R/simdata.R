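# Synthetic embryo-transcriptome simulator.
#
# Generates count matrices, annotations and sample sheets with the structure
# the staging analysis assumes -- maternal transcript decay, zygotic
# activation waves peaking around the 4-cell/8-cell transition, a cloned-group
# activation delay, blastocyst ICM/TE lineage markers and negative-binomial
# count noise -- together with a ground-truth table for recovery scoring.

GENE_CLASSES <- c("maternal", "zygotic", "housekeeping", "stage_specific",
                  "lineage_icm", "lineage_te", "silent")

DEFAULT_STAGES <- c("oocyte", "1-cell", "2-cell", "4-cell", "8-cell",
                    "morula", "blastocyst")

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic
#' embryo-transcriptome generator. Defaults describe a desk-scale experiment:
#' seven developmental stages, a zygotic activation wave concentrated on the
#' 4-cell and 8-cell stages, geometric decay of maternal transcripts with
#' complete degradation by the 8-cell stage, and cloned groups whose zygotic
#' activation is delayed by one stage with per-group probability and damped
#' in magnitude.
#'
#' @param n_genes Number of genes to simulate.
#' @param class_fractions Named fractions over gene classes
#'   (`maternal`, `zygotic`, `housekeeping`, `stage_specific`, `lineage_icm`,
#'   `lineage_te`); must sum to at most 1, the remainder is `silent`.
#' @param stage_labels Ordered developmental stage labels.
#' @param activation_weights Named probabilities (over `stage_labels`) for a
#'   zygotic gene's activation stage; mass is concentrated on the 4-cell and
#'   8-cell stages by default.
#' @param maternal_decay Per-stage multiplicative decay factor for maternal
#'   transcripts, in (0, 1).
#' @param degradation_stage Stage at and after which maternal true FPKM is 0.
#' @param group_perturbations Named list, one entry per embryo group, each a
#'   list with `delay_prob` (probability that a zygotic gene's activation is
#'   shifted one stage later in that group) and `damping` (multiplier <= 1 on
#'   zygotic/stage-specific expression in that group).
#' @param dispersion Negative-binomial dispersion alpha >= 0 of the count
#'   noise; 0 degenerates to Poisson.
#' @param depth_log_mean,depth_log_sd Log-normal parameters of the per-sample
#'   depth scale `D_j` entering the count mean `mu * L * D / 1e9`. The default
#'   depth scale yields roughly 5e5 counted fragments per library under the
#'   default transcriptome.
#' @param it_mixture Fraction rho of ICM signal in a bisected-blastocyst IT
#'   sample (and in whole blastocysts), in (0, 1).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of per-gene
#'   baseline true FPKM.
#' @param frac_named Fraction of genes carrying a gene name in the simulated
#'   annotation (the rest emulate accession-only annotation entries).
#' @param seed Master integer seed; every stochastic operation derives its own
#'   stream from it by a stable label.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       class_fractions = c(maternal = 0.25, zygotic = 0.30,
                                           housekeeping = 0.20,
                                           stage_specific = 0.05,
                                           lineage_icm = 0.02,
                                           lineage_te = 0.02),
                       stage_labels = DEFAULT_STAGES,
                       activation_weights = c("2-cell" = 0.02,
                                              "4-cell" = 0.55,
                                              "8-cell" = 0.35,
                                              "morula" = 0.06,
                                              "blastocyst" = 0.02),
                       maternal_decay = 0.4,
                       degradation_stage = "8-cell",
                       group_perturbations = list(
                         "IV-D"  = list(delay_prob = 0.0, damping = 1.0),
                         "NT-LW" = list(delay_prob = 0.2, damping = 0.8),
                         "NT-D"  = list(delay_prob = 0.4, damping = 0.6)),
                       dispersion = 0.05,
                       depth_log_mean = log(3e6),
                       depth_log_sd = 0.3,
                       it_mixture = 0.5,
                       baseline_log_mean = log(20),
                       baseline_log_sd = 1,
                       frac_named = 0.85,
                       seed = 1L) {
  cfg_error <- function(field, msg) {
    abort(sprintf("invalid simulation configuration: %s %s", field, msg),
          class = "embryodyn_config_error")
  }
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    cfg_error("n_genes", "must be a positive integer")
  }
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% setdiff(GENE_CLASSES, "silent"))) {
    cfg_error("class_fractions", sprintf(
      "must be named from {%s}",
      paste(setdiff(GENE_CLASSES, "silent"), collapse = ", ")))
  }
  if (any(class_fractions < 0) || sum(class_fractions) > 1 + 1e-9) {
    cfg_error("class_fractions", "must be non-negative and sum to <= 1")
  }
  if (length(stage_labels) == 0 || anyDuplicated(stage_labels)) {
    cfg_error("stage_labels", "must be non-empty and unique")
  }
  if (is.null(names(activation_weights)) ||
      !all(names(activation_weights) %in% stage_labels)) {
    cfg_error("activation_weights", "must be named by stage labels")
  }
  if (any(activation_weights < 0) || sum(activation_weights) <= 0) {
    cfg_error("activation_weights", "must be non-negative with positive sum")
  }
  if (!is.numeric(maternal_decay) || maternal_decay <= 0 ||
      maternal_decay >= 1) {
    cfg_error("maternal_decay", "must lie in (0, 1)")
  }
  if (!degradation_stage %in% stage_labels) {
    cfg_error("degradation_stage", "must be one of stage_labels")
  }
  for (g in names(group_perturbations)) {
    pert <- group_perturbations[[g]]
    if (!is.list(pert) || is.null(pert$delay_prob) || is.null(pert$damping)) {
      cfg_error("group_perturbations", sprintf(
        "entry '%s' must list delay_prob and damping", g))
    }
    if (pert$delay_prob < 0 || pert$delay_prob > 1) {
      cfg_error("group_perturbations", sprintf(
        "delay_prob for '%s' must lie in [0, 1]", g))
    }
    if (pert$damping <= 0 || pert$damping > 1) {
      cfg_error("group_perturbations", sprintf(
        "damping for '%s' must lie in (0, 1]", g))
    }
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    cfg_error("dispersion", "must be >= 0")
  }
  if (it_mixture <= 0 || it_mixture >= 1) {
    cfg_error("it_mixture", "must lie in (0, 1)")
  }
  if (frac_named < 0 || frac_named > 1) {
    cfg_error("frac_named", "must lie in [0, 1]")
  }

  structure(list(
    n_genes = as.integer(n_genes),
    class_fractions = class_fractions,
    stage_labels = stage_labels,
    activation_weights = activation_weights / sum(activation_weights),
    maternal_decay = maternal_decay,
    degradation_stage = degradation_stage,
    group_perturbations = group_perturbations,
    dispersion = dispersion,
    depth_log_mean = depth_log_mean,
    depth_log_sd = depth_log_sd,
    it_mixture = it_mixture,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    frac_named = frac_named,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Emulate a study design as a sample sheet
#'
#' `"design27"` is the replicated design: two embryo groups (NT-D cloned,
#' IV-D in vivo fertilized) at four critical stages (oocyte, 4-cell, 8-cell,
#' blastocyst) with three biological replicates each, plus three donor-cell
#' samples (27 rows). `"design25"` is the unreplicated staging design: three
#' embryo groups (NT-LW, NT-D, IV-D) across seven consecutive stages, plus
#' two donor-cell samples and two additional MII oocyte samples (25 rows).
#' A custom design may be supplied as a data frame with columns `sample_id`,
#' `group`, `stage` (and optionally `replicate`, `lineage`).
#'
#' @param design `"design27"`, `"design25"`, or a data frame.
#' @param bisect If `TRUE`, add bisected-blastocyst IT/TE sample pairs (3
#'   replicates per embryo group present at the blastocyst stage); the IT half
#'   contains ICM and TE, the other half TE only.
#' @param stage_labels Stage ordering used to validate stage labels.
#'
#' @return A tibble sample sheet: `sample_id`, `group`, `stage`, `replicate`,
#'   `lineage` (`none`, `IT` or `TE`).
#' @export
emulate_design <- function(design = "design27", bisect = FALSE,
                           stage_labels = DEFAULT_STAGES) {
  if (is.data.frame(design)) {
    sheet <- as_tibble(design)
    required <- c("sample_id", "group", "stage")
    missing_cols <- setdiff(required, names(sheet))
    if (length(missing_cols) > 0) {
      abort(sprintf("custom design is missing columns: %s",
                    paste(missing_cols, collapse = ", ")))
    }
    if (!"replicate" %in% names(sheet)) sheet$replicate <- 1L
    if (!"lineage" %in% names(sheet)) sheet$lineage <- "none"
  } else if (identical(design, "design27")) {
    embryo <- tidyr::expand_grid(
      group = c("NT-D", "IV-D"),
      stage = c("oocyte", "4-cell", "8-cell", "blastocyst"),
      replicate = 1:3)
    donor <- tibble(group = "donor", stage = "donor", replicate = 1:3)
    sheet <- dplyr::bind_rows(embryo, donor)
    sheet$lineage <- "none"
    sheet$sample_id <- sprintf("%s_%s_r%d", sheet$group, sheet$stage,
                               sheet$replicate)
  } else if (identical(design, "design25")) {
    embryo <- tidyr::expand_grid(
      group = c("NT-LW", "NT-D", "IV-D"),
      stage = stage_labels,
      replicate = 1L)
    extra <- tibble(
      group = c("donor", "donor", "MII", "MII"),
      stage = c("donor", "donor", "oocyte", "oocyte"),
      replicate = c(1L, 2L, 1L, 2L))
    sheet <- dplyr::bind_rows(embryo, extra)
    sheet$lineage <- "none"
    sheet$sample_id <- sprintf("%s_%s_r%d", sheet$group, sheet$stage,
                               sheet$replicate)
  } else {
    abort(sprintf(
      "unknown design '%s'; valid names are 'design25', 'design27' (or pass a data frame)",
      design))
  }

  if (isTRUE(bisect)) {
    blast <- sheet |>
      filter(.data$stage == "blastocyst", .data$group != "donor") |>
      distinct(.data$group)
    if (nrow(blast) > 0) {
      halves <- tidyr::expand_grid(group = blast$group, replicate = 1:3,
                                   lineage = c("IT", "TE"))
      halves$stage <- "blastocyst"
      halves$sample_id <- sprintf("%s_blastocyst_r%d_%s", halves$group,
                                  halves$replicate, halves$lineage)
      sheet <- dplyr::bind_rows(sheet, halves)
    }
  }

  sheet <- sheet |>
    select("sample_id", "group", "stage", "replicate", "lineage") |>
    mutate(replicate = as.integer(.data$replicate))

  if (anyDuplicated(sheet$sample_id)) {
    abort("sample sheet has duplicated sample_id values")
  }
  known_stages <- c(stage_labels, "donor")
  bad <- setdiff(unique(sheet$stage), known_stages)
  if (length(bad) > 0) {
    abort(sprintf("sample sheet stages not in the stage ordering: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(sheet$lineage %in% c("none", "IT", "TE"))) {
    abort("lineage tags must be one of 'none', 'IT', 'TE'")
  }
  sheet
}

#' Simulate a gene annotation table
#'
#' Gene lengths are drawn log-uniformly in \[500, 10000\] bp (transcript-union
#' lengths); a fraction of genes is generated without a gene name to emulate
#' annotation gaps in draft genome assemblies.
#'
#' @param config A [sim_config()].
#' @return Tibble with `gene_id`, `gene_name` (`NA` when unnamed), `length_bp`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  with_stream(config$seed, "annotation", {
    length_bp <- round(exp(runif(n, log(500), log(10000))))
    named <- runif(n) < config$frac_named
    gene_name <- ifelse(named, sprintf("SIM%05d", seq_len(n)), NA_character_)
    tibble(gene_id = gene_id, gene_name = gene_name, length_bp = length_bp)
  })
}

#' Simulate the ground-truth expression table
#'
#' Assigns every gene a class, baseline level and (for zygotic and
#' stage-specific genes) an activation stage, applies the cloned-group
#' perturbation (activation shifted one stage later with probability
#' `delay_prob`; expression multiplied by `damping`), and evaluates the true
#' FPKM of every gene in every sample of the sheet. Maternal transcripts decay
#' geometrically from the oocyte and drop to zero at the degradation stage;
#' zygotic genes are zero before their activation stage; housekeeping genes
#' are constant; lineage markers appear only at the blastocyst stage, with IT
#' halves carrying `it_mixture` of the ICM signal.
#'
#' @param config A [sim_config()].
#' @param samples A sample sheet from [emulate_design()].
#' @return List of class `embryo_truth`: `genes` (per-gene class, baseline,
#'   activation stage), `group_activation` (per gene x group realized
#'   activation stage and damping), `fpkm` (true FPKM matrix genes x samples),
#'   `samples`, `config`.
#' @export
simulate_truth <- function(config, samples = emulate_design("design27")) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  stages <- config$stage_labels
  gene_id <- sprintf("G%05d", seq_len(n))

  fr <- config$class_fractions[intersect(GENE_CLASSES, names(config$class_fractions))]
  counts <- diff(c(0, round(cumsum(fr) * n)))
  counts <- pmax(counts, 0)
  n_silent <- n - sum(counts)
  class_vec <- c(rep(names(fr), counts), rep("silent", n_silent))
  class_vec <- with_stream(config$seed, "classes", sample(class_vec))

  baseline <- with_stream(config$seed, "baseline", {
    e <- exp(rnorm(n, config$baseline_log_mean, config$baseline_log_sd))
    e[class_vec == "silent"] <- 0
    e
  })

  act_stage <- rep(NA_character_, n)
  zyg <- which(class_vec == "zygotic")
  if (length(zyg) > 0) {
    act_stage[zyg] <- with_stream(config$seed, "activation",
      sample(names(config$activation_weights), length(zyg), replace = TRUE,
             prob = config$activation_weights))
  }
  spec <- which(class_vec == "stage_specific")
  if (length(spec) > 0) {
    act_stage[spec] <- with_stream(config$seed, "stage_specific",
      sample(stages, length(spec), replace = TRUE))
  }

  genes <- tibble(gene_id = gene_id, class = class_vec,
                  baseline_fpkm = baseline, activation_stage = act_stage)

  groups <- setdiff(unique(samples$group), "donor")
  group_activation <- purrr::map_dfr(groups, function(g) {
    pert <- config$group_perturbations[[g]] %||%
      list(delay_prob = 0, damping = 1)
    delayed <- rep(FALSE, n)
    if (pert$delay_prob > 0 && length(zyg) > 0) {
      delayed[zyg] <- with_stream(config$seed, paste0("perturb:", g),
        runif(length(zyg)) < pert$delay_prob)
    }
    idx <- match(act_stage, stages)
    idx[delayed] <- idx[delayed] + 1L
    realized <- ifelse(is.na(idx) | idx > length(stages),
                       NA_character_, stages[pmin(idx, length(stages))])
    realized[is.na(act_stage)] <- NA_character_
    tibble(gene_id = gene_id, group = g,
           activation_stage = realized, delayed = delayed,
           damping = pert$damping)
  })

  deg_idx <- match(config$degradation_stage, stages)
  fpkm <- matrix(0, nrow = n, ncol = nrow(samples),
                 dimnames = list(gene_id, samples$sample_id))
  act_by_group <- split(group_activation, group_activation$group)

  for (j in seq_len(nrow(samples))) {
    grp <- samples$group[j]
    stg <- samples$stage[j]
    lin <- samples$lineage[j]
    mu <- numeric(n)
    if (stg == "donor") {
      hk <- class_vec == "housekeeping"
      mu[hk] <- baseline[hk]
    } else {
      t_idx <- match(stg, stages)
      ga <- act_by_group[[grp]]
      gamma <- if (!is.null(ga)) ga$damping[1] else 1
      realized <- if (!is.null(ga)) ga$activation_stage else act_stage

      hk <- class_vec == "housekeeping"
      mu[hk] <- baseline[hk]

      mat <- class_vec == "maternal"
      if (t_idx < deg_idx) {
        mu[mat] <- baseline[mat] * config$maternal_decay^(t_idx - 1)
      }

      zg <- class_vec == "zygotic"
      a_idx <- match(realized, stages)
      on <- zg & !is.na(a_idx) & t_idx >= a_idx
      mu[on] <- baseline[on] * gamma

      sp <- class_vec == "stage_specific" & !is.na(a_idx) & a_idx == t_idx
      mu[sp] <- baseline[sp] * gamma

      if (stg == "blastocyst") {
        rho <- config$it_mixture
        icm <- class_vec == "lineage_icm"
        te <- class_vec == "lineage_te"
        if (lin == "TE") {
          mu[icm] <- 0
          mu[te] <- baseline[te]
        } else {
          # whole blastocysts and IT halves both contain ICM and TE
          mu[icm] <- rho * baseline[icm]
          mu[te] <- (1 - rho) * baseline[te]
        }
      }
    }
    fpkm[, j] <- mu
  }

  structure(list(genes = genes, group_activation = group_activation,
                 fpkm = fpkm, samples = samples, config = config),
            class = "embryo_truth")
}

#' Draw negative-binomial counts from a truth table
#'
#' Counts follow `k_ij ~ NB(mean = mu_ij * L_i * D_j / 1e9, dispersion alpha)`
#' with variance `m (1 + alpha m)`; `alpha = 0` degenerates to Poisson. Each
#' sample has its own RNG stream so matrices are reproducible column-wise.
#'
#' @param truth An `embryo_truth` from [simulate_truth()].
#' @param annotation Annotation tibble with `gene_id` and `length_bp`.
#' @param config The [sim_config()] used for the truth.
#' @param depths Optional named per-sample depth scales; drawn log-normally
#'   when `NULL`.
#' @return A count table (tibble, `gene_id` + one integer column per sample)
#'   with the realized `depths` attached as an attribute.
#' @export
sample_counts <- function(truth, annotation, config = truth$config,
                          depths = NULL) {
  stopifnot(inherits(truth, "embryo_truth"))
  L <- annotation$length_bp[match(rownames(truth$fpkm), annotation$gene_id)]
  if (anyNA(L) || any(L <= 0)) {
    abort("annotation must supply a positive length_bp for every gene")
  }
  sample_ids <- colnames(truth$fpkm)
  if (is.null(depths)) {
    depths <- vapply(sample_ids, function(id) {
      with_stream(config$seed, paste0("depth:", id),
                  exp(rnorm(1, config$depth_log_mean, config$depth_log_sd)))
    }, numeric(1))
  } else {
    if (is.null(names(depths))) names(depths) <- sample_ids
    depths <- depths[sample_ids]
    if (anyNA(depths) || any(depths <= 0)) {
      abort("depths must be positive and cover every sample")
    }
  }

  alpha <- config$dispersion
  k <- matrix(0L, nrow = nrow(truth$fpkm), ncol = length(sample_ids),
              dimnames = dimnames(truth$fpkm))
  for (j in seq_along(sample_ids)) {
    m <- truth$fpkm[, j] * L * depths[j] / 1e9
    if (any(m < 0)) abort("internal error: negative count mean")
    k[, j] <- with_stream(config$seed, paste0("counts:", sample_ids[j]), {
      if (alpha == 0) rpois(length(m), m)
      else rnbinom(length(m), mu = m, size = 1 / alpha)
    })
  }
  out <- expr_tibble(k)
  attr(out, "depths") <- depths
  out
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running [emulate_design()], [simulate_annotation()],
#' [simulate_truth()] and [sample_counts()] under one configuration.
#'
#' @param config A [sim_config()].
#' @inheritParams emulate_design
#' @return List of class `embryo_sim` with elements `counts`, `annotation`,
#'   `sample_sheet`, `truth`, `depths` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), design = "design27",
                                bisect = FALSE) {
  sheet <- emulate_design(design, bisect = bisect,
                          stage_labels = config$stage_labels)
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(config, sheet)
  counts <- sample_counts(truth, annotation, config)
  structure(list(counts = counts, annotation = annotation,
                 sample_sheet = sheet, truth = truth,
                 depths = attr(counts, "depths"), config = config),
            class = "embryo_sim")
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("<embryo_sim> %d genes x %d samples (seed %d)\n",
              x$config$n_genes, nrow(x$sample_sheet), x$config$seed))
  cls <- table(x$truth$genes$class)
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  groups:",
      paste(unique(x$sample_sheet$group), collapse = ", "), "\n")
  invisible(x)
}

#' @method glance embryo_sim
#' @export
glance.embryo_sim <- function(x, ...) {
  tibble(n_genes = x$config$n_genes,
         n_samples = nrow(x$sample_sheet),
         n_groups = dplyr::n_distinct(x$sample_sheet$group),
         n_stages = dplyr::n_distinct(x$sample_sheet$stage),
         dispersion = x$config$dispersion,
         seed = x$config$seed)
}

#' @method tidy embryo_truth
#' @export
tidy.embryo_truth <- function(x, ...) {
  as_tibble(x$fpkm, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "true_fpkm")
}

#' @method tidy embryo_sim
#' @export
tidy.embryo_sim <- function(x, ...) tidy(x$truth, ...)

#' Write a simulated experiment to tab-delimited files
#'
#' Writes `counts.tsv`, `annotation.tsv` (missing gene names as `.`),
#' `samples.tsv`, `gene_truth.tsv` and `true_fpkm.tsv` under `dir`.
#'
#' @param sim An `embryo_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "embryo_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             samples = file.path(dir, "samples.tsv"),
             gene_truth = file.path(dir, "gene_truth.tsv"),
             true_fpkm = file.path(dir, "true_fpkm.tsv"))
  readr::write_tsv(sim$counts, paths["counts"])
  ann <- sim$annotation |>
    mutate(gene_name = ifelse(is.na(.data$gene_name), ".", .data$gene_name))
  readr::write_tsv(ann, paths["annotation"])
  readr::write_tsv(sim$sample_sheet, paths["samples"])
  readr::write_tsv(sim$truth$genes, paths["gene_truth"])
  readr::write_tsv(tidy(sim$truth), paths["true_fpkm"])
  invisible(paths)
}
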