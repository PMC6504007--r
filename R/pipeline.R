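# Configuration-driven orchestration: quantify -> differential expression ->
# staging -> lineage panels -> QC, with a reproducibility manifest.

#' Build a pipeline configuration
#'
#' Either `counts`/`annotation`/`samples` paths or a `simulate` block must be
#' given. The configuration is a plain list and can equally be read from a
#' YAML file with [read_pipeline_config()].
#'
#' @param counts,annotation,samples Paths to input TSVs (see [read_counts()],
#'   [read_annotation()], [read_samples()]).
#' @param simulate Optional list of [sim_config()] arguments plus optional
#'   `design` and `bisect`; when present, inputs are simulated instead of
#'   read.
#' @param ordering Ordered stage labels.
#' @param mode Contrast mode passed to [run_contrast()].
#' @param thresholds A [de_thresholds()].
#' @param panels Optional character vector of built-in panel names (or a GMT
#'   path) for trajectory extraction.
#' @param gene_sets Optional GMT path for over-representation testing of the
#'   DEG union.
#' @param seed Master seed (overrides any seed inside `simulate`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, annotation = NULL, samples = NULL,
                            simulate = NULL, ordering = DEFAULT_STAGES,
                            mode = "auto", thresholds = de_thresholds(),
                            panels = NULL, gene_sets = NULL, seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(counts) || is.null(annotation) || is.null(samples)) {
      abort("config must give counts, annotation and samples paths, or a simulate block")
    }
    for (p in c(counts, annotation, samples)) {
      if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
    }
  }
  structure(list(counts = counts, annotation = annotation, samples = samples,
                 simulate = simulate, ordering = ordering, mode = mode,
                 thresholds = thresholds, panels = panels,
                 gene_sets = gene_sets, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thr <- if (!is.null(raw$thresholds)) do.call(de_thresholds, raw$thresholds)
         else de_thresholds()
  pipeline_config(counts = raw$counts, annotation = raw$annotation,
                  samples = raw$samples, simulate = raw$simulate,
                  ordering = raw$ordering %||% DEFAULT_STAGES,
                  mode = raw$mode %||% "auto", thresholds = thr,
                  panels = raw$panels, gene_sets = raw$gene_sets,
                  seed = raw$seed %||% 1L)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "embryodyn_pipeline_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes quantification, all configured contrasts, the staging analyses,
#' lineage/panel extraction where the design supports them, and QC, writing
#' every module's TSV plus a `manifest.json` (configuration echo, seed,
#' package version, row counts). Runs are deterministic for a fixed
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    written[[name]] <<- path
    df
  }

  inputs <- pipeline_stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      design <- sim_args$design %||% "design27"
      bisect <- isTRUE(sim_args$bisect)
      sim_args$design <- NULL
      sim_args$bisect <- NULL
      sim_args$seed <- config$seed
      sim <- simulate_experiment(do.call(sim_config, sim_args),
                                 design = design, bisect = bisect)
      list(counts = sim$counts, annotation = sim$annotation,
           sheet = sim$sample_sheet)
    } else {
      list(counts = read_counts(config$counts),
           annotation = read_annotation(config$annotation),
           sheet = read_samples(config$samples))
    }
  })
  counts <- inputs$counts
  annotation <- inputs$annotation
  sheet <- inputs$sheet
  ordering <- config$ordering

  fpkm <- pipeline_stage("quantify", {
    fpkm <- compute_fpkm(counts, annotation)
    emit("fpkm", fpkm)
    emit("norm_factors", trimmed_mean_factors(counts))
    emit("expressed", call_expressed(fpkm) |> select(-"genes"))
    fpkm
  })

  embryo_groups <- setdiff(unique(sheet$group), c("donor", "MII"))
  de_succ <- pipeline_stage("diffexpr", {
    de_succ <- purrr::map_dfr(embryo_groups, function(g) {
      run_successive_de(counts, sheet, g, ordering, mode = config$mode,
                        annotation = annotation,
                        thresholds = config$thresholds)
    })
    emit("de_successive", de_succ)
    if (length(embryo_groups) >= 2) {
      pairs <- utils::combn(sort(embryo_groups), 2, simplify = FALSE)
      de_groups <- purrr::map_dfr(pairs, function(pr) {
        shared <- intersect(
          ordering[ordering %in% sheet$stage[sheet$group == pr[1]]],
          ordering[ordering %in% sheet$stage[sheet$group == pr[2]]])
        purrr::map_dfr(shared, function(s) {
          ids1 <- sheet$sample_id[sheet$group == pr[1] & sheet$stage == s &
                                    sheet$lineage == "none"]
          ids2 <- sheet$sample_id[sheet$group == pr[2] & sheet$stage == s &
                                    sheet$lineage == "none"]
          run_contrast(counts, ids1, ids2, annotation = annotation,
                       mode = config$mode, thresholds = config$thresholds,
                       contrast = sprintf("%s_%s_vs_%s_%s",
                                          pr[1], s, pr[2], s)) |>
            mutate(group_a = pr[1], group_b = pr[2], stage = s)
        })
      })
      emit("de_groups", de_groups)
    }
    de_succ
  })

  stagedyn_out <- pipeline_stage("stagedyn", {
    emit("transitions",
         successive_stage_degs(de_succ, ordering = ordering))
    ss <- purrr::map_dfr(embryo_groups, function(g) {
      classify_stage_specific(fpkm, sheet, g, ordering,
                              annotation = annotation)
    })
    emit("stage_specific", ss)
    fe <- purrr::map_dfr(embryo_groups, function(g) {
      detect_first_expressed(fpkm, de_succ, sheet, g, ordering)
    })
    emit("first_expressed", fe)
    if (length(embryo_groups) >= 2 && nrow(fe) > 0) {
      venn <- purrr::map_dfr(unique(fe$stage), function(s) {
        sets <- lapply(embryo_groups, function(g) {
          fe$gene_id[fe$group == g & fe$stage == s]
        })
        names(sets) <- embryo_groups
        overlap_sets(sets) |> mutate(stage = s, .before = 1)
      })
      emit("venn_first_expressed", venn)
    }
    if (!is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      deg_union <- unique(de_succ$gene_id[de_succ$significant])
      emit("ora", ora_fisher(deg_union, unique(de_succ$gene_id), sets))
    }
    list(fe = fe)
  })

  pipeline_stage("lineage_panels", {
    if (any(sheet$lineage == "IT") && any(sheet$lineage == "TE")) {
      emit("icm_markers", icm_markers(fpkm, sheet))
    }
    if (!is.null(config$panels)) {
      panels <- if (length(config$panels) == 1 && file.exists(config$panels))
        read_gmt(config$panels) else builtin_panels()[config$panels]
      traj <- purrr::map_dfr(names(panels), function(nm) {
        panel_trajectories(fpkm, panels[[nm]], sheet, annotation,
                           ordering) |>
          mutate(panel = nm, .before = 1)
      })
      emit("trajectories", traj)
    }
    NULL
  })

  pipeline_stage("qc", {
    deg_union <- unique(de_succ$gene_id[de_succ$significant])
    hc_genes <- if (length(deg_union) >= 2) deg_union else NULL
    hc <- hclust_samples(fpkm, genes = hc_genes)
    emit("linkage", tidy(hc))
    write_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    written$dendrogram <- file.path(out_dir, "dendrogram.nwk")
    pca <- pca_samples(fpkm)
    emit("pca", tidy(pca))
    r2 <- pairwise_r2(fpkm)
    emit("r2", as_tibble(r2, rownames = "sample_id"))
    NULL
  })

  pipeline_stage("manifest", {
    manifest <- list(
      package = "embryodyn",
      version = as.character(packageVersion("embryodyn")),
      seed = config$seed,
      mode = config$mode,
      ordering = config$ordering,
      thresholds = unclass(config$thresholds),
      simulate = config$simulate,
      inputs = list(counts = config$counts, annotation = config$annotation,
                    samples = config$samples),
      n_genes = nrow(counts), n_samples = nrow(sheet),
      tables = lapply(written, function(p) {
        if (grepl("\\.tsv$", p)) length(readr::read_lines(p)) - 1L else NA
      })
    )
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    written$manifest <- path
  })

  invisible(written)
}
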