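#' Build a pipeline run configuration
#'
#' Collects input locations (or a synthetic-study configuration), stage
#' toggles and all stage parameters. Defaults follow the analysis
#' conventions used throughout the package: q < 0.05, gene fold-change rule
#' |log2FC| >= log2(1.5), bottom-40 percent expression filter, metabolite
#' clustering (min size 3, deepSplit 3, merge 0.60), gene clustering (min
#' size 100, deepSplit 3), |rho| > 0.5 overlap, top-20 hub table.
#'
#' @param synthetic a [synthetic_config()], or `NULL` to read matrices from
#'   `inputs`.
#' @param inputs named list of paths: `metabolome`, `transcriptome`, `meta`
#'   (ignored when `synthetic` is given).
#' @param out_dir output directory for stage tables and the manifest.
#' @param stages named logical vector toggling `differential`, `benchmark`,
#'   `modules`, `integration`, `enrichment`.
#' @param gmt optional path to a GMT collection for the enrichment stage
#'   (synthetic runs derive a collection from the planted gene modules when
#'   absent).
#' @param seed integer seed for every stochastic step.
#' @param ... parameter overrides (see Details in the package vignette):
#'   `q_threshold`, `fc_threshold`, `low_expr_fraction`,
#'   `overlap_threshold`, `met_min_size`, `met_deep_split`, `met_merge`,
#'   `gene_min_size`, `gene_deep_split`, `gene_merge`, `top_k`, `n_perm`,
#'   `benchmark_methods`, `eb_estimate_on`.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL, out_dir,
                            stages = c(differential = TRUE, benchmark = TRUE,
                                       modules = TRUE, integration = TRUE,
                                       enrichment = TRUE),
                            gmt = NULL, seed = 1, ...) {
  params <- list(q_threshold = 0.05, fc_threshold = log2(1.5),
                 low_expr_fraction = 0.4, overlap_threshold = 0.5,
                 met_min_size = 3, met_deep_split = 3, met_merge = 0.60,
                 gene_min_size = 100, gene_deep_split = 3, gene_merge = 0.75,
                 top_k = 20, n_perm = 200,
                 benchmark_methods = c("batch_mean", "baseline", "eb"),
                 eb_estimate_on = "baseline")
  over <- list(...)
  unknown <- setdiff(names(over), names(params))
  if (length(unknown)) stopf("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  params[names(over)] <- over
  all_stages <- c(differential = TRUE, benchmark = TRUE, modules = TRUE,
                  integration = TRUE, enrichment = TRUE)
  all_stages[names(stages)] <- stages
  structure(list(synthetic = synthetic, inputs = inputs, out_dir = out_dir,
                 stages = all_stages, gmt = gmt, seed = as.integer(seed),
                 params = params),
            class = "run_config")
}

preflight <- function(config) {
  if (is.null(config$synthetic)) {
    if (is.null(config$inputs)) stopf("either 'synthetic' or 'inputs' is required")
    for (f in c("metabolome", "transcriptome", "meta")) {
      p <- config$inputs[[f]]
      if (is.null(p) || !file.exists(p)) stopf("input '%s' missing or not found: %s", f, p %||% "<NULL>")
    }
  }
  if (!is.null(config$gmt) && !file.exists(config$gmt))
    stopf("GMT file not found: %s", config$gmt)
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — ingest/simulate,
#' differential calling, batch-correction benchmark, coexpression modules,
#' gene-metabolite integration, enrichment — writing every stage output as
#' TSV under `out_dir` together with a JSON manifest (inputs, parameters,
#' seed, output file hashes). Re-running with an identical configuration
#' reproduces identical outputs. A stage failure aborts with the stage
#' name; outputs produced so far are moved under `failed/`.
#'
#' @param config a [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  preflight(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  p <- config$params
  outputs <- character()
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$synthetic)) {
      study <- generate_study(config$synthetic)
      metab <- inject_batch_effects(study$metabolome, study$meta, study$truth)
      trans <- inject_batch_effects(study$transcriptome, study$meta, study$truth)
      meta <- study$meta
      truth <- study$truth
    } else {
      metab <- read_matrix(config$inputs$metabolome, "metabolite", "raw")
      trans <- read_matrix(config$inputs$transcriptome, "gene", "raw")
      meta <- read_sample_meta(config$inputs$meta)
      truth <- NULL
    }
    align_study(metab, meta); align_study(trans, meta)  # validation only
    metab_log <- log_transform(impute_missing(metab))
    trans_log <- low_expression_filter(log_transform(impute_missing(trans)),
                                       p$low_expr_fraction)
    results <- list()

    if (config$stages[["differential"]]) {
      stage <- "differential"
      dm <- differential_analysis(metab_log, meta, p$q_threshold)
      dg <- differential_analysis(trans_log, meta, p$q_threshold, p$fc_threshold)
      outputs <- c(outputs,
                   write_tsv(dm, file.path(out, "differential_metabolites.tsv")),
                   write_tsv(dg, file.path(out, "differential_genes.tsv")))
      results$diff_met <- dm; results$diff_gene <- dg
    }

    if (config$stages[["benchmark"]]) {
      stage <- "benchmark"
      methods <- p$benchmark_methods
      if (!any(meta$role == "qc")) methods <- setdiff(methods, "qc")
      bench <- benchmark_methods(metab, meta, methods = methods,
                                 eb_estimate_on = p$eb_estimate_on)
      outputs <- c(outputs, write_tsv(bench$summary, file.path(out, "benchmark_summary.tsv")))
      results$benchmark <- bench
    }

    if (config$stages[["modules"]]) {
      stage <- "modules"
      met_prof <- collapse_replicates_median(metab_log, meta)
      mods_met <- cluster_modules(met_prof$values, min_size = p$met_min_size,
                                  deep_split = p$met_deep_split,
                                  merge_threshold = p$met_merge)
      gene_prof <- collapse_replicates_median(trans_log, meta)
      mods_gene <- cluster_modules(gene_prof$values, min_size = p$gene_min_size,
                                   deep_split = p$gene_deep_split,
                                   merge_threshold = p$gene_merge)
      outputs <- c(outputs,
        write_tsv(data.frame(feature_id = names(mods_met$labels),
                             module = mods_met$labels),
                  file.path(out, "metabolite_modules.tsv")),
        write_tsv(data.frame(feature_id = names(mods_gene$labels),
                             module = mods_gene$labels),
                  file.path(out, "gene_modules.tsv")))
      results$modules_met <- mods_met; results$modules_gene <- mods_gene
      corrected <- eb_location_scale_adjust(metab_log, meta,
                                            estimate_on = p$eb_estimate_on)
      pca <- trajectory_pca(corrected, meta)
      outputs <- c(outputs, write_tsv(
        data.frame(component = seq_along(pca$percent_variance),
                   percent_variance = pca$percent_variance),
        file.path(out, "trajectory_pca_variance.tsv")))
      results$pca <- pca
    }

    if (config$stages[["integration"]]) {
      stage <- "integration"
      diff_g <- if (!is.null(results$diff_gene)) select_differential(results$diff_gene)
                else feature_ids(trans_log)
      diff_m <- if (!is.null(results$diff_met)) select_differential(results$diff_met)
                else feature_ids(metab_log)
      if (length(diff_g) == 0 || length(diff_m) == 0)
        stopf("no differential features to integrate")
      gsub_ <- subset_features(trans_log, diff_g)
      msub <- subset_features(metab_log, diff_m)
      tables <- lapply(unique(meta$batch), function(b)
        spearman_pairs(gsub_, msub, meta, b))
      pairs <- overlap_select(tables, p$overlap_threshold)
      if (nrow(pairs) > 0) {
        graph <- build_network(pairs)
        hubs <- rank_hubs(graph, top_k = p$top_k)
        sif <- data.frame(nodeA = graph$edges$gene_id, interaction = "pp",
                          nodeB = graph$edges$metabolite_id)
        outputs <- c(outputs,
                     write_tsv(pairs, file.path(out, "network_pairs.tsv")),
                     write_tsv(sif, file.path(out, "network_edges.sif")),
                     write_tsv(betweenness_centrality(graph),
                               file.path(out, "network_nodes.tsv")),
                     write_tsv(hubs, file.path(out, "network_hubs.tsv")))
        results$graph <- graph; results$hubs <- hubs
      } else {
        outputs <- c(outputs, write_tsv(pairs, file.path(out, "network_pairs.tsv")))
      }
      results$correlations <- tables
    }

    if (config$stages[["enrichment"]]) {
      stage <- "enrichment"
      sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
      else if (!is.null(truth)) {
        gm <- truth$gene_modules
        s <- split(names(gm), gm)
        s <- s[names(s) != "0"]
        names(s) <- paste0("planted_module_", names(s))
        s
      } else NULL
      if (!is.null(sets) && length(sets)) {
        universe <- feature_ids(trans_log)
        query <- if (!is.null(results$diff_gene))
          intersect(select_differential(results$diff_gene), universe) else universe
        ora <- hypergeometric_ora(query, lapply(sets, intersect, universe), universe)
        ranked <- rank_genes_by_foldchange(trans_log, meta, unique(meta$batch)[1])
        gsea <- tryCatch(
          preranked_gsea(ranked, sets[[1]], n_perm = p$n_perm, seed = config$seed),
          error = function(e) NULL)
        outputs <- c(outputs, write_tsv(ora, file.path(out, "enrichment_ora.tsv")))
        if (!is.null(gsea))
          outputs <- c(outputs, write_tsv(
            data.frame(set_id = names(sets)[1], es = gsea$es, nes = gsea$nes,
                       p_value = gsea$p_value, n_perm = gsea$n_perm),
            file.path(out, "enrichment_gsea.tsv")))
        results$ora <- ora; results$gsea <- gsea
      }
    }

    manifest <- list(
      seed = config$seed,
      parameters = p[setdiff(names(p), "benchmark_methods")],
      benchmark_methods = p$benchmark_methods,
      stages = as.list(config$stages),
      synthetic = !is.null(config$synthetic),
      outputs = as.list(stats::setNames(
        as.character(tools::md5sum(sort(outputs))), basename(sort(outputs)))))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
               file.path(out, "manifest.json"))
    results
  }, error = function(e) e)
  if (inherits(res, "error")) {
    fail <- file.path(out, "failed")
    dir.create(fail, showWarnings = FALSE)
    file.rename(outputs, file.path(fail, basename(outputs)))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(res))
  }
  attr(out, "results") <- res
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Writes a plain-text `report.txt` from the stage tables in a run
#' directory: differential counts per batch, benchmark ranking, module
#' counts and sizes, the top-hub table, and enrichment results. Sections
#' without outputs are flagged as skipped; regenerating the report is
#' idempotent.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return Path to `report.txt`, invisibly.
#' @export
make_report <- function(run_dir) {
  if (!dir.exists(run_dir)) stopf("run directory not found: %s", run_dir)
  grab <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  lines <- c("Analysis run summary", strrep("=", 20), "")
  dm <- grab("differential_metabolites.tsv")
  dg <- grab("differential_genes.tsv")
  if (!is.null(dm)) {
    cnt <- tapply(dm$significant, dm$batch, sum)
    lines <- c(lines, "Differential metabolites per batch (q < threshold):",
               sprintf("  %s: %d", names(cnt), cnt),
               sprintf("  union across batches: %d", length(unique(dm$feature_id[dm$significant]))), "")
  } else lines <- c(lines, "Differential stage: skipped", "")
  if (!is.null(dg)) {
    cnt <- tapply(dg$significant, dg$batch, sum)
    lines <- c(lines, "Differential genes per batch (q + fold-change rule):",
               sprintf("  %s: %d", names(cnt), cnt), "")
  }
  bench <- grab("benchmark_summary.tsv")
  if (!is.null(bench)) {
    lines <- c(lines, "Batch-correction benchmark (median r.s.d. | median repeatability | mean batch DB):",
               sprintf("  %-12s %.4f | %.4f | %.4f", bench$method, bench$median_rsd,
                       bench$median_repeatability, bench$mean_batch_bhattacharyya), "")
  } else lines <- c(lines, "Benchmark stage: skipped", "")
  mods <- grab("metabolite_modules.tsv")
  if (!is.null(mods)) {
    tab <- table(mods$module)
    lines <- c(lines, sprintf("Metabolite modules: %d (sizes %s; %d unassigned)",
                              sum(names(tab) != "0"),
                              paste(tab[names(tab) != "0"], collapse = ", "),
                              if ("0" %in% names(tab)) tab[["0"]] else 0L), "")
  } else lines <- c(lines, "Module stage: skipped", "")
  hubs <- grab("network_hubs.tsv")
  if (!is.null(hubs)) {
    lines <- c(lines, "Top network hubs by betweenness:",
               sprintf("  %2d. %-10s %-10s degree %3d  betweenness %.1f",
                       hubs$rank, hubs$id, hubs$type, hubs$degree, hubs$betweenness), "")
  } else lines <- c(lines, "Integration stage: skipped or empty network", "")
  ora <- grab("enrichment_ora.tsv")
  if (!is.null(ora)) {
    top <- ora[order(ora$p_value), ][seq_len(min(5, nrow(ora))), ]
    lines <- c(lines, "Top over-represented sets:",
               sprintf("  %-20s overlap %d/%d  p %.3g  q %.3g", top$set_id,
                       top$overlap, top$set_size, top$p_value, top$q_value), "")
  } else lines <- c(lines, "Enrichment stage: skipped", "")
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(file.path(run_dir, "report.txt"))
}
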