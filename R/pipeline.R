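#' Build and validate a pipeline configuration
#'
#' All analysis defaults live here: the TPM cutoff (2.0), the posterior
#' calling threshold (0.80), four MDS dimensions, K-means over K = 2..6,
#' Bonferroni adjustment for the cell-type test and FDR <= 0.10 for ORA.
#'
#' @param expr,samples,tree Paths to the TPM table, sample-to-taxon map
#'   and rooted Newick tree (required).
#' @param counts,labels Optional single-cell counts (`.mtx` or TSV) and
#'   cell-label TSV; enables the cell-type enrichment stage.
#' @param gmt Optional GMT collection path; enables the ORA stage.
#' @param branch Branch of interest as `"parent->child"`; defaults to the
#'   branch with the most events.
#' @param threshold TPM cutoff.
#' @param replicate_rule Replicate collapse rule (mean/any/all).
#' @param bpp_threshold Posterior calling threshold.
#' @param metric Binary distance metric.
#' @param mds_dims MDS dimensions.
#' @param k_min,k_max K-means range.
#' @param adjust Cell-type p adjustment (bonferroni/BH).
#' @param fdr_max ORA FDR cutoff.
#' @param sc_min_genes,sc_max_genes,sc_max_mito Single-cell QC bounds.
#' @param n_categories Rate categories.
#' @param seed Integer master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, samples = NULL, tree,
                            counts = NULL, labels = NULL, gmt = NULL,
                            branch = NULL,
                            threshold = 2.0, replicate_rule = "mean",
                            bpp_threshold = 0.80, metric = "hamming",
                            mds_dims = 4L, k_min = 2L, k_max = 6L,
                            adjust = "bonferroni", fdr_max = 0.10,
                            sc_min_genes = 1000L, sc_max_genes = 5000L,
                            sc_max_mito = 0.05,
                            n_categories = 4L, seed = 1L) {
  cfg <- list(expr = expr, samples = samples, tree = tree, counts = counts,
              labels = labels, gmt = gmt, branch = branch,
              threshold = as.numeric(threshold),
              replicate_rule = replicate_rule,
              bpp_threshold = as.numeric(bpp_threshold),
              metric = metric, mds_dims = as.integer(mds_dims),
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              adjust = adjust, fdr_max = as.numeric(fdr_max),
              sc_min_genes = as.integer(sc_min_genes),
              sc_max_genes = as.integer(sc_max_genes),
              sc_max_mito = as.numeric(sc_max_mito),
              n_categories = as.integer(n_categories),
              seed = as.integer(seed))
  .stop_if(cfg$threshold <= 0, "config: threshold must be > 0")
  .stop_if(cfg$bpp_threshold <= 0.5 || cfg$bpp_threshold > 1,
           "config: bpp_threshold must be in (0.5, 1]")
  .stop_if(!cfg$replicate_rule %in% c("mean", "any", "all"),
           "config: replicate_rule must be mean/any/all")
  .stop_if(!cfg$metric %in% c("hamming", "jaccard"),
           "config: metric must be hamming/jaccard")
  .stop_if(cfg$mds_dims < 1L, "config: mds_dims must be >= 1")
  .stop_if(cfg$k_min < 1L || cfg$k_max < cfg$k_min, "config: bad K range")
  .stop_if(!cfg$adjust %in% c("bonferroni", "BH"),
           "config: adjust must be bonferroni/BH")
  .stop_if(cfg$fdr_max <= 0 || cfg$fdr_max > 1, "config: fdr_max must be in (0, 1]")
  .stop_if(cfg$sc_min_genes < 0L || cfg$sc_max_genes < cfg$sc_min_genes,
           "config: bad single-cell detected-gene bounds")
  .stop_if(cfg$sc_max_mito < 0 || cfg$sc_max_mito > 1,
           "config: sc_max_mito must be in [0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as a flat key = value file
#'
#' One `key = value` pair per line; `#` starts a comment; unset optional
#' keys are simply omitted. Serialization is deterministic (keys in a
#' fixed order).
#'
#' @param path Config file path.
#' @param cfg A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  .stop_if(!file.exists(path), "config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    .stop_if(!grepl("=", ln, fixed = TRUE), "config line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  do.call(pipeline_config, kv)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  keys <- c("expr", "samples", "tree", "counts", "labels", "gmt", "branch",
            "threshold", "replicate_rule", "bpp_threshold", "metric",
            "mds_dims", "k_min", "k_max", "adjust", "fdr_max",
            "sc_min_genes", "sc_max_genes", "sc_max_mito",
            "n_categories", "seed")
  lines <- character(0L)
  for (k in keys) {
    if (!is.null(cfg[[k]])) lines <- c(lines, paste(k, "=", cfg[[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes binarize -> model fit -> ancestral reconstruction -> gain/loss
#' tracing -> ordination -> (optional) cell-type enrichment and ORA, and
#' writes every artifact into `out_dir` along with a provenance record
#' (config hash, package version) and a timestamped log. Outputs are pure
#' functions of (inputs, config, seed): a rerun with identical inputs
#' reproduces identical artifacts.
#'
#' @param config A `pipeline_config` or path to a config file.
#' @param out_dir Run directory (created if absent).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  .stop_if(!inherits(cfg, "pipeline_config"), "invalid config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), "  ", sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, fun) {
    logf("stage %s: start", name)
    res <- tryCatch(fun(), error = function(e) {
      cat(sprintf("FAILED at stage %s: %s\n", name, conditionMessage(e)),
          file = file.path(out_dir, "FAILED"))
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %s: done", name)
    res
  }
  seeds <- split_seed(cfg$seed, 4L)
  art <- list()

  cfg_path <- file.path(out_dir, "config.txt")
  write_pipeline_config(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logf("config hash %s, exprevo %s", cfg_hash,
       as.character(utils::packageVersion("exprevo")))

  states <- stage("binarize", function() {
    expr <- read_expression_table(cfg$expr, cfg$samples)
    s <- binarize(expr, threshold = cfg$threshold,
                  replicate_rule = cfg$replicate_rule)
    write_binary_states(s, file.path(out_dir, "states.tsv"))
    s
  })
  art$states <- file.path(out_dir, "states.tsv")

  fit <- stage("fit", function() {
    tree <- read_newick(cfg$tree)
    f <- optimize_parameters(tree, states, seed = seeds[1L],
                             n_categories = cfg$n_categories)
    write_model_json(f$params, file.path(out_dir, "model.json"), loglik = f$loglik)
    write_newick(f$tree, file.path(out_dir, "fitted.nwk"))
    f
  })
  art$model <- file.path(out_dir, "model.json")
  art$fitted_tree <- file.path(out_dir, "fitted.nwk")

  bpp <- stage("asr", function() {
    b <- marginal_posteriors(fit$tree, fit$params, states)
    write_bpp_table(b, file.path(out_dir, "bpp.tsv"))
    b
  })
  art$bpp <- file.path(out_dir, "bpp.tsv")

  events <- stage("trace", function() {
    ev <- trace_events(fit$tree, bpp, states, bpp_threshold = cfg$bpp_threshold)
    write_events(ev, file.path(out_dir, "events.tsv"))
    utils::write.table(branch_rates(ev), file.path(out_dir, "branch_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ev
  })
  art$events <- file.path(out_dir, "events.tsv")
  art$branch_rates <- file.path(out_dir, "branch_rates.tsv")

  gene_sets <- stage("gene_sets", function() {
    branch <- cfg$branch
    if (is.null(branch)) {
      key <- paste(events$branch_parent, events$branch_child, sep = "->")
      counts <- sort(table(key), decreasing = TRUE)
      .stop_if(length(counts) == 0L, "no events; specify `branch` explicitly")
      branch <- names(counts)[1L]
      logf("no branch configured; using busiest branch %s", branch)
    }
    gs <- lineage_gene_sets(events, branch)
    writeLines(gs$gained, file.path(out_dir, "gained.txt"))
    writeLines(gs$lost, file.path(out_dir, "lost.txt"))
    write_gmt(list(gained = gs$gained, lost = gs$lost),
              file.path(out_dir, "gene_sets.gmt"),
              descriptions = c(gained = branch, lost = branch))
    gs
  })
  art$gained <- file.path(out_dir, "gained.txt")
  art$lost <- file.path(out_dir, "lost.txt")

  stage("ordinate", function() {
    anc <- ancestral_map_states(bpp)
    all_states <- cbind(unclass(states), anc)
    d <- binary_distance(all_states, metric = cfg$metric)
    utils::write.table(data.frame(label = rownames(d), d, check.names = FALSE),
                       file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emb <- classical_mds(d, k = cfg$mds_dims)
    write_embedding(emb, file.path(out_dir, "mds.tsv"))
    ks <- cfg$k_min:min(cfg$k_max, nrow(d) - 1L)
    grp <- kmeans_cluster(emb, k_range = ks, seed = seeds[2L])
    for (K in names(grp$per_k)) {
      utils::write.table(
        data.frame(label = names(grp$per_k[[K]]$cluster),
                   cluster = unname(grp$per_k[[K]]$cluster)),
        file.path(out_dir, sprintf("kmeans_K%s.tsv", K)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(grp$summary, file.path(out_dir, "kmeans_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    NULL
  })
  art$mds <- file.path(out_dir, "mds.tsv")
  art$kmeans <- file.path(out_dir, "kmeans_summary.tsv")

  if (!is.null(cfg$counts)) {
    stage("enrich_celltypes", function() {
      cm <- read_cell_counts(cfg$counts, cfg$labels)
      cm <- filter_cells(cm, min_genes = cfg$sc_min_genes,
                         max_genes = cfg$sc_max_genes,
                         max_mito_frac = cfg$sc_max_mito)
      pb <- pseudobulk(normalize_cells(cm), cm$cell_labels)
      enr <- celltype_enrichment(pb, gene_sets$gained, adjust = cfg$adjust)
      utils::write.table(enr, file.path(out_dir, "celltype_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
    art$celltype_enrichment <- file.path(out_dir, "celltype_enrichment.tsv")
  }

  if (!is.null(cfg$gmt)) {
    stage("ora", function() {
      collections <- read_gmt(cfg$gmt)
      res <- ora(gene_sets$gained, collections,
                 universe = rownames(states), fdr_max = cfg$fdr_max)
      utils::write.table(res, file.path(out_dir, "ora.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      NULL
    })
    art$ora <- file.path(out_dir, "ora.tsv")
  }

  jsonlite::write_json(
    list(config_hash = cfg_hash,
         exprevo_version = as.character(utils::packageVersion("exprevo")),
         artifacts = names(art)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  logf("pipeline complete: %d artifacts", length(art))
  invisible(art)
}
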