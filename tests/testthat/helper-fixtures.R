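# Build a complete on-disk input fixture for the pipeline: a TPM table
# whose binarization reproduces states simulated under the model, the
# generating tree, a single-cell dataset and a GMT collection. Returns the
# file paths plus the simulation truth.
make_pipeline_fixture <- function(dir, n_taxa = 12L, n_genes = 400L, seed = 100L,
                                  missing_rate = 0.05, with_cells = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(seed, 6L)
  old <- exprevo:::.save_rng(); on.exit(exprevo:::.restore_rng(old))
  set.seed(seeds[1L])
  tree <- random_tree(n_taxa, min_len = 0.05, max_len = 0.9)
  params <- model_params(0.35, weights = c(.4, .3, .2, .1),
                         rates = c(.25, .7, 1.4, 2.8))
  sim <- simulate_binary_evolution(tree, params, n_genes, seed = seeds[2L])
  masked <- inject_missingness(sim$states, missing_rate, seed = seeds[3L])

  # expression values consistent with the binary truth: expressed genes get
  # high TPM, silent genes low TPM, masked entries become NA
  set.seed(seeds[4L])
  tpm <- matrix(0, n_genes, n_taxa, dimnames = dimnames(sim$states))
  on_idx <- which(masked$states == 1L)
  off_idx <- which(masked$states == 0L)
  tpm[on_idx] <- pmax(2^rnorm(length(on_idx), log2(19), 1), 2.0)
  tpm[off_idx] <- pmin(2^rnorm(length(off_idx), log2(0.11), 1), 1.9)
  tpm[is.na(masked$states)] <- NA

  expr_path <- file.path(dir, "expr.tsv")
  utils::write.table(data.frame(gene = rownames(tpm), tpm, check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tree_path <- file.path(dir, "tree.nwk")
  write_newick(tree, tree_path)

  out <- list(expr = expr_path, tree = tree_path, truth = sim$truth,
              masked = masked, params = params)

  if (with_cells) {
    sc <- simulate_single_cell(
      cell_types = c(planted = 40L, other1 = 40L, other2 = 40L),
      n_genes = min(n_genes, 600L),
      recruited = rownames(sim$states)[seq_len(min(50L, n_genes))],
      planted_types = "planted", effect = c(0.85, 0.3), seed = seeds[5L])
    mtx <- file.path(dir, "cells.mtx")
    lab <- file.path(dir, "labels.tsv")
    write_cell_counts(sc$cells, mtx, lab)
    out$counts <- mtx; out$labels <- lab; out$sc_truth <- sc$truth

    set.seed(seeds[6L])
    sets <- lapply(1:5, function(i)
      sample(rownames(sim$states), min(40L, n_genes)))
    names(sets) <- sprintf("set%02d", 1:5)
    gmt <- file.path(dir, "sets.gmt")
    write_gmt(sets, gmt)
    out$gmt <- gmt
  }
  out
}

# small fixed scenario used by several blocks: 4-tip ladder tree with
# hand-written BPP and tip tables so the expected event list can be
# enumerated by applying the calling rule directly
gl_fixture <- function() {
  tree <- read_newick("(((A:1,B:1)N3:1,C:1)N2:1,D:1)N1;")
  tips <- matrix(c(1L, 1L, 0L, 0L,   # gW
                   1L, 0L, 0L, 0L,   # gX
                   0L, 0L, 1L, NA,   # gY
                   1L, 1L, 1L, 1L),  # gZ
                 nrow = 4L, byrow = TRUE,
                 dimnames = list(c("gW", "gX", "gY", "gZ"), c("A", "B", "C", "D")))
  bpp <- matrix(c(
    # N1    N2    N3
    0.10, 0.15, 0.95,   # gW: gain on N2->N3
    0.05, 0.10, 0.70,   # gX: N3 ambiguous; tip A=1 but no parent call
    0.90, 0.85, 0.25,   # gY: N3 ambiguous (BPP0 = 0.75), no events
    0.95, 0.92, 0.99),  # gZ: all expressed, no change
    nrow = 4L, byrow = TRUE,
    dimnames = list(c("gW", "gX", "gY", "gZ"), c("N1", "N2", "N3")))
  class(bpp) <- c("bpp_table", class(bpp))
  list(tree = tree, tips = tips, bpp = bpp)
}

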