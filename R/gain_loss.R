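#' Trace expression gains and losses along branches
#'
#' For every branch and gene, the states at both endpoints are called:
#' internal nodes via [map_states()] at `bpp_threshold`, tips from the
#' observed character (support 1.0; unknown tips are not callable). An
#' event is emitted only when both endpoint calls are unambiguous and
#' differ: a gain when the parent is 0 and the child 1, a loss when the
#' parent is 1 and the child 0. Requiring both endpoints prevents phantom
#' events passing through ambiguous nodes.
#'
#' @param tree Rooted [ape::phylo] with node labels.
#' @param bpp A `bpp_table` from [marginal_posteriors()] covering all
#'   internal nodes.
#' @param tips Integer gene-by-taxon matrix (0/1/`NA`) covering all tips.
#' @param bpp_threshold Calling threshold in (0.5, 1\].
#' @return A data.frame of class `gain_loss_events` with columns
#'   `branch_parent`, `branch_child`, `gene`, `direction` (gain/loss),
#'   `parent_support`, `child_support`.
#' @export
trace_events <- function(tree, bpp, tips, bpp_threshold = 0.80) {
  ts <- .tree_struct(tree)
  internal_labels <- ts$labels[(ts$ntip + 1L):ts$nnode]
  missing_nodes <- setdiff(internal_labels, colnames(bpp))
  .stop_if(length(missing_nodes) > 0L,
           "BPP table lacks internal nodes: ", paste(missing_nodes, collapse = ", "))
  X <- .align_states(ts, tips)
  genes <- rownames(bpp)
  .stop_if(is.null(genes) || !setequal(genes, rownames(X)),
           "gene sets of `bpp` and `tips` must match")
  X <- X[genes, , drop = FALSE]

  # per-node call and support matrices over all nodes (genes x nnode)
  calls <- matrix(NA_integer_, length(genes), ts$nnode)
  support <- matrix(NA_real_, length(genes), ts$nnode)
  calls[, seq_len(ts$ntip)] <- X
  support[, seq_len(ts$ntip)] <- ifelse(is.na(X), NA_real_, 1.0)
  bppm <- unclass(bpp)[, internal_labels, drop = FALSE]
  ic <- map_states(bppm, bpp_threshold)
  calls[, (ts$ntip + 1L):ts$nnode] <- ic
  support[, (ts$ntip + 1L):ts$nnode] <- ifelse(ic == 1L, bppm, 1 - bppm)

  res <- vector("list", nrow(ts$edge))
  for (e in seq_len(nrow(ts$edge))) {
    p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    pc <- calls[, p]; cc <- calls[, ch]
    hit <- which(!is.na(pc) & !is.na(cc) & pc != cc)
    if (length(hit) == 0L) next
    res[[e]] <- data.frame(
      branch_parent = ts$labels[p],
      branch_child = ts$labels[ch],
      gene = genes[hit],
      direction = ifelse(pc[hit] == 0L, "gain", "loss"),
      parent_support = support[hit, p],
      child_support = support[hit, ch],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(branch_parent = character(), branch_child = character(),
                      gene = character(), direction = character(),
                      parent_support = numeric(), child_support = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$branch_parent, out$branch_child, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scored") <- .branch_scored_counts(ts, calls)
  class(out) <- c("gain_loss_events", class(out))
  out
}

# genes with unambiguous calls at both endpoints, per branch
.branch_scored_counts <- function(ts, calls) {
  n <- integer(nrow(ts$edge))
  names(n) <- paste(ts$labels[ts$edge[, 1L]], ts$labels[ts$edge[, 2L]], sep = "->")
  for (e in seq_len(nrow(ts$edge))) {
    n[e] <- sum(!is.na(calls[, ts$edge[e, 1L]]) & !is.na(calls[, ts$edge[e, 2L]]))
  }
  n
}

#' Per-branch event rates
#'
#' The combined gain + loss count on each branch divided by the number of
#' genes scoreable on that branch (unambiguous calls at both endpoints).
#' This is the quantity branch lengths are proportional to when a
#' phylogeny is drawn in units of expression changes per gene.
#'
#' @param events A `gain_loss_events` data.frame from [trace_events()].
#' @param n_scored_genes Named integer vector of scoreable-gene counts per
#'   branch (`"parent->child"` names); defaults to the counts recorded by
#'   [trace_events()].
#' @return A data.frame with `branch`, `gains`, `losses`, `n_scored`,
#'   `rate` (`NA` where no gene is scoreable).
#' @export
branch_rates <- function(events, n_scored_genes = attr(events, "n_scored")) {
  .stop_if(is.null(n_scored_genes), "per-branch scored-gene counts are required")
  key <- paste(events$branch_parent, events$branch_child, sep = "->")
  gains <- table(factor(key[events$direction == "gain"], levels = names(n_scored_genes)))
  losses <- table(factor(key[events$direction == "loss"], levels = names(n_scored_genes)))
  data.frame(
    branch = names(n_scored_genes),
    gains = as.integer(gains),
    losses = as.integer(losses),
    n_scored = as.integer(n_scored_genes),
    rate = ifelse(n_scored_genes > 0,
                  (as.integer(gains) + as.integer(losses)) / as.integer(n_scored_genes),
                  NA_real_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gained and lost gene sets on one branch
#'
#' @param events A `gain_loss_events` data.frame.
#' @param branch_of_interest Branch as `"parent->child"` (or
#'   `"parent:child"`).
#' @return A list with sorted character vectors `gained` and `lost`.
#' @export
lineage_gene_sets <- function(events, branch_of_interest) {
  b <- sub(":", "->", branch_of_interest, fixed = TRUE)
  key <- paste(events$branch_parent, events$branch_child, sep = "->")
  known <- attr(events, "n_scored")
  if (!is.null(known)) {
    .stop_if(!(b %in% names(known)), "unknown branch: ", branch_of_interest)
  } else {
    .stop_if(!(b %in% key) && nrow(events) > 0L && !(b %in% key),
             "unknown branch: ", branch_of_interest)
  }
  sel <- events[key == b, , drop = FALSE]
  list(gained = sort(sel$gene[sel$direction == "gain"]),
       lost = sort(sel$gene[sel$direction == "loss"]))
}

#' Write gain/loss events to TSV
#'
#' @param events A `gain_loss_events` data.frame.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
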