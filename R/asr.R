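#' Marginal ancestral state posteriors (empirical Bayes)
#'
#' For every internal node and gene, the posterior probability that the
#' node was in the expressed state (BPP1), computed under the plug-in
#' maximum-likelihood model (no integration over parameter uncertainty).
#' Posteriors marginalize over the free-rate categories with per-gene
#' empirical category weights `w_k L_k`, and are computed for all nodes in
#' one inside-outside pass per gene rather than by repeatedly clamping
#' each node.
#'
#' @param tree Rooted [ape::phylo] with fitted branch lengths.
#' @param params A fitted [model_params()] object.
#' @param matrix Integer gene-by-taxon matrix (0/1/`NA`).
#' @return A numeric gene-by-node matrix of BPP1 values (columns are the
#'   internal node labels, root first), of class `bpp_table`.
#'   `BPP0 = 1 - BPP1`.
#' @export
marginal_posteriors <- function(tree, params, matrix) {
  .stop_if(!inherits(params, "gtr2_model"), "`params` must be a fitted gtr2_model")
  ts <- .tree_struct(tree)
  X_full <- .align_states(ts, matrix)
  pat <- .compress_patterns(X_full)
  X <- pat$X
  G <- nrow(X)
  K <- length(params$rates)
  internal <- (ts$ntip + 1L):ts$nnode
  logw <- log(params$weights)

  # log joint at (gene, node, state, category); accumulate the two states'
  # marginals with a running log-sum-exp over categories
  l1 <- matrix(-Inf, G, length(internal))
  l0 <- matrix(-Inf, G, length(internal))
  for (k in seq_len(K)) {
    d <- .down_pass(ts, params, X, params$rates[k])
    u <- .up_pass(ts, params, d, params$rates[k])
    sc <- d$lsc[, internal, drop = FALSE] + u$usc[, internal, drop = FALSE]
    j0 <- log(d$L0[, internal, drop = FALSE] * u$U0[, internal, drop = FALSE]) + sc + logw[k]
    j1 <- log(d$L1[, internal, drop = FALSE] * u$U1[, internal, drop = FALSE]) + sc + logw[k]
    l0 <- .pmax_logadd(l0, j0)
    l1 <- .pmax_logadd(l1, j1)
  }
  bpp <- 1 / (1 + exp(l0 - l1))
  bpp[l0 == -Inf & l1 == -Inf] <- NA_real_  # cannot occur for valid input
  dimnames(bpp) <- list(rownames(X), ts$labels[internal])
  idx <- match(pat$key, pat$key[pat$first])  # expand patterns back to genes
  out <- bpp[idx, , drop = FALSE]
  rownames(out) <- rownames(X_full)
  class(out) <- c("bpp_table", class(out))
  out
}

# elementwise log(exp(a) + exp(b)) with -Inf handling
.pmax_logadd <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

#' Threshold posterior probabilities into state calls
#'
#' A node-gene pair is called 1 when `BPP1 >= bpp_threshold`, 0 when
#' `BPP0 >= bpp_threshold`, and ambiguous otherwise. Comparisons are
#' inclusive. Thresholds at or below 0.5 would allow both states to pass
#' and are rejected.
#'
#' @param table A `bpp_table` from [marginal_posteriors()] (or any numeric
#'   matrix/vector of BPP1 values).
#' @param bpp_threshold Calling threshold in (0.5, 1\].
#' @return Integer structure matching `table`: 1, 0 or `NA` (ambiguous).
#' @export
map_states <- function(table, bpp_threshold = 0.80) {
  .stop_if(bpp_threshold <= 0.5 || bpp_threshold > 1,
           "bpp_threshold must be in (0.5, 1]")
  bpp1 <- unclass(table)
  out <- ifelse(bpp1 >= bpp_threshold, 1L,
                ifelse(1 - bpp1 >= bpp_threshold, 0L, NA_integer_))
  storage.mode(out) <- "integer"
  out
}

#' Write / read a BPP table as TSV
#'
#' Rows are genes, columns internal node labels, cells BPP1 to 6 decimals.
#'
#' @param bpp A `bpp_table`.
#' @param path File path.
#' @export
write_bpp_table <- function(bpp, path) {
  df <- data.frame(gene = rownames(bpp),
                   format(round(unclass(bpp), 6L), trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bpp_table
#' @export
read_bpp_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  .stop_if(any(m < 0 | m > 1, na.rm = TRUE), "BPP values must lie in [0, 1]")
  class(m) <- c("bpp_table", class(m))
  m
}
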