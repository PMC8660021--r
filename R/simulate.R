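#' Simulate binary expression characters along a phylogeny
#'
#' Forward simulation of the inference model: per gene a rate category is
#' drawn from the category weights, the root state from the stationary
#' frequencies, and states propagate down every branch with the
#' closed-form transition probabilities. All node states and every
#' endpoint-difference event are recorded as ground truth.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param params A [model_params()] object.
#' @param n_genes Number of characters.
#' @param seed Integer seed.
#' @return A list with `states` (gene-by-taxon 0/1 matrix for the tips)
#'   and `truth`: `node_states` (gene-by-node matrix over ALL nodes,
#'   labels as column names), `events` (branch/gene/direction data.frame),
#'   `categories` (per-gene category index), `params`, `tree`, `seed`.
#' @export
simulate_binary_evolution <- function(tree, params, n_genes, seed = 1L) {
  .stop_if(n_genes < 1L, "n_genes must be >= 1")
  ts <- .tree_struct(tree)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  K <- length(params$rates)
  cat_idx <- sample.int(K, n_genes, replace = TRUE, prob = params$weights)
  node_states <- matrix(NA_integer_, n_genes, ts$nnode)
  node_states[, ts$root] <- stats::rbinom(n_genes, 1L, params$pi[2L])
  pi0 <- params$pi[1L]; pi1 <- params$pi[2L]
  mu <- 1 / (2 * pi0 * pi1)
  # preorder: reverse postorder guarantees parents are assigned first
  for (e in rev(seq_len(nrow(ts$edge)))) {
    p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    decay <- exp(-mu * ts$edge_length[e] * params$rates[cat_idx])
    ps <- node_states[, p]
    # closed-form P(child = 1 | parent), per gene at its own rate category
    p1 <- ifelse(ps == 1L, pi1 + pi0 * decay, pi1 * (1 - decay))
    node_states[, ch] <- stats::rbinom(n_genes, 1L, p1)
  }
  colnames(node_states) <- ts$labels
  rownames(node_states) <- sprintf("g%05d", seq_len(n_genes))
  events <- .true_events(ts, node_states)
  tips <- node_states[, seq_len(ts$ntip), drop = FALSE]
  class(tips) <- c("binary_states", class(tips))
  list(states = tips,
       truth = list(node_states = node_states, events = events,
                    categories = cat_idx, params = params,
                    tree = ts$tree, seed = as.integer(seed)))
}

.true_events <- function(ts, node_states) {
  res <- list()
  for (e in seq_len(nrow(ts$edge))) {
    p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
    diff <- which(node_states[, p] != node_states[, ch])
    if (length(diff) == 0L) next
    res[[length(res) + 1L]] <- data.frame(
      branch_parent = ts$labels[p], branch_child = ts$labels[ch],
      gene = rownames(node_states)[diff],
      direction = ifelse(node_states[diff, p] == 0L, "gain", "loss"),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) {
    return(data.frame(branch_parent = character(), branch_child = character(),
                      gene = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Simulate a TPM expression matrix from a two-component mixture
#'
#' Emulates the bimodal log-scale distribution of transcript abundances:
#' with probability `zero_fraction` a cell is an exact zero (undetected
#' transcript), otherwise log2 TPM is drawn from a two-component Gaussian
#' mixture and exponentiated. The default components straddle the TPM = 2
#' cutoff the binarization uses: means of about 0.11 and 19 TPM on the
#' natural scale.
#'
#' @param n_genes Number of genes.
#' @param samples_per_taxon Named integer vector: samples per taxon.
#' @param mixture List with `means` (log2 scale, length 2), `sds`
#'   (length 2), `weight_low` (mixture weight of the low component).
#' @param zero_fraction Probability of an exact zero (default 0.1).
#' @param seed Integer seed.
#' @return An [expression_matrix()].
#' @export
simulate_tpm_matrix <- function(n_genes,
                                samples_per_taxon = c(speciesA = 1L, speciesB = 1L),
                                mixture = list(means = log2(c(0.11, 19)),
                                               sds = c(1.2, 1.5),
                                               weight_low = 0.35),
                                zero_fraction = 0.1, seed = 1L) {
  .stop_if(zero_fraction < 0 || zero_fraction >= 1, "zero_fraction must be in [0, 1)")
  .stop_if(length(mixture$means) != 2L || length(mixture$sds) != 2L,
           "mixture must have 2 means and 2 sds")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  samples <- unlist(lapply(names(samples_per_taxon), function(tx)
    paste0(tx, "_s", seq_len(samples_per_taxon[[tx]]))))
  species <- rep(names(samples_per_taxon), times = samples_per_taxon)
  names(species) <- samples
  n <- n_genes * length(samples)
  comp <- stats::rbinom(n, 1L, 1 - mixture$weight_low) + 1L  # 1 = low, 2 = high
  logv <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
  vals <- 2^logv
  vals[stats::runif(n) < zero_fraction] <- 0
  m <- matrix(vals, nrow = n_genes, ncol = length(samples),
              dimnames = list(sprintf("g%05d", seq_len(n_genes)), samples))
  expression_matrix(m, species)
}

#' Expected expressed fraction of the simulated TPM mixture
#'
#' Closed-form probability that a simulated TPM value is at or above
#' `threshold`: the mixture mass above `log2(threshold)` scaled by the
#' nonzero fraction.
#'
#' @inheritParams simulate_tpm_matrix
#' @param threshold TPM cutoff.
#' @return A single probability.
#' @export
expected_expressed_fraction <- function(mixture = list(means = log2(c(0.11, 19)),
                                                       sds = c(1.2, 1.5),
                                                       weight_low = 0.35),
                                        zero_fraction = 0.1, threshold = 2.0) {
  lt <- log2(threshold)
  mass <- mixture$weight_low * stats::pnorm(lt, mixture$means[1L], mixture$sds[1L],
                                            lower.tail = FALSE) +
    (1 - mixture$weight_low) * stats::pnorm(lt, mixture$means[2L], mixture$sds[2L],
                                            lower.tail = FALSE)
  (1 - zero_fraction) * mass
}

#' Simulate a labeled single-cell count matrix with planted enrichment
#'
#' Per (gene, cell type) an on/off state is drawn once with a Bernoulli
#' probability — recruited genes use `effect[1]` in the planted cell
#' types and `effect[2]` elsewhere; background genes use `effect[2]`
#' everywhere — so the fraction of genes expressed in a type matches the
#' planted probability. Counts of switched-on genes are Poisson with mean
#' `depth` in every cell of the type; switched-off genes are exact zeros.
#' A small fixed block of mitochondrial genes (`MT-` prefix) is always on
#' at a low rate so the quality filters are exercised.
#'
#' @param cell_types Named integer vector: cells per cell type.
#' @param n_genes Number of (non-mitochondrial) genes.
#' @param recruited Character vector of recruited gene IDs (subset of the
#'   generated `g…` IDs) or an integer count to pick the first genes.
#' @param planted_types Character vector of cell types carrying the
#'   planted recruitment signal.
#' @param effect Numeric length-2: `(p_expr_recruited, p_expr_background)`.
#' @param depth Poisson mean count for an expressed gene (default 5).
#' @param n_mito Number of mitochondrial genes (default 5).
#' @param seed Integer seed.
#' @return A list with `cells` (a [cell_matrix()]) and `truth`
#'   (`recruited`, `planted_types`, `effect`, and the drawn `on_state`
#'   gene-by-type matrix).
#' @export
simulate_single_cell <- function(cell_types = c(typeA = 60L, typeB = 60L, typeC = 60L),
                                 n_genes = 800L, recruited = 100L,
                                 planted_types = "typeA",
                                 effect = c(0.9, 0.3), depth = 5,
                                 n_mito = 5L, seed = 1L) {
  .stop_if(!all(planted_types %in% names(cell_types)),
           "planted_types must be a subset of cell_types")
  .stop_if(any(effect <= 0) || any(effect >= 1), "effect probabilities must be in (0, 1)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (is.numeric(recruited) && length(recruited) == 1L) {
    recruited <- genes[seq_len(recruited)]
  }
  .stop_if(!all(recruited %in% genes), "recruited genes must be among the generated genes")
  mito <- if (n_mito > 0L) sprintf("MT-g%03d", seq_len(n_mito)) else character(0L)
  all_genes <- c(genes, mito)
  cells <- unlist(lapply(names(cell_types), function(ty)
    paste0(ty, "_c", seq_len(cell_types[[ty]]))))
  labels <- stats::setNames(rep(names(cell_types), times = cell_types), cells)

  on_prob <- matrix(effect[2L], length(all_genes), length(cell_types),
                    dimnames = list(all_genes, names(cell_types)))
  on_prob[recruited, planted_types] <- effect[1L]
  on_prob[mito, ] <- 1  # mito genes always on (at low depth)

  on <- matrix(stats::runif(length(on_prob)) < on_prob, nrow(on_prob),
               dimnames = dimnames(on_prob))
  lam <- ifelse(startsWith(all_genes, "MT-"), depth * 0.2, depth)
  counts <- matrix(0L, length(all_genes), length(cells),
                   dimnames = list(all_genes, cells))
  for (ci in seq_along(cells)) {
    ty <- labels[ci]
    g_on <- on[, ty]
    counts[g_on, ci] <- stats::rpois(sum(g_on), lam[g_on])
  }
  # guarantee positive totals: give empty cells one count of the first gene
  empty <- colSums(counts) == 0L
  counts[1L, empty] <- 1L
  list(cells = cell_matrix(counts, labels),
       truth = list(recruited = recruited, planted_types = planted_types,
                    effect = effect, on_state = on, seed = as.integer(seed)))
}

#' Mask entries of a character matrix as unknown
#'
#' Independently replaces entries with `NA` (`?`) at a per-taxon rate,
#' emulating genes without data in some species. The pre-masking values
#' are returned as ground truth.
#'
#' @param matrix Integer gene-by-taxon matrix (0/1/`NA`).
#' @param rate Single rate or named per-taxon vector in \[0, 1).
#' @param seed Integer seed.
#' @return A list with `states` (masked matrix) and `truth` (the original
#'   matrix plus the logical `masked` positions).
#' @export
inject_missingness <- function(matrix, rate = 0.1, seed = 1L) {
  .stop_if(any(rate < 0) || any(rate >= 1), "rates must be in [0, 1)")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rates <- if (length(rate) == 1L) {
    stats::setNames(rep(rate, ncol(matrix)), colnames(matrix))
  } else rate
  .stop_if(!all(colnames(matrix) %in% names(rates)), "rate missing for some taxa")
  masked <- matrix(FALSE, nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  out <- matrix
  for (tx in colnames(matrix)) {
    hit <- stats::runif(nrow(matrix)) < rates[tx]
    masked[hit, tx] <- TRUE
    out[hit, tx] <- NA_integer_
  }
  list(states = out, truth = list(original = matrix, masked = masked,
                                  seed = as.integer(seed)))
}
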