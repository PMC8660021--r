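# Independent brute-force oracles used across the suite. These enumerate
# states directly and never touch the pruning machinery they check.

# random rooted tree with node labels and positive branch lengths
random_tree <- function(ntip, min_len = 0.05, max_len = 1) {
  tree <- ape::rtree(ntip)
  tree$edge.length <- stats::runif(nrow(tree$edge), min_len, max_len)
  prepare_tree(tree)
}

random_params <- function(K = 4L) {
  model_params(stats::runif(1, 0.15, 0.85),
               weights = stats::runif(K, 0.2, 1),
               rates = stats::runif(K, 0.1, 3))
}

# likelihood by exhaustive enumeration over internal-state assignments and
# rate categories
brute_loglik <- function(tree, params, column) {
  ts <- exprevo:::.tree_struct(tree)
  internal <- (ts$ntip + 1L):ts$nnode
  x <- column[ts$labels[seq_len(ts$ntip)]]
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  for (k in seq_along(params$rates)) {
    P_by_edge <- lapply(seq_len(nrow(ts$edge)), function(e)
      transition_matrix(params, ts$edge_length[e], params$rates[k]))
    lik_k <- 0
    for (gi in seq_len(nrow(grid))) {
      s <- integer(ts$nnode)
      s[internal] <- grid[gi, ]
      pr <- params$pi[s[ts$root] + 1L]
      for (e in seq_len(nrow(ts$edge))) {
        p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
        child_state <- if (ch <= ts$ntip) x[ch] else s[ch]
        if (is.na(child_state)) next  # unknown tip marginalizes to 1
        pr <- pr * P_by_edge[[e]][s[p] + 1L, child_state + 1L]
      }
      lik_k <- lik_k + pr
    }
    total <- total + params$weights[k] * lik_k
  }
  log(unname(total))
}

# marginal posterior of state 1 at one internal node, by clamping within
# the same exhaustive enumeration
brute_clamped_bpp <- function(tree, params, column, node_label) {
  ts <- exprevo:::.tree_struct(tree)
  internal <- (ts$ntip + 1L):ts$nnode
  node_pos <- which(ts$labels[internal] == node_label)
  x <- column[ts$labels[seq_len(ts$ntip)]]
  num <- c(0, 0)
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  for (k in seq_along(params$rates)) {
    P_by_edge <- lapply(seq_len(nrow(ts$edge)), function(e)
      transition_matrix(params, ts$edge_length[e], params$rates[k]))
    for (gi in seq_len(nrow(grid))) {
      s <- integer(ts$nnode)
      s[internal] <- grid[gi, ]
      pr <- params$pi[s[ts$root] + 1L]
      for (e in seq_len(nrow(ts$edge))) {
        p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
        child_state <- if (ch <= ts$ntip) x[ch] else s[ch]
        if (is.na(child_state)) next
        pr <- pr * P_by_edge[[e]][s[p] + 1L, child_state + 1L]
      }
      st <- grid[gi, node_pos]
      num[st + 1L] <- num[st + 1L] + params$weights[k] * pr
    }
  }
  num[2L] / sum(num)
}

# two-sided Fisher exact p by enumerating the hypergeometric support:
# sum of probabilities of tables as or less probable than the observed one
fisher_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by summing the pmf
hyper_upper_oracle <- function(overlap, term_size, universe_size, query_size) {
  xs <- overlap:min(term_size, query_size)
  sum(stats::dhyper(xs, term_size, universe_size - term_size, query_size))
}

# shared medium simulation for gain/loss style checks (built once per run)
toy_binary_matrix <- function() {
  m <- matrix(c(1L, 1L, 0L, NA,
                1L, 0L, 0L, 1L,
                0L, 0L, 1L, 1L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("t1", "t2", "t3", "t4")))
  m
}
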