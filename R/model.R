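#' Construct a two-state GTR substitution model with free-rate heterogeneity
#'
#' The model is the general time-reversible Markov process on states
#' \{0 = not expressed, 1 = expressed\} with stationary frequencies
#' `(pi0, pi1)` estimated by maximum likelihood, combined with a free-rate
#' mixture over `K` rate categories: category `k` has weight `w_k` and rate
#' multiplier `r_k`, constrained so the mean rate `sum(w * r) = 1`. Branch
#' lengths are therefore in expected state changes per character at the
#' mean rate.
#'
#' Categories are canonicalized to ascending rate order; rates are
#' renormalized to satisfy the mean-rate constraint exactly.
#'
#' @param pi1 Stationary frequency of the expressed state, in (0, 1).
#' @param weights Nonnegative category weights, summing to 1.
#' @param rates Positive rate multipliers, one per category.
#' @return An object of class `gtr2_model` with elements `pi`, `weights`,
#'   `rates`.
#' @export
model_params <- function(pi1 = 0.5, weights = rep(0.25, 4), rates = c(0.2, 0.6, 1.2, 2.4)) {
  .stop_if(length(pi1) != 1L || pi1 <= 0 || pi1 >= 1, "pi1 must be in (0, 1)")
  .stop_if(length(weights) != length(rates), "weights and rates must have equal length")
  .stop_if(any(weights < 0), "weights must be nonnegative")
  .stop_if(any(rates <= 0), "rates must be positive")
  weights <- weights / sum(weights)
  rates <- rates / sum(weights * rates)  # mean rate 1
  ord <- order(rates)
  structure(list(pi = c(`0` = 1 - pi1, `1` = pi1),
                 weights = weights[ord], rates = rates[ord]),
            class = "gtr2_model")
}

#' @export
print.gtr2_model <- function(x, ...) {
  cat(sprintf("GTR2 model: pi = (%.4f, %.4f)\n", x$pi[1L], x$pi[2L]))
  cat(sprintf("  %d rate categories (mean rate 1):\n", length(x$weights)))
  for (k in seq_along(x$weights)) {
    cat(sprintf("    w = %.4f  r = %.4f\n", x$weights[k], x$rates[k]))
  }
  invisible(x)
}

#' Transition probability matrix of the two-state GTR process
#'
#' Closed form for the 2x2 transition matrix over a branch of length `t` at
#' rate multiplier `r`. The generator is normalized to one expected change
#' per unit branch length at rate multiplier 1, i.e. `mu = 1 / (2 pi0 pi1)` and
#' `P(t) = exp(Q t r)` with `Q = mu * [[-pi1, pi1], [pi0, -pi0]]`.
#'
#' @param params A [model_params()] object.
#' @param t Branch length, `>= 0`.
#' @param r Rate multiplier, `> 0`.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @export
transition_matrix <- function(params, t, r = 1) {
  .stop_if(t < 0, "branch length must be >= 0")
  .stop_if(r <= 0, "rate multiplier must be > 0")
  pi0 <- params$pi[1L]; pi1 <- params$pi[2L]
  .stop_if(pi0 <= 0 || pi1 <= 0, "stationary frequencies must be positive")
  mu <- 1 / (2 * pi0 * pi1)
  e <- exp(-mu * t * r)
  matrix(c(pi0 + pi1 * e, pi1 * (1 - e),
           pi0 * (1 - e), pi1 + pi0 * e),
         nrow = 2L, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
}

# ---- internal likelihood machinery ------------------------------------------
# States enter as an integer matrix genes x taxa (NA = unknown). The
# pruning passes run in C++ (src/pruning.cpp) over genes-by-node
# conditional likelihood matrices for the two states, rescaled per node
# with accumulated log scalers so products never underflow.

# Align a character matrix with the tree's tips: returns G x ntip integer.
.align_states <- function(ts, matrix) {
  .stop_if(is.null(colnames(matrix)), "character matrix must have taxon colnames")
  tips <- ts$labels[seq_len(ts$ntip)]
  missing <- setdiff(tips, colnames(matrix))
  .stop_if(length(missing) > 0L, "taxa missing from character matrix: ",
           paste(missing, collapse = ", "))
  extra <- setdiff(colnames(matrix), tips)
  .stop_if(length(extra) > 0L, "taxa absent from tree: ",
           paste(extra, collapse = ", "))
  m <- matrix[, tips, drop = FALSE]
  storage.mode(m) <- "integer"
  .stop_if(any(!(m %in% c(0L, 1L, NA_integer_))), "states must be 0, 1 or NA")
  m
}

# Per-edge transition entries for one rate multiplier (vectorized scalars).
.edge_P <- function(params, lens, r) {
  pi0 <- params$pi[1L]; pi1 <- params$pi[2L]
  mu <- 1 / (2 * pi0 * pi1)
  e <- exp(-mu * lens * r)
  list(P00 = pi0 + pi1 * e, P01 = pi1 * (1 - e),
       P10 = pi0 * (1 - e), P11 = pi1 + pi0 * e)
}

# Tip partial-likelihood indicators from a G x ntip state matrix:
# observed 0 -> (1,0), observed 1 -> (0,1), unknown -> (1,1).
.tip_partials <- function(X) {
  list(tip0 = (is.na(X) | X == 0L) * 1,
       tip1 = (is.na(X) | X == 1L) * 1)
}

# Felsenstein down (inside) pass for one rate category.
# Returns conditional likelihoods L0/L1 and log scalers lsc (G x nnode),
# plus per-edge messages E0/E1 (G x nedge).
.down_pass <- function(ts, params, X, r, lens = ts$edge_length) {
  tp <- .tip_partials(X)
  .cpp_down_pass(ts$edge, lens, ts$ntip, ts$nnode, tp$tip0, tp$tip1,
                 params$pi[1L], params$pi[2L], r)
}

# Outside (up) pass for one rate category, given the matching down pass.
.up_pass <- function(ts, params, down, r, lens = ts$edge_length) {
  .cpp_up_pass(ts$edge, lens, ts$ntip, ts$nnode,
               params$pi[1L], params$pi[2L], r,
               down$lsc, down$E0, down$E1)
}

# Per-gene log-likelihood matrix (G x K): category-conditional values.
.category_logliks <- function(ts, params, X, lens = ts$edge_length) {
  tp <- .tip_partials(X)
  .cpp_category_logliks(ts$edge, lens, ts$ntip, ts$nnode, tp$tip0, tp$tip1,
                        params$pi[1L], params$pi[2L], params$rates)
}

# Total log-likelihood given per-pattern weights.
.total_loglik <- function(ts, params, X, wts = rep(1, nrow(X)), lens = ts$edge_length) {
  cl <- .category_logliks(ts, params, X, lens)
  per_gene <- .logsumexp_rows(sweep(cl, 2L, log(params$weights), `+`))
  sum(per_gene * wts)
}

#' Log-likelihood of one gene's states under the fitted model
#'
#' Felsenstein pruning over the rooted tree, mixed over the free-rate
#' categories: `log( sum_k w_k L_k )`, with the root weighted by the
#' stationary frequencies and unknown tips (`NA`/`?`) contributing the
#' uninformative partial vector (1, 1).
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param params A [model_params()] object.
#' @param column Named integer vector (0/1/`NA`) over the tree's tips.
#' @return The log-likelihood (a single numeric).
#' @export
pruning_loglik <- function(tree, params, column) {
  ts <- .tree_struct(tree)
  X <- .align_states(ts, matrix(column, nrow = 1L,
                                dimnames = list("g", names(column))))
  .total_loglik(ts, params, X)
}

#' Log-likelihood of a whole character matrix
#'
#' Sum of [pruning_loglik()] over genes (characters are independent);
#' all-unknown genes contribute exactly 0. Identical columns are collapsed
#' to patterns internally.
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param params A [model_params()] object.
#' @param matrix Integer gene-by-taxon matrix (0/1/`NA`).
#' @return The total log-likelihood.
#' @export
matrix_loglik <- function(tree, params, matrix) {
  ts <- .tree_struct(tree)
  X <- .align_states(ts, matrix)
  pat <- .compress_patterns(X)
  .total_loglik(ts, params, pat$X, pat$weights)
}

.compress_patterns <- function(X) {
  key <- apply(X, 1L, function(z) paste(ifelse(is.na(z), "?", z), collapse = ""))
  idx <- which(!duplicated(key))
  wts <- as.numeric(table(factor(key, levels = key[idx])))
  list(X = X[idx, , drop = FALSE], weights = wts, key = key, first = idx)
}

# ---- parameter optimization -------------------------------------------------

.pack_theta <- function(params) {
  K <- length(params$weights)
  th <- stats::qlogis(params$pi[2L])
  if (K > 1L) th <- c(th, log(params$rates[-1L] / params$rates[1L]))
  th
}

# category weights are held fixed during the quasi-Newton step (they have
# their own closed-form EM update, .update_weights)
.unpack_theta <- function(theta, K, weights) {
  pi1 <- stats::plogis(theta[1L])
  if (K == 1L) return(model_params(pi1, weights = 1, rates = 1))
  r <- c(1, exp(theta[2:K]))
  model_params(pi1, weights = weights, rates = r)  # renormalizes sum(w r) = 1
}

# Exact coordinate maximization over the category weights: the
# category-conditional likelihoods L_gk do not involve w, so iterating the
# mixture EM weight update at fixed L converges to the optimal simplex
# point without further likelihood evaluations. The mean-rate-1 constraint
# is restored by rescaling rates and branch lengths jointly, which leaves
# every product (branch length x rate) — hence the likelihood — unchanged.
.update_weights <- function(ts, params, X, wts, lens, rescale_lens = TRUE) {
  cl <- .category_logliks(ts, params, X, lens)
  cl <- cl - do.call(pmax, as.data.frame(cl))  # row max, K columns
  el <- exp(cl)  # category likelihood ratios; zero-safe after shift
  w <- params$weights
  for (it in seq_len(500L)) {
    num <- sweep(el, 2L, w, `*`)
    resp <- num / rowSums(num)
    w_new <- colSums(resp * wts) / sum(wts)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < 1e-12) break
  }
  w <- pmax(w, 1e-12); w <- w / sum(w)
  s <- sum(w * params$rates)
  new_params <- model_params(params$pi[2L], weights = w,
                             rates = params$rates / s)
  if (!rescale_lens) return(list(params = new_params, lens = lens))
  list(params = new_params, lens = pmin(pmax(lens * s, 1e-8), 10))
}

# Brent profile over a single branch length using cached outside/inside
# partials; exact for the current values of all other branches.
.edge_profile <- function(ts, params, X, wts, e, passes) {
  pi0 <- params$pi[1L]; pi1 <- params$pi[2L]
  mu <- 1 / (2 * pi0 * pi1)
  K <- length(params$rates)
  p <- ts$edge[e, 1L]; ch <- ts$edge[e, 2L]
  pre <- vector("list", K)
  for (k in seq_len(K)) {
    d <- passes[[k]]$down; u <- passes[[k]]$up
    A0 <- u$U0[, p]; A1 <- u$U1[, p]
    asc <- u$usc[, p]
    for (e2 in ts$children[[as.character(p)]]) {
      if (e2 == e) next
      A0 <- A0 * d$E0[, e2]
      A1 <- A1 * d$E1[, e2]
      asc <- asc + d$lsc[, ts$edge[e2, 2L]]
    }
    pre[[k]] <- list(A0 = A0, A1 = A1,
                     D0 = d$L0[, ch], D1 = d$L1[, ch],
                     sc = asc + d$lsc[, ch])
  }
  logw <- log(params$weights)
  function(t) {
    cl <- matrix(0, length(wts), K)
    for (k in seq_len(K)) {
      ee <- exp(-mu * t * params$rates[k])
      P00 <- pi0 + pi1 * ee; P01 <- pi1 * (1 - ee)
      P10 <- pi0 * (1 - ee); P11 <- pi1 + pi0 * ee
      z <- pre[[k]]
      lik <- z$A0 * (P00 * z$D0 + P01 * z$D1) +
             z$A1 * (P10 * z$D0 + P11 * z$D1)
      cl[, k] <- ifelse(lik > 0, log(lik), -Inf) + z$sc + logw[k]
    }
    sum(.logsumexp_rows(cl) * wts)
  }
}

.all_passes <- function(ts, params, X) {
  lapply(seq_along(params$rates), function(k) {
    d <- .down_pass(ts, params, X, params$rates[k])
    list(down = d, up = .up_pass(ts, params, d, params$rates[k]))
  })
}

#' Fit model parameters (and branch lengths) on a fixed topology
#'
#' Maximum-likelihood coordinate ascent: bounded quasi-Newton (L-BFGS-B)
#' over the stationary frequency, category weights and rate multipliers,
#' alternated with Brent line searches on each branch length (bounds
#' `[1e-8, 10]`), iterated until the total log-likelihood improves by less
#' than `tol`. The tree topology is never changed.
#'
#' @param tree Rooted [ape::phylo]; its branch lengths are the starting
#'   point when `optimize_branch_lengths = TRUE` (missing lengths start at
#'   0.1).
#' @param matrix Integer gene-by-taxon matrix (0/1/`NA`).
#' @param optimize_branch_lengths Optimize branch lengths as well as model
#'   parameters.
#' @param seed Integer seed (initialization jitter).
#' @param n_categories Number of free-rate categories (4 matches the
#'   fitted model; 1 gives the homogeneous-rate special case).
#' @param init Optional [model_params()] starting values.
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_rounds Cap on coordinate-ascent rounds. Parameter estimates
#'   stabilize within the first few rounds; later rounds refine branch
#'   lengths in ever smaller steps, so the cap bounds runtime on large
#'   matrices without affecting the estimates at reporting precision.
#' @return A list with `params` (canonicalized [model_params()]), `tree`
#'   (fitted branch lengths), `loglik`, and `trace` (per-round log-likelihoods).
#' @export
optimize_parameters <- function(tree, matrix, optimize_branch_lengths = TRUE,
                                seed = 1L, n_categories = 4L, init = NULL,
                                tol = 1e-6, max_rounds = 15L) {
  ts <- .tree_struct(tree)
  X_full <- .align_states(ts, matrix)
  pat <- .compress_patterns(X_full)
  X <- pat$X; wts <- pat$weights
  K <- as.integer(n_categories)

  informative <- apply(X, 1L, function(z) !all(is.na(z)))
  n_patterns <- length(unique(apply(X[informative, , drop = FALSE], 1L,
                                    paste, collapse = "/")))
  if (n_patterns < 2L) {
    warning("fewer than 2 distinct observed character patterns; ",
            "branch lengths are set to the lower bound")
    # no-change data: branch lengths are unidentifiable along a likelihood
    # ridge, so they are pinned at the lower bound and only the stationary
    # frequency is informative
    ts$edge_length <- rep(1e-8, nrow(ts$edge))
    optimize_branch_lengths <- FALSE
  }

  if (is.null(init)) {
    p1 <- mean(X == 1L, na.rm = TRUE)
    p1 <- min(max(p1, 0.02), 0.98)
    init <- if (K == 1L) model_params(p1, weights = 1, rates = 1)
            else model_params(p1, weights = rep(1 / K, K),
                              rates = seq(0.25, 2, length.out = K))
  }
  params <- init
  lens <- ts$edge_length

  # two free branch-length scales (internal and terminal edges) are
  # optimized jointly with the model parameters; they absorb the strongly
  # correlated rate-versus-tree-scale directions so the alternation with
  # the per-branch line searches converges quickly
  terminal <- ts$edge[, 2L] <= ts$ntip
  scale_lens <- function(lens, s_int, s_term) {
    out <- lens
    out[!terminal] <- out[!terminal] * exp(s_int)
    out[terminal] <- out[terminal] * exp(s_term)
    pmin(pmax(out, 1e-8), 10)
  }
  n_scales <- if (optimize_branch_lengths) 2L else 0L
  obj <- function(theta) {
    np <- length(theta) - n_scales
    pr <- try(.unpack_theta(theta[seq_len(np)], K, params$weights),
              silent = TRUE)
    if (inherits(pr, "try-error")) return(-1e10)
    cur_lens <- if (n_scales > 0L) {
      scale_lens(lens, theta[np + 1L], theta[np + 2L])
    } else lens
    ll <- .total_loglik(ts, pr, X, wts, cur_lens)
    if (!is.finite(ll)) -1e10 else ll
  }

  tp <- .tip_partials(X)
  ll <- .total_loglik(ts, params, X, wts, lens)
  trace <- ll
  for (round in seq_len(max_rounds)) {
    # closed-form EM step for the category weights
    if (K > 1L) {
      upd <- .update_weights(ts, params, X, wts, lens,
                             rescale_lens = optimize_branch_lengths)
      upd_ll <- .total_loglik(ts, upd$params, X, wts, upd$lens)
      if (upd_ll > ll) {
        params <- upd$params
        lens <- upd$lens
        ts$edge_length <- lens
        ll <- upd_ll
      }
    }
    # stationary frequency, rates and the two tree scales by quasi-Newton
    # at fixed weights; a long first step, short refinements afterwards
    theta <- c(.pack_theta(params), rep(0, n_scales))
    np <- length(theta) - n_scales
    opt <- stats::optim(theta, obj, method = "L-BFGS-B",
                        lower = c(rep(-12, np), rep(-3, n_scales)),
                        upper = c(rep(12, np), rep(3, n_scales)),
                        control = list(fnscale = -1,
                                       maxit = if (round == 1L) 50L
                                               else if (round <= 3L) 10L else 5L))
    if (opt$value > ll) {
      cand_params <- .unpack_theta(opt$par[seq_len(np)], K, params$weights)
      cand_lens <- if (n_scales > 0L) {
        scale_lens(lens, opt$par[np + 1L], opt$par[np + 2L])
      } else lens
      cand_ll <- .total_loglik(ts, cand_params, X, wts, cand_lens)
      if (cand_ll > ll) {  # exact value at the folded (bounded) lengths
        params <- cand_params
        lens <- cand_lens
        ts$edge_length <- lens
        ll <- cand_ll
      }
    }
    # branch lengths: Brent coordinate ascent with lazily refreshed
    # partials; the resulting lengths are re-scored exactly before use
    if (optimize_branch_lengths) {
      sw <- .cpp_branch_sweep(ts$edge, lens, ts$ntip, ts$nnode,
                              tp$tip0, tp$tip1,
                              params$pi[1L], params$pi[2L],
                              params$weights, params$rates, wts,
                              1e-8, 10, if (round <= 2L) 1L else 3L, tol,
                              1e-4)
      sw_ll <- .total_loglik(ts, params, X, wts, sw$lens)
      if (sw_ll > ll) {
        lens <- sw$lens
        ll <- sw_ll
        ts$edge_length <- lens
      }
    }
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol) break
  }

  fitted <- ts$tree
  # map postorder edge lengths back onto the tree's own edge order
  po <- ape::reorder.phylo(fitted, "postorder")
  key_po <- paste(ts$edge[, 1L], ts$edge[, 2L])
  key_orig <- paste(fitted$edge[, 1L], fitted$edge[, 2L])
  fitted$edge.length <- lens[match(key_orig, key_po)]
  list(params = params, tree = fitted, loglik = ll, trace = trace)
}

#' Serialize / deserialize a fitted model as JSON
#'
#' @param params A [model_params()] object.
#' @param path Output (input) path.
#' @param loglik Optional log-likelihood to store alongside.
#' @return `read_model_json` returns a [model_params()] (with a `loglik`
#'   attribute when present).
#' @export
write_model_json <- function(params, path, loglik = NULL) {
  obj <- list(pi = unname(params$pi), weights = unname(params$weights),
              rates = unname(params$rates))
  if (!is.null(loglik)) obj$loglik <- loglik
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- model_params(pi1 = obj$pi[2L], weights = obj$weights, rates = obj$rates)
  if (!is.null(obj$loglik)) attr(p, "loglik") <- obj$loglik
  p
}
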