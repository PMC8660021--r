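#' Pairwise distances between binary transcriptomes
#'
#' Distances are computed over pairwise-complete genes (scored in both
#' labels). `"hamming"` is the proportion of disagreeing genes;
#' `"jaccard"` is `1 - |both expressed| / |either expressed|`.
#'
#' @param states Integer gene-by-label matrix (0/1/`NA`), e.g. extant taxa
#'   columns from [binarize()] bound with ancestral columns from
#'   [ancestral_map_states()].
#' @param metric `"hamming"` or `"jaccard"`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
binary_distance <- function(states, metric = c("hamming", "jaccard")) {
  metric <- match.arg(metric)
  .stop_if(ncol(states) < 2L, "need at least 2 labels")
  labs <- colnames(states)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- states[, i]; b <- states[, j]
      ok <- !is.na(a) & !is.na(b)
      .stop_if(!any(ok), "no shared scored genes between ", labs[i], " and ", labs[j])
      if (metric == "hamming") {
        d[i, j] <- mean(a[ok] != b[ok])
      } else {
        either <- sum(a[ok] == 1L | b[ok] == 1L)
        both <- sum(a[ok] == 1L & b[ok] == 1L)
        d[i, j] <- if (either == 0L) 0 else 1 - both / either
      }
      d[j, i] <- d[i, j]
    }
  }
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Principal coordinates analysis: eigendecomposition of the
#' double-centered squared-distance matrix, coordinates scaled by the
#' square roots of the eigenvalues (via [stats::cmdscale()]).
#' Negative-eigenvalue axes are dropped; if fewer than `k` positive axes
#' exist, fewer dimensions are returned with a warning.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of retained dimensions (default 4).
#' @return A list of class `mds_embedding` with `coordinates`
#'   (label-by-dimension), `eigenvalues` (all, descending), `labels`.
#' @export
classical_mds <- function(d, k = 4L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  .stop_if(k >= nrow(d), "k must be smaller than the number of labels")
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (n_pos < k) {
    warning(sprintf("only %d positive eigenvalue axes available (requested %d)",
                    n_pos, k))
  }
  coords <- fit$points
  if (is.null(coords)) coords <- matrix(0, nrow(d), 0L)
  keep <- seq_len(min(k, max(n_pos, 0L), ncol(coords)))
  coords <- coords[, keep, drop = FALSE]
  dimnames(coords) <- list(rownames(d), if (ncol(coords) > 0L)
    paste0("dim", seq_len(ncol(coords))))
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 labels = rownames(d)),
            class = "mds_embedding")
}

#' K-means grouping of an embedding over a range of K
#'
#' Runs [stats::kmeans()] with `n_init` restarts for each K, keeping the
#' best (lowest within-cluster sum of squares) solution, and reports the
#' mean silhouette width alongside so the number of clusters can be
#' chosen by inspection. Deterministic given `seed`.
#'
#' @param emb An `mds_embedding` (or a numeric coordinate matrix).
#' @param k_range Integer vector of K values (default 2:6).
#' @param seed Integer seed.
#' @param n_init Restarts per K.
#' @return A list of class `kmeans_grouping`: per-K list with `cluster`
#'   (named memberships), `wss` (total within-cluster SS), `silhouette`;
#'   plus a `summary` data.frame.
#' @export
kmeans_cluster <- function(emb, k_range = 2:6, seed = 1L, n_init = 50L) {
  coords <- if (inherits(emb, "mds_embedding")) emb$coordinates else as.matrix(emb)
  n <- nrow(coords)
  .stop_if(any(k_range > n), "every K must be at most the number of labels")
  .stop_if(any(k_range < 1L), "K must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  d_full <- as.matrix(stats::dist(coords))
  per_k <- list()
  for (K in k_range) {
    if (K == n) {  # trivial partition: every point its own cluster
      cl <- stats::setNames(seq_len(n), rownames(coords))
      per_k[[as.character(K)]] <- list(cluster = cl, wss = 0,
                                       silhouette = .mean_silhouette(cl, d_full))
      next
    }
    km <- stats::kmeans(coords, centers = K, nstart = n_init, iter.max = 100L)
    sil <- .mean_silhouette(km$cluster, d_full)
    per_k[[as.character(K)]] <- list(
      cluster = stats::setNames(km$cluster, rownames(coords)),
      wss = km$tot.withinss,
      silhouette = sil)
  }
  summary <- data.frame(
    K = as.integer(names(per_k)),
    wss = vapply(per_k, `[[`, numeric(1L), "wss"),
    silhouette = vapply(per_k, `[[`, numeric(1L), "silhouette"),
    row.names = NULL)
  structure(list(per_k = per_k, summary = summary), class = "kmeans_grouping")
}

.mean_silhouette <- function(cluster, d) {
  ks <- sort(unique(cluster))
  if (length(ks) < 2L) return(NA_real_)
  s <- numeric(length(cluster))
  for (i in seq_along(cluster)) {
    own <- cluster == cluster[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(ks[ks != cluster[i]],
                    function(k2) mean(d[i, cluster == k2]), numeric(1L)))
    s[i] <- if (sum(own) == 0L) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Maximum a posteriori ancestral states for ordination
#'
#' Collapses a BPP table to hard states for distance computation:
#' `BPP1 >= 0.5` maps to 1 (ties break to 1), otherwise 0. This
#' intentionally ignores the stricter event-calling threshold so that
#' ancestral transcriptomes enter the ordination without unknowns.
#'
#' @param bpp A `bpp_table` from [marginal_posteriors()].
#' @return Integer gene-by-node matrix of 0/1 states.
#' @export
ancestral_map_states <- function(bpp) {
  out <- ifelse(unclass(bpp) >= 0.5, 1L, 0L)
  storage.mode(out) <- "integer"
  out
}

#' Write an embedding (and optional groupings) to TSV
#'
#' @param emb An `mds_embedding`.
#' @param path Output path.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(label = emb$labels, emb$coordinates, check.names = FALSE)
  attr_line <- paste0("# eigenvalues: ",
                      paste(signif(emb$eigenvalues, 8L), collapse = ", "))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
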