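#' Construct an expression matrix object
#'
#' A light container for a gene-by-sample TPM table with an explicit
#' missing-data mask and a sample-to-species (taxon) map. Missing cells
#' (genes without data in a species, e.g. unannotated orthologs) are kept
#' distinct from zeros: a zero is an observed absence of transcripts, a
#' missing cell is no information at all.
#'
#' @param values Numeric gene-by-sample matrix of TPM values, with row and
#'   column names. `NA` entries are treated as missing.
#' @param species_of_sample Named character vector mapping every sample
#'   (column) to a taxon name. If `NULL`, each sample is its own taxon.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `missing_mask`, `gene_ids`, `sample_ids`, `species_of_sample`.
#' @export
expression_matrix <- function(values, species_of_sample = NULL) {
  .stop_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix")
  .stop_if(is.null(rownames(values)) || is.null(colnames(values)),
           "`values` must have gene rownames and sample colnames")
  .stop_if(anyDuplicated(rownames(values)) > 0L, "duplicate gene IDs")
  .stop_if(anyDuplicated(colnames(values)) > 0L, "duplicate sample IDs")
  if (is.null(species_of_sample)) {
    species_of_sample <- stats::setNames(colnames(values), colnames(values))
  }
  .stop_if(!all(colnames(values) %in% names(species_of_sample)),
           "every sample must map to exactly one taxon")
  species_of_sample <- species_of_sample[colnames(values)]
  mask <- is.na(values)
  .stop_if(any(values[!mask] < 0), "negative TPM values are not allowed")
  structure(list(
    values = values,
    missing_mask = mask,
    gene_ids = rownames(values),
    sample_ids = colnames(values),
    species_of_sample = species_of_sample
  ), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d taxa), %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$species_of_sample)),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' Read a TPM table from TSV
#'
#' Expects a header row; first column gene IDs, remaining columns samples.
#' Empty cells and `NA` become missing entries.
#'
#' @param path Path to a tab-separated file.
#' @param species_map Optional path to a two-column TSV (sample, taxon) or a
#'   named character vector.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, species_map = NULL) {
  .stop_if(!file.exists(path), "file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  .stop_if(ncol(tab) < 2L, "expected a gene-ID column plus >= 1 sample column")
  genes <- tab[[1L]]
  .stop_if(anyDuplicated(genes) > 0L,
           "duplicate gene ID: ", genes[duplicated(genes)][1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.na(vals) & is.na(num), arr.ind = TRUE)
  .stop_if(nrow(bad) > 0L,
           sprintf("non-numeric value at line %d, sample '%s'",
                   bad[1L, 1L] + 1L, colnames(vals)[bad[1L, 2L]]))
  dimnames(num) <- list(genes, colnames(vals))
  .stop_if(any(num < 0, na.rm = TRUE), "negative TPM value in ", path)
  if (is.character(species_map) && length(species_map) == 1L && file.exists(species_map)) {
    sm <- utils::read.delim(species_map, header = TRUE, sep = "\t",
                            colClasses = "character")
    species_map <- stats::setNames(sm[[2L]], sm[[1L]])
  }
  expression_matrix(num, species_map)
}

#' Write a TPM table to TSV
#'
#' Inverse of [read_expression_table()]; missing entries are written as `NA`.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  vals <- expr$values
  vals[expr$missing_mask] <- NA
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a two-component Gaussian mixture to log2 TPM values
#'
#' Models the bimodal distribution of log-scale transcript abundances as a
#' mixture of an unexpressed (low-mean) and an expressed (high-mean)
#' component, the classical justification for a TPM cutoff separating
#' active from inactive genes. Zeros must be excluded by the caller (they
#' form a point mass that the log-scale mixture does not describe).
#'
#' @param log2_tpm_values Numeric vector of log2 TPM values (finite).
#' @param n_components Number of components; only 2 is supported.
#' @param seed Integer seed for the restarts.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   log-likelihood change.
#' @return An object of class `mixture_fit` with `component_means`,
#'   `component_sds`, `component_weights` (ordered by ascending mean),
#'   `loglik_trace` and `n_points`.
#' @export
fit_expression_mixture <- function(log2_tpm_values, n_components = 2L,
                                   seed = 1L, max_iter = 500L, tol = 1e-8) {
  .stop_if(n_components != 2L, "only 2-component mixtures are supported")
  x <- log2_tpm_values[is.finite(log2_tpm_values)]
  .stop_if(length(x) < 50L, "need >= 50 finite values to fit the mixture")
  .stop_if(stats::sd(x) == 0, "degenerate fit: all values identical")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  best <- NULL
  for (restart in seq_len(5L)) {
    init <- .mixture_init(x, restart)
    fit <- .em_two_gaussian(x, init, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  structure(list(
    component_means = best$mu[ord],
    component_sds = best$sigma[ord],
    component_weights = best$w[ord],
    loglik_trace = best$trace,
    n_points = length(x)
  ), class = "mixture_fit")
}

# One initialization per restart: k-means on the 1-D values for the first
# restarts, spread quantile pairs afterwards.
.mixture_init <- function(x, restart) {
  if (restart <= 3L) {
    km <- stats::kmeans(x, centers = 2L, nstart = 5L)
    mu <- as.numeric(km$centers)
    w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
    s <- rep(max(stats::sd(x) / 2, 1e-3), 2L)
  } else {
    qs <- if (restart == 4L) c(0.25, 0.75) else c(0.1, 0.9)
    mu <- as.numeric(stats::quantile(x, qs))
    w <- c(0.5, 0.5)
    s <- rep(max(stats::sd(x) / 2, 1e-3), 2L)
  }
  list(mu = mu, sigma = s, w = pmax(w, 0.05) / sum(pmax(w, 0.05)))
}

.em_two_gaussian <- function(x, init, max_iter, tol) {
  mu <- init$mu; sigma <- init$sigma; w <- init$w
  n <- length(x)
  trace <- numeric(0L)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sigma[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sigma[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(c(sum(r1 * (x - mu[1L])^2) / n1,
                    sum(r2 * (x - mu[2L])^2) / n2))
    sigma <- pmax(sigma, 1e-6)  # guard collapse onto a single point
  }
  list(mu = mu, sigma = sigma, w = w, loglik = trace[length(trace)],
       trace = trace)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "two-component Gaussian mixture on log2 TPM (n = %d)\n",
    "  low : mean %.3f (TPM %.3g), sd %.3f, weight %.3f\n",
    "  high: mean %.3f (TPM %.3g), sd %.3f, weight %.3f\n"),
    x$n_points,
    x$component_means[1L], 2^x$component_means[1L],
    x$component_sds[1L], x$component_weights[1L],
    x$component_means[2L], 2^x$component_means[2L],
    x$component_sds[2L], x$component_weights[2L]))
  invisible(x)
}

#' Posterior probability that a TPM value comes from the expressed component
#'
#' The responsibility of the higher-mean mixture component at `log2(tpm)` —
#' an explicit probability-of-active-expression curve. With equal component
#' standard deviations it is monotone nondecreasing in TPM.
#'
#' @param fit A [fit_expression_mixture()] result.
#' @param tpm Positive TPM value(s).
#' @return Probability in \[0, 1\], vectorized over `tpm`.
#' @export
expression_probability <- function(fit, tpm) {
  .stop_if(!inherits(fit, "mixture_fit"), "`fit` must be a mixture_fit")
  .stop_if(any(tpm <= 0), "tpm must be > 0 (zeros are a separate point mass)")
  x <- log2(tpm)
  d_lo <- fit$component_weights[1L] *
    stats::dnorm(x, fit$component_means[1L], fit$component_sds[1L])
  d_hi <- fit$component_weights[2L] *
    stats::dnorm(x, fit$component_means[2L], fit$component_sds[2L])
  tot <- d_lo + d_hi
  out <- d_hi / tot
  # far outside both components the densities underflow; decide by distance
  deg <- tot == 0
  if (any(deg)) {
    z_lo <- abs(x[deg] - fit$component_means[1L]) / fit$component_sds[1L]
    z_hi <- abs(x[deg] - fit$component_means[2L]) / fit$component_sds[2L]
    out[deg] <- as.numeric(z_hi < z_lo)
  }
  out
}

#' Binarize a TPM expression matrix into presence/absence characters
#'
#' Genes with (collapsed) TPM at or above `threshold` are coded expressed
#' (1), below it not expressed (0), and genes missing in all of a taxon's
#' samples are coded unknown (`NA`, written as `?`). Replicate samples of a
#' taxon are collapsed by `replicate_rule` before thresholding:
#' `"mean"` thresholds the mean TPM over non-missing replicates, `"any"`
#' codes 1 if any replicate passes, `"all"` only if all do.
#'
#' @param expr An [expression_matrix()].
#' @param threshold Positive TPM cutoff (default 2.0).
#' @param replicate_rule One of `"mean"`, `"any"`, `"all"`.
#' @return Integer gene-by-taxon matrix with values 0, 1 or `NA`, of class
#'   `binary_states`.
#' @export
binarize <- function(expr, threshold = 2.0, replicate_rule = c("mean", "any", "all")) {
  .stop_if(!inherits(expr, "expression_matrix"), "`expr` must be an expression_matrix")
  .stop_if(threshold <= 0, "threshold must be > 0")
  replicate_rule <- match.arg(replicate_rule)
  taxa <- unique(unname(expr$species_of_sample))
  out <- matrix(NA_integer_, nrow = nrow(expr$values), ncol = length(taxa),
                dimnames = list(expr$gene_ids, taxa))
  for (tx in taxa) {
    cols <- which(unname(expr$species_of_sample) == tx)
    .stop_if(length(cols) == 0L, "taxon with zero samples: ", tx)
    v <- expr$values[, cols, drop = FALSE]
    v[expr$missing_mask[, cols, drop = FALSE]] <- NA
    n_obs <- rowSums(!is.na(v))
    state <- switch(replicate_rule,
      mean = as.integer(rowMeans(v, na.rm = TRUE) >= threshold),
      any  = as.integer(apply(v >= threshold, 1L, any, na.rm = TRUE)),
      all  = as.integer(apply(v >= threshold, 1L, all, na.rm = TRUE)))
    state[n_obs == 0L] <- NA_integer_
    out[, tx] <- state
  }
  class(out) <- c("binary_states", class(out))
  out
}

#' Read/write a binary character matrix as TSV
#'
#' Cells are `0`, `1` or `?`; rows are genes, columns taxa.
#'
#' @param x Integer matrix (0/1/`NA`) with gene rownames and taxon colnames.
#' @param path File path.
#' @return `read_binary_states` returns the integer matrix; the writer
#'   returns `path` invisibly.
#' @export
write_binary_states <- function(x, path) {
  chr <- matrix(as.character(x), nrow = nrow(x), dimnames = dimnames(x))
  chr[is.na(x)] <- "?"
  df <- data.frame(gene = rownames(x), chr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binary_states
#' @export
read_binary_states <- function(path) {
  .stop_if(!file.exists(path), "file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  genes <- tab[[1L]]
  .stop_if(anyDuplicated(genes) > 0L, "duplicate gene IDs in ", path)
  chr <- as.matrix(tab[, -1L, drop = FALSE])
  .stop_if(!all(chr %in% c("0", "1", "?")),
           "states must be 0, 1 or ? in ", path)
  out <- matrix(NA_integer_, nrow = nrow(chr), ncol = ncol(chr),
                dimnames = list(genes, colnames(chr)))
  out[chr == "0"] <- 0L
  out[chr == "1"] <- 1L
  class(out) <- c("binary_states", class(out))
  out
}

#' Write a binary matrix as a relaxed-PHYLIP binary alignment
#'
#' One sequence per taxon over the symbols `0`, `1`, `-` (unknown), for
#' interoperability with phylogenetic tools.
#'
#' @param x Integer gene-by-taxon matrix (0/1/`NA`).
#' @param path Output path.
#' @export
write_phylip_binary <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", ncol(x), nrow(x)), con)
  for (tx in colnames(x)) {
    s <- as.character(x[, tx])
    s[is.na(x[, tx])] <- "-"
    writeLines(paste0(tx, "  ", paste(s, collapse = "")), con)
  }
  invisible(path)
}
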