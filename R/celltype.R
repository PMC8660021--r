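#' Construct a single-cell count matrix object
#'
#' Genes are rows, cells columns (sparse or dense). Every cell carries a
#' cell-type label; mitochondrial genes are flagged by name prefix so
#' that per-cell mitochondrial count fractions can be computed.
#'
#' @param counts Nonnegative integer gene-by-cell matrix (base matrix or
#'   [Matrix::Matrix()]), with dimnames.
#' @param cell_labels Named character vector mapping every cell to a
#'   cell-type name.
#' @param mito_prefixes Gene-name prefixes marking mitochondrial genes.
#' @return An object of class `cell_matrix` with `counts`, `cell_labels`,
#'   `mito_genes`, `total_counts`.
#' @export
cell_matrix <- function(counts, cell_labels, mito_prefixes = "MT-") {
  .stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "`counts` needs gene rownames and cell colnames")
  .stop_if(any(counts < 0), "counts must be nonnegative")
  .stop_if(any(counts != round(counts)), "counts must be integers")
  .stop_if(!all(colnames(counts) %in% names(cell_labels)),
           "every cell must be labeled")
  cell_labels <- cell_labels[colnames(counts)]
  mito <- rep(FALSE, nrow(counts))
  for (pre in mito_prefixes) {
    mito <- mito | startsWith(rownames(counts), pre)
  }
  structure(list(counts = counts,
                 cell_labels = cell_labels,
                 mito_genes = rownames(counts)[mito],
                 total_counts = Matrix::colSums(counts)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells, %d cell types, %d mito genes\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_labels)), length(x$mito_genes)))
  invisible(x)
}

#' Quality-filter cells
#'
#' Keeps cells whose number of detected genes (count >= 1) lies in
#' `[min_genes, max_genes]` inclusive and whose mitochondrial count
#' fraction is at most `max_mito_frac`.
#'
#' @param m A [cell_matrix()].
#' @param min_genes,max_genes Detected-gene bounds (defaults 1000 / 5000).
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.05).
#' @return A filtered [cell_matrix()].
#' @export
filter_cells <- function(m, min_genes = 1000L, max_genes = 5000L,
                         max_mito_frac = 0.05) {
  detected <- Matrix::colSums(m$counts >= 1L)
  mito_frac <- if (length(m$mito_genes) > 0L) {
    Matrix::colSums(m$counts[m$mito_genes, , drop = FALSE]) /
      pmax(m$total_counts, 1)
  } else rep(0, ncol(m$counts))
  keep <- detected >= min_genes & detected <= max_genes & mito_frac <= max_mito_frac
  .stop_if(!any(keep), "no cells pass the quality filters")
  out <- cell_matrix(m$counts[, keep, drop = FALSE], m$cell_labels[keep],
                     mito_prefixes = character(0L))
  out$mito_genes <- m$mito_genes  # filtering cells does not change gene flags
  out
}

#' Library-size normalize and log-transform counts
#'
#' Each count is divided by the cell's total, multiplied by 10,000, and
#' natural-log transformed as `ln(1 + x)`.
#'
#' @param m A [cell_matrix()].
#' @return A numeric gene-by-cell matrix of normalized values.
#' @export
normalize_cells <- function(m) {
  totals <- m$total_counts
  .stop_if(any(totals == 0), "cell with zero total counts; filter first")
  sf <- 1e4 / totals
  norm <- sweep(as.matrix(m$counts), 2L, sf, `*`)
  log1p(norm)
}

#' Pseudobulk expression by cell type
#'
#' Arithmetic mean of normalized values per (cell type, gene).
#'
#' @param norm Normalized gene-by-cell matrix from [normalize_cells()].
#' @param labels Named character vector mapping cells to cell types.
#' @return A cell-type-by-gene matrix of means.
#' @export
pseudobulk <- function(norm, labels) {
  .stop_if(!all(colnames(norm) %in% names(labels)), "every cell must be labeled")
  labels <- labels[colnames(norm)]
  types <- sort(unique(unname(labels)))
  out <- matrix(0, length(types), nrow(norm),
                dimnames = list(types, rownames(norm)))
  for (ty in types) {
    cols <- which(unname(labels) == ty)
    .stop_if(length(cols) == 0L, "cell type with no cells: ", ty)
    out[ty, ] <- rowMeans(norm[, cols, drop = FALSE])
  }
  out
}

#' Cell-type enrichment of a recruited gene set
#'
#' Per cell type, a gene counts as expressed when its pseudobulk mean
#' exceeds `expressed_min`. Observed is the expressed fraction among
#' recruited genes, Expected the expressed fraction among all other
#' genes; the enrichment ratio is Observed / Expected. Significance is a
#' two-sided Fisher exact test on the 2x2 table (recruited vs other)
#' x (expressed vs not), adjusted across cell types.
#'
#' @param pb Cell-type-by-gene pseudobulk matrix from [pseudobulk()].
#' @param recruited Character vector of recruited gene IDs; members absent
#'   from the pseudobulk are dropped with a warning.
#' @param expressed_min Pseudobulk expression floor (default 0: any
#'   nonzero mean counts as expressed).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return A data.frame with one row per cell type: `cell_type`,
#'   `observed`, `expected`, `ratio`, `a`, `b`, `c`, `d` (contingency:
#'   recruited-expressed, recruited-not, other-expressed, other-not),
#'   `p_raw`, `p_adj`.
#' @export
celltype_enrichment <- function(pb, recruited, expressed_min = 0,
                                adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  genes <- colnames(pb)
  dropped <- setdiff(recruited, genes)
  if (length(dropped) > 0L) {
    warning(sprintf("%d recruited genes absent from the pseudobulk were dropped",
                    length(dropped)))
  }
  recruited <- intersect(recruited, genes)
  .stop_if(length(recruited) == 0L, "no recruited genes present in the pseudobulk")
  is_rec <- genes %in% recruited
  rows <- lapply(rownames(pb), function(ty) {
    expressed <- pb[ty, ] > expressed_min
    a <- sum(is_rec & expressed); b <- sum(is_rec & !expressed)
    cc <- sum(!is_rec & expressed); d <- sum(!is_rec & !expressed)
    obs <- a / (a + b)
    exp_ <- cc / (cc + d)
    ratio <- if (exp_ > 0) obs / exp_ else if (obs > 0) Inf else NA_real_
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE))$p.value
    data.frame(cell_type = ty, observed = obs, expected = exp_, ratio = ratio,
               a = a, b = b, c = cc, d = d, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = if (adjust == "BH") "BH" else "bonferroni")
  out
}

#' Over-representation analysis of a gene set against GMT collections
#'
#' Hypergeometric upper-tail test of the overlap between the query set
#' and each term, restricted to the stated universe, with
#' Benjamini-Hochberg adjustment across terms within the collection.
#'
#' @param query Character vector of query genes (intersected with
#'   `universe`).
#' @param collections Named list of gene sets (as from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param fdr_max Adjusted-p cutoff used for the `significant` flag
#'   (default 0.10).
#' @return A data.frame per term: `term`, `term_size` (in-universe),
#'   `overlap`, `p_raw`, `p_adj`, `significant`. Terms with empty
#'   in-universe membership are skipped with a message.
#' @export
ora <- function(query, collections, universe, fdr_max = 0.10) {
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  .stop_if(length(universe) == 0L, "empty universe")
  rows <- list()
  for (nm in names(collections)) {
    term <- unique(intersect(collections[[nm]], universe))
    if (length(term) == 0L) {
      message("skipping term with no in-universe genes: ", nm)
      next
    }
    k <- length(intersect(query, term))
    # P(overlap >= k) drawing |query| genes from the universe
    p <- stats::phyper(k - 1L, length(term), length(universe) - length(term),
                       length(query), lower.tail = FALSE)
    rows[[nm]] <- data.frame(term = nm, term_size = length(term), overlap = k,
                             p_raw = p, stringsAsFactors = FALSE)
  }
  .stop_if(length(rows) == 0L, "no testable terms")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adj <= fdr_max
  out
}

#' Read / write gene-set collections in GMT format
#'
#' Tab-delimited lines: set name, description, then member genes.
#' Duplicate genes within a term are removed.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  .stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0L)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    .stop_if(length(parts) < 3L,
             sprintf("GMT line %d has fewer than 3 fields", i))
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
    desc[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(sets)) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm])) descriptions[nm] else "na"
    writeLines(paste(c(nm, d, unique(sets[[nm]])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write single-cell counts in Matrix Market or dense TSV form
#'
#' The Matrix Market layout is the conventional triplet `.mtx` with
#' `genes` and `barcodes` sidecar files (one name per line) next to it.
#'
#' @param path `.mtx` path (sidecars `<stem>.genes.txt`,
#'   `<stem>.barcodes.txt`) or a dense TSV (genes x cells, header).
#' @param labels_path Two-column TSV (cell, cell_type).
#' @param mito_prefixes Passed to [cell_matrix()].
#' @return A [cell_matrix()].
#' @export
read_cell_counts <- function(path, labels_path, mito_prefixes = "MT-") {
  if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    counts <- as.matrix(Matrix::readMM(path))
    rownames(counts) <- readLines(paste0(stem, ".genes.txt"))
    colnames(counts) <- readLines(paste0(stem, ".barcodes.txt"))
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    counts <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(counts) <- tab[[1L]]
  }
  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  cell_matrix(counts, stats::setNames(lab[[2L]], lab[[1L]]), mito_prefixes)
}

#' @rdname read_cell_counts
#' @param m A [cell_matrix()].
#' @export
write_cell_counts <- function(m, path, labels_path) {
  stem <- sub("\\.mtx$", "", path)
  Matrix::writeMM(Matrix::Matrix(as.matrix(m$counts), sparse = TRUE), path)
  writeLines(rownames(m$counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(m$counts), paste0(stem, ".barcodes.txt"))
  utils::write.table(
    data.frame(cell = names(m$cell_labels), cell_type = unname(m$cell_labels)),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
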