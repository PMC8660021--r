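# small deterministic cell fixture: 6 real genes + 1 mito gene, 8 cells
cell_fixture <- function() {
  genes <- c(sprintf("g%d", 1:6), "MT-1")
  counts <- matrix(0L, 7L, 8L,
                   dimnames = list(genes, sprintf("c%d", 1:8)))
  counts["g1", ] <- c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L)
  counts["g2", ] <- c(3L, 0L, 3L, 3L, 3L, 3L, 0L, 3L)
  counts["g3", ] <- c(2L, 2L, 0L, 2L, 2L, 2L, 0L, 2L)
  counts["g4", ] <- c(0L, 0L, 0L, 4L, 4L, 4L, 0L, 0L)
  counts["g5", ] <- c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L)
  counts["g6", ] <- c(0L, 2L, 2L, 0L, 2L, 2L, 0L, 0L)
  counts["MT-1", ] <- c(0L, 0L, 0L, 0L, 0L, 2L, 0L, 0L)
  labels <- stats::setNames(rep(c("T1", "T2"), each = 4L), colnames(counts))
  cell_matrix(counts, labels)
}

test_that("cell filters apply the inclusive detected-gene and mito rules", {
  m <- cell_fixture()
  # detected genes per cell: c1..c8 = 4,4,4,5,5,7,1,4; c6 and c7 fall
  # outside [4, 5] so six cells survive
  kept <- filter_cells(m, min_genes = 4L, max_genes = 5L, max_mito_frac = 0.05)
  expect_setequal(colnames(kept$counts), c("c1", "c2", "c3", "c4", "c5", "c8"))

  # boundary: exactly min_genes detected is kept, one fewer is removed
  kept_min <- filter_cells(m, min_genes = 1L, max_genes = 10L)
  expect_true("c7" %in% colnames(kept_min$counts))
  expect_error(filter_cells(m, min_genes = 7L, max_genes = 10L), "no cells")
  # mito fraction 2/18 > 0.05 removes c6; raising the cap keeps it
  expect_false("c6" %in% colnames(
    filter_cells(m, min_genes = 1L, max_genes = 10L, max_mito_frac = 0.05)$counts))
  expect_true("c6" %in% colnames(
    filter_cells(m, min_genes = 1L, max_genes = 10L, max_mito_frac = 0.2)$counts))
})

test_that("normalization is ln(1 + count/total * 1e4)", {
  m <- cell_fixture()
  norm <- normalize_cells(m)
  tot <- Matrix::colSums(m$counts)
  expect_equal(norm["g1", "c1"], log1p(5 / tot[["c1"]] * 1e4), tolerance = 1e-12)
  expect_equal(norm["g4", "c1"], 0)
  # a cell where one gene holds every count reaches ln(1 + 1e4)
  solo <- cell_matrix(matrix(7L, 1L, 1L, dimnames = list("gX", "cX")),
                      c(cX = "T"))
  expect_equal(normalize_cells(solo)[1L, 1L], log(1 + 1e4), tolerance = 1e-12)
  # full matrix matches direct evaluation
  direct <- log1p(sweep(as.matrix(m$counts), 2L, 1e4 / tot, `*`))
  expect_equal(norm, direct, tolerance = 1e-12)
})

test_that("pseudobulk is the per-type mean of normalized values", {
  m <- cell_fixture()
  norm <- normalize_cells(m)
  pb <- pseudobulk(norm, m$cell_labels)
  expect_equal(dim(pb), c(2L, 7L))
  expect_equal(pb["T1", "g2"], mean(norm["g2", 1:4]), tolerance = 1e-12)
  expect_equal(pb["T2", "g4"], mean(norm["g4", 5:8]), tolerance = 1e-12)
  # identical cells: pseudobulk equals any single cell
  ident <- cell_matrix(matrix(rep(c(2L, 0L, 3L), 4L), 3L, 4L,
                              dimnames = list(c("a", "b", "c"), sprintf("c%d", 1:4))),
                       stats::setNames(rep("T", 4L), sprintf("c%d", 1:4)))
  ni <- normalize_cells(ident)
  expect_equal(unname(pseudobulk(ni, ident$cell_labels)["T", ]), unname(ni[, 1L]))
})

test_that("enrichment ratios and Fisher tests follow the 2x2 construction", {
  # homogeneous table: recruited and background expressed at equal rates
  pb <- rbind(T1 = c(rep(1, 50), rep(0, 50), rep(1, 500), rep(0, 500)))
  colnames(pb) <- sprintf("g%04d", seq_len(ncol(pb)))
  recruited <- colnames(pb)[1:100]
  res <- celltype_enrichment(pb, recruited)
  expect_equal(res$ratio, 1)
  expect_equal(res$p_raw, 1)
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(50L, 50L, 500L, 500L))
})

test_that("two-sided Fisher p matches exhaustive enumeration over small tables", {
  tables <- list()
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if (a + b > 0 && cc + d > 0) tables[[length(tables) + 1L]] <- c(a, b, cc, d)
  }
  set.seed(17)
  tables <- tables[sample(length(tables), 400L)]
  for (tb in tables) {
    got <- stats::fisher.test(matrix(tb, 2L, byrow = TRUE))$p.value
    want <- fisher_two_sided_oracle(tb[1L], tb[2L], tb[3L], tb[4L])
    expect_equal(got, min(want, 1), tolerance = 1e-10)
  }
  # the specific table from the rule: transpose invariance too
  p1 <- stats::fisher.test(matrix(c(8, 2, 2, 8), 2L))$p.value
  expect_equal(p1, fisher_two_sided_oracle(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(p1, stats::fisher.test(t(matrix(c(8, 2, 2, 8), 2L)))$p.value,
               tolerance = 1e-12)
})

test_that("planted recruited-gene enrichment is detected with Bonferroni control", {
  sim <- simulate_single_cell(
    cell_types = c(planted = 50L, other1 = 50L, other2 = 50L),
    n_genes = 2200L, recruited = 200L, planted_types = "planted",
    effect = c(0.9, 0.3), depth = 5, seed = 23L)
  cm <- filter_cells(sim$cells, min_genes = 1L, max_genes = 3000L,
                     max_mito_frac = 1)
  pb <- pseudobulk(normalize_cells(cm), cm$cell_labels)
  res <- celltype_enrichment(pb, sim$truth$recruited)
  planted_row <- res[res$cell_type == "planted", ]
  expect_lt(planted_row$p_adj, 0.05)
  expect_gt(planted_row$ratio, 1)
  expect_equal(res$cell_type[which.max(res$ratio)], "planted")
  # Bonferroni dominates BH dominates raw
  res_bh <- celltype_enrichment(pb, sim$truth$recruited, adjust = "BH")
  expect_true(all(res$p_adj >= res_bh$p_adj - 1e-15))
  expect_true(all(res_bh$p_adj >= res_bh$p_raw - 1e-15))
  expect_true(all(res$p_adj <= 1))
})

test_that("enrichment ratio exceeds 1 exactly when the odds ratio does", {
  set.seed(18)
  for (i in 1:50) {
    a <- sample(1:30, 1L); b <- sample(1:30, 1L)
    cc <- sample(1:30, 1L); d <- sample(1:30, 1L)
    obs <- a / (a + b); exp_ <- cc / (cc + d)
    or <- (a * d) / (b * cc)
    if (or != 1) expect_equal(obs / exp_ > 1, or > 1)
  }
})

test_that("hypergeometric ORA matches the summed-pmf oracle and flags by FDR", {
  sets <- list(term20 = sprintf("u%03d", 1:20),
               all = sprintf("u%03d", 1:100),
               off_universe = c("zzz1", "zzz2"))
  universe <- sprintf("u%03d", 1:100)
  query <- c(sprintf("u%03d", 1:8), sprintf("u%03d", 60:61))  # overlap 8 with term20
  expect_message(res <- ora(query, sets, universe), "off_universe")
  t20 <- res[res$term == "term20", ]
  expect_equal(t20$overlap, 8L)
  expect_equal(t20$p_raw, hyper_upper_oracle(8L, 20L, 100L, 10L),
               tolerance = 1e-12)
  expect_equal(res[res$term == "all", "p_raw"], 1, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed vector", {
  expect_equal(stats::p.adjust(c(0.001, 0.01, 0.03, 0.9), method = "BH"),
               c(0.004, 0.02, 0.04, 0.9))
})

test_that("GMT files round-trip and deduplicate members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg2\tg3",
               "setB\tother\tg4"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(length(sets$setB), 1L)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely\tonlydesc", bad)
  expect_error(read_gmt(bad), "fewer than 3")

  set.seed(19)
  big <- lapply(1:50, function(i)
    sample(sprintf("gene%03d", 1:200), sample(3:30, 1L)))
  names(big) <- sprintf("S%02d", 1:50)
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(big, out)
  back <- read_gmt(out)
  expect_equal(lapply(back, sort)[names(big)], lapply(big, sort))
})

test_that("cell matrices round-trip through Matrix Market with sidecars", {
  m <- cell_fixture()
  mtx <- withr::local_tempfile(fileext = ".mtx")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_cell_counts(m, mtx, lab)
  back <- read_cell_counts(mtx, lab)
  expect_equal(as.matrix(back$counts), as.matrix(m$counts), ignore_attr = TRUE)
  expect_equal(back$cell_labels, m$cell_labels)
  expect_equal(back$mito_genes, m$mito_genes)
})
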