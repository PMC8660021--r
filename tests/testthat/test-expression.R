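test_that("TPM tables parse, flag missing cells, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2",
               "g1\t0.5\t3.2",
               "g2\tNA\t1.0",
               "g3\t7\t0"), path)
  expr <- read_expression_table(path)
  expect_equal(dim(expr$values), c(3L, 2L))
  expect_equal(sum(expr$missing_mask), 1L)
  expect_true(expr$missing_mask["g2", "s1"])

  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(expr, out)
  back <- read_expression_table(out)
  expect_equal(back$values[!back$missing_mask], expr$values[!expr$missing_mask])
  expect_equal(back$missing_mask, expr$missing_mask)
})

test_that("large synthetic table round-trips exactly", {
  expr <- simulate_tpm_matrix(500L, c(sp1 = 2L, sp2 = 1L, sp3 = 1L), seed = 11L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(expr, path)
  sm <- stats::setNames(unname(expr$species_of_sample), expr$sample_ids)
  back <- read_expression_table(path, sm)
  expect_equal(back$values, expr$values, tolerance = 1e-12)
  expect_equal(back$species_of_sample, expr$species_of_sample)
})

test_that("malformed expression input is rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t1.0", "g1\t2.0"), path)
  expect_error(read_expression_table(path), "duplicate gene")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1", "g1\t-3"), path2)
  expect_error(read_expression_table(path2), "negative")
})

test_that("mixture EM recovers well-separated generating components", {
  set.seed(1)
  x <- c(rnorm(5000, -3, 1), rnorm(5000, 4.25, 1))
  fit <- fit_expression_mixture(x, seed = 1L)
  expect_lt(abs(fit$component_means[1L] - (-3)), 0.1)
  expect_lt(abs(fit$component_means[2L] - 4.25), 0.1)
  expect_equal(sum(fit$component_weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("mixture EM rejects degenerate input", {
  expect_error(fit_expression_mixture(rep(1.5, 100)), "degenerate|identical")
  expect_error(fit_expression_mixture(rnorm(100), n_components = 3L), "only 2")
  expect_error(fit_expression_mixture(rnorm(10)), ">= 50")
})

test_that("mixture EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust resolves helpers via the search path
  set.seed(5)
  x <- c(rnorm(3000, -2, 0.8), rnorm(6000, 3, 1.2))
  fit <- fit_expression_mixture(x, seed = 2L)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$component_means), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("expression probability is the exact two-Gaussian Bayes posterior", {
  # exact generating parameters: responsibility must equal the closed form
  fit <- structure(list(component_means = c(-3, 4.25),
                        component_sds = c(1, 1),
                        component_weights = c(0.5, 0.5),
                        loglik_trace = 0, n_points = 100L),
                   class = "mixture_fit")
  tpms <- 2^seq(-6, 8, by = 0.5)
  bayes <- function(x) {
    d_hi <- 0.5 * dnorm(x, 4.25, 1)
    d_lo <- 0.5 * dnorm(x, -3, 1)
    d_hi / (d_hi + d_lo)
  }
  expect_equal(expression_probability(fit, tpms), bayes(log2(tpms)),
               tolerance = 1e-12)
  # symmetric fit: equal-responsibility crossing is the midpoint
  expect_equal(expression_probability(fit, 2^((4.25 - 3) / 2)), 0.5,
               tolerance = 1e-12)
  expect_gt(expression_probability(fit, 2^8), 0.99)
  expect_error(expression_probability(fit, 0), "> 0")
})

test_that("fitted mixture posterior matches generating-density Bayes posterior", {
  set.seed(1)
  x <- c(rnorm(5000, -3, 1), rnorm(5000, 4.25, 1))
  fit <- fit_expression_mixture(x, seed = 1L)
  d_hi <- 0.5 * dnorm(4.25, 4.25, 1); d_lo <- 0.5 * dnorm(4.25, -3, 1)
  expect_equal(expression_probability(fit, 2^4.25), d_hi / (d_hi + d_lo),
               tolerance = 0.02)
})

test_that("binarization applies the inclusive TPM cutoff exactly", {
  vals <- matrix(c(2.0, 1.99, 0, NA), ncol = 1L,
                 dimnames = list(paste0("g", 1:4), "s1"))
  expr <- expression_matrix(vals, c(s1 = "taxon1"))
  states <- binarize(expr, threshold = 2.0)
  expect_identical(unclass(states)[, "taxon1"],
                   c(g1 = 1L, g2 = 0L, g3 = 0L, g4 = NA))
})

test_that("replicates collapse per rule and missing-in-all becomes unknown", {
  vals <- matrix(c(3, 1,      # mean 2 -> 1 under mean rule
                   1, 1,      # all below
                   NA, NA,    # fully missing
                   5, NA),    # observed in one replicate
                 ncol = 2L, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), c("r1", "r2")))
  expr <- expression_matrix(vals, c(r1 = "tx", r2 = "tx"))
  expect_identical(unname(unclass(binarize(expr, 2, "mean"))[, 1L]),
                   c(1L, 0L, NA, 1L))
  expect_identical(unname(unclass(binarize(expr, 2, "any"))[, 1L]),
                   c(1L, 0L, NA, 1L))
  expect_identical(unname(unclass(binarize(expr, 2, "all"))[, 1L]),
                   c(0L, 0L, NA, 1L))
})

test_that("binarization is monotone in the threshold and permutation-stable", {
  expr <- simulate_tpm_matrix(300L, c(a = 2L, b = 3L, c = 1L), seed = 3L)
  s1 <- binarize(expr, 1.0)
  s2 <- binarize(expr, 2.0)
  s4 <- binarize(expr, 4.0)
  expect_true(all(unclass(s2)[unclass(s4) == 1L] == 1L, na.rm = TRUE))
  expect_true(all(unclass(s1)[unclass(s2) == 1L] == 1L, na.rm = TRUE))

  perm <- sample(ncol(expr$values))
  expr_p <- expression_matrix(expr$values[, perm], expr$species_of_sample[perm])
  sp <- binarize(expr_p, 2.0)
  expect_equal(unclass(s2)[, colnames(sp)], unclass(sp))
})

test_that("binary state matrices round-trip through TSV and PHYLIP export", {
  m <- toy_binary_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_binary_states(m, path)
  back <- read_binary_states(path)
  expect_identical(unclass(back), unclass(m))

  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip_binary(m, phy)
  lines <- readLines(phy)
  expect_equal(lines[1L], "4 3")
  expect_match(lines[2L], "^t1  110$")
})
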