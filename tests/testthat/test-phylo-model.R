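test_that("Newick parsing validates and round-trips", {
  tree <- read_newick("((A:0.1,B:0.1):0.2,C:0.3);")
  expect_equal(ape::Ntip(tree), 3L)
  expect_equal(nrow(tree$edge), 4L)
  expect_true(ape::is.rooted(tree))
  expect_true(all(nzchar(tree$node.label)))

  set.seed(20)
  big <- random_tree(33L)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(big, path)
  back <- read_newick(path)
  expect_equal(ape::dist.topo(ape::unroot(big), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(big$edge.length), tolerance = 1e-9)

  expect_error(read_newick("((A:1,A:1):1,B:1);"), "duplicate tip")
})

test_that("transition matrix has the exact closed form", {
  p <- model_params(0.3, weights = 1, rates = 1)
  expect_equal(transition_matrix(p, 0), diag(2), ignore_attr = TRUE)

  long <- transition_matrix(p, 500)
  expect_equal(long[1L, ], c(`0` = 0.7, `1` = 0.3), tolerance = 1e-12)
  expect_equal(long[2L, ], c(`0` = 0.7, `1` = 0.3), tolerance = 1e-12)

  # against the matrix exponential of the generator, over a grid
  for (pi1 in c(0.1, 0.3, 0.5, 0.77)) {
    for (t in c(0.01, 0.5, 2)) {
      for (r in c(0.2, 1, 3.1)) {
        pp <- model_params(pi1, weights = 1, rates = 1)
        mu <- 1 / (2 * (1 - pi1) * pi1)
        Q <- mu * matrix(c(-pi1, pi1, 1 - pi1, -(1 - pi1)), 2L, byrow = TRUE)
        expected <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t * r)))
        expect_equal(unclass(transition_matrix(pp, t, r)), expected,
                     tolerance = 1e-12, ignore_attr = TRUE)
        expect_equal(rowSums(transition_matrix(pp, t, r)), c(`0` = 1, `1` = 1),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(transition_matrix(p, -1), ">= 0")
})

test_that("detailed balance and Chapman-Kolmogorov hold", {
  for (pi1 in c(0.2, 0.5, 0.9)) {
    p <- model_params(pi1, weights = 1, rates = 1)
    pi_vec <- c(1 - pi1, pi1)
    for (t in c(0.1, 1, 4)) {
      P <- transition_matrix(p, t)
      expect_equal(pi_vec[1L] * P[1L, 2L], pi_vec[2L] * P[2L, 1L],
                   tolerance = 1e-12)
    }
    P1 <- transition_matrix(p, 0.4)
    P2 <- transition_matrix(p, 1.3)
    expect_equal(P1 %*% P2, unclass(transition_matrix(p, 1.7)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pruning likelihood handles fully unknown and degenerate columns", {
  tree <- read_newick("(A:0.5,B:0.5);")
  p <- random_params()
  expect_equal(pruning_loglik(tree, p, c(A = NA, B = NA)), 0)

  tree0 <- read_newick("(A:0,B:0);")
  expect_equal(pruning_loglik(tree0, p, c(A = 1L, B = 1L)),
               log(p$pi[2L]), ignore_attr = TRUE)
})

test_that("pruning equals exhaustive enumeration on small random instances", {
  set.seed(101)
  for (rep in 1:30) {
    ntip <- sample(3:6, 1L)
    tree <- random_tree(ntip)
    p <- random_params(sample(c(1L, 4L), 1L))
    column <- sample(c(0L, 1L, NA), ntip, replace = TRUE, prob = c(.4, .4, .2))
    names(column) <- tree$tip.label
    got <- pruning_loglik(tree, p, column)
    want <- brute_loglik(tree, p, column)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("matrix log-likelihood sums per-gene values and ignores order", {
  set.seed(33)
  tree <- random_tree(6L)
  p <- random_params()
  m <- matrix(sample(c(0L, 1L, NA), 6L * 40L, replace = TRUE, prob = c(.4, .4, .2)),
              nrow = 40L, dimnames = list(sprintf("g%02d", 1:40), tree$tip.label))
  total <- matrix_loglik(tree, p, m)
  per_gene <- vapply(seq_len(nrow(m)), function(i)
    pruning_loglik(tree, p, m[i, ]), numeric(1L))
  expect_equal(total, sum(per_gene), tolerance = 1e-8)

  expect_equal(matrix_loglik(tree, p, m[sample(nrow(m)), ]), total,
               tolerance = 1e-10)
  expect_equal(matrix_loglik(tree, p, m[1L, , drop = FALSE]),
               pruning_loglik(tree, p, m[1L, ]), tolerance = 1e-12)
})

test_that("single-category free-rate model equals the homogeneous model", {
  set.seed(44)
  tree <- random_tree(5L)
  p_multi <- model_params(0.4, weights = c(1, 0, 0, 0) + 1e-300,
                          rates = c(1, 1, 1, 1))
  p_one <- model_params(0.4, weights = 1, rates = 1)
  column <- c(1L, 0L, 1L, NA, 0L)
  names(column) <- tree$tip.label
  # all categories at rate 1: mixture collapses to the homogeneous value
  expect_equal(pruning_loglik(tree, p_multi, column),
               pruning_loglik(tree, p_one, column), tolerance = 1e-9)
})

test_that("constant matrices drive branch lengths to the lower bound", {
  tree <- random_tree(4L)
  m <- matrix(1L, 30L, 4L, dimnames = list(sprintf("g%02d", 1:30), tree$tip.label))
  expect_warning(fit <- optimize_parameters(tree, m, seed = 1L,
                                            n_categories = 1L, max_rounds = 3L),
                 "fewer than 2")
  expect_true(all(fit$tree$edge.length < 1e-6))
  expect_gt(fit$params$pi[2L], 0.9)
})

test_that("duplicating every character leaves the ML estimates unchanged", {
  set.seed(55)
  tree <- random_tree(5L)
  sim <- simulate_binary_evolution(tree, model_params(0.35), 150L, seed = 5L)
  m2 <- rbind(sim$states, sim$states)
  rownames(m2) <- sprintf("g%03d", seq_len(nrow(m2)))
  f1 <- optimize_parameters(tree, sim$states, seed = 2L, n_categories = 1L,
                            max_rounds = 4L)
  f2 <- optimize_parameters(tree, m2, seed = 2L, n_categories = 1L,
                            max_rounds = 4L)
  expect_equal(f1$params$pi, f2$params$pi, tolerance = 1e-4)
  expect_equal(f1$tree$edge.length, f2$tree$edge.length, tolerance = 1e-3)
  expect_equal(2 * f1$loglik, f2$loglik, tolerance = 1e-4)
})

test_that("optimization attains at least the true-parameter likelihood", {
  set.seed(66)
  tree <- random_tree(8L)
  true <- model_params(0.3, weights = c(.4, .6), rates = c(.5, 1.8))
  sim <- simulate_binary_evolution(tree, true, 400L, seed = 9L)
  fit <- optimize_parameters(tree, sim$states, seed = 3L, n_categories = 2L,
                             max_rounds = 6L)
  expect_gte(fit$loglik, matrix_loglik(tree, true, sim$states) - 1e-6)
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("model JSON round-trips", {
  p <- model_params(0.27, weights = c(.3, .3, .2, .2), rates = c(.2, .7, 1.4, 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(p, path, loglik = -123.45)
  back <- read_model_json(path)
  expect_equal(back$pi, p$pi, tolerance = 1e-12)
  expect_equal(back$weights, p$weights, tolerance = 1e-12)
  expect_equal(back$rates, p$rates, tolerance = 1e-12)
  expect_equal(attr(back, "loglik"), -123.45)
})
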