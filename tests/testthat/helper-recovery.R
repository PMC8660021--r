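# The 20-tip / 10,000-character recovery study shared by the parameter
# recovery and posterior calibration checks. Computed once per test run.
.recovery_cache <- new.env(parent = emptyenv())

recovery_study <- function() {
  if (!is.null(.recovery_cache$fit)) return(as.list(.recovery_cache))
  set.seed(2024)
  tree <- random_tree(20L, min_len = 0.02, max_len = 1)
  true <- model_params(0.3, weights = c(0.4, 0.3, 0.2, 0.1),
                       rates = c(0.2, 0.7, 1.5, 3.1))
  sim <- simulate_binary_evolution(tree, true, 10000L, seed = 7L)
  fit <- optimize_parameters(tree, sim$states, seed = 7L)
  bpp <- marginal_posteriors(fit$tree, fit$params, sim$states)
  .recovery_cache$tree <- tree
  .recovery_cache$true <- true
  .recovery_cache$sim <- sim
  .recovery_cache$fit <- fit
  .recovery_cache$bpp <- bpp
  as.list(.recovery_cache)
}
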