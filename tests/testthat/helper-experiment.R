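# The desk-scale parameter-recovery experiment shared by the end-to-end
# tests: 16 training + 8 test phantom cases on 16^3 grids, baseline n0 = 4
# trained 2000 steps.  Computed once per test run and cached.

.experiment_cache <- new.env(parent = emptyenv())

desk_experiment <- function() {
  if (!is.null(.experiment_cache$main)) return(.experiment_cache$main)
  train_cases <- generate_cases(phantom_spec(), n_cases = 16, seed = 101)
  test_cases <- generate_cases(phantom_spec(), n_cases = 8, seed = 202)
  fit <- train_network(train_cases, desk_train_config(max_iters = 2000,
                                                      seed = 1))
  res <- list(train_cases = train_cases, test_cases = test_cases, fit = fit,
              before = evaluate_run(test_cases, net = NULL),
              after = evaluate_run(test_cases, fit$net))
  .experiment_cache$main <- res
  res
}
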