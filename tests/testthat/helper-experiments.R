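# Memoized desk-scale training experiments shared by the acceptance tests.
# Each runs once per test session.

.exp_env <- new.env(parent = emptyenv())

memo_exp <- function(name, build) {
  if (!exists(name, envir = .exp_env)) assign(name, build(), envir = .exp_env)
  get(name, envir = .exp_env)
}

exp_overfit <- function() memo_exp("overfit", function()
  run_overfit_experiment(epochs = 40L, seed = 101L))

exp_variant_cmp <- function() memo_exp("variant_cmp", function()
  run_variant_comparison(seed = 202L))

exp_elevation <- function() memo_exp("elevation", function()
  run_elevation_experiment(exp_variant_cmp()))

exp_ctcf <- function() memo_exp("ctcf", function()
  run_ctcf_experiment(seed = 303L))
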