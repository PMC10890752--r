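# shared helpers for the test suite

# unit loading vector of a group within a batch
group_unit <- function(batch, i) {
  ch <- batch$groups[[i]]$channels
  u <- rep(0, ncol(batch$data))
  u[ch] <- 1 / sqrt(length(ch))
  u
}

# memoised heavy runs shared between property and acceptance tests
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# one population-network condition (cached across test files)
pop_cond <- function(variant, heterogeneous, seed, n_samples = 3e5) {
  key <- paste("pop", variant, heterogeneous, seed, n_samples, sep = "_")
  cached(key, population_condition(variant, heterogeneous, n_samples, seed))
}

# one converged single-neuron subgroup run (tail-averaged weights)
subgroup_run <- function(variant, seed, n_train = 1.5e6) {
  key <- paste("sub", variant, seed, n_train, sep = "_")
  cached(key, {
    batch <- gen_subgroup_dataset(variant, 2e5, seed)
    held <- gen_subgroup_dataset(variant, 1e5, seed + 500L)
    tr <- train_neuron(batch, rule_config("corr_invariant"),
                       train_config(n_samples = n_train, seed = seed))
    list(batch = batch, held = held, w = tail_averaged_w(tr))
  })
}
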