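# Expensive fixtures (trained networks, recorded activity) are built once
# per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# One shared pair of 200-sequence training/testing sets.
shared_sequences <- function() cached("seqs", {
  set.seed(101)
  list(train = generate_sequences(200), test = generate_sequences(200))
})

# Ensembles of passing networks (5 per architecture keeps the default test
# run short; the acceptance script uses 10).
shared_ens7 <- function() cached("ens7", {
  sq <- shared_sequences()
  train_ensemble(5L, sq$train, encoding_scheme("one_hot_6"),
                 training_config(7L), test_sequences = sq$test,
                 first_init_seed = 1L, batch_seed = 1000L,
                 max_attempts = 40L)
})

shared_ens60 <- function() cached("ens60", {
  sq <- shared_sequences()
  train_ensemble(5L, sq$train, encoding_scheme("circular_2"),
                 training_config(60L), test_sequences = sq$test,
                 first_init_seed = 1L, batch_seed = 1000L,
                 max_attempts = 20L)
})

# A single passing 7-unit network and its recorded activity.
shared_net7 <- function() shared_ens7()$networks[[1]]

shared_act7 <- function() cached("act7", {
  record_hidden_activity(shared_net7(), shared_sequences()$train)
})

# Per-network subspace analyses.
shared_analyses7 <- function() cached("analyses7", {
  sq <- shared_sequences()
  lapply(shared_ens7()$networks, function(net)
    analyze_subspaces(record_hidden_activity(net, sq$train)))
})

shared_analyses60 <- function() cached("analyses60", {
  sq <- shared_sequences()
  lapply(shared_ens60()$networks, function(net)
    analyze_subspaces(record_hidden_activity(net, sq$train)))
})

# Small random activity tensor with labels, for exercising the averaging
# and dPCA plumbing without training anything.
random_tensor <- function(n_trials = 24, n_time = 5, n_units = 4, seed = 1,
                          clock = "timestep",
                          time = c("pre1", "d1.2", "n1", "d2.2", "n2")) {
  set.seed(seed)
  labels <- data.frame(
    stim_id = rep_len(1:6, n_trials),
    probe_id = rep_len(rep(1:6, each = 2), n_trials),
    decision = rep_len(c("match", "nonmatch"), n_trials))
  activity_tensor(array(rnorm(n_trials * n_time * n_units),
                        dim = c(n_trials, n_time, n_units)),
                  labels, time = time, clock = clock)
}
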