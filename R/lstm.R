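#' Network and training configuration
#'
#' The model is a single-layer LSTM receiving one encoded stimulus vector
#' per timestep, read out by linearly rectifying the hidden state and
#' applying a linear layer to a single output unit whose target is 1 (match)
#' or 0 (non-match) at decision timesteps. Training minimizes the mean
#' squared error between output and target across all timesteps, with Adam.
#'
#' @param n_hidden Number of LSTM hidden units (7 for the one-hot networks,
#'   60 for the circular-input networks).
#' @param n_iterations Adam iterations (5000 for 7 units, 1500 for 60).
#' @param batch_size Sequences per iteration, sampled with replacement from
#'   the training set.
#' @param learning_rate Adam step size.
#' @return A list of class `wm_train_config`.
#' @export
training_config <- function(n_hidden = 7L, n_iterations = if (n_hidden >= 60) 1500L else 5000L,
                            batch_size = 20L, learning_rate = 1e-3) {
  structure(list(n_hidden = as.integer(n_hidden),
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate),
            class = "wm_train_config")
}

# Uniform fan-in initialization: every weight and bias ~ U(-k, k) with
# k = 1/sqrt(n_hidden), the standard scheme for LSTM layers; the readout
# layer has fan-in n_hidden and uses the same bound.
init_lstm_params <- function(n_input, n_hidden) {
  k <- 1 / sqrt(n_hidden)
  u <- function(n) stats::runif(n, -k, k)
  g4 <- 4L * n_hidden
  list(Wih = matrix(u(g4 * n_input), g4, n_input),
       Whh = matrix(u(g4 * n_hidden), g4, n_hidden),
       bih = u(g4), bhh = u(g4),
       wout = u(n_hidden), bout = u(1))
}

# Stack encoded sequences into the array layout the C++ core expects:
# inputs n_input x timesteps x sequences, targets timesteps x sequences.
stack_encoded <- function(encoded) {
  n_t <- encoded[[1]]$n_timesteps
  n_in <- ncol(encoded[[1]]$inputs)
  inputs <- array(0, dim = c(n_in, n_t, length(encoded)))
  targets <- matrix(0, n_t, length(encoded))
  for (i in seq_along(encoded)) {
    inputs[, , i] <- t(encoded[[i]]$inputs)
    targets[, i] <- encoded[[i]]$targets
  }
  list(inputs = inputs, targets = targets)
}

#' Train an LSTM on the 2-back task
#'
#' Initializes all parameters from the uniform fan-in scheme under
#' `init_seed`, then runs Adam on mini-batches drawn (with replacement)
#' under `batch_seed`. Keeping the two seeds separate means an ensemble
#' trained with a fixed `batch_seed` differs only in its weight
#' initialization. The initial hidden and cell states are zero.
#'
#' @param sequences List of `wm_sequence` training sequences.
#' @param scheme A `wm_encoding`.
#' @param config A `wm_train_config`.
#' @param init_seed Seed for the weight initialization.
#' @param batch_seed Seed for mini-batch sampling (shared across an ensemble).
#' @param test_sequences Optional held-out sequences; if supplied, held-out
#'   accuracy and the 99.5% pass criterion are recorded.
#' @return A `wm_network`: trained parameters, configs, the loss trace,
#'   `test_accuracy` (or `NA`), and `passed_criterion`.
#' @export
train_network <- function(sequences, scheme, config = training_config(),
                          init_seed = 1L, batch_seed = 1000L,
                          test_sequences = NULL) {
  stopifnot(inherits(scheme, "wm_encoding"), inherits(config, "wm_train_config"))
  encoded <- lapply(sequences, encode_sequence, scheme = scheme)
  stacked <- stack_encoded(encoded)

  set.seed(init_seed)
  par0 <- init_lstm_params(scheme$n_input, config$n_hidden)
  set.seed(batch_seed)
  batch_idx <- matrix(
    sample.int(length(sequences), config$batch_size * config$n_iterations,
               replace = TRUE),
    nrow = config$batch_size)

  fit <- lstm_train_cpp(stacked$inputs, stacked$targets, batch_idx,
                        par0$Wih, par0$Whh, par0$bih, par0$bhh,
                        par0$wout, par0$bout, lr = config$learning_rate)
  net <- structure(
    list(params = fit[c("Wih", "Whh", "bih", "bhh", "wout", "bout")],
         scheme = scheme, config = config,
         init_seed = init_seed, batch_seed = batch_seed,
         loss_trace = as.numeric(fit$loss_trace),
         test_accuracy = NA_real_, passed_criterion = NA),
    class = "wm_network")
  if (!is.null(test_sequences)) {
    net$test_accuracy <- evaluate_accuracy(net, test_sequences)
    net$passed_criterion <- net$test_accuracy >= 0.995
  }
  net
}

#' @export
print.wm_network <- function(x, ...) {
  cat(sprintf("LSTM 2-back network: %d hidden units, %s inputs\n",
              x$config$n_hidden, x$scheme$kind))
  cat(sprintf("final training loss %.2e; held-out accuracy %s\n",
              utils::tail(x$loss_trace, 1),
              ifelse(is.na(x$test_accuracy), "not evaluated",
                     sprintf("%.2f%%", 100 * x$test_accuracy))))
  invisible(x)
}

# Correct response: absolute output-target difference strictly below 0.5.
response_correct <- function(output, target) abs(output - target) < 0.5

# Output activations of the network on a list of sequences (timesteps x n).
network_outputs <- function(net, sequences) {
  encoded <- lapply(sequences, encode_sequence, scheme = net$scheme)
  stacked <- stack_encoded(encoded)
  p <- net$params
  lstm_forward_cpp(stacked$inputs, p$Wih, p$Whh, p$bih, p$bhh, p$wout, p$bout)
}

#' Held-out task accuracy of a trained network
#'
#' A response is correct when the absolute difference between the output
#' activation and the target is strictly below 0.5, judged only at decision
#' timesteps: the presentation timesteps of stimuli 3 onward, where a 2-back
#' comparison exists. Returns the fraction correct pooled over all decision
#' timesteps of all sequences.
#'
#' @param net A `wm_network`.
#' @param sequences List of `wm_sequence` objects to evaluate on.
#' @export
evaluate_accuracy <- function(net, sequences) {
  fwd <- network_outputs(net, sequences)
  correct <- 0L
  total <- 0L
  for (i in seq_along(sequences)) {
    enc_t <- 3L * (seq_along(sequences[[i]]$identities) - 1L) + 1L
    dec_t <- enc_t[-(1:2)]
    targ <- as.numeric(sequences[[i]]$match_flags[-(1:2)])
    out <- fwd$outputs[dec_t, i]
    correct <- correct + sum(response_correct(out, targ))
    total <- total + length(dec_t)
  }
  correct / total
}

#' Train an ensemble of networks differing only in initialization
#'
#' Trains networks with successive initialization seeds until `n_keep` reach
#' the 99.5% held-out accuracy criterion, sharing training/testing sequences,
#' hyperparameters, and the batch-sampling seed. Networks below criterion
#' are discarded, mirroring the keep-10-discard-below-criterion protocol.
#'
#' @inheritParams train_network
#' @param n_keep Number of passing networks to return.
#' @param max_attempts Cap on trainings before returning a partial ensemble
#'   with a warning.
#' @param first_init_seed Initialization seed of the first attempt; attempt
#'   `j` uses `first_init_seed + j - 1`.
#' @return A list of class `wm_ensemble` with `networks` (passing only),
#'   `n_attempted`, and `accuracies` of every attempt.
#' @export
train_ensemble <- function(n_keep, sequences, scheme,
                           config = training_config(),
                           test_sequences, first_init_seed = 1L,
                           batch_seed = 1000L,
                           max_attempts = 2L * n_keep) {
  stopifnot(n_keep >= 1L)
  networks <- list()
  accs <- numeric(0)
  attempt <- 0L
  while (length(networks) < n_keep && attempt < max_attempts) {
    attempt <- attempt + 1L
    net <- train_network(sequences, scheme, config,
                         init_seed = first_init_seed + attempt - 1L,
                         batch_seed = batch_seed,
                         test_sequences = test_sequences)
    accs <- c(accs, net$test_accuracy)
    if (isTRUE(net$passed_criterion)) networks[[length(networks) + 1L]] <- net
  }
  if (length(networks) < n_keep)
    warning("only ", length(networks), " of ", n_keep,
            " networks reached criterion in ", attempt, " attempts")
  structure(list(networks = networks, n_attempted = attempt,
                 accuracies = accs),
            class = "wm_ensemble")
}

#' Record trial-aligned hidden-layer activity
#'
#' Runs the network over the sequences and slices the LSTM hidden state
#' (before readout rectification) into the 13-timestep trial windows of
#' [label_trials()]. With 200 twenty-stimulus sequences this yields the
#' standard 3200 trials (16 per sequence). Timesteps falling past the end of
#' a sequence (the third delay of each sequence's last trial) are `NA`.
#'
#' @param net A trained `wm_network`.
#' @param sequences Sequences to record from (normally the training set).
#' @param rectified If `TRUE`, record the rectified hidden state used by the
#'   readout instead of the raw hidden state.
#' @return An [activity_tensor()] with trial labels.
#' @export
record_hidden_activity <- function(net, sequences, rectified = FALSE) {
  fwd <- network_outputs(net, sequences)
  hid <- fwd$hidden                      # H x N x T
  if (rectified) hid <- pmax(hid, 0)
  n_hidden <- dim(hid)[1]
  roles <- trial_timestep_roles()
  labels <- do.call(rbind, lapply(seq_along(sequences), function(i) {
    lab <- label_trials(sequences[[i]])
    lab$sequence <- i
    lab
  }))
  tcols <- paste0("t_", roles)
  n_trials <- nrow(labels)
  values <- array(NA_real_, dim = c(n_trials, length(roles), n_hidden))
  for (j in seq_along(roles)) {
    tt <- labels[[tcols[j]]]
    ok <- !is.na(tt)
    # hid[unit, sequence, timestep] gathered into a trials x units block
    flat <- hid[cbind(rep(seq_len(n_hidden), times = sum(ok)),
                      rep(labels$sequence[ok], each = n_hidden),
                      rep(tt[ok], each = n_hidden))]
    values[ok, j, ] <- t(matrix(flat, n_hidden, sum(ok)))
  }
  activity_tensor(values,
                  labels = labels[, c("sequence", "trial", "stim_id",
                                      "probe_id", "decision")],
                  time = roles, clock = "timestep")
}

#' PCA visualization of pooled hidden activity
#'
#' Fits ordinary PCA to the hidden-state vectors pooled across all trials
#' and timesteps and returns per-trial, per-timestep coordinates in the top
#' components, plus the per-component explained-variance fractions.
#'
#' @param act An [activity_tensor()].
#' @param n_components Number of components to keep (default 2).
#' @return A list with `scores` (trials x timesteps x components),
#'   `explained` (variance fractions), `rotation`, and `center`.
#' @export
pca_visualize <- function(act, n_components = 2L) {
  stopifnot(inherits(act, "wm_activity"))
  d <- dim(act$values)
  flat <- matrix(aperm(act$values, c(1, 2, 3)), d[1] * d[2], d[3])
  ok <- stats::complete.cases(flat)
  fit <- stats::prcomp(flat[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- array(NA_real_, dim = c(d[1], d[2], n_components))
  centered <- sweep(flat, 2, fit$center)
  proj <- centered %*% fit$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) scores[, , k] <- matrix(proj[, k], d[1], d[2])
  list(scores = scores, explained = explained[seq_len(n_components)],
       rotation = fit$rotation[, seq_len(n_components), drop = FALSE],
       center = fit$center)
}
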