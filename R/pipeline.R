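#' Subspace analysis of one dataset
#'
#' The common analysis applied identically to recorded network activity and
#' EEG-like channel data: fit the UMI, PMI, and decision dPC planes at
#' their conventional windows, compute percent-variance-explained tables,
#' the three pairwise alignment angles, and the scalar-transform traces
#' through the UMI and PMI subspaces.
#'
#' @param act An [activity_tensor()].
#' @param ridge Ridge penalty passed to the dPCA fits (default 0).
#' @return A list with the three `wm_dpca` fits (`umi`, `pmi`, `dec`), a
#'   `pev` data frame, an `angles` data frame, and `traces` (list of
#'   `wm_scalar_trace` for the UMI and PMI subspaces).
#' @export
analyze_subspaces <- function(act, ridge = 0) {
  umi <- fit_stimulus_dpca(act, "UMI", ridge = ridge)
  pmi <- fit_stimulus_dpca(act, "PMI", ridge = ridge)
  dec <- fit_decision_dpca(act, ridge = ridge)
  pev <- rbind(cbind(marginalization = "UMI", umi$pev),
               cbind(marginalization = "PMI", pmi$pev),
               cbind(marginalization = "decision", dec$pev))
  al <- list(subspace_alignment(umi, dec),
             subspace_alignment(pmi, dec),
             subspace_alignment(umi, pmi))
  angles <- data.frame(
    pair = vapply(al, `[[`, character(1), "pair"),
    alignment = vapply(al, `[[`, numeric(1), "alignment"),
    angle_deg = vapply(al, `[[`, numeric(1), "angle_deg"))
  traces <- list(UMI = fit_scalar_transform(act, umi),
                 PMI = fit_scalar_transform(act, pmi))
  list(umi = umi, pmi = pmi, dec = dec, pev = pev, angles = angles,
       traces = traces)
}

#' Run a complete experiment
#'
#' Orchestrates one of the three study configurations end to end and
#' returns the report tables:
#' \describe{
#'   \item{`rnn7`}{one-hot inputs, 7 hidden units, 5000 Adam iterations.}
#'   \item{`rnn60`}{circular `[cos 2 theta, sin 2 theta]` inputs, 60 hidden
#'     units, 1500 iterations.}
#'   \item{`synthetic_eeg`}{the synthetic EEG-like generator followed by the
#'     identical subspace analysis (one "subject" per seed).}
#' }
#' For the network experiments: generates 200 training and 200 testing
#' sequences, trains networks until `n_networks` pass the 99.5% held-out
#' criterion, records hidden activity on the training sequences (3200
#' trials per network), runs [analyze_subspaces()] per network, and
#' optionally the bootstrap dispersion test on the first network. All
#' randomness derives from `seed` through per-stage seeds.
#'
#' @param experiment `"rnn7"`, `"rnn60"`, or `"synthetic_eeg"`.
#' @param n_networks Networks to train (or synthetic subjects to simulate).
#' @param seed Master seed.
#' @param n_sequences Training (and testing) sequences per set.
#' @param config Optional `wm_train_config` override.
#' @param synth_config Optional [synthetic_config()] override.
#' @param dispersion_n_boot Bootstrap draws for the dispersion test; 0
#'   skips it.
#' @param max_attempts Training attempts allowed while collecting
#'   `n_networks` passing networks (default `4 * n_networks`; not every
#'   initialization reaches criterion).
#' @param out_dir If non-`NULL`, the report tables are written there as CSV.
#' @return A list of class `wm_report`: `experiment`, `seq_stats`,
#'   `accuracies`, `pev`, `pev_summary`, `angles`, `angle_summary`,
#'   `traces` (per-timepoint mean, SD, SEM of the scalar transform),
#'   `dispersion`, and `per_network` (the raw analyses).
#' @export
run_experiment <- function(experiment = c("rnn7", "rnn60", "synthetic_eeg"),
                           n_networks = 10L, seed = 1L,
                           n_sequences = 200L, config = NULL,
                           synth_config = NULL,
                           dispersion_n_boot = 2000L,
                           max_attempts = 4L * n_networks, out_dir = NULL) {
  experiment <- match.arg(experiment)
  set.seed(seed)
  stage_seed <- sample.int(2147483646L, 6L)

  if (experiment == "synthetic_eeg") {
    if (is.null(synth_config)) synth_config <- synthetic_config()
    analyses <- lapply(seq_len(n_networks), function(i)
      analyze_subspaces(generate_synthetic_dataset(
        synth_config, seed = stage_seed[1] %% 100000L + i)$act))
    report <- assemble_report(experiment, analyses, seq_stats = NULL,
                              accuracies = NULL, dispersion = NULL)
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  scheme <- if (experiment == "rnn7") encoding_scheme("one_hot_6") else
    encoding_scheme("circular_2")
  n_hidden <- if (experiment == "rnn7") 7L else 60L
  if (is.null(config)) config <- training_config(n_hidden = n_hidden)

  set.seed(stage_seed[1])
  train_seqs <- generate_sequences(n_sequences)
  set.seed(stage_seed[2])
  test_seqs <- generate_sequences(n_sequences)
  seq_stats <- data.frame(
    set = c("train", "test"),
    mean_matches = c(sequence_match_stats(train_seqs)$mean,
                     sequence_match_stats(test_seqs)$mean),
    sd_matches = c(sequence_match_stats(train_seqs)$sd,
                   sequence_match_stats(test_seqs)$sd))

  ens <- train_ensemble(n_networks, train_seqs, scheme, config,
                        test_sequences = test_seqs,
                        first_init_seed = stage_seed[3] %% 100000L,
                        batch_seed = stage_seed[4],
                        max_attempts = max_attempts)
  accuracies <- data.frame(attempt = seq_along(ens$accuracies),
                           accuracy = ens$accuracies,
                           passed = ens$accuracies >= 0.995)

  analyses <- lapply(ens$networks, function(net)
    analyze_subspaces(record_hidden_activity(net, train_seqs)))

  dispersion <- NULL
  if (dispersion_n_boot > 0 && length(ens$networks)) {
    act1 <- record_hidden_activity(ens$networks[[1]], train_seqs)
    dispersion <- bootstrap_dispersion_test(
      act1, n_boot = dispersion_n_boot, seed = stage_seed[5])
  }

  report <- assemble_report(experiment, analyses, seq_stats, accuracies,
                            dispersion)
  report$ensemble <- ens
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Aggregate per-network analyses into the report tables.
assemble_report <- function(experiment, analyses, seq_stats, accuracies,
                            dispersion) {
  pev <- do.call(rbind, lapply(seq_along(analyses), function(i)
    cbind(network = i, analyses[[i]]$pev)))
  pev_summary <- stats::aggregate(
    cbind(cum_stimulus, cum_global) ~ marginalization + component,
    data = pev, FUN = mean)
  angles <- do.call(rbind, lapply(seq_along(analyses), function(i)
    cbind(network = i, analyses[[i]]$angles)))
  angle_summary <- merge(
    stats::aggregate(angle_deg ~ pair, data = angles, FUN = mean),
    stats::aggregate(angle_deg ~ pair, data = angles, FUN = stats::sd),
    by = "pair", suffixes = c("_mean", "_sd"))
  traces <- lapply(c(UMI = "UMI", PMI = "PMI"), function(sub) {
    k <- do.call(rbind, lapply(analyses, function(a) a$traces[[sub]]$k_hat))
    data.frame(time = names(analyses[[1]]$traces[[sub]]$k_hat),
               mean = colMeans(k),
               sd = apply(k, 2, stats::sd),
               sem = apply(k, 2, stats::sd) / sqrt(nrow(k)),
               row.names = NULL)
  })
  structure(list(experiment = experiment, seq_stats = seq_stats,
                 accuracies = accuracies, pev = pev,
                 pev_summary = pev_summary, angles = angles,
                 angle_summary = angle_summary, traces = traces,
                 dispersion = dispersion, per_network = analyses),
            class = "wm_report")
}

#' @export
print.wm_report <- function(x, ...) {
  cat("experiment:", x$experiment, "\n")
  if (!is.null(x$seq_stats)) {
    cat("\nsequence match counts:\n")
    print(x$seq_stats, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$accuracies))
    cat(sprintf("\nnetworks: %d passing of %d attempted (accuracy %.4f-%.4f)\n",
                sum(x$accuracies$passed), nrow(x$accuracies),
                min(x$accuracies$accuracy), max(x$accuracies$accuracy)))
  cat("\ncumulative PEV (ensemble means):\n")
  print(x$pev_summary, row.names = FALSE, digits = 4)
  cat("\nsubspace angles (deg):\n")
  print(x$angle_summary, row.names = FALSE, digits = 4)
  invisible(x)
}

# Write the canonical CSV tables of a report.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$seq_stats, "sequence_stats.csv")
  w(report$accuracies, "accuracies.csv")
  w(report$pev, "pev.csv")
  w(report$pev_summary, "pev_summary.csv")
  w(report$angles, "angles.csv")
  w(report$angle_summary, "angle_summary.csv")
  for (sub in names(report$traces))
    w(report$traces[[sub]], paste0("scalar_trace_", sub, ".csv"))
  if (!is.null(report$dispersion))
    w(report$dispersion$tests, "dispersion_tests.csv")
  invisible(out_dir)
}
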