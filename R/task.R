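#' Generate a random 2-back stimulus sequence
#'
#' Draws stimulus identities i.i.d. uniformly from `1:n_identities` and
#' rejects whole sequences until the number of 2-back matches reaches
#' `min_matches`. A position `p` (for `p >= 3`) is a match when
#' `identities[p] == identities[p - 2]`, so a sequence of length `S` has
#' `S - 2` eligible positions. The rejection constraint mimics the roughly
#' 1:2 match:non-match ratio of the human 2-back task.
#'
#' @param n_stimuli Sequence length (20 for the standard network blocks).
#' @param n_identities Number of distinct stimulus identities (default 6).
#' @param min_matches Minimum number of 2-back matches required (default 5).
#' @param max_attempts Cap on whole-sequence resampling before giving up.
#' @return An object of class `wm_sequence`: a list with `identities`
#'   (integer vector), `match_flags` (logical, `NA` for positions 1-2), and
#'   `n_match` (count of matches over the eligible positions).
#' @examples
#' set.seed(1)
#' seq <- generate_sequence(20, 6, 5)
#' seq$n_match
#' @export
generate_sequence <- function(n_stimuli = 20L, n_identities = 6L,
                              min_matches = 5L, max_attempts = 10000L) {
  stopifnot(n_stimuli >= 3L, n_identities >= 2L, min_matches >= 0L)
  for (attempt in seq_len(max_attempts)) {
    ids <- sample.int(n_identities, n_stimuli, replace = TRUE)
    flags <- match_flags(ids)
    n_match <- sum(flags, na.rm = TRUE)
    if (n_match >= min_matches) {
      return(structure(
        list(identities = ids, match_flags = flags, n_match = n_match),
        class = "wm_sequence"))
    }
  }
  stop("no sequence with >= ", min_matches, " matches found in ",
       max_attempts, " attempts; constraint may be infeasible")
}

#' @rdname generate_sequence
#' @param n Number of sequences to generate.
#' @return `generate_sequences()` returns a list of `wm_sequence` objects.
#' @export
generate_sequences <- function(n, n_stimuli = 20L, n_identities = 6L,
                               min_matches = 5L, max_attempts = 10000L) {
  replicate(n, generate_sequence(n_stimuli, n_identities, min_matches,
                                 max_attempts),
            simplify = FALSE)
}

# 2-back match indicator; NA for the first two positions (no 2-back item).
match_flags <- function(identities) {
  n <- length(identities)
  flags <- rep(NA, n)
  if (n >= 3L) flags[3:n] <- identities[3:n] == identities[1:(n - 2L)]
  flags
}

#' @export
print.wm_sequence <- function(x, ...) {
  cat("2-back sequence:", paste(x$identities, collapse = " "), "\n")
  cat("matches:", x$n_match, "\n")
  invisible(x)
}

#' Stimulus input encoding schemes
#'
#' Three encodings of the six stimulus identities used as network input:
#' \describe{
#'   \item{`one_hot_6`}{six input units, unit `s` active for stimulus `s`.}
#'   \item{`circular_2`}{two input units carrying `[cos 2 theta, sin 2 theta]`
#'     for the grating orientation `theta` assigned to the identity
#'     (10, 40, 70, 100, 130, 160 degrees). Doubling the angle matches the
#'     180-degree periodicity of oriented gratings, so `theta` and
#'     `theta + 180` encode identically.}
#'   \item{`basis_sin6`}{six units following the inverted-encoding-model
#'     basis `sin^6`, i.e. unit `j`'s response to stimulus `s` is
#'     `sin(pi/2 + (j - s) * pi/6)^6`, giving a graded tuning curve peaking
#'     at the presented identity.}
#' }
#'
#' @param kind One of `"one_hot_6"`, `"circular_2"`, `"basis_sin6"`.
#' @param angles Orientation values in degrees, one per identity
#'   (`circular_2` only).
#' @return A list of class `wm_encoding` with fields `kind`, `n_input`, and
#'   (for `circular_2`) `angles`.
#' @export
encoding_scheme <- function(kind = c("one_hot_6", "circular_2", "basis_sin6"),
                            angles = c(10, 40, 70, 100, 130, 160)) {
  kind <- match.arg(kind)
  n_input <- if (kind == "circular_2") 2L else 6L
  structure(list(kind = kind, n_input = n_input, angles = angles),
            class = "wm_encoding")
}

# Encoded input vector for a single stimulus identity.
encode_stimulus <- function(identity, scheme) {
  switch(scheme$kind,
    one_hot_6 = {
      v <- numeric(6)
      v[identity] <- 1
      v
    },
    circular_2 = {
      theta <- scheme$angles[identity] * pi / 180
      c(cos(2 * theta), sin(2 * theta))
    },
    basis_sin6 = {
      j <- seq_len(6)
      sin(pi / 2 + (j - identity) * pi / 6)^6
    },
    stop("unknown encoding scheme: ", scheme$kind))
}

#' Encode a stimulus sequence as a timestep-level network input
#'
#' Expands a stimulus sequence into per-timestep input vectors and targets.
#' Each stimulus presentation occupies one timestep and is followed by two
#' all-zero "delay" timesteps; no delay follows the last stimulus, so a
#' sequence of `S` stimuli spans `3 * (S - 1) + 1` timesteps. The target is 1
#' at the presentation timestep of a 2-back match, and 0 at every other
#' timestep (delays, and the first two presentations, which have no 2-back
#' comparison).
#'
#' @param seq A `wm_sequence` from [generate_sequence()].
#' @param scheme A `wm_encoding` from [encoding_scheme()].
#' @return A list of class `wm_encoded` with `inputs` (timesteps x n_input
#'   matrix), `targets` (numeric vector), `roles` (`"stim"`, `"delay1"`,
#'   `"delay2"` per timestep), `stim_timesteps` (timestep index of each
#'   presentation), and `n_timesteps`.
#' @export
encode_sequence <- function(seq, scheme) {
  stopifnot(inherits(seq, "wm_sequence"), inherits(scheme, "wm_encoding"))
  S <- length(seq$identities)
  n_t <- 3L * (S - 1L) + 1L
  stim_t <- 3L * (seq_len(S) - 1L) + 1L
  inputs <- matrix(0, nrow = n_t, ncol = scheme$n_input)
  targets <- numeric(n_t)
  roles <- character(n_t)
  roles[stim_t] <- "stim"
  roles[stim_t[-S] + 1L] <- "delay1"
  roles[stim_t[-S] + 2L] <- "delay2"
  for (p in seq_len(S)) {
    inputs[stim_t[p], ] <- encode_stimulus(seq$identities[p], scheme)
    if (p >= 3L && isTRUE(seq$match_flags[p])) targets[stim_t[p]] <- 1
  }
  structure(list(inputs = inputs, targets = targets, roles = roles,
                 stim_timesteps = stim_t, n_timesteps = n_t),
            class = "wm_encoded")
}

#' Trial labels and timestep windows for a sequence
#'
#' A "stimulus event" is one presentation plus its two delay timesteps; a
#' "trial" tracks item `n` across two consecutive events, over which it
#' transitions from probe (at its own presentation, compared against
#' `n - 2`) to unprioritized memory item (UMI, during the first delay) to
#' prioritized memory item (PMI, during the second delay), ending with the
#' `n`-vs-`n + 2` decision at the presentation of `n + 2`. Of the 18 trials
#' in a 20-stimulus sequence only 16 are analyzed: trials starting at the
#' first two presentations are dropped because those positions have no
#' 2-back decision of their own.
#'
#' The returned window spans 13 timesteps per trial: the three timesteps
#' preceding the presentation of `n` (the previous stimulus event, used as a
#' no-information baseline by the dispersion test), the 9-timestep core
#' (`n`, `d1:1`, `d1:2`, `n+1`, `d2:1`, `d2:2`, `n+2`, `d3:1`, `d3:2`), and
#' the presentation of `n + 3`. Indices past the end of the sequence (the
#' last trial has no third delay) are `NA`.
#'
#' @param seq A `wm_sequence`.
#' @return A data frame with one row per analyzed trial: `trial` (index of
#'   stimulus `n`), `stim_id` (identity of `n`; the UMI and, later, PMI
#'   condition), `probe_id` (identity of `n + 2`), `decision` (`"match"` or
#'   `"nonmatch"` for the `n`-vs-`n + 2` comparison), and one `t_*` column
#'   of timestep indices per window position.
#' @export
label_trials <- function(seq) {
  stopifnot(inherits(seq, "wm_sequence"))
  S <- length(seq$identities)
  stopifnot(S >= 5L)
  n_t <- 3L * (S - 1L) + 1L
  stim_t <- 3L * (seq_len(S) - 1L) + 1L
  trials <- 3:(S - 2L)
  offsets <- -3:9
  win <- outer(stim_t[trials], offsets, `+`)
  win[win > n_t] <- NA_integer_
  colnames(win) <- paste0("t_", trial_timestep_roles())
  probe <- seq$identities[trials + 2L]
  out <- data.frame(
    trial = trials,
    stim_id = seq$identities[trials],
    probe_id = probe,
    decision = ifelse(probe == seq$identities[trials], "match", "nonmatch"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(win))
}

# Canonical role names for the 13 timesteps of a trial window.
trial_timestep_roles <- function() {
  c("pre1", "pre2", "pre3",
    "n", "d1.1", "d1.2", "n1", "d2.1", "d2.2", "n2", "d3.1", "d3.2", "n3")
}

#' Match-count statistics of a set of sequences
#'
#' @param seqs List of `wm_sequence` objects.
#' @return A list with `mean`, `sd`, and the per-sequence counts `n_match`.
#' @export
sequence_match_stats <- function(seqs) {
  counts <- vapply(seqs, function(s) s$n_match, numeric(1))
  list(mean = mean(counts), sd = stats::sd(counts), n_match = counts)
}

#' Write sequences to CSV
#'
#' One row per sequence: `seq` index, identities as a dash-separated string,
#' and the match count. [read_sequences_csv()] inverts the format.
#'
#' @param seqs List of `wm_sequence` objects.
#' @param path Output file.
#' @export
write_sequences_csv <- function(seqs, path) {
  df <- data.frame(
    seq = seq_along(seqs),
    identities = vapply(seqs, function(s) paste(s$identities, collapse = "-"),
                        character(1)),
    n_match = vapply(seqs, function(s) s$n_match, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @export
read_sequences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ids <- as.integer(strsplit(df$identities[i], "-", fixed = TRUE)[[1]])
    flags <- match_flags(ids)
    structure(list(identities = ids, match_flags = flags,
                   n_match = sum(flags, na.rm = TRUE)),
              class = "wm_sequence")
  })
}
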