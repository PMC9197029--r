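#' Trial-aligned population activity tensor
#'
#' The common container for recorded network activity and EEG-like channel
#' data: a `trials x timepoints x units` array plus per-trial labels. The
#' time axis is either a set of named task timesteps (`clock = "timestep"`,
#' e.g. `"d1.2"`) or a millisecond grid of bin left edges relative to the
#' onset of stimulus `n + 1` (`clock = "ms"`).
#'
#' @param values Numeric array, `trials x timepoints x units`. `NA` marks
#'   timepoints absent for a trial (e.g. the third delay of a sequence's
#'   last trial).
#' @param labels Data frame with one row per trial; must contain `stim_id`
#'   (the identity of item `n`, which is the condition for both the UMI and
#'   the PMI marginalizations), and for decision analyses `probe_id` and
#'   `decision`.
#' @param time Character timestep roles, or numeric ms bin left edges.
#' @param clock `"timestep"` or `"ms"`.
#' @return An object of class `wm_activity`.
#' @export
activity_tensor <- function(values, labels, time, clock = c("timestep", "ms")) {
  clock <- match.arg(clock)
  stopifnot(length(dim(values)) == 3L,
            nrow(labels) == dim(values)[1],
            length(time) == dim(values)[2])
  structure(list(values = values, labels = labels, time = time,
                 clock = clock),
            class = "wm_activity")
}

#' @export
print.wm_activity <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("activity tensor: %d trials x %d timepoints x %d units (%s clock)\n",
              d[1], d[2], d[3], x$clock))
  invisible(x)
}

#' Time-window specification
#'
#' Windows on the trial clock: for timestep data a set of role names (e.g.
#' `"d1.2"`); for ms data a half-open interval `[a, b)` of bin left edges,
#' 0-referenced to stimulus `n + 1` onset.
#'
#' @param roles Character timestep roles (timestep clock).
#' @param bounds Numeric `c(a, b)` in ms (ms clock).
#' @export
window_spec <- function(roles = NULL, bounds = NULL) {
  stopifnot(xor(is.null(roles), is.null(bounds)))
  structure(list(roles = roles, bounds = bounds), class = "wm_window")
}

# Index of the timepoints a window retains.
window_index <- function(act, window) {
  if (is.null(window)) return(seq_along(act$time))
  if (inherits(window, "wm_window")) {
    if (!is.null(window$roles)) {
      stopifnot(act$clock == "timestep")
      idx <- match(window$roles, act$time)
      if (anyNA(idx)) stop("unknown timestep role(s): ",
                           paste(window$roles[is.na(idx)], collapse = ", "))
      return(idx)
    }
    stopifnot(act$clock == "ms")
    idx <- which(act$time >= window$bounds[1] & act$time < window$bounds[2])
    if (!length(idx)) stop("window [", window$bounds[1], ", ",
                           window$bounds[2], ") contains no timepoints")
    return(idx)
  }
  # raw role names or indices are accepted for convenience
  if (is.character(window)) return(window_index(act, window_spec(roles = window)))
  as.integer(window)
}

#' Restrict an activity tensor to a time window
#'
#' @param act An [activity_tensor()].
#' @param window A [window_spec()], character roles, or timepoint indices.
#' @export
slice_window <- function(act, window) {
  idx <- window_index(act, window)
  activity_tensor(act$values[, idx, , drop = FALSE], act$labels,
                  act$time[idx], act$clock)
}

#' Marginalized condition averages
#'
#' Trial-averages the activity by condition inside a window, producing the
#' quantities the demixed-PCA losses are written in: the per-condition,
#' per-timepoint means `x_ts`, their time average `x_bar_s`, the
#' across-condition mean per timepoint `x_bar_t`, and the global mean
#' `x_bar`. The global mean is always taken over *all* trials and *all*
#' timepoints of the tensor (not just the window), pooling every non-missing
#' sample.
#'
#' For `factor = "decision"` the conditions are the crossing of the probe
#' identity with the match/non-match decision; cells whose probe condition
#' lacks one of the two decisions are dropped with a warning.
#'
#' @param act An [activity_tensor()].
#' @param factor `"stimulus"` (conditions = `stim_id`) or `"decision"`.
#' @param window Window to average within (default: all timepoints).
#' @return For `"stimulus"`: a list of class `wm_marginal` with `x_ts`
#'   (units x conditions x timepoints), `x_bar_s`, `x_bar_t`, `x_bar`,
#'   `conditions`, `time`. For `"decision"`: additionally `x_tsd`
#'   (units x conditions x 2 x timepoints) and `x_bar_ts` (the per-cell mean
#'   over the two decisions); `x_ts` then holds the decision-averaged cells.
#' @export
condition_average <- function(act, factor = c("stimulus", "decision"),
                              window = NULL) {
  factor <- match.arg(factor)
  stopifnot(inherits(act, "wm_activity"))
  idx <- window_index(act, window)
  d <- dim(act$values)
  n_units <- d[3]
  global <- global_mean(act)

  if (factor == "stimulus") {
    cond <- sort(unique(act$labels$stim_id))
    if (length(cond) < 2L) stop("need >= 2 stimulus conditions")
    x_ts <- array(NA_real_, dim = c(n_units, length(cond), length(idx)))
    for (ci in seq_along(cond)) {
      rows <- act$labels$stim_id == cond[ci]
      if (!any(rows)) stop("no trials for condition ", cond[ci])
      for (tj in seq_along(idx)) {
        block <- act$values[rows, idx[tj], , drop = FALSE]
        x_ts[, ci, tj] <- colMeans(matrix(block, sum(rows), n_units),
                                   na.rm = TRUE)
      }
    }
    if (anyNA(x_ts)) stop("a condition has no finite samples in the window")
    out <- list(x_ts = x_ts,
                x_bar_s = apply(x_ts, c(1, 2), mean),
                x_bar_t = apply(x_ts, c(1, 3), mean),
                x_bar = global,
                conditions = cond, time = act$time[idx], factor = factor)
    return(structure(out, class = "wm_marginal"))
  }

  stopifnot(all(c("probe_id", "decision") %in% names(act$labels)))
  cond <- sort(unique(act$labels$probe_id))
  decs <- c("match", "nonmatch")
  keep <- logical(length(cond))
  for (ci in seq_along(cond)) {
    have <- vapply(decs, function(dd)
      any(act$labels$probe_id == cond[ci] & act$labels$decision == dd),
      logical(1))
    keep[ci] <- all(have)
  }
  if (!all(keep)) {
    warning("dropping probe condition(s) missing a decision class: ",
            paste(cond[!keep], collapse = ", "))
    cond <- cond[keep]
  }
  if (length(cond) < 1L) stop("no probe condition has both decision classes")
  x_tsd <- array(NA_real_, dim = c(n_units, length(cond), 2L, length(idx)))
  for (ci in seq_along(cond)) for (di in 1:2) {
    rows <- act$labels$probe_id == cond[ci] & act$labels$decision == decs[di]
    for (tj in seq_along(idx)) {
      block <- act$values[rows, idx[tj], , drop = FALSE]
      x_tsd[, ci, di, tj] <- colMeans(matrix(block, sum(rows), n_units),
                                      na.rm = TRUE)
    }
  }
  x_bar_ts <- (x_tsd[, , 1, , drop = FALSE] + x_tsd[, , 2, , drop = FALSE]) / 2
  dim(x_bar_ts) <- dim(x_tsd)[c(1, 2, 4)]
  structure(list(x_tsd = x_tsd, x_bar_ts = x_bar_ts, x_ts = x_bar_ts,
                 x_bar = global, conditions = cond, decisions = decs,
                 time = act$time[idx], factor = factor),
            class = "wm_marginal")
}

# Global mean over all trials and timepoints, pooling non-missing samples.
global_mean <- function(act) {
  d <- dim(act$values)
  flat <- matrix(act$values, d[1] * d[2], d[3])
  colMeans(flat, na.rm = TRUE)
}
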