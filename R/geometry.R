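#' Scalar-transform trace of representational dynamics
#'
#' At every timepoint `t`, finds the scalar `k` best mapping the reference
#' early-delay stimulus geometry onto the current geometry inside a fixed
#' 2-D dPC subspace:
#' `k_t = argmin_k sum_s || W'(x_ts - x_bar_t) - k W'(xbar_s - xbar) ||^2`,
#' with closed form `k_t = sum_s <a_ts, b_s> / sum_s ||b_s||^2`, where
#' `a_ts = W'(x_ts - x_bar_t)`, `b_s = W'(xbar_s - xbar)`. The reference
#' `xbar_s` is the per-condition activity averaged over the first half of
#' the first delay (timestep `d1.1`, or [-2800, -1400) ms), i.e. the item's
#' early UMI representation, and `x_bar_t` is the across-condition mean at
#' `t`, so the trace tracks only the relational geometry of the stimuli.
#' `k` near 1 means the code is unchanged; a sign reversal means the
#' stimulus-activity mapping has flipped.
#'
#' @param act An [activity_tensor()].
#' @param res A `wm_dpca` fit (UMI or PMI) supplying `W` and `x_bar`.
#' @param reference_window Window defining `xbar_s` (default: first half of
#'   the first delay on the tensor's clock).
#' @param trace_window Timepoints to trace over (default: stimulus `n`
#'   through the end of the second delay for timestep data; the whole trial
#'   for ms data).
#' @return A `wm_scalar_trace`: `k_hat` (named per timepoint), `time`,
#'   `zero_crossing` (first timepoint at which the sign flips at or after
#'   the trace's peak, `NA` if none), and for ms data
#'   `zero_crossing_interp` (linear interpolation of that crossing).
#' @export
fit_scalar_transform <- function(act, res,
                                 reference_window = NULL,
                                 trace_window = NULL) {
  stopifnot(inherits(act, "wm_activity"), inherits(res, "wm_dpca"))
  if (is.null(reference_window))
    reference_window <- if (act$clock == "timestep")
      window_spec(roles = "d1.1") else window_spec(bounds = c(-2800, -1400))
  if (is.null(trace_window))
    trace_window <- if (act$clock == "timestep")
      window_spec(roles = c("n", "d1.1", "d1.2", "n1", "d2.1", "d2.2")) else
      window_spec(bounds = c(-2800, 3551))
  ref <- condition_average(act, "stimulus", reference_window)
  b <- t(res$W) %*% (ref$x_bar_s - res$x_bar)      # 2 x S
  denom <- sum(b * b)
  if (denom < 1e-300) stop("all-zero reference projections; scale undefined")
  marg <- condition_average(act, "stimulus", trace_window)
  n_time <- length(marg$time)
  k_hat <- numeric(n_time)
  for (tj in seq_len(n_time)) {
    x_t <- marg$x_ts[, , tj, drop = TRUE]          # units x S
    a <- t(res$W) %*% (x_t - marg$x_bar_t[, tj])
    k_hat[tj] <- sum(a * b) / denom
  }
  names(k_hat) <- as.character(marg$time)
  # zero crossing: the first sign change at or after the trace's peak, so
  # that near-zero jitter before the representation is established (e.g.
  # the ramp-in at the start of an ms-resolution trial) is ignored
  peak <- which.max(k_hat)
  sgn <- sign(k_hat)
  flip <- which(sgn[-1] * sgn[-n_time] < 0)
  flip <- flip[flip >= peak]
  zc <- if (length(flip)) marg$time[flip[1] + 1] else NA
  zc_interp <- NA_real_
  if (length(flip) && act$clock == "ms") {
    i <- flip[1]
    t0 <- as.numeric(marg$time[i]); t1 <- as.numeric(marg$time[i + 1])
    zc_interp <- t0 + (t1 - t0) * k_hat[i] / (k_hat[i] - k_hat[i + 1])
  }
  structure(list(k_hat = k_hat, time = marg$time, subspace = res$role,
                 zero_crossing = zc, zero_crossing_interp = zc_interp),
            class = "wm_scalar_trace")
}

#' @export
print.wm_scalar_trace <- function(x, ...) {
  cat(sprintf("scalar transform trace (%s subspace):\n", x$subspace))
  print(round(x$k_hat, 3))
  cat("zero crossing:", as.character(x$zero_crossing), "\n")
  invisible(x)
}

#' Alignment angle between two dPC subspaces
#'
#' The product-of-cosines alignment between corresponding unit-norm encoder
#' columns, `|v1a . v1b| * |v2a . v2b|`, mapped to an angle by the inverse
#' cosine. 0 degrees means the component pairs are parallel, 90 degrees
#' that at least one pair is orthogonal. The metric is symmetric and
#' invariant to sign flips of any encoder column.
#'
#' @param a,b `wm_dpca` fits in the same activity space.
#' @return A list with `alignment` (in `[0, 1]`), `angle_deg`, and `pair`.
#' @export
subspace_alignment <- function(a, b) {
  stopifnot(inherits(a, "wm_dpca"), inherits(b, "wm_dpca"))
  if (nrow(a$V) != nrow(b$V))
    stop("dimension mismatch between subspaces")
  alignment <- abs(sum(a$V[, 1] * b$V[, 1])) * abs(sum(a$V[, 2] * b$V[, 2]))
  alignment <- min(max(alignment, 0), 1)
  list(alignment = alignment,
       angle_deg = acos(alignment) * 180 / pi,
       pair = paste(a$role, b$role, sep = "-"))
}

#' Principal angles between two fitted planes
#'
#' Internal diagnostic complementing [subspace_alignment()]: the principal
#' angles between the column spaces of the two encoders, which are
#' basis-invariant (the product-of-cosines metric is not). Used to validate
#' recovery of planted subspaces on synthetic data.
#'
#' @param Va,Vb Matrices with orthonormal columns (or `wm_dpca` fits).
#' @return Principal angles in degrees, ascending.
#' @export
principal_angles <- function(Va, Vb) {
  if (inherits(Va, "wm_dpca")) Va <- Va$V
  if (inherits(Vb, "wm_dpca")) Vb <- Vb$V
  qa <- qr.Q(qr(Va)); qb <- qr.Q(qr(Vb))
  sv <- svd(t(qa) %*% qb)$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}

#' Dispersion of projected condition means
#'
#' The variance across the (six) stimulus condition trial-averages projected
#' into a dPC subspace at one timepoint, summed over the two projection
#' dimensions -- a proxy for stimulus discriminability in that subspace.
#' Variance uses the sample (n - 1) denominator.
#'
#' @param act An [activity_tensor()].
#' @param res A `wm_dpca` fit (typically the PMI subspace).
#' @param timepoint A single timepoint: role name, ms window, or index.
#' @export
dispersion <- function(act, res, timepoint) {
  marg <- condition_average(act, "stimulus", timepoint)
  if (length(marg$conditions) < 2L) stop("need >= 2 conditions")
  stopifnot(length(marg$time) == 1L)
  z <- t(res$W) %*% (marg$x_ts[, , 1] - res$x_bar)   # 2 x S
  sum(apply(z, 1, stats::var))
}

# dispersion from an already-projected 2 x S matrix of condition means
dispersion_from_proj <- function(z) sum(apply(z, 1, stats::var))

#' Bootstrap test for the presence of stimulus information
#'
#' Builds an empirical null for the dispersion of stimulus condition means
#' in the PMI subspace from baseline timepoints at which no information
#' about the item can exist (the three timepoints preceding its
#' presentation). Each bootstrap iteration resamples trials with
#' replacement within each stimulus condition, refits the PMI dPCA on the
#' resampled data (same window, global mean recomputed from the resample),
#' computes the dispersion of the resampled condition means at each baseline
#' timepoint, and records the maximum over the baseline timepoints --
#' a conservative null. A test timepoint is declared to carry stimulus
#' information when its observed dispersion (under the full-data fit)
#' exceeds the null's `1 - alpha` quantile (one-tailed).
#'
#' @param act An [activity_tensor()].
#' @param pmi_window Window for the PMI dPCA fit (default per clock).
#' @param baseline_timepoints Roles/indices of the (three) pre-stimulus
#'   baseline timepoints (default `c("pre1", "pre2", "pre3")`).
#' @param test_timepoints Roles/indices of the timepoints to test (default:
#'   the timesteps after the item's last use: `d3.1`, `d3.2`, `n3`).
#' @param n_boot Bootstrap iterations (10000 for reported results).
#' @param alpha One-tailed level (default 0.05).
#' @param seed RNG seed for the resampling.
#' @return A `wm_dispersion_test`: `null_distribution`, `criterion`, and a
#'   data frame `tests` with per-timepoint dispersion and decision.
#' @export
bootstrap_dispersion_test <- function(act, pmi_window = NULL,
                                      baseline_timepoints = c("pre1", "pre2", "pre3"),
                                      test_timepoints = c("d3.1", "d3.2", "n3"),
                                      n_boot = 10000L, alpha = 0.05,
                                      seed = 1L) {
  stopifnot(inherits(act, "wm_activity"))
  if (n_boot < 100L) warning("n_boot < 100 gives an unstable percentile")
  if (is.null(pmi_window)) pmi_window <- default_window(act, "PMI")
  fit_idx <- window_index(act, pmi_window)
  base_idx <- window_index(act, baseline_timepoints)
  test_idx <- window_index(act, test_timepoints)

  full_fit <- fit_stimulus_dpca(act, "PMI", window = pmi_window)
  observed <- vapply(test_idx, function(i) dispersion(act, full_fit, i),
                     numeric(1))

  # Precompute per-trial summaries so each bootstrap refit only needs
  # grouped means: time-summed activity (for the resampled global mean) and
  # the trial-by-unit slices at the fit and baseline timepoints.
  d <- dim(act$values)
  n_units <- d[3]
  tsum <- apply(act$values, c(1, 3), sum, na.rm = TRUE)
  tcnt <- rowSums(!is.na(act$values[, , 1, drop = TRUE]))
  slices <- lapply(c(fit_idx, base_idx), function(i)
    matrix(act$values[, i, ], d[1], n_units))
  names(slices) <- as.character(c(fit_idx, base_idx))

  cond <- sort(unique(act$labels$stim_id))
  rows_by_cond <- lapply(cond, function(cc) which(act$labels$stim_id == cc))
  if (any(vapply(rows_by_cond, length, integer(1)) < 2L))
    stop("each condition needs >= 2 trials for resampling")
  n_fit <- length(fit_idx)

  set.seed(seed)
  null_dist <- numeric(n_boot)
  for (bb in seq_len(n_boot)) {
    idx <- unlist(lapply(rows_by_cond, function(r)
      r[sample.int(length(r), length(r), replace = TRUE)]))
    n_per <- vapply(rows_by_cond, length, integer(1))
    grp <- rep(seq_along(cond), times = n_per)
    x_bar <- colSums(tsum[idx, , drop = FALSE]) / sum(tcnt[idx])
    # condition means at the fit timepoints -> refit the PMI plane
    cm <- lapply(seq_len(n_fit), function(j)
      t(rowsum(slices[[j]][idx, , drop = FALSE], grp) / n_per))
    Xc <- do.call(cbind, cm) - x_bar
    x_bar_s <- Reduce(`+`, cm) / n_fit
    Y <- matrix(rep(x_bar_s - x_bar, times = n_fit), nrow = n_units)
    fit <- rrr_fit(Y, Xc, rank = 2L)
    disp <- vapply(seq_along(base_idx), function(j) {
      m <- t(rowsum(slices[[n_fit + j]][idx, , drop = FALSE], grp) / n_per)
      dispersion_from_proj(t(fit$W) %*% (m - x_bar))
    }, numeric(1))
    null_dist[bb] <- max(disp)
  }
  criterion <- stats::quantile(null_dist, 1 - alpha, names = FALSE)
  tests <- data.frame(timepoint = as.character(act$time[test_idx]),
                      dispersion = observed,
                      information = observed > criterion)
  structure(list(null_distribution = null_dist, criterion = criterion,
                 alpha = alpha, tests = tests,
                 baseline = as.character(act$time[base_idx])),
            class = "wm_dispersion_test")
}

#' @export
print.wm_dispersion_test <- function(x, ...) {
  cat(sprintf("bootstrap dispersion test (%d draws, alpha = %.2f)\n",
              length(x$null_distribution), x$alpha))
  cat(sprintf("null 95th-percentile criterion: %.4g\n", x$criterion))
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
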