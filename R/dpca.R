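# Moore-Penrose pseudoinverse with a relative singular-value cutoff.
# Single-timepoint fits on few conditions are exactly rank-deficient, so a
# hard cutoff (default 1e-10 relative) keeps the solution stable.
pinv <- function(x, rel_tol = 1e-10) {
  sv <- svd(x)
  keep <- sv$d > rel_tol * max(sv$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

# Reduced-rank regression: minimize ||Y - V W' X||_F^2 over rank-r (V, W),
# columns of Y and X being samples. Closed form: the ordinary least-squares
# map B = Y X^+ followed by rank truncation via the SVD of the fitted values
# B X. The encoder V gets the top-r left singular vectors (unit norm by
# construction) and the decoder W = B' V absorbs the scale. Optional ridge
# replaces X^+ by X'(XX' + lambda I)^{-1} for noisy data.
rrr_fit <- function(Y, X, rank = 2L, ridge = 0, rel_tol = 1e-10) {
  stopifnot(nrow(Y) == nrow(X), ncol(Y) == ncol(X))
  if (ridge > 0) {
    G <- X %*% t(X)
    diag(G) <- diag(G) + ridge
    B <- Y %*% t(X) %*% solve(G)
  } else {
    B <- Y %*% pinv(X, rel_tol)
  }
  fitted <- B %*% X
  sv <- svd(fitted)
  # if the marginalized variance supports fewer than `rank` directions the
  # remaining encoder columns are an (orthonormal) arbitrary complement
  # with near-zero decoder weight
  V <- sv$u[, seq_len(rank), drop = FALSE]
  W <- t(B) %*% V
  list(V = V, W = W, B = B)
}

# Sum over columns of squared norms.
ss <- function(M) sum(M * M)

# Objective of the reduced-rank problem for a candidate (V, W).
rrr_objective <- function(Y, X, V, W) ss(Y - V %*% t(W) %*% X)

# Deterministic sign convention: make each encoder column's
# largest-magnitude coordinate positive, flipping the decoder jointly.
fix_signs <- function(V, W) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      W[, j] <- -W[, j]
    }
  }
  list(V = V, W = W)
}

# Percent-variance-explained table for a fitted (V, W): per component and
# cumulative, against the raw centered data (global) and the marginalized
# targets (marginal).
pev_table <- function(V, W, Xc, Ym) {
  r <- ncol(V)
  one <- function(Vk, Wk, M)
    1 - ss(M - Vk %*% t(Wk) %*% M) / ss(M)
  per_global <- vapply(seq_len(r), function(j)
    one(V[, j, drop = FALSE], W[, j, drop = FALSE], Xc), numeric(1))
  per_marg <- vapply(seq_len(r), function(j)
    one(V[, j, drop = FALSE], W[, j, drop = FALSE], Ym), numeric(1))
  cum_global <- vapply(seq_len(r), function(j)
    one(V[, seq_len(j), drop = FALSE], W[, seq_len(j), drop = FALSE], Xc),
    numeric(1))
  cum_marg <- vapply(seq_len(r), function(j)
    one(V[, seq_len(j), drop = FALSE], W[, seq_len(j), drop = FALSE], Ym),
    numeric(1))
  data.frame(component = seq_len(r), pev_global = per_global,
             pev_stimulus = per_marg, cum_global = cum_global,
             cum_stimulus = cum_marg)
}

#' Stimulus (UMI/PMI) demixed principal components
#'
#' Fits the rank-2 encoder/decoder pair `(V, W)` minimizing
#' `sum_{s,t} || (xbar_s - xbar) - V W' (x_ts - xbar) ||^2`, i.e. the
#' fluctuations of activity attributable to the identity of the remembered
#' stimulus, independent of time. The problem is reduced-rank regression and
#' is solved in closed form (least squares followed by SVD truncation of the
#' fitted values). `role` selects the conventional fitting window: the
#' second timestep of the first delay for the UMI, of the second delay for
#' the PMI (timestep data), or the second half of the corresponding delay
#' ([-1400, 0) ms and [2150, 3550) ms relative to stimulus `n + 1` onset)
#' for ms data. Components are ordered by descending stimulus PEV, encoder
#' columns are unit norm, and signs follow a fixed convention (largest
#' encoder coordinate positive).
#'
#' @param act An [activity_tensor()].
#' @param role `"UMI"` or `"PMI"` (sets the default window and the label).
#' @param window Optional [window_spec()] overriding the default.
#' @param n_components Number of components (default 2).
#' @param ridge Optional ridge penalty on the least-squares step (default 0).
#' @return A `wm_dpca` object: `V`, `W` (units x components), `x_bar`,
#'   `pev` (per-component and cumulative global/stimulus PEV), `role`,
#'   `window`, `conditions`.
#' @export
fit_stimulus_dpca <- function(act, role = c("UMI", "PMI"), window = NULL,
                              n_components = 2L, ridge = 0) {
  role <- match.arg(role)
  if (is.null(window)) window <- default_window(act, role)
  marg <- condition_average(act, "stimulus", window)
  n_cond <- length(marg$conditions)
  if (n_cond < n_components)
    stop("need at least ", n_components, " conditions, got ", n_cond)
  n_time <- length(marg$time)
  X <- matrix(marg$x_ts, nrow = dim(marg$x_ts)[1]) - marg$x_bar
  Y <- matrix(rep(marg$x_bar_s - marg$x_bar, times = n_time),
              nrow = nrow(X))
  if (ss(Y) < 1e-300)
    stop("zero between-condition variance; degenerate marginalization")
  fit <- rrr_fit(Y, X, rank = n_components, ridge = ridge)
  res <- finalize_dpca(fit, X, Y, marg, role, window)
  res
}

#' Decision demixed principal components
#'
#' Fits the rank-2 pair minimizing
#' `sum_{s,t,d} || (x_tsd - xbar_ts) - V W' (x_tsd - xbar) ||^2`, where the
#' target is the activity centered on the per-(probe, time) mean over the
#' two decisions -- the component of activity attributable to the match /
#' non-match decision. The default window is the probe presentation timestep
#' (timestep data) or [200, 700) ms post-probe onset (ms data).
#'
#' @inheritParams fit_stimulus_dpca
#' @return A `wm_dpca` object with `role = "decision"`.
#' @export
fit_decision_dpca <- function(act, window = NULL, n_components = 2L,
                              ridge = 0) {
  if (is.null(window)) window <- default_window(act, "decision")
  marg <- condition_average(act, "decision", window)
  n_units <- dim(marg$x_tsd)[1]
  # columns ordered (condition, decision, time)
  X <- matrix(marg$x_tsd, nrow = n_units) - marg$x_bar
  Ybar <- array(rep(marg$x_bar_ts, times = 2),
                dim = c(n_units, length(marg$conditions), 2L,
                        length(marg$time)))
  Ybar[, , 1, ] <- marg$x_bar_ts
  Ybar[, , 2, ] <- marg$x_bar_ts
  Y <- matrix(marg$x_tsd - Ybar, nrow = n_units)
  if (ss(Y) < 1e-300)
    stop("zero decision variance; degenerate marginalization")
  fit <- rrr_fit(Y, X, rank = n_components, ridge = ridge)
  finalize_dpca(fit, X, Y, marg, "decision", window)
}

# Order components by descending marginalized PEV, fix signs, build tables.
finalize_dpca <- function(fit, X, Y, marg, role, window) {
  V <- fit$V; W <- fit$W
  per_marg <- vapply(seq_len(ncol(V)), function(j)
    1 - ss(Y - V[, j, drop = FALSE] %*% t(W[, j, drop = FALSE]) %*% Y) / ss(Y),
    numeric(1))
  ord <- order(per_marg, decreasing = TRUE)
  V <- V[, ord, drop = FALSE]
  W <- W[, ord, drop = FALSE]
  sg <- fix_signs(V, W)
  # marginal PEV measures reconstruction of the marginalized targets from
  # the targets themselves (how much marginalized variance the plane holds)
  Ym <- if (role == "decision") Y else
    (marg$x_bar_s - marg$x_bar)
  structure(list(V = sg$V, W = sg$W, x_bar = marg$x_bar,
                 pev = pev_table(sg$V, sg$W, X, Ym),
                 role = role, window = window,
                 conditions = marg$conditions,
                 objective = rrr_objective(Y, X, sg$V, sg$W)),
            class = "wm_dpca")
}

#' @export
print.wm_dpca <- function(x, ...) {
  cat(sprintf("dPCA (%s): %d components in %d-unit space\n",
              x$role, ncol(x$V), nrow(x$V)))
  print(x$pev, row.names = FALSE, digits = 4)
  invisible(x)
}

# Conventional fitting windows per marginalization and clock.
default_window <- function(act, role) {
  if (act$clock == "timestep") {
    switch(role,
           UMI = window_spec(roles = "d1.2"),
           PMI = window_spec(roles = "d2.2"),
           decision = window_spec(roles = "n2"))
  } else {
    switch(role,
           UMI = window_spec(bounds = c(-1400, 0)),
           PMI = window_spec(bounds = c(2150, 3550)),
           decision = window_spec(bounds = c(200, 700)))
  }
}

#' Project activity into a fitted dPC subspace
#'
#' Computes `z = W' (x - x_bar)` with the global mean stored at fit time.
#'
#' @param x Numeric vector, or matrix with units in rows (columns are
#'   samples).
#' @param res A `wm_dpca` fit.
#' @return A `components x samples` matrix (or a length-2 vector for a
#'   single sample).
#' @export
dpca_project <- function(x, res) {
  stopifnot(inherits(res, "wm_dpca"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != nrow(res$W))
    stop("dimension mismatch: data has ", nrow(x), " units, fit has ",
         nrow(res$W))
  z <- t(res$W) %*% (x - res$x_bar)
  if (ncol(z) == 1L) drop(z) else z
}
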