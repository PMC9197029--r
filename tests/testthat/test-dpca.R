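# Numerical minimization oracle for the reduced-rank objective: direct
# optimization over the entries of (V, W) from several random starts.
rrr_oracle <- function(Y, X, rank = 2L, n_starts = 4L, seed = 1) {
  set.seed(seed)
  n <- nrow(Y)
  obj <- function(par) {
    V <- matrix(par[1:(n * rank)], n, rank)
    W <- matrix(par[-(1:(n * rank))], n, rank)
    sum((Y - V %*% t(W) %*% X)^2)
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    fit <- stats::optim(rnorm(2 * n * rank, sd = 0.5), obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

test_that("the closed-form reduced-rank solution attains the oracle optimum", {
  set.seed(51)
  for (rep in 1:6) {
    Y <- matrix(rnorm(4 * 6), 4, 6)
    X <- matrix(rnorm(4 * 6), 4, 6)
    fit <- wmpriority:::rrr_fit(Y, X, rank = 2L)
    ours <- wmpriority:::rrr_objective(Y, X, fit$V, fit$W)
    oracle <- rrr_oracle(Y, X, seed = rep)
    expect_lt(ours, oracle + 1e-6)
    expect_equal(ours, oracle, tolerance = 1e-5)
  }
})

test_that("noiseless planted low-rank stimulus structure is recovered exactly", {
  set.seed(52)
  n_units <- 7
  basis <- qr.Q(qr(matrix(rnorm(n_units^2), n_units)))[, 1:2]
  n_trials <- 60
  labels <- data.frame(stim_id = rep_len(1:6, n_trials),
                       probe_id = rep_len(rep(1:6, each = 2), n_trials),
                       decision = rep_len(c("match", "nonmatch"), n_trials))
  coords <- cbind(cos(2 * pi * labels$stim_id / 6),
                  sin(2 * pi * labels$stim_id / 6))
  patt <- coords %*% t(basis)                      # trials x units, rank 2
  values <- array(NA_real_, dim = c(n_trials, 3, n_units))
  for (tt in 1:3) values[, tt, ] <- patt
  act <- activity_tensor(values, labels, c("d1.1", "d1.2", "d2.2"), "timestep")
  fit <- fit_stimulus_dpca(act, "UMI", window = "d1.2")
  expect_lt(max(principal_angles(fit$V, basis)), 1e-6)
  expect_equal(fit$pev$cum_stimulus[2], 1, tolerance = 1e-10)
  expect_equal(fit$pev$cum_global[2], 1, tolerance = 1e-10)
})

test_that("encoder columns are unit norm, ordered by stimulus PEV, sign-fixed", {
  act <- shared_act7()
  for (fit in list(fit_stimulus_dpca(act, "UMI"),
                   fit_stimulus_dpca(act, "PMI"),
                   fit_decision_dpca(act))) {
    expect_equal(colSums(fit$V^2), c(1, 1), tolerance = 1e-12)
    expect_gte(fit$pev$pev_stimulus[1], fit$pev$pev_stimulus[2])
    for (j in 1:2) expect_gt(fit$V[which.max(abs(fit$V[, j])), j], 0)
    # cumulative stimulus PEV is within [0, 1] and non-decreasing
    expect_true(all(diff(fit$pev$cum_stimulus) >= -1e-12))
    expect_true(all(fit$pev$cum_stimulus >= 0 & fit$pev$cum_stimulus <= 1))
  }
})

test_that("fitting is invariant to a constant shift of all activity", {
  act <- random_tensor(n_trials = 24, n_time = 5, n_units = 4, seed = 53)
  shift <- act
  shift$values <- act$values + rep(c(5, -3, 2, 9), each = 24 * 5)
  f0 <- fit_stimulus_dpca(act, "UMI", window = "d1.2")
  f1 <- fit_stimulus_dpca(shift, "UMI", window = "d1.2")
  expect_equal(f0$V, f1$V, tolerance = 1e-8)
  expect_equal(f0$pev, f1$pev, tolerance = 1e-8)
})

test_that("decision dPCA finds a single planted decision axis", {
  set.seed(54)
  n_units <- 6
  axis <- rnorm(n_units); axis <- axis / sqrt(sum(axis^2))
  n_trials <- 36
  labels <- data.frame(stim_id = rep_len(1:6, n_trials),
                       probe_id = rep_len(rep(1:6, each = 2), n_trials),
                       decision = rep_len(c("match", "nonmatch"), n_trials))
  base <- matrix(rnorm(6 * n_units), 6, n_units)   # probe-specific pattern
  d <- ifelse(labels$decision == "match", 1, -1)
  patt <- base[labels$probe_id, ] + outer(d, axis)
  act <- activity_tensor(array(patt, dim = c(n_trials, 1, n_units)),
                         labels, "n2", "timestep")
  fit <- fit_decision_dpca(act)
  expect_equal(abs(sum(fit$V[, 1] * axis)), 1, tolerance = 1e-8)
})

test_that("projection is the stored-mean-centered linear map", {
  act <- shared_act7()
  fit <- fit_stimulus_dpca(act, "UMI")
  expect_equal(dpca_project(fit$x_bar, fit), c(0, 0), tolerance = 1e-12)
  set.seed(55)
  x1 <- rnorm(7); x2 <- rnorm(7)
  a <- 0.3; b <- 0.5
  z <- dpca_project(a * x1 + b * x2 + (1 - a - b) * fit$x_bar, fit)
  expect_equal(z, a * dpca_project(x1, fit) + b * dpca_project(x2, fit),
               tolerance = 1e-10)
  expect_error(dpca_project(rnorm(9), fit), "dimension mismatch")
})

test_that("degenerate marginalizations are rejected", {
  act <- random_tensor(n_trials = 12, n_time = 2, n_units = 3, seed = 56,
                       time = c("d1.2", "d2.2"))
  act$labels$stim_id <- rep(1L, 12)               # single condition
  expect_error(fit_stimulus_dpca(act, "UMI", window = "d1.2"), "conditions")
  # identical activity in every trial: no between-condition variance
  act2 <- random_tensor(n_trials = 12, n_time = 2, n_units = 3, seed = 57,
                        time = c("d1.2", "d2.2"))
  act2$values[] <- 1
  expect_error(fit_stimulus_dpca(act2, "UMI", window = "d1.2"),
               "degenerate|zero")
})
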