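# Build a tensor whose condition means follow a planted 2-D trajectory:
# mean_s(t) = g(t) * B c_s (+ optional per-trial noise).
planted_trace_tensor <- function(g, n_units = 5, trials_per_cond = 4,
                                 noise_sd = 0, seed = 1,
                                 time = NULL, clock = "timestep") {
  set.seed(seed)
  n_time <- length(g)
  if (is.null(time)) time <- c("d1.1", "d1.2", "n1", "d2.1", "d2.2",
                               "n2")[seq_len(n_time)]
  B <- qr.Q(qr(matrix(rnorm(n_units^2), n_units)))[, 1:2]
  labels <- data.frame(stim_id = rep(1:6, each = trials_per_cond))
  cs <- cbind(cos(2 * pi * (1:6) / 6), sin(2 * pi * (1:6) / 6))
  values <- array(NA_real_, dim = c(nrow(labels), n_time, n_units))
  for (tt in seq_len(n_time)) {
    m <- g[tt] * cs[labels$stim_id, ] %*% t(B)
    values[, tt, ] <- m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))
  }
  list(act = activity_tensor(values, labels, time, clock), B = B)
}

test_that("the scalar transform has its closed-form fixed points", {
  # constant geometry: k = 1 everywhere; negated geometry: k = -1
  p <- planted_trace_tensor(g = c(1, 1, 1, -1, -1), seed = 61)
  fit <- fit_stimulus_dpca(p$act, "UMI", window = "d1.1")
  tr <- fit_scalar_transform(p$act, fit, reference_window = "d1.1",
                             trace_window = window_spec(roles = p$act$time))
  expect_equal(unname(tr$k_hat), c(1, 1, 1, -1, -1), tolerance = 1e-8)
  expect_identical(tr$zero_crossing, "d2.1")
})

test_that("k-hat matches a 1-D optimization oracle on random instances", {
  set.seed(62)
  for (rep in 1:8) {
    p <- planted_trace_tensor(g = runif(5, -1.5, 1.5), noise_sd = 0.3,
                              seed = 62 + rep)
    fit <- fit_stimulus_dpca(p$act, "UMI", window = "d1.1")
    tr <- fit_scalar_transform(p$act, fit, reference_window = "d1.1",
                               trace_window = window_spec(roles = p$act$time))
    marg <- condition_average(p$act, "stimulus")
    ref <- condition_average(p$act, "stimulus", "d1.1")
    b <- t(fit$W) %*% (ref$x_bar_s - fit$x_bar)
    for (tj in seq_along(p$act$time)) {
      a <- t(fit$W) %*% (marg$x_ts[, , tj] - marg$x_bar_t[, tj])
      f <- function(k) sum((a - k * b)^2)
      # golden section, then one parabolic-interpolation step (exact for a
      # quadratic objective, lifting the sqrt(eps) limit of value-based
      # search)
      k0 <- stats::optimize(f, c(-20, 20), tol = 1e-10)$minimum
      h <- 0.01
      oracle <- k0 - 0.5 * h * (f(k0 + h) - f(k0 - h)) /
        (f(k0 + h) - 2 * f(k0) + f(k0 - h))
      expect_equal(unname(tr$k_hat[tj]), oracle, tolerance = 1e-8)
    }
  }
})

test_that("k-hat is invariant to orthonormal rotation of the projection plane", {
  p <- planted_trace_tensor(g = c(1, 0.6, 0.1, -0.4, -1), noise_sd = 0.2,
                            seed = 63)
  fit <- fit_stimulus_dpca(p$act, "UMI", window = "d1.1")
  tr0 <- fit_scalar_transform(p$act, fit, reference_window = "d1.1",
                              trace_window = window_spec(roles = p$act$time))
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- fit
  rot$V <- fit$V %*% R
  rot$W <- fit$W %*% R
  tr1 <- fit_scalar_transform(p$act, rot, reference_window = "d1.1",
                              trace_window = window_spec(roles = p$act$time))
  expect_equal(tr0$k_hat, tr1$k_hat, tolerance = 1e-10)
})

test_that("subspace alignment evaluates the product-of-cosines formula", {
  mk <- function(V) structure(list(V = V, W = V, role = "UMI"),
                              class = "wm_dpca")
  e <- diag(6)
  a <- mk(e[, 1:2])
  expect_equal(subspace_alignment(a, a)$alignment, 1)
  expect_equal(subspace_alignment(a, a)$angle_deg, 0)
  # first pair orthogonal -> alignment 0, angle 90
  b <- mk(e[, 3:4])
  expect_equal(subspace_alignment(a, b)$angle_deg, 90)
  # v1 pair at 60 degrees, v2 pair parallel -> alignment 0.5, angle 60
  th <- 60 * pi / 180
  c_ <- mk(cbind(cos(th) * e[, 1] + sin(th) * e[, 3], e[, 2]))
  al <- subspace_alignment(a, c_)
  expect_equal(al$alignment, 0.5, tolerance = 1e-12)
  expect_equal(al$angle_deg, 60, tolerance = 1e-10)
  # symmetry and sign-flip invariance
  expect_equal(subspace_alignment(c_, a)$alignment, al$alignment)
  flipped <- mk(cbind(-c_$V[, 1], c_$V[, 2]))
  expect_equal(subspace_alignment(a, flipped)$alignment, al$alignment)
  expect_error(subspace_alignment(a, mk(diag(4)[, 1:2])), "mismatch")
})

test_that("principal angles recover known plane relationships", {
  e <- diag(6)
  expect_equal(principal_angles(e[, 1:2], e[, 1:2]), c(0, 0), tolerance = 1e-7)
  expect_equal(principal_angles(e[, 1:2], e[, 3:4]), c(90, 90))
  th <- 35 * pi / 180
  tilted <- cbind(cos(th) * e[, 1] + sin(th) * e[, 3],
                  cos(th) * e[, 2] + sin(th) * e[, 4])
  expect_equal(principal_angles(e[, 1:2], tilted), c(35, 35), tolerance = 1e-8)
})

test_that("dispersion equals the direct variance computation", {
  p <- planted_trace_tensor(g = c(1, 0.5, 0), noise_sd = 0.1, seed = 64,
                            time = c("d1.2", "d2.2", "n2"))
  fit <- fit_stimulus_dpca(p$act, "PMI", window = "d2.2")
  for (tp in p$act$time) {
    marg <- condition_average(p$act, "stimulus", tp)
    z <- t(fit$W) %*% (marg$x_ts[, , 1] - fit$x_bar)
    expect_equal(dispersion(p$act, fit, tp), var(z[1, ]) + var(z[2, ]),
                 tolerance = 1e-12)
  }
  # identical condition means -> zero dispersion
  flat <- p$act
  flat$values[] <- rep(seq_len(5), each = 24 * 3)
  expect_equal(dispersion(flat, fit, "d1.2"), 0, tolerance = 1e-12)
  # means at +/- u along one axis: dispersion is the variance of those coords
  u <- c(2, -2, 2, -2, 2, -2)
  mk <- array(0, dim = c(6, 1, 5))
  for (i in 1:6) mk[i, 1, ] <- fit$W[, 1] / sum(fit$W[, 1]^2) * u[i]
  act_u <- activity_tensor(mk, data.frame(stim_id = 1:6), "d2.2", "timestep")
  fit0 <- fit
  fit0$x_bar <- rep(0, 5)
  expect_equal(dispersion(act_u, fit0, "d2.2"),
               var(u) + var(drop(t(fit$W[, 2]) %*% t(mk[, 1, ]) / 1)),
               tolerance = 1e-10)
})

test_that("the bootstrap null flags information inside the PMI window and is monotone", {
  act <- shared_act7()
  dt <- bootstrap_dispersion_test(act, n_boot = 400, seed = 71,
                                  test_timepoints = c("d2.2", "d3.2"))
  # the PMI-defining timestep must reject (the subspace is fitted to it)
  expect_true(dt$tests$information[dt$tests$timepoint == "d2.2"])
  # decisions are monotone in the dispersion value given the fixed null
  o <- order(dt$tests$dispersion)
  expect_true(all(diff(as.integer(dt$tests$information[o])) >= 0))
  # percentile criterion is monotone in alpha
  q90 <- quantile(dt$null_distribution, 0.90, names = FALSE)
  expect_lte(q90, dt$criterion)
  # low n_boot warns
  expect_warning(
    bootstrap_dispersion_test(act, n_boot = 50, seed = 72,
                              test_timepoints = "d3.2"),
    "unstable")
})
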