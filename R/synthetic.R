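#' Configuration for the synthetic EEG-like dataset
#'
#' The generator emulates the statistical structure of trial-epoched
#' multichannel recordings from the human 2-back task: 60 channels, a
#' millisecond trial clock from -2800 to 3550 ms relative to the onset of
#' stimulus `n + 1` (one stimulus event lasts 3550 ms), six circular
#' stimulus conditions entering only through `[cos 2 theta, sin 2 theta]`,
#' and a 1:2 match:non-match ratio. Stimulus information lives in planted
#' 2-D channel-space planes with time-varying gains: a UMI plane carrying
#' the current item, a PMI plane carrying the previous item early in the
#' trial and the current item after it becomes prioritized, and a decision
#' plane active around probe onset. Per-channel Gaussian noise (optionally
#' AR(1) in time) is added on top. It does not model electrode geometry,
#' volume conduction, artifacts, or preprocessing.
#'
#' The three planes are drawn by orthonormalizing seeded Gaussian matrices
#' and rotating so that each pair of planes is isoclinic at the requested
#' angle (both principal angles equal). Defaults mirror the geometry
#' observed in trained networks: UMI-PMI 84 degrees, UMI-decision 81,
#' PMI-decision 35. The PMI-decision angle must lie in
#' `[|a - b|, min(a + b, 180 - a - b)]` for the construction to exist.
#'
#' @param n_channels Number of channels (default 60).
#' @param trials_per_condition Trials per stimulus condition (default 80,
#'   on the order of a human session's four 125-trial blocks over six
#'   conditions).
#' @param bin_ms Time bin width in ms (default 50).
#' @param t_range Trial clock `c(first, last)` bin left edges in ms.
#' @param angles Stimulus orientations in degrees.
#' @param angle_umi_pmi,angle_umi_dec,angle_pmi_dec Planted pairwise plane
#'   angles in degrees.
#' @param g_umi,g_pmi,g_pmi_prev,g_dec Gain trajectories, functions of time
#'   in ms. Defaults: the UMI gain ramps in early in the first delay, holds
#'   at 1, declines after probe onset, reverses sign (crossing zero at
#'   ~1077 ms) and fades out before the late second delay; the PMI gain
#'   ramps from probe onset to 1 by 2150 ms; the previous item's PMI trace
#'   holds during the first delay and decays after probe onset; the
#'   decision gain is a half-sine bump over `[0, 900]` ms.
#' @param noise_sd Per-channel, per-bin Gaussian noise SD (default 0.25;
#'   signal vectors have unit norm spread over the channels, so this gives
#'   the low single-trial SNR typical of scalp recordings while leaving
#'   usable condition averages at the default trial counts).
#' @param ar_coef AR(1) coefficient for temporally smooth noise (default 0,
#'   i.e. white).
#' @return A list of class `wm_synth_config`.
#' @export
synthetic_config <- function(n_channels = 60L, trials_per_condition = 80L,
                             bin_ms = 50, t_range = c(-2800, 3550),
                             angles = c(10, 40, 70, 100, 130, 160),
                             angle_umi_pmi = 84, angle_umi_dec = 81,
                             angle_pmi_dec = 35,
                             g_umi = default_g_umi, g_pmi = default_g_pmi,
                             g_pmi_prev = default_g_pmi_prev,
                             g_dec = default_g_dec,
                             noise_sd = 0.25, ar_coef = 0) {
  structure(list(n_channels = as.integer(n_channels),
                 trials_per_condition = as.integer(trials_per_condition),
                 bin_ms = bin_ms, t_range = t_range, angles = angles,
                 angle_umi_pmi = angle_umi_pmi,
                 angle_umi_dec = angle_umi_dec,
                 angle_pmi_dec = angle_pmi_dec,
                 g_umi = g_umi, g_pmi = g_pmi, g_pmi_prev = g_pmi_prev,
                 g_dec = g_dec, noise_sd = noise_sd, ar_coef = ar_coef),
            class = "wm_synth_config")
}

#' @rdname synthetic_config
#' @param t Time in ms relative to stimulus `n + 1` onset.
#' @export
default_g_umi <- function(t)
  ifelse(t < -2600, 0,
         ifelse(t < -2300, (t + 2600) / 300,
                ifelse(t < 0, 1,
                       ifelse(t < 1400, 1 - 1.3 * t / 1400,
                              ifelse(t < 2150, -0.3 * (2150 - t) / 750, 0)))))

#' @rdname synthetic_config
#' @export
default_g_pmi <- function(t)
  ifelse(t < 0, 0, ifelse(t < 2150, t / 2150, 1))

#' @rdname synthetic_config
#' @export
default_g_pmi_prev <- function(t)
  ifelse(t < 0, 1, ifelse(t < 1000, 1 - t / 1000, 0))

#' @rdname synthetic_config
#' @export
default_g_dec <- function(t)
  ifelse(t >= 0 & t <= 900, sin(pi * t / 900), 0)

# Circular stimulus code: unit vector [cos 2 theta, sin 2 theta].
circ_code <- function(theta_deg) {
  th <- theta_deg * pi / 90
  c(cos(th), sin(th))
}

# Draw three 2-D orthonormal frames in n-dim space with prescribed
# isoclinic pairwise angles (degrees). Frame pairs (U,P) and (U,D) hit
# their angles by construction; the (P,D) angle fixes the remaining
# rotational freedom and must be feasible given the other two.
planted_frames <- function(n, a_up, a_ud, a_pd) {
  stopifnot(n >= 6L)
  r <- function(x) x * pi / 180
  base <- qr.Q(qr(matrix(stats::rnorm(n * 6L), n, 6L)))
  U <- base[, 1:2]; Wp <- base[, 3:4]; Z <- base[, 5:6]
  P <- cos(r(a_up)) * U + sin(r(a_up)) * Wp
  cph <- (cos(r(a_pd)) - cos(r(a_up)) * cos(r(a_ud))) /
    (sin(r(a_up)) * sin(r(a_ud)))
  if (!is.finite(cph) || abs(cph) > 1 + 1e-9)
    stop("requested PMI-decision angle infeasible given the other two")
  cph <- min(max(cph, -1), 1)
  D <- cos(r(a_ud)) * U + sin(r(a_ud)) * (cph * Wp + sqrt(1 - cph^2) * Z)
  list(U = U, P = P, D = D)
}

#' Per-trial condition labels for the synthetic dataset
#'
#' Balanced stimulus conditions (`trials_per_condition` trials of each of
#' the six orientations for the analyzed item `n`), a uniformly random
#' previous item and probe identity per trial, and a match:non-match ratio
#' of 1:2 within each stimulus condition (up to rounding).
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame with `stim_id`, `prev_id`, `probe_id`, `decision`.
#' @export
make_condition_labels <- function(cfg) {
  k <- cfg$trials_per_condition
  n_cond <- length(cfg$angles)
  stim_id <- rep(seq_len(n_cond), each = k)
  n <- length(stim_id)
  n_match <- round(k / 3)
  decision <- unlist(lapply(seq_len(n_cond), function(i)
    sample(rep(c("match", "nonmatch"), c(n_match, k - n_match)))))
  data.frame(stim_id = stim_id,
             prev_id = sample.int(n_cond, n, replace = TRUE),
             probe_id = sample.int(n_cond, n, replace = TRUE),
             decision = decision,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic EEG-like dataset with known ground truth
#'
#' Each trial's channel-by-time activity is
#' `g_umi(t) U c(theta_n) + g_pmi(t) P c(theta_n) +
#'  g_pmi_prev(t) P c(theta_{n-1}) + g_dec(t) D e(d, t) + noise`,
#' where `c(theta) = [cos 2 theta, sin 2 theta]`, `U`, `P`, `D` are the
#' planted channel-space frames, and the decision code `e(d, t)` is the
#' sign of the decision times a unit vector that rotates across the
#' decision window (so decision variability genuinely spans the plane).
#'
#' @param cfg A [synthetic_config()].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A list with `act` (an [activity_tensor()], ms clock) and
#'   `truth` (planted frames, gain trajectories evaluated on the bin grid,
#'   labels, config, seed).
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config(), seed = 1L) {
  stopifnot(inherits(cfg, "wm_synth_config"))
  set.seed(seed)
  frames <- planted_frames(cfg$n_channels, cfg$angle_umi_pmi,
                           cfg$angle_umi_dec, cfg$angle_pmi_dec)
  labels <- make_condition_labels(cfg)
  tgrid <- seq(cfg$t_range[1], cfg$t_range[2] - cfg$bin_ms, by = cfg$bin_ms)
  n_time <- length(tgrid)
  n_trials <- nrow(labels)
  gu <- cfg$g_umi(tgrid); gp <- cfg$g_pmi(tgrid)
  gq <- cfg$g_pmi_prev(tgrid); gd <- cfg$g_dec(tgrid)
  # decision code rotates through the active window so that decision
  # variability genuinely spans the planted plane
  dec_phase <- pi * pmin(pmax(tgrid, 0), 900) / 900
  e1 <- cos(dec_phase); e2 <- sin(dec_phase)

  values <- array(NA_real_, dim = c(n_trials, n_time, cfg$n_channels))
  for (i in seq_len(n_trials)) {
    cu <- circ_code(cfg$angles[labels$stim_id[i]])
    cq <- circ_code(cfg$angles[labels$prev_id[i]])
    dsign <- if (labels$decision[i] == "match") 1 else -1
    sig <- outer(gu, drop(frames$U %*% cu)) +
      outer(gp, drop(frames$P %*% cu)) +
      outer(gq, drop(frames$P %*% cq)) +
      (gd * dsign) * (outer(e1, drop(frames$D[, 1])) +
                        outer(e2, drop(frames$D[, 2])))
    noise <- matrix(stats::rnorm(n_time * cfg$n_channels, sd = cfg$noise_sd),
                    n_time, cfg$n_channels)
    if (cfg$ar_coef != 0) {
      phi <- cfg$ar_coef
      for (tt in 2:n_time)
        noise[tt, ] <- phi * noise[tt - 1, ] +
          sqrt(1 - phi^2) * noise[tt, ]
    }
    values[i, , ] <- sig + noise
  }
  act <- activity_tensor(values, labels, tgrid, clock = "ms")
  truth <- list(frames = frames,
                g = list(umi = gu, pmi = gp, pmi_prev = gq, dec = gd),
                tgrid = tgrid, labels = labels, config = cfg, seed = seed)
  list(act = act, truth = truth)
}
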