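test_that("2-back match flags and the rejection constraint hold by construction", {
  # definition of a 2-back match on a hand-built sequence
  s <- structure(list(identities = c(3L, 1L, 3L, 1L, 2L)), class = "wm_sequence")
  flags <- wmpriority:::match_flags(s$identities)
  expect_identical(flags, c(NA, NA, TRUE, TRUE, FALSE))

  set.seed(5)
  seqs <- generate_sequences(50)
  for (s in seqs) {
    expect_length(s$identities, 20)
    recomputed <- wmpriority:::match_flags(s$identities)
    expect_identical(sum(recomputed, na.rm = TRUE), s$n_match)
    expect_identical(sum(!is.na(recomputed)), 18L)
    expect_gte(s$n_match, 5)
  }

  # infeasible constraint errors out rather than looping forever
  expect_error(generate_sequence(3, 6, 2, max_attempts = 50), "attempts")
})

test_that("accepted-sequence mean match count converges to the truncated binomial expectation", {
  # enumeration oracle: X ~ Binomial(18, 1/6) conditioned on X >= 5
  k <- 0:18
  p <- dbinom(k, 18, 1 / 6)
  expected <- sum(k[k >= 5] * p[k >= 5]) / sum(p[k >= 5])
  expect_equal(expected, 5.550380, tolerance = 1e-6)

  set.seed(17)
  counts <- vapply(generate_sequences(600), function(s) s$n_match, numeric(1))
  # Monte-Carlo error: sd about 0.78/sqrt(600) ~ 0.032
  expect_lt(abs(mean(counts) - expected), 0.12)
})

test_that("stimulus encodings match their defining formulas", {
  one_hot <- encoding_scheme("one_hot_6")
  expect_equal(wmpriority:::encode_stimulus(3, one_hot), c(0, 0, 1, 0, 0, 0))
  for (i in 1:6)
    expect_equal(sum(wmpriority:::encode_stimulus(i, one_hot)), 1)

  circ <- encoding_scheme("circular_2")
  v <- wmpriority:::encode_stimulus(1, circ)     # theta = 10 deg
  expect_equal(v, c(cos(20 * pi / 180), sin(20 * pi / 180)), tolerance = 1e-12)
  expect_equal(v, c(0.9397, 0.3420), tolerance = 1e-4)
  for (i in 1:6)
    expect_equal(sum(wmpriority:::encode_stimulus(i, circ)^2), 1,
                 tolerance = 1e-12)
  # 180-degree periodicity of the doubled-angle code
  shifted <- encoding_scheme("circular_2", angles = c(10, 40, 70, 100, 130, 160) + 180)
  for (i in 1:6)
    expect_equal(wmpriority:::encode_stimulus(i, shifted),
                 wmpriority:::encode_stimulus(i, circ), tolerance = 1e-12)

  basis <- encoding_scheme("basis_sin6")
  b3 <- wmpriority:::encode_stimulus(3, basis)
  expect_lt(max(abs(b3 - c(0.0156, 0.4219, 1, 0.4219, 0.0156, 0))), 1e-4)
  # symmetric about the active identity
  expect_equal(b3[2], b3[4])
  expect_equal(b3[1], b3[5])
})

test_that("sequence encoding installs two zero-input delay steps per stimulus", {
  set.seed(2)
  s <- generate_sequence(20)
  enc <- encode_sequence(s, encoding_scheme("one_hot_6"))
  expect_identical(enc$n_timesteps, 58L)          # 3*(20-1)+1
  expect_identical(sum(enc$roles == "stim"), 20L)
  delay_rows <- enc$roles %in% c("delay1", "delay2")
  expect_true(all(enc$inputs[delay_rows, ] == 0))
  expect_true(all(enc$targets[delay_rows] == 0))
  # targets: 1 exactly at matching presentations from position 3 on
  stim_t <- enc$stim_timesteps
  expect_equal(enc$targets[stim_t[1:2]], c(0, 0))
  expect_equal(enc$targets[stim_t[3:20]],
               as.numeric(s$match_flags[3:20]))
})

test_that("trial labels cover 16 analyzed trials with correct windows", {
  set.seed(3)
  s <- generate_sequence(20)
  lab <- label_trials(s)
  expect_identical(nrow(lab), 16L)
  expect_identical(lab$trial, 3:18)
  # UMI window: the two delays after the presentation of n
  expect_equal(lab$t_d1.1, lab$t_n + 1)
  expect_equal(lab$t_d1.2, lab$t_n + 2)
  expect_equal(lab$t_n2, lab$t_n + 6)
  # decision label is the n-vs-n+2 comparison
  expect_identical(lab$decision,
                   ifelse(s$identities[5:20] == s$identities[3:18],
                          "match", "nonmatch"))
  # the last analyzed trial has no third delay or n+3 presentation
  last <- lab[nrow(lab), ]
  expect_true(is.na(last$t_d3.1) && is.na(last$t_d3.2) && is.na(last$t_n3))
  expect_false(anyNA(lab[-nrow(lab), grepl("^t_", names(lab))]))
})

test_that("sequence CSV round-trips", {
  set.seed(4)
  seqs <- generate_sequences(5)
  path <- tempfile(fileext = ".csv")
  write_sequences_csv(seqs, path)
  back <- read_sequences_csv(path)
  expect_identical(lapply(back, `[[`, "identities"),
                   lapply(seqs, `[[`, "identities"))
  expect_identical(vapply(back, `[[`, numeric(1), "n_match"),
                   vapply(seqs, `[[`, numeric(1), "n_match"))
})
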