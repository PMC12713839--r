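# Synthetic-data generator: Markov hypnograms, state-conditioned
# signals, activity model and genotype presets.

test_that("degenerate kinetics behave as absorbing / forbidden chains", {
  I3 <- diag(3)
  hyp <- simulate_hypnogram(uniform_kinetics(I3, pi0 = c(0, 1, 0)),
                            days = 1, seed = 1)
  expect_true(all(hyp$labels == "N"))
  # no N->R anywhere: REM unreachable from the bulk states
  P <- matrix(c(0.9, 0.1, 0,
                0.1, 0.9, 0,
                0.1, 0.1, 0.8), nrow = 3, byrow = TRUE)
  hyp2 <- simulate_hypnogram(uniform_kinetics(P, pi0 = c(0.5, 0.5, 0)),
                             days = 1, seed = 2)
  expect_false(any(hyp2$labels == "R"))
})

test_that("kinetics constructor enforces stochasticity and no W->R", {
  bad <- matrix(c(0.5, 0.4, 0.2,
                  0.1, 0.9, 0,
                  0.1, 0.1, 0.8), nrow = 3, byrow = TRUE)
  expect_error(uniform_kinetics(bad), "sum to 1")
  wr <- matrix(c(0.5, 0.4, 0.1,
                 0.1, 0.9, 0,
                 0.1, 0.1, 0.8), nrow = 3, byrow = TRUE)
  expect_error(uniform_kinetics(wr), "W -> R")
})

test_that("empirical N->R hazard converges to the kinetics entry", {
  # 30 simulated days at P[N->R] = 0.05/epoch; binomial CI oracle
  P <- mixing_matrix(p_nr = 0.05)
  hyp <- simulate_hypnogram(uniform_kinetics(P, pi0 = c(0, 1, 0)),
                            days = 30, seed = 11)
  lab <- hyp$labels
  at_n <- which(lab[-length(lab)] == "N")
  phat <- mean(lab[at_n + 1L] == "R")
  expect_equal(phat, 0.05, tolerance = 0.005 / 0.05)  # +/- 0.005 absolute
  ci <- stats::binom.test(sum(lab[at_n + 1L] == "R"), length(at_n))$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  kin <- genotype_presets()$WT$kinetics
  h1 <- simulate_hypnogram(kin, days = 1, seed = 99)
  h2 <- simulate_hypnogram(kin, days = 1, seed = 99)
  expect_identical(h1$labels, h2$labels)
  a1 <- simulate_activity(genotype_presets()$WT$activity, seed = 99)
  a2 <- simulate_activity(genotype_presets()$WT$activity, seed = 99)
  expect_identical(a1$counts, a2$counts)
  r1 <- synthesize_signals(hypnogram(rep("N", 6)), preset_recipe(), seed = 99,
                           n_eeg = 1, n_emg = 1)
  r2 <- synthesize_signals(hypnogram(rep("N", 6)), preset_recipe(), seed = 99,
                           n_eeg = 1, n_emg = 1)
  expect_identical(r1$channels$EEG1, r2$channels$EEG1)
})

test_that("zero-amplitude recipe gives all-zero EEG", {
  rec0 <- spectral_recipe(list(
    W = list(bands = data.frame(center_hz = numeric(), bw_hz = numeric(),
                                amp_uv = numeric()),
             bg_exponent = 1, bg_rms_uv = 0, emg_rms_uv = 0),
    N = list(bands = data.frame(center_hz = numeric(), bw_hz = numeric(),
                                amp_uv = numeric()),
             bg_exponent = 1, bg_rms_uv = 0, emg_rms_uv = 0),
    R = list(bands = data.frame(center_hz = numeric(), bw_hz = numeric(),
                                amp_uv = numeric()),
             bg_exponent = 1, bg_rms_uv = 0, emg_rms_uv = 0)))
  rec <- synthesize_signals(hypnogram(c("W", "N", "R")), rec0, seed = 1,
                            n_eeg = 1, n_emg = 1)
  expect_true(all(rec$channels$EEG1 == 0))
  expect_true(all(rec$channels$EMG1 == 0))
})

test_that("REM epochs carry a theta peak near the recipe centre", {
  hyp <- hypnogram(rep("R", 30))
  rec <- synthesize_signals(hyp, preset_recipe(), seed = 5,
                            n_eeg = 1, n_emg = 1)
  sp <- epoch_spectra(rec)
  for (i in c(1, 15, 30)) {
    pk <- sp$frequencies[which.max(sp$power[, i])]
    expect_gte(pk, 6.5); expect_lte(pk, 7.5)
  }
})

test_that("per-state band powers follow the recipe ordering", {
  hyp <- hypnogram(rep(c("W", "N", "R"), each = 20))
  rec <- synthesize_signals(hyp, preset_recipe(), seed = 6,
                            n_eeg = 1, n_emg = 1)
  sp <- epoch_spectra(rec)
  f <- sp$frequencies
  swa <- colSums(sp$power[f >= 0.5 & f < 4, ])
  theta <- colSums(sp$power[f >= 6 & f < 9, ])
  st <- hyp$labels
  expect_gt(mean(swa[st == "N"]), mean(swa[st == "R"]))   # NREM delta dominant
  expect_gt(mean(theta[st == "R"]), mean(theta[st == "N"]))
  # EMG tone ordered W > N > R
  spe <- 10 * 128
  tone <- vapply(seq_along(st), function(i)
    emg_tone(rec$channels$EMG1[((i - 1) * spe + 1):(i * spe)]), numeric(1))
  expect_gt(mean(tone[st == "W"]), mean(tone[st == "N"]))
  expect_gt(mean(tone[st == "N"]), mean(tone[st == "R"]))
})

test_that("activity waveform confines counts to the dark phase", {
  model <- activity_model(dark_fraction = 1, mean_counts = 10,
                          days_ld = 3, days_dd = 0)
  act <- simulate_activity(model, seed = 4)
  zt <- (act$start_zt + (seq_along(act$counts) - 1) / 60) %% 24
  expect_true(all(act$counts[zt < 12] == 0))
  expect_gt(sum(act$counts[zt >= 12]), 0)
})

test_that("DD onsets stay put at 24 h and drift at the free-running period", {
  m24 <- activity_model(period_h = 24, mean_counts = 20, days_ld = 0,
                        days_dd = 8, dispersion = 50)
  on24 <- activity_onsets(simulate_activity(m24, seed = 8))
  drift24 <- stats::coef(stats::lm(onset_h - 24 * (day - 1) ~ day,
                                   data = on24))[2]
  expect_lt(abs(drift24), 0.05)

  m237 <- activity_model(period_h = 23.7, mean_counts = 20, days_ld = 0,
                         days_dd = 10, dispersion = 50)
  on <- activity_onsets(simulate_activity(m237, seed = 9))
  rel <- on$onset_h - 24 * (on$day - 1)
  slope <- stats::coef(stats::lm(rel ~ on$day))[2]
  expect_equal(unname(slope), -0.3, tolerance = 0.05 / 0.3)
})

test_that("genotype presets inject the documented effect directions", {
  pre <- genotype_presets()
  # stationary-distribution oracle: WT REM fraction higher in light than dark
  pi_l <- stationary_distribution(pre$WT$kinetics$light)
  pi_d <- stationary_distribution(pre$WT$kinetics$dark)
  expect_gt(pi_l["R"], pi_d["R"])
  # MUT dark N->R hazard above WT; light below WT (by preset definition)
  expect_gt(pre$MUT$kinetics$dark["N", "R"], pre$WT$kinetics$dark["N", "R"])
  expect_lt(pre$MUT$kinetics$light["N", "R"], pre$WT$kinetics$light["N", "R"])
  # expected daily activity lower in MUT (model expectation)
  expect_lt(pre$MUT$activity$mean_counts, pre$WT$activity$mean_counts)
  # mutant REM fraction flattened across phases relative to WT
  mi_l <- stationary_distribution(pre$MUT$kinetics$light)
  mi_d <- stationary_distribution(pre$MUT$kinetics$dark)
  expect_lt(abs(mi_l["R"] - mi_d["R"]), abs(pi_l["R"] - pi_d["R"]))
  expect_gt(mi_d["R"], pi_d["R"])
})
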