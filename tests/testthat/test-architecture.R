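# Hypnogram-derived architecture statistics.

test_that("episodes are maximal runs reconstructing the hypnogram", {
  allN <- hypnogram(rep("N", 8640))
  e1 <- find_episodes(allN)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$length_epochs, 8640)
  e2 <- find_episodes(hyp_from_string("WNRN"))
  expect_equal(nrow(e2), 4)
  expect_equal(e2$state, c("W", "N", "R", "N"))
  # change-point oracle on a random day
  hyp <- simulate_hypnogram(genotype_presets()$WT$kinetics, days = 1,
                            seed = 31)
  eps <- find_episodes(hyp)
  expect_equal(nrow(eps), 1 + sum(diff(match(hyp$labels, c("W", "N", "R"))) != 0))
  expect_equal(sum(eps$duration_s), length(hyp$labels) * hyp$epoch_s)
  # reconstruction
  expect_identical(rep(eps$state, eps$length_epochs), hyp$labels)
})

test_that("state time profiles conserve bin length", {
  allW <- hypnogram(rep("W", 8640))
  pr <- state_time_profile(allW, 1)
  expect_equal(pr$minutes[pr$state == "W"], rep(60, 24))
  expect_true(all(pr$minutes[pr$state != "W"] == 0))
  hyp <- simulate_hypnogram(genotype_presets()$WT$kinetics, days = 2,
                            seed = 32)
  for (bh in c(1, 6, 12)) {
    pr <- state_time_profile(hyp, bh)
    sums <- tapply(pr$minutes, pr$bin_start_zt, sum)
    expect_equal(as.vector(sums), rep(bh * 60, 24 / bh))
  }
  # light-phase NREM exceeds dark-phase NREM for the nocturnal preset
  pr12 <- state_time_profile(hyp, 12)
  n_light <- pr12$minutes[pr12$state == "N" & pr12$bin_start_zt == 0]
  n_dark <- pr12$minutes[pr12$state == "N" & pr12$bin_start_zt == 12]
  expect_gt(n_light, n_dark)
  expect_error(state_time_profile(hypnogram(rep("W", 100)), 1),
               "not a whole multiple")
})

test_that("transition table implements the conditional-probability formula", {
  # alternating W/N: only W>N and N>W, counts equal within 1
  alt <- hypnogram(rep(c("W", "N"), 4320))
  tt <- transition_table(alt, 12)
  byt <- tapply(tt$table$count, tt$table$type, sum)
  expect_lte(abs(byt[["W>N"]] - byt[["N>W"]]), 1)
  expect_equal(as.vector(byt[c("N>R", "R>N", "R>W")]), c(0, 0, 0))
  # explicit formula: 3 N>R and 7 N>W in the light phase -> 0.3 / 0.7
  lab <- c(rep(c(rep("N", 5), "R"), 3),              # 3 N>R
           rep(c(rep("N", 5), "W"), 7))              # 7 N>W
  lab <- c(lab, rep("N", 8640 - length(lab)))        # pad to a full day
  hyp <- hypnogram(lab)
  tt2 <- transition_table(hyp, 12)$table
  expect_equal(tt2$prob[tt2$type == "N>R" & tt2$bin_start_zt == 0], 0.3)
  expect_equal(tt2$prob[tt2$type == "N>W" & tt2$bin_start_zt == 0], 0.7)
})

test_that("transition counts match a brute-force pairwise scan", {
  for (seed in 1:3) {
    hyp <- simulate_hypnogram(uniform_kinetics(mixing_matrix(0.03),
                                               pi0 = c(1, 0, 0)),
                              days = 1, seed = seed)   # 8640 epochs <= 1e4
    tt <- transition_table(hyp, 24)
    brute <- brute_transitions(hyp$labels)
    byt <- tapply(tt$table$count, tt$table$type, sum)
    for (ty in names(byt)) expect_equal(unname(byt[ty]), unname(brute[ty]))
    expect_equal(tt$w_to_r, unname(brute["W>R"]))
    # conditional probabilities per pre-state sum to 1 where defined
    probs <- tt$table
    for (pre in c("N", "R")) {
      sel <- startsWith(as.character(probs$type), pre)
      if (sum(probs$count[sel]) > 0)
        expect_equal(sum(probs$prob[sel]), 1, tolerance = 1e-12)
    }
  }
})

test_that("phase transition matrices are row-stochastic", {
  hyp <- simulate_hypnogram(genotype_presets()$WT$kinetics, days = 2,
                            seed = 33)
  tm <- transition_matrix(hyp)
  for (ph in c("light", "dark")) {
    rs <- rowSums(tm[[ph]])
    expect_equal(unname(rs[rs > 0]), rep(1, sum(rs > 0)), tolerance = 1e-12)
    expect_equal(tm[[ph]]["W", "R"], 0)    # excluded type
  }
})

test_that("REM latency measures from NREM onset with wake resets", {
  h1 <- hyp_from_string("WNNR")
  expect_equal(rem_latencies(h1)$latency_s, 20)
  hist1 <- rem_latency_histogram(h1)
  expect_equal(hist1$count[hist1$phase == "light" & hist1$bin_lo_s == 0], 1L)
  # W, 14 N, R -> latency 140 s in bin [100, 150)
  h2 <- hypnogram(c("W", rep("N", 14), "R"))
  expect_equal(rem_latencies(h2)$latency_s, 140)
  hist2 <- rem_latency_histogram(h2)
  expect_equal(hist2$count[hist2$phase == "light" & hist2$bin_lo_s == 100], 1L)
  # N R N R with no intervening wake: both latencies from the same onset
  h3 <- hyp_from_string("WNRNR")
  expect_equal(rem_latencies(h3)$latency_s, c(10, 30))
  # wake between: clock resets at the new W>N onset
  h4 <- hyp_from_string("WNRWNR")
  expect_equal(rem_latencies(h4)$latency_s, c(10, 10))
  # wake shorter than the reset threshold does not reset
  h5 <- hyp_from_string("WNRWNR")
  expect_equal(rem_latencies(h5, wake_reset_min_epochs = 2)$latency_s,
               c(10, 40))
  # REM with no preceding NREM onset is excluded and QC-counted
  h6 <- hyp_from_string("RNNR")
  lat6 <- rem_latencies(h6)
  expect_equal(nrow(lat6), 1)
  expect_equal(attr(lat6, "qc_excluded"), 1L)
  # conservation: histogram counts + excluded = all REM episodes
  hyp <- simulate_hypnogram(genotype_presets()$WT$kinetics, days = 2,
                            seed = 34)
  hh <- rem_latency_histogram(hyp)
  n_rem <- sum(find_episodes(hyp)$state == "R")
  expect_equal(sum(hh$count) + attr(hh, "qc_excluded"), n_rem)
})

test_that("episode summaries bin by onset and flag empty cells", {
  one <- episode_summary(find_episodes(hypnogram(rep("N", 8640))), 6)
  expect_equal(one$count[one$state == "N" & one$bin_start_zt == 0], 1L)
  expect_true(all(one$count[one$state != "N"] == 0))
  expect_true(all(is.na(one$mean_duration_s[one$count == 0])))
  alt <- episode_summary(find_episodes(hypnogram(rep(c("W", "N"), 360))), 6)
  expect_equal(alt$mean_duration_s[alt$count > 0], c(10, 10))
})

test_that("mean NREM episode duration follows the geometric oracle", {
  # single-phase chain: mean bout length = epoch_s / (1 - P[N,N])
  P <- mixing_matrix(0.02)            # P[N,N] = 0.90
  hyp <- simulate_hypnogram(uniform_kinetics(P, pi0 = c(0, 1, 0)),
                            days = 30, seed = 35)
  eps <- find_episodes(hyp)
  mean_n <- mean(eps$duration_s[eps$state == "N"])
  expect_equal(mean_n, 10 / (1 - 0.90), tolerance = 0.05)
})

test_that("SWA time course is normalised to the 24-h NREM mean", {
  n_ep <- 8640
  freqs <- seq(0, 64, 0.5)
  hyp <- simulate_hypnogram(genotype_presets()$WT$kinetics, days = 1,
                            seed = 36)
  # constant synthetic spectra: flat SWA -> 100% everywhere with NREM
  power <- matrix(1, length(freqs), n_ep)
  sw <- swa_timecourse(list(frequencies = freqs, power = power), hyp, 6)
  expect_equal(sw$swa_pct[sw$n_nrem_epochs > 0],
               rep(100, sum(sw$n_nrem_epochs > 0)))
  # scale invariance: doubling amplitude (4x power) leaves the course
  sw2 <- swa_timecourse(list(frequencies = freqs, power = 4 * power), hyp, 6)
  expect_equal(sw2$swa_pct, sw$swa_pct)
  # doubled delta power in light-phase NREM epochs -> light bins above 100%
  zt <- (seq_len(n_ep) - 1) * 10 / 3600
  boosted <- power
  dsel <- freqs >= 0.5 & freqs < 4
  boost_cols <- zt < 12 & hyp$labels == "N"
  boosted[dsel, boost_cols] <- 2 * boosted[dsel, boost_cols]
  sw3 <- swa_timecourse(list(frequencies = freqs, power = boosted), hyp, 6)
  expect_true(all(sw3$swa_pct[sw3$bin_start_zt < 12] > 100))
  expect_true(all(sw3$swa_pct[sw3$bin_start_zt >= 12] < 100))
})

test_that("stage spectra are relative and stage-resolved", {
  hyp <- hypnogram(rep(c("N", "R"), each = 30))
  rec <- synthesize_signals(hyp, preset_recipe(), seed = 37,
                            n_eeg = 1, n_emg = 1)
  sp <- epoch_spectra(rec)
  ss <- stage_spectra(sp, hyp)
  expect_setequal(unique(ss$stage), c("W", "N", "R"))
  expect_true(all(is.na(ss$power[ss$stage == "W"])))   # no wake epochs
  n_delta <- ss$power[ss$stage == "N" & ss$frequency_hz == 2]
  r_delta <- ss$power[ss$stage == "R" & ss$frequency_hz == 2]
  expect_gt(n_delta, r_delta)
  # relative spectra sum to ~1 over the reporting range
  expect_equal(sum(ss$power[ss$stage == "N"]), 1, tolerance = 1e-6)
})
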