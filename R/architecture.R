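## Hypnogram-derived sleep architecture statistics: episodes, state time
## profiles, transition tables, REM-sleep latency and SWA time courses.
## Multi-day recordings are folded onto the 24-h zeitgeber clock (events
## are assigned to ZT bins by onset, per-day averages where noted).

#' Find vigilance episodes
#'
#' Maximal runs of consecutive same-state epochs (no smoothing or
#' minimum-bout filtering; a single epoch is an episode).
#'
#' @param hyp A [hypnogram()].
#' @return data.frame with columns `state`, `start_epoch` (0-based),
#'   `length_epochs`, `start_zt` (h), `duration_s`.
#' @export
find_episodes <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"), length(hyp$labels) >= 1)
  r <- rle(hyp$labels)
  start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  data.frame(state = r$values,
             start_epoch = start,
             length_epochs = r$lengths,
             start_zt = (hyp$start_zt + start * hyp$epoch_s / 3600) %% 24,
             duration_s = r$lengths * hyp$epoch_s)
}

check_bin_alignment <- function(hyp, bin_h) {
  dur_h <- length(hyp$labels) * hyp$epoch_s / 3600
  if (abs(dur_h / bin_h - round(dur_h / bin_h)) > 1e-9)
    stop("recording (", dur_h, " h) is not a whole multiple of the ",
         bin_h, "-h bin")
  k <- (bin_h * 3600) / hyp$epoch_s
  if (abs(k - round(k)) > 1e-9)
    stop("epochs do not tile the bin")
  if (abs(hyp$start_zt - round(hyp$start_zt)) > 1e-9)
    stop("recording must start on a whole zeitgeber hour for binning")
  if (24 %% bin_h != 0) stop("bins must tile 24 h")
}

#' Time-in-state profile
#'
#' Minutes spent in each vigilance state per zeitgeber bin, averaged
#' over recorded days.  States sum to the bin length in every bin.
#'
#' @param hyp A [hypnogram()] covering whole bins.
#' @param bin_h Bin width in hours (must divide 24).
#' @return data.frame with columns `bin_start_zt`, `state`, `minutes`.
#' @export
state_time_profile <- function(hyp, bin_h = 1) {
  check_bin_alignment(hyp, bin_h)
  zt <- epoch_zt(hyp)
  bin <- floor(zt / bin_h) * bin_h
  days <- length(hyp$labels) * hyp$epoch_s / 86400
  lv <- state_levels()
  tab <- table(bin = factor(bin, levels = seq(0, 24 - bin_h, by = bin_h)),
               state = factor(hyp$labels, lv))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  # only bins the recording actually covers (sub-day recordings)
  covered <- unique(bin)
  df <- df[df$bin %in% as.character(covered), ]
  data.frame(bin_start_zt = as.numeric(as.character(df$bin)),
             state = df$state,
             minutes = df$Freq * hyp$epoch_s / 60 / days)
}

transition_types <- function() c("W>N", "N>W", "N>R", "R>N", "R>W")

#' Transition table
#'
#' Counts and conditional probabilities of the five analysed state
#' transitions (`W>N`, `N>W`, `N>R`, `R>N`, `R>W`) per zeitgeber bin.
#' A transition is counted at each epoch boundary where the label
#' changes and assigned to the bin containing the post-transition epoch.
#' The conditional probability of, e.g., `N>W` is its count divided by
#' all transitions out of NREM in that bin (`N>W + N>R`).  Direct
#' `W>R` occurrences are excluded from the table and reported in the
#' `w_to_r` QC field.
#'
#' @param hyp A [hypnogram()] covering whole bins.
#' @param bin_h Bin width in hours (6 or 12 in the standard analyses).
#' @return List with `table` (data.frame: `bin_start_zt`, `type`,
#'   `count`, `prob`) and `w_to_r` (count of excluded direct W-to-REM
#'   transitions).
#' @export
transition_table <- function(hyp, bin_h = 6) {
  check_bin_alignment(hyp, bin_h)
  lab <- hyp$labels
  n <- length(lab)
  from <- lab[-n]; to <- lab[-1]
  chg <- which(from != to)
  zt_post <- epoch_zt(hyp)[chg + 1L]
  bin <- floor(zt_post / bin_h) * bin_h
  type <- paste0(from[chg], ">", to[chg])
  w_to_r <- sum(type == "W>R")
  keep <- type %in% transition_types()
  bins <- seq(0, 24 - bin_h, by = bin_h)
  tab <- table(bin = factor(bin[keep], levels = bins),
               type = factor(type[keep], levels = transition_types()))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$bin <- as.numeric(as.character(df$bin))
  pre <- substr(df$type, 1, 1)
  key <- paste(df$bin, pre)
  denom <- stats::ave(df$Freq, key, FUN = sum)
  out <- data.frame(bin_start_zt = df$bin, type = df$type, count = df$Freq,
                    prob = ifelse(denom > 0, df$Freq / denom, NA_real_))
  list(table = out[order(out$bin_start_zt), ], w_to_r = w_to_r)
}

#' Phase transition probability matrix
#'
#' 3x3 conditional transition matrix per photic phase: entry (s, s') is
#' the probability that a transition out of state s goes to s', among
#' all transitions out of s whose post-transition epoch falls in that
#' phase.  Direct W-to-REM transitions are excluded (QC-only).
#'
#' @param hyp A [hypnogram()].
#' @return List with `light` and `dark` 3x3 matrices (rows = pre-state)
#'   and `w_to_r` QC count.
#' @export
transition_matrix <- function(hyp) {
  lab <- hyp$labels
  n <- length(lab)
  from <- lab[-n]; to <- lab[-1]
  chg <- which(from != to)
  phase <- zt_phase(epoch_zt(hyp)[chg + 1L], hyp$schedule)
  type <- paste0(from[chg], ">", to[chg])
  w_to_r <- sum(type == "W>R")
  keep <- type %in% transition_types()
  lv <- state_levels()
  mk <- function(ph) {
    sel <- keep & phase == ph
    m <- table(factor(from[chg][sel], lv), factor(to[chg][sel], lv))
    m <- matrix(as.numeric(m), 3, 3, dimnames = list(from = lv, to = lv))
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    m
  }
  list(light = mk("light"), dark = mk("dark"), w_to_r = w_to_r)
}

#' REM-sleep latencies
#'
#' Latency of each REM episode from NREM sleep onset: the time from the
#' start of the most recent wake-to-NREM transition (with no intervening
#' wake episode of at least `wake_reset_min_epochs` epochs) to REM
#' onset.  REM episodes with no preceding NREM onset (e.g. at the start
#' of the recording) are excluded and counted in the QC field.
#'
#' @param hyp A [hypnogram()].
#' @param wake_reset_min_epochs Minimum wake-episode length (epochs)
#'   that resets the latency clock; 1 = any wake resets (strictest
#'   reading of "NREM sleep onset").
#' @return data.frame with columns `latency_s`, `onset_zt`, `phase`,
#'   with attribute `qc_excluded` (count of undefined latencies).
#' @export
rem_latencies <- function(hyp, wake_reset_min_epochs = 1) {
  eps <- find_episodes(hyp)
  nrem_onset <- NA_real_   # start epoch of the active NREM-sleep onset
  lat <- numeric(0); onset_zt <- numeric(0)
  excluded <- 0L
  for (i in seq_len(nrow(eps))) {
    st <- eps$state[i]
    if (st == "W" && eps$length_epochs[i] >= wake_reset_min_epochs) {
      nrem_onset <- NA_real_
    } else if (st == "N" && is.na(nrem_onset)) {
      nrem_onset <- eps$start_epoch[i]
    } else if (st == "R") {
      if (is.na(nrem_onset)) {
        excluded <- excluded + 1L
      } else {
        lat <- c(lat, (eps$start_epoch[i] - nrem_onset) * hyp$epoch_s)
        onset_zt <- c(onset_zt, eps$start_zt[i])
      }
    }
  }
  out <- data.frame(latency_s = lat, onset_zt = onset_zt,
                    phase = zt_phase(onset_zt, hyp$schedule))
  attr(out, "qc_excluded") <- excluded
  out
}

#' REM-latency histogram
#'
#' Histogram of REM-sleep latencies in fixed-width bins from 0, per
#' photic phase (phase of the REM onset), with a final open-ended
#' overflow bin.
#'
#' @param hyp A [hypnogram()].
#' @param bin_s Bin width in seconds.
#' @param max_s Upper edge of the last closed bin.
#' @param wake_reset_min_epochs Passed to [rem_latencies()].
#' @return data.frame with columns `phase`, `bin_lo_s`, `bin_hi_s`
#'   (`Inf` for the overflow bin), `count`; attribute `qc_excluded`.
#' @export
rem_latency_histogram <- function(hyp, bin_s = 50, max_s = 600,
                                  wake_reset_min_epochs = 1) {
  lat <- rem_latencies(hyp, wake_reset_min_epochs)
  edges <- c(seq(0, max_s, by = bin_s), Inf)
  phases <- c("light", "dark")
  out <- do.call(rbind, lapply(phases, function(ph) {
    x <- lat$latency_s[lat$phase == ph]
    cnt <- as.integer(table(cut(x, edges, right = FALSE)))
    data.frame(phase = ph, bin_lo_s = edges[-length(edges)],
               bin_hi_s = edges[-1], count = cnt)
  }))
  attr(out, "qc_excluded") <- attr(lat, "qc_excluded")
  out
}

#' Episode summary per bin
#'
#' Mean episode duration and episode count per state and zeitgeber bin;
#' an episode belongs to the bin containing its onset.  Empty cells get
#' count 0 and a missing duration.
#'
#' @param episodes data.frame from [find_episodes()].
#' @param bin_h Bin width in hours.
#' @return data.frame with columns `bin_start_zt`, `state`,
#'   `mean_duration_s`, `count`.
#' @export
episode_summary <- function(episodes, bin_h = 6) {
  stopifnot(all(c("state", "start_zt", "duration_s") %in% names(episodes)))
  bins <- seq(0, 24 - bin_h, by = bin_h)
  bin <- floor((episodes$start_zt %% 24) / bin_h) * bin_h
  grid <- expand.grid(bin_start_zt = bins, state = state_levels(),
                      stringsAsFactors = FALSE)
  grid$mean_duration_s <- NA_real_
  grid$count <- 0L
  for (i in seq_len(nrow(grid))) {
    sel <- bin == grid$bin_start_zt[i] & episodes$state == grid$state[i]
    grid$count[i] <- sum(sel)
    if (any(sel)) grid$mean_duration_s[i] <- mean(episodes$duration_s[sel])
  }
  grid
}

#' Slow-wave-activity time course
#'
#' Mean SWA (delta-band EEG power) over NREM epochs per zeitgeber bin,
#' normalised per subject so that the 24-h mean NREM SWA is 100%.
#' Bins without NREM epochs get a missing value.
#'
#' @param spectra Result of [epoch_spectra()] aligned to `hyp` (one
#'   spectrum column per epoch).
#' @param hyp A [hypnogram()].
#' @param bin_h Bin width in hours.
#' @param swa_band SWA band in Hz.
#' @return data.frame with columns `bin_start_zt`, `swa_pct`,
#'   `n_nrem_epochs`.
#' @export
swa_timecourse <- function(spectra, hyp, bin_h = 6, swa_band = c(0.5, 4)) {
  stopifnot(ncol(spectra$power) == length(hyp$labels))
  check_bin_alignment(hyp, bin_h)
  dsel <- spectra$frequencies >= swa_band[1] & spectra$frequencies < swa_band[2]
  swa <- colSums(spectra$power[dsel, , drop = FALSE])
  nrem <- hyp$labels == "N"
  ref <- mean(swa[nrem])
  zt <- epoch_zt(hyp)
  bins <- seq(0, 24 - bin_h, by = bin_h)
  bin <- floor(zt / bin_h) * bin_h
  out <- data.frame(bin_start_zt = bins, swa_pct = NA_real_,
                    n_nrem_epochs = 0L)
  for (i in seq_along(bins)) {
    sel <- nrem & bin == bins[i]
    out$n_nrem_epochs[i] <- sum(sel)
    if (any(sel)) out$swa_pct[i] <- 100 * mean(swa[sel]) / ref
  }
  out
}

#' Stage-wise power spectra
#'
#' Mean EEG power spectrum per vigilance state over a reporting range,
#' optionally with each epoch's spectrum first normalised to its total
#' power in that range (relative power, used when comparing groups).
#'
#' @param spectra Result of [epoch_spectra()] aligned to `hyp`.
#' @param hyp A [hypnogram()].
#' @param range Reporting range in Hz.
#' @param normalize Logical; normalise per epoch to total power in
#'   `range`.
#' @return Long data.frame with columns `stage`, `frequency_hz`,
#'   `power` (uV^2 or relative).
#' @export
stage_spectra <- function(spectra, hyp, range = c(0.5, 30),
                          normalize = TRUE) {
  stopifnot(ncol(spectra$power) == length(hyp$labels))
  sel <- spectra$frequencies >= range[1] & spectra$frequencies <= range[2]
  P <- spectra$power[sel, , drop = FALSE]
  if (normalize) {
    tot <- colSums(P)
    tot[tot == 0] <- 1
    P <- sweep(P, 2, tot, "/")
  }
  do.call(rbind, lapply(state_levels(), function(s) {
    cols <- hyp$labels == s
    data.frame(stage = s, frequency_hz = spectra$frequencies[sel],
               power = if (any(cols)) rowMeans(P[, cols, drop = FALSE])
                       else NA_real_)
  }))
}
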