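## Synthetic polysomnography and locomotor activity.  The hypnogram comes
## from the Markov kinetics (synthetic-kinetics.R); this file adds the
## state-conditioned EEG/EMG synthesiser and the entrained/free-running
## activity model.

#' State-conditioned spectral recipe
#'
#' Describes, per vigilance state, the EEG as a sum of narrow-band
#' oscillations over a 1/f background, plus a white-noise EMG at a fixed
#' RMS tone.  The preset constraint that NREM delta exceeds REM delta and
#' that wake EMG tone exceeds sleep tone is enforced by
#' [preset_recipe()], not by this constructor.
#'
#' @param states Named list with elements `W`, `N`, `R`; each a list with
#'   `bands` (data.frame with columns `center_hz`, `bw_hz`, `amp_uv`),
#'   `bg_exponent` (1/f spectral exponent), `bg_rms_uv` (background RMS)
#'   and `emg_rms_uv`.
#' @return An object of class `spectral_recipe`.
#' @export
spectral_recipe <- function(states) {
  stopifnot(setequal(names(states), state_levels()))
  for (s in state_levels()) {
    st <- states[[s]]
    stopifnot(all(c("bands", "bg_exponent", "bg_rms_uv", "emg_rms_uv") %in%
                    names(st)))
    if (nrow(st$bands) > 0)
      stopifnot(all(st$bands$amp_uv >= 0), all(st$bands$center_hz > 0))
    stopifnot(st$bg_rms_uv >= 0, st$emg_rms_uv >= 0)
  }
  structure(states, class = "spectral_recipe")
}

#' Preset spectral recipe for the synthetic cohort
#'
#' Delta-dominant NREM (2 Hz oscillation), theta-dominant REM (sharp
#' 7 Hz), broadband low-voltage wake EEG, and EMG tone ordered
#' wake > NREM > REM.  Amplitudes are in the range typical of mouse
#' epidural screw EEG (tens of microvolts).
#'
#' @return A [spectral_recipe()].
#' @export
preset_recipe <- function() {
  band <- function(center, bw, amp)
    data.frame(center_hz = center, bw_hz = bw, amp_uv = amp)
  spectral_recipe(list(
    W = list(bands = band(8, 1.5, 8), bg_exponent = 1, bg_rms_uv = 18,
             emg_rms_uv = 30),
    N = list(bands = band(2, 0.6, 40), bg_exponent = 1, bg_rms_uv = 15,
             emg_rms_uv = 8),
    R = list(bands = band(7, 0.3, 30), bg_exponent = 1, bg_rms_uv = 10,
             emg_rms_uv = 4)
  ))
}

# 1/f^exponent background noise, length n, sampling rate fs, target RMS.
one_over_f_noise <- function(n, fs, exponent, rms) {
  if (rms <= 0 || n < 2) return(numeric(n))
  half <- n %/% 2
  f <- fs * seq_len(half) / n
  amp <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) full[half + 1] <- complex(real = amp[half])  # real Nyquist
  if (half > 1) full[n:(n - half + 2)] <- Conj(spec[seq_len(half - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * rms
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' Per episode (maximal same-state run), the EEG is the sum of the
#' recipe's band-limited oscillations -- frequency drawn once per episode
#' around the band centre, phase continuous across epoch boundaries
#' within the episode and reset at episode boundaries -- plus 1/f
#' background noise; the EMG is white noise at the state's RMS tone.
#'
#' @param hyp A [hypnogram()].
#' @param recipe A [spectral_recipe()].
#' @param fs Sampling rate in Hz (>= 64).
#' @param seed Integer seed.
#' @param n_eeg,n_emg Number of EEG / EMG channels to synthesise.
#' @return A [signal_record()] with channels `EEG1..`, `EMG1..`.
#' @export
synthesize_signals <- function(hyp, recipe, fs = 128, seed = 1,
                               n_eeg = 2, n_emg = 2) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(recipe, "spectral_recipe"),
            fs >= 64, n_eeg >= 1, n_emg >= 1)
  eps <- find_episodes(hyp)
  n_total <- length(hyp$labels) * hyp$epoch_s * fs
  if (n_total != round(n_total))
    stop("epoch_s * fs must be an integer number of samples")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  eeg <- replicate(n_eeg, numeric(n_total), simplify = FALSE)
  emg <- replicate(n_emg, numeric(n_total), simplify = FALSE)
  pos <- 0L
  for (k in seq_len(nrow(eps))) {
    st <- recipe[[eps$state[k]]]
    n <- as.integer(eps$length_epochs[k] * hyp$epoch_s * fs)
    tt <- (seq_len(n) - 1) / fs
    for (ch in seq_len(n_eeg)) {
      x <- one_over_f_noise(n, fs, st$bg_exponent, st$bg_rms_uv)
      if (nrow(st$bands) > 0) {
        for (b in seq_len(nrow(st$bands))) {
          f0 <- stats::rnorm(1, st$bands$center_hz[b], st$bands$bw_hz[b] / 4)
          x <- x + st$bands$amp_uv[b] * sin(2 * pi * f0 * tt +
                                              stats::runif(1, 0, 2 * pi))
        }
      }
      eeg[[ch]][(pos + 1):(pos + n)] <- x
    }
    for (ch in seq_len(n_emg))
      emg[[ch]][(pos + 1):(pos + n)] <-
        if (st$emg_rms_uv > 0) stats::rnorm(n, 0, st$emg_rms_uv) else numeric(n)
    pos <- pos + n
  }
  channels <- c(stats::setNames(eeg, paste0("EEG", seq_len(n_eeg))),
                stats::setNames(emg, paste0("EMG", seq_len(n_emg))))
  signal_record(channels, sampling_rate = fs, start_zt = hyp$start_zt,
                schedule = hyp$schedule)
}

#' Locomotor activity model
#'
#' Parametric nocturnal activity waveform: a fraction `dark_fraction` of
#' daily counts falls in the (subjective) dark phase, of which
#' `early_peak_weight` falls in its first half (the early-dark activity
#' peak).  Under LD the waveform is locked to the 24-h zeitgeber; under
#' DD the phase free-runs at `period_h`, continuing smoothly from the
#' last LD phase.  Counts are negative-binomial around the waveform
#' (beam-break counts are over-dispersed).
#'
#' @param period_h Free-running period in hours (20-28).
#' @param mean_counts Mean counts per minute over the day.
#' @param dark_fraction Fraction of daily counts in the dark phase.
#' @param early_peak_weight Fraction of dark-phase counts in its first
#'   6 h.
#' @param dispersion Negative-binomial size parameter (larger = closer
#'   to Poisson); `Inf` gives Poisson noise.
#' @param days_ld,days_dd Days recorded under LD and DD.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(period_h = 23.7, mean_counts = 10,
                           dark_fraction = 0.85, early_peak_weight = 0.6,
                           dispersion = 3, days_ld = 7, days_dd = 10) {
  stopifnot(period_h >= 20, period_h <= 28,
            mean_counts >= 0, dark_fraction >= 0, dark_fraction <= 1,
            early_peak_weight >= 0, early_peak_weight <= 1,
            dispersion > 0, days_ld >= 0, days_dd >= 0)
  structure(list(period_h = period_h, mean_counts = mean_counts,
                 dark_fraction = dark_fraction,
                 early_peak_weight = early_peak_weight,
                 dispersion = dispersion, days_ld = days_ld,
                 days_dd = days_dd),
            class = "activity_model")
}

# expected counts per bin at circadian phase theta (hours in [0,24))
activity_waveform <- function(theta, model, bin_min) {
  daily <- model$mean_counts * 1440
  per_h <- ifelse(theta < 12,
                  (1 - model$dark_fraction) / 12,
                  ifelse(theta < 18,
                         model$dark_fraction * model$early_peak_weight / 6,
                         model$dark_fraction * (1 - model$early_peak_weight) / 6))
  daily * per_h * bin_min / 60
}

#' Simulate locomotor activity
#'
#' Generates `days_ld` entrained days followed by `days_dd` free-running
#' days at `period_h`, in `bin_min`-minute bins.  The returned series
#' carries the LD schedule; `split_activity()` separates the LD and DD
#' segments (the DD segment gets a DD light schedule).
#'
#' @param model An [activity_model()].
#' @param seed Integer seed.
#' @param bin_min Bin width in minutes.
#' @param start_zt Zeitgeber hour of the first bin.
#' @return An [activity_series()] with an extra element `dd_from_bin`
#'   (1-based index of the first DD bin, or `NA` if none).
#' @export
simulate_activity <- function(model, seed = 1, bin_min = 1, start_zt = 0) {
  stopifnot(inherits(model, "activity_model"))
  n_ld <- as.integer(model$days_ld * 1440 / bin_min)
  n_dd <- as.integer(model$days_dd * 1440 / bin_min)
  t_h <- (seq_len(n_ld + n_dd) - 0.5) * bin_min / 60   # bin midpoints, h
  theta <- numeric(n_ld + n_dd)
  if (n_ld > 0)
    theta[seq_len(n_ld)] <- (start_zt + t_h[seq_len(n_ld)]) %% 24
  if (n_dd > 0) {
    t0 <- n_ld * bin_min / 60
    phase0 <- (start_zt + t0) %% 24
    theta[(n_ld + 1):(n_ld + n_dd)] <-
      (phase0 + (t_h[(n_ld + 1):(n_ld + n_dd)] - t0) * 24 / model$period_h) %% 24
  }
  mu <- activity_waveform(theta, model, bin_min)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  counts <- if (is.finite(model$dispersion))
    stats::rnbinom(length(mu), size = model$dispersion, mu = mu)
  else stats::rpois(length(mu), mu)
  act <- activity_series(counts, bin_min = bin_min, start_zt = start_zt)
  act$dd_from_bin <- if (n_dd > 0) n_ld + 1L else NA_integer_
  act
}

#' Split a simulated series into LD and DD segments
#'
#' @param act An [activity_series()] from [simulate_activity()] (or any
#'   series with a `dd_from_bin` element).
#' @return List with elements `ld` and `dd` (either may be `NULL`).
#' @export
split_activity <- function(act) {
  stopifnot(inherits(act, "activity_series"))
  i <- act$dd_from_bin
  if (is.null(i) || is.na(i)) return(list(ld = act, dd = NULL))
  ld <- if (i > 1)
    activity_series(act$counts[seq_len(i - 1)], bin_min = act$bin_min,
                    start_zt = act$start_zt, schedule = act$schedule)
  dd_start_zt <- (act$start_zt + (i - 1) * act$bin_min / 60) %% 24
  dd <- activity_series(act$counts[i:length(act$counts)],
                        bin_min = act$bin_min, start_zt = dd_start_zt,
                        schedule = light_schedule(dd = TRUE))
  list(ld = ld, dd = dd)
}
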