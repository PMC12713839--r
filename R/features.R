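## Per-epoch and per-window EEG/EMG features: Hann-windowed FFT band
## powers, EMG tone, sample entropy, detrended fluctuation analysis and
## theta regularity.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# One-sided Hann periodogram of each column of `segs` (n x m).  Power is
# normalized so that the bin sum equals the window-weighted mean square
# of the (demeaned) segment: sum_k P_k = sum(w^2 x^2) / sum(w^2).
segment_periodograms <- function(segs) {
  n <- nrow(segs)
  w <- hann_window(n)
  segs <- sweep(segs, 2, colMeans(segs))
  X <- stats::mvfft(segs * w)
  half <- n %/% 2
  P <- Mod(X[1:(half + 1), , drop = FALSE])^2
  P <- P * 2 / (n * sum(w^2))
  P[1, ] <- P[1, ] / 2
  if (n %% 2 == 0) P[half + 1, ] <- P[half + 1, ] / 2
  P
}

#' Epoch power spectrum
#'
#' Spectrum of one scoring epoch: the mean of consecutive, non-overlapping
#' Hann-windowed FFT periodograms tiling the epoch (five 2-s windows for
#' the default 10-s epoch).  At 128 Hz with a 256-point window the
#' frequency spacing is 0.5 Hz.
#'
#' @param eeg_segment Numeric vector of exactly `epoch_s * sampling_rate`
#'   samples.
#' @param cfg A [study_config()].
#' @return An object of class `epoch_spectrum`: list with `frequencies`
#'   (Hz, 0 to Nyquist) and `power` (uV^2 per bin).
#' @export
epoch_spectrum <- function(eeg_segment, cfg = study_config()) {
  n_expected <- cfg$epoch_s * cfg$sampling_rate
  if (length(eeg_segment) != n_expected)
    stop("segment must have ", n_expected, " samples (epoch_s * fs), got ",
         length(eeg_segment))
  nw <- cfg$fft_points
  k <- cfg$epoch_s / cfg$fft_window_s
  segs <- matrix(eeg_segment, nrow = nw, ncol = k)
  P <- rowMeans(segment_periodograms(segs))
  structure(list(frequencies = cfg$sampling_rate * (0:(nw %/% 2)) / nw,
                 power = P),
            class = "epoch_spectrum")
}

#' Spectra for every epoch of a recording
#'
#' Batch version of [epoch_spectrum()] over the first EEG channel of a
#' record (optionally notch-filtered per the config), chunked to bound
#' memory.
#'
#' @param record A [signal_record()].
#' @param cfg A [study_config()].
#' @param channel Channel name; default first EEG channel.
#' @return List with `frequencies` and `power`, a `n_freq x n_epoch`
#'   matrix.
#' @export
epoch_spectra <- function(record, cfg = study_config(), channel = NULL) {
  stopifnot(inherits(record, "signal_record"))
  if (is.null(channel)) channel <- names(record$channels)[record$roles == "EEG"][1]
  x <- record$channels[[channel]]
  if (!is.null(cfg$notch_hz))
    x <- notch_filter(x, record$sampling_rate, cfg$notch_hz)
  spe <- cfg$epoch_s * record$sampling_rate         # samples per epoch
  n_epoch <- length(x) %/% spe
  nw <- cfg$fft_points
  k <- cfg$epoch_s / cfg$fft_window_s
  power <- matrix(0, nw %/% 2 + 1, n_epoch)
  chunk <- max(1, 2e6 %/% spe)
  for (from in seq(1, n_epoch, by = chunk)) {
    to <- min(from + chunk - 1, n_epoch)
    seg <- matrix(x[((from - 1) * spe + 1):(to * spe)], nrow = nw)
    P <- segment_periodograms(seg)
    # average the k consecutive windows belonging to each epoch
    grp <- rep(seq_len(to - from + 1), each = k)
    power[, from:to] <- t(rowsum(t(P), grp) / k)
  }
  list(frequencies = record$sampling_rate * (0:(nw %/% 2)) / nw,
       power = power)
}

#' Band power
#'
#' Sum of spectral power over bins with `lo <= f < hi`.
#'
#' @param spec An `epoch_spectrum` (or any list with `frequencies` and a
#'   `power` vector).
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= ` Nyquist.
#' @return Power in uV^2.
#' @export
band_power <- function(spec, lo, hi) {
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi")
  ny <- max(spec$frequencies)
  if (hi > ny + 1e-9)
    stop("band exceeds the Nyquist frequency (", ny, " Hz)")
  sel <- spec$frequencies >= lo & spec$frequencies < hi
  if (abs(hi - ny) <= 1e-9)                 # hi at Nyquist: include the edge
    sel <- sel | spec$frequencies == ny
  sum(spec$power[sel])
}

#' EMG tone
#'
#' Root-mean-square of a mean-removed EMG segment.
#'
#' @param emg_segment Non-empty numeric vector.
#' @return RMS in uV.
#' @export
emg_tone <- function(emg_segment) {
  stopifnot(length(emg_segment) >= 1)
  sqrt(mean((emg_segment - mean(emg_segment))^2))
}

#' Sample entropy
#'
#' Standard sample entropy SampEn(m, r): the negative log of the
#' conditional probability that two templates of length `m` that match
#' within Chebyshev tolerance `r` still match at length `m + 1`.
#' Self-matches are excluded.  With no template matches at either length
#' the sentinel `Inf` is returned with attribute `flagged = TRUE`.
#'
#' @param series Numeric vector, length >= 100.
#' @param m Embedding dimension.
#' @param r Tolerance; default 0.2 x SD of the series.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  n <- length(series)
  if (n < 100) stop("series too short for sample entropy (need >= 100)")
  n_templates <- n - m
  # Chebyshev match counts at lengths m and m+1, i < j, vectorized over j
  A <- 0; B <- 0
  for (i in seq_len(n_templates - 1)) {
    js <- (i + 1):n_templates
    d <- abs(series[js] - series[i])
    for (k in seq_len(m - 1))
      d <- pmax(d, abs(series[js + k] - series[i + k]))
    match_m <- d <= r
    B <- B + sum(match_m)
    d1 <- pmax(d, abs(series[js + m] - series[i + m]))
    A <- A + sum(match_m & d1 <= r)
  }
  if (B == 0 || A == 0)
    return(structure(Inf, flagged = TRUE))
  -log(A / B)
}

#' Detrended fluctuation analysis exponent
#'
#' DFA with linear detrending over non-overlapping windows: the series is
#' integrated (cumulative sum of deviations from the mean), split into
#' windows of `n` samples, each window is linearly detrended, and
#' `F(n)` is the RMS residual.  The exponent is the least-squares slope
#' of `log F(n)` on `log n`.  White noise gives alpha ~ 0.5; Brownian
#' motion (its cumulative sum) gives alpha ~ 1.5.
#'
#' @param series Numeric vector; length must be >= 4 x the largest scale.
#' @param scales Integer window sizes (>= 3 of them, each >= 4).
#'   Default: 8 log-spaced scales from 16 to 512 samples.
#' @return Scaling exponent alpha.
#' @export
dfa_alpha <- function(series,
                      scales = round(exp(seq(log(16), log(512),
                                             length.out = 8)))) {
  scales <- unique(as.integer(scales))
  if (length(scales) < 3) stop("need at least 3 scales")
  if (any(scales < 4)) stop("scales must be >= 4 samples")
  if (length(series) < 4 * max(scales))
    stop("series too short: need >= 4 x max scale = ", 4 * max(scales))
  y <- cumsum(series - mean(series))
  Fn <- vapply(scales, function(n) {
    nw <- length(y) %/% n
    t <- seq_len(n)
    tc <- t - mean(t)
    stt <- sum(tc^2)
    resid2 <- 0
    for (w in seq_len(nw)) {
      seg <- y[((w - 1) * n + 1):(w * n)]
      b <- sum(tc * seg) / stt
      a <- mean(seg)
      resid2 <- resid2 + sum((seg - a - b * tc)^2)
    }
    sqrt(resid2 / (nw * n))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(Fn) ~ log(scales)))[2])
}

#' Theta regularity
#'
#' Sharpness of the theta peak: power in the peak bin plus its 0.5-Hz
#' neighbours, divided by total theta-band power, clipped to [0, 1].
#' Zero theta power is defined as regularity 0.
#'
#' @param spec An `epoch_spectrum` covering the theta band.
#' @param band Theta band in Hz.
#' @return Value in [0, 1].
#' @export
theta_regularity <- function(spec, band = c(6, 9)) {
  sel <- which(spec$frequencies >= band[1] & spec$frequencies < band[2])
  if (length(sel) < 1) stop("spectrum does not cover the theta band")
  p <- spec$power[sel]
  tot <- sum(p)
  if (tot <= 0) return(0)
  pk <- which.max(p)
  nb <- max(1, pk - 1):min(length(p), pk + 1)
  min(1, max(0, sum(p[nb]) / tot))
}

#' Mains notch filter
#'
#' Second-order Butterworth band-stop (default 49-51 Hz), applied
#' forwards and backwards for zero phase shift.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param center_hz Notch centre frequency.
#' @param width_hz Full stop-band width.
#' @return Filtered signal.
#' @export
notch_filter <- function(x, fs, center_hz = 50, width_hz = 2) {
  ny <- fs / 2
  if (center_hz + width_hz / 2 >= ny)
    stop("notch band exceeds the Nyquist frequency")
  bf <- signal::butter(2, c(center_hz - width_hz / 2,
                            center_hz + width_hz / 2) / ny, type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

#' Full per-epoch feature set
#'
#' Computes, for every epoch of a record, the features used by the
#' scoring rules and the fragmentation analyses: delta and theta band
#' power, theta regularity, EMG tone, and (optionally, they are an order
#' of magnitude slower) sample entropy and the DFA exponent of the EEG.
#'
#' @param record A [signal_record()].
#' @param cfg A [study_config()].
#' @param entropy,dfa Logical; include sample entropy / DFA per epoch.
#' @return data.frame with one row per epoch.
#' @export
epoch_features <- function(record, cfg = study_config(),
                           entropy = FALSE, dfa = FALSE) {
  sp <- epoch_spectra(record, cfg)
  f <- sp$frequencies
  dsel <- f >= cfg$swa_band[1] & f < cfg$swa_band[2]
  tsel <- f >= cfg$theta_band[1] & f < cfg$theta_band[2]
  n_epoch <- ncol(sp$power)
  treg <- vapply(seq_len(n_epoch), function(i)
    theta_regularity(list(frequencies = f, power = sp$power[, i]),
                     cfg$theta_band), numeric(1))
  emg_ch <- names(record$channels)[record$roles == "EMG"][1]
  spe <- cfg$epoch_s * record$sampling_rate
  emg <- record$channels[[emg_ch]][seq_len(n_epoch * spe)]
  emg_ms <- colMeans(matrix(emg, nrow = spe)^2) -
    colMeans(matrix(emg, nrow = spe))^2
  out <- data.frame(epoch_index = seq_len(n_epoch) - 1L,
                    delta_power = colSums(sp$power[dsel, , drop = FALSE]),
                    theta_power = colSums(sp$power[tsel, , drop = FALSE]),
                    theta_regularity = treg,
                    emg_tone = sqrt(pmax(emg_ms, 0)))
  if (entropy || dfa) {
    eeg_ch <- names(record$channels)[record$roles == "EEG"][1]
    eeg <- record$channels[[eeg_ch]]
    if (entropy)
      out$entropy <- vapply(seq_len(n_epoch), function(i)
        as.numeric(sample_entropy(eeg[((i - 1) * spe + 1):(i * spe)])),
        numeric(1))
    if (dfa) {
      scales <- round(exp(seq(log(16), log(spe %/% 4), length.out = 8)))
      out$dfa_alpha <- vapply(seq_len(n_epoch), function(i)
        dfa_alpha(eeg[((i - 1) * spe + 1):(i * spe)], scales), numeric(1))
    }
  }
  out
}
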