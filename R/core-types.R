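#' @keywords internal
"_PACKAGE"

## Single source of truth for the three-state vigilance alphabet.
## Integer codes: W = 0, N = 1, R = 2.

#' Vigilance state alphabet
#'
#' The three vigilance states used throughout the package, in canonical
#' order: `"W"` (wakefulness), `"N"` (NREM sleep), `"R"` (REM sleep).
#' Integer codes are `W = 0, N = 1, R = 2`.
#'
#' @return Character vector `c("W", "N", "R")`.
#' @export
state_levels <- function() c("W", "N", "R")

#' @rdname state_levels
#' @param labels Character vector of state labels.
#' @export
state_code <- function(labels) {
  idx <- match(labels, state_levels())
  if (anyNA(idx) && !anyNA(labels)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown vigilance label(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' @rdname state_levels
#' @param codes Integer vector of state codes (0, 1, 2).
#' @export
state_label <- function(codes) {
  if (any(!codes %in% 0:2, na.rm = TRUE))
    stop("state codes must be 0 (W), 1 (N) or 2 (R)")
  state_levels()[codes + 1L]
}

#' Light schedule descriptor
#'
#' @param lights_on_zt,lights_off_zt Zeitgeber hours of lights-on/off.
#'   Under the package's ZT convention lights-on defines ZT0, so the
#'   defaults are 0 and 12 (12:12 LD).
#' @param dd Logical; `TRUE` for constant darkness (free-running
#'   conditions), in which case ZT bookkeeping still runs on a nominal
#'   24-h clock but no phase is labelled "light".
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(lights_on_zt = 0, lights_off_zt = 12, dd = FALSE) {
  stopifnot(lights_on_zt >= 0, lights_on_zt < 24,
            lights_off_zt > 0, lights_off_zt <= 24)
  structure(list(lights_on_zt = lights_on_zt, lights_off_zt = lights_off_zt,
                 dd = isTRUE(dd)),
            class = "light_schedule")
}

#' Phase (light/dark) of a zeitgeber time
#'
#' @param zt Numeric zeitgeber hours (any real; reduced mod 24).
#' @param schedule A [light_schedule()]. Under DD every hour is "dark".
#' @return Character vector, `"light"` or `"dark"`.
#' @export
zt_phase <- function(zt, schedule = light_schedule()) {
  zt <- zt %% 24
  if (schedule$dd) return(rep("dark", length(zt)))
  ifelse(zt >= schedule$lights_on_zt & zt < schedule$lights_off_zt,
         "light", "dark")
}

#' Multichannel EEG/EMG signal record
#'
#' Container for a polysomnographic recording: a list of equally long
#' channels sampled at one rate, with zeitgeber alignment and light
#' schedule metadata.  Channel roles are `"EEG"` or `"EMG"`; staging
#' requires at least one of each.
#'
#' @param channels Named list of numeric vectors (samples in microvolts).
#' @param roles Character vector, one of `"EEG"`/`"EMG"` per channel.
#'   Defaults to inference from the channel-name prefix.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param start_zt Zeitgeber hour at the first sample, in `[0, 24)`.
#' @param schedule A [light_schedule()].
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(channels, roles = NULL, sampling_rate,
                          start_zt = 0, schedule = light_schedule()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            sampling_rate > 0, start_zt >= 0, start_zt < 24)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named")
  n <- lengths(channels)
  if (length(unique(n)) != 1L)
    stop("all channels must have the same length (got ",
         paste(n, collapse = ", "), ")")
  if (is.null(roles)) roles <- infer_channel_roles(names(channels))
  roles <- match.arg(roles, c("EEG", "EMG"), several.ok = TRUE)
  if (length(roles) != length(channels))
    stop("one role per channel required")
  structure(list(channels = channels, roles = roles,
                 sampling_rate = sampling_rate, start_zt = start_zt,
                 schedule = schedule),
            class = "signal_record")
}

infer_channel_roles <- function(labels) {
  up <- toupper(labels)
  roles <- ifelse(startsWith(up, "EEG"), "EEG",
                  ifelse(startsWith(up, "EMG"), "EMG", NA_character_))
  if (anyNA(roles))
    stop("cannot infer channel role (EEG/EMG) from label(s): ",
         paste(labels[is.na(roles)], collapse = ", "),
         "; pass `roles` explicitly")
  roles
}

#' @export
print.signal_record <- function(x, ...) {
  dur <- length(x$channels[[1]]) / x$sampling_rate
  cat(sprintf("<signal_record> %d channel(s), %.6g Hz, %.6g s (start ZT %.3g)\n",
              length(x$channels), x$sampling_rate, dur, x$start_zt))
  cat("  ", paste(sprintf("%s[%s]", names(x$channels), x$roles),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Duration of a signal record in seconds
#' @param record A [signal_record()].
#' @return Numeric seconds.
#' @export
record_duration <- function(record) {
  length(record$channels[[1]]) / record$sampling_rate
}

#' Per-epoch hypnogram
#'
#' A sequence of vigilance-state labels on a fixed epoch grid (10 s by
#' default), aligned to zeitgeber time, with subject metadata.
#'
#' @param labels Character vector over `c("W","N","R")` (or integer
#'   codes 0/1/2, which are converted).
#' @param epoch_s Epoch length in seconds (> 0).
#' @param start_zt Zeitgeber hour of epoch 0.
#' @param subject_id,genotype,sex Subject metadata; `genotype` is
#'   `"WT"` or `"MUT"`, `sex` is `"M"` or `"F"`.
#' @param schedule A [light_schedule()].
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 10, start_zt = 0,
                      subject_id = "s1", genotype = c("WT", "MUT"),
                      sex = c("M", "F"), schedule = light_schedule()) {
  if (is.numeric(labels)) labels <- state_label(as.integer(labels))
  if (any(!labels %in% state_levels()))
    stop("labels must be drawn from {W, N, R}")
  stopifnot(epoch_s > 0, start_zt >= 0, start_zt < 24, length(labels) >= 1)
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  structure(list(labels = labels, epoch_s = epoch_s, start_zt = start_zt,
                 subject_id = subject_id, genotype = genotype, sex = sex,
                 schedule = schedule),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = state_levels()))
  cat(sprintf("<hypnogram> %s (%s, %s): %d epochs x %g s, start ZT %.3g\n",
              x$subject_id, x$genotype, x$sex, length(x$labels), x$epoch_s,
              x$start_zt))
  cat(sprintf("  W %.1f%%  N %.1f%%  R %.1f%%\n",
              100 * tab[["W"]] / length(x$labels),
              100 * tab[["N"]] / length(x$labels),
              100 * tab[["R"]] / length(x$labels)))
  invisible(x)
}

#' Zeitgeber time at each epoch onset
#' @param hyp A [hypnogram()].
#' @return Numeric vector of ZT hours (mod 24) of epoch onsets.
#' @export
epoch_zt <- function(hyp) {
  (hyp$start_zt + (seq_along(hyp$labels) - 1) * hyp$epoch_s / 3600) %% 24
}

#' Locomotor activity series
#'
#' Non-negative activity counts (infrared beam breaks or wheel turns) in
#' fixed-width bins, 1 min by default.
#'
#' @param counts Non-negative numeric vector of counts per bin.
#' @param bin_min Bin width in minutes; must divide 60.
#' @param start_zt Zeitgeber hour of the first bin.
#' @param schedule A [light_schedule()]; use `dd = TRUE` for
#'   constant-darkness (free-running) segments.
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(counts, bin_min = 1, start_zt = 0,
                            schedule = light_schedule()) {
  stopifnot(length(counts) >= 1, bin_min > 0)
  if (60 %% bin_min != 0) stop("bin_min must divide 60")
  if (any(counts < 0)) stop("activity counts must be non-negative")
  structure(list(counts = as.numeric(counts), bin_min = bin_min,
                 start_zt = start_zt, schedule = schedule),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d bins x %g min (%.2f days)%s\n",
              length(x$counts), x$bin_min,
              length(x$counts) * x$bin_min / 1440,
              if (x$schedule$dd) ", DD" else ", LD"))
  invisible(x)
}

#' Study configuration
#'
#' Bundles the fixed analysis parameters: epoching, FFT scheme, spectral
#' bands, binning grids, REM-latency histogram resolution, periodogram
#' search range and the type-I error level.
#'
#' @param epoch_s Scoring epoch (s).
#' @param fft_window_s FFT window length (s); 2 s at 128 Hz gives the
#'   256-point window and 0.5 Hz resolution.
#' @param fft_points FFT length in samples.
#' @param sampling_rate Signal sampling rate (Hz).
#' @param swa_band Slow-wave activity band, Hz (`c(lo, hi)`).
#' @param theta_band Theta band, Hz.
#' @param spectral_range Reporting range for power spectra, Hz.
#' @param rem_latency_bin_s REM-latency histogram bin width (s).
#' @param rem_latency_max_s Upper edge of the last closed latency bin (s);
#'   an open-ended overflow bin follows.
#' @param periodogram_range Candidate period search range (h).
#' @param alpha Type-I error level.
#' @param notch_hz Optional mains notch centre frequency (Hz) applied to
#'   EEG before feature extraction; `NULL` disables (synthetic data needs
#'   none).
#' @param seed Optional integer seed recorded with the config.
#' @return An object of class `study_config`.
#' @export
study_config <- function(epoch_s = 10, fft_window_s = 2, fft_points = 256,
                         sampling_rate = 128, swa_band = c(0.5, 4),
                         theta_band = c(6, 9), spectral_range = c(0.5, 30),
                         rem_latency_bin_s = 50, rem_latency_max_s = 600,
                         periodogram_range = c(20, 28), alpha = 0.05,
                         notch_hz = NULL, seed = NULL) {
  stopifnot(epoch_s > 0, fft_window_s > 0, fft_points >= 2,
            sampling_rate > 0, alpha > 0, alpha < 1)
  if (fft_points != fft_window_s * sampling_rate)
    stop("fft_points must equal fft_window_s * sampling_rate (",
         fft_window_s * sampling_rate, ")")
  if (epoch_s %% fft_window_s != 0)
    stop("fft windows must tile the epoch exactly")
  structure(list(epoch_s = epoch_s, fft_window_s = fft_window_s,
                 fft_points = fft_points, sampling_rate = sampling_rate,
                 swa_band = swa_band, theta_band = theta_band,
                 spectral_range = spectral_range,
                 rem_latency_bin_s = rem_latency_bin_s,
                 rem_latency_max_s = rem_latency_max_s,
                 periodogram_range = periodogram_range, alpha = alpha,
                 notch_hz = notch_hz, seed = seed),
            class = "study_config")
}
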