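## Rule-based vigilance staging.  The dominant state of a 25-s window is
## decided from EMG tone, the delta ratio delta/(delta+theta) and theta
## regularity; windows are slid at 1-s increments to give per-second
## labels, which are aggregated to 10-s epochs by majority.

#' Staging thresholds
#'
#' Decision cuts for the rule-based stager.  The wake cut on EMG tone is
#' per-subject adaptive: with `emg_wake_quantile = "auto"` (default) the
#' subject's window-tone distribution is split into its two modes
#' (2-means on log tone) and the cut is placed midway between the
#' cluster centres; a numeric value in (0, 1) instead takes that
#' quantile of the tone distribution.
#'
#' @param emg_wake_quantile `"auto"` or a quantile in (0, 1).
#' @param delta_ratio_cut Minimum delta/(delta+theta) for NREM.
#' @param theta_reg_cut Minimum theta regularity for REM.
#' @param emg_wake_cut Optional pre-resolved absolute tone cut (uV RMS);
#'   normally filled in by [resolve_thresholds()].
#' @return An object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(emg_wake_quantile = "auto",
                               delta_ratio_cut = 0.55,
                               theta_reg_cut = 0.5,
                               emg_wake_cut = NULL) {
  if (is.numeric(emg_wake_quantile))
    stopifnot(emg_wake_quantile > 0, emg_wake_quantile < 1)
  else if (!identical(emg_wake_quantile, "auto"))
    stop("emg_wake_quantile must be \"auto\" or a quantile in (0,1)")
  stopifnot(delta_ratio_cut > 0, delta_ratio_cut < 1,
            theta_reg_cut > 0, theta_reg_cut < 1)
  structure(list(emg_wake_quantile = emg_wake_quantile,
                 delta_ratio_cut = delta_ratio_cut,
                 theta_reg_cut = theta_reg_cut,
                 emg_wake_cut = emg_wake_cut),
            class = "staging_thresholds")
}

#' Resolve the subject-specific wake cut
#'
#' @param thr A [staging_thresholds()].
#' @param tones Numeric vector of per-window EMG tones for the subject.
#' @return `thr` with `emg_wake_cut` filled in (uV RMS).
#' @export
resolve_thresholds <- function(thr, tones) {
  stopifnot(inherits(thr, "staging_thresholds"), length(tones) >= 2)
  if (!is.null(thr$emg_wake_cut)) return(thr)
  if (is.numeric(thr$emg_wake_quantile)) {
    thr$emg_wake_cut <- unname(stats::quantile(tones, thr$emg_wake_quantile))
  } else {
    lt <- log(pmax(tones, 1e-9))
    km <- stats::kmeans(lt, centers = range(lt), iter.max = 50)
    thr$emg_wake_cut <- exp(mean(km$centers))
  }
  thr
}

#' Score one staging window
#'
#' Rule order: wake if EMG tone exceeds the subject's wake cut; else
#' NREM if the delta ratio delta/(delta+theta) reaches
#' `delta_ratio_cut`; else REM if theta regularity reaches
#' `theta_reg_cut`; else NREM (fallback).
#'
#' @param features List or one-row data.frame with `emg_tone`,
#'   `delta_power`, `theta_power`, `theta_regularity`.
#' @param thr A resolved [staging_thresholds()] (`emg_wake_cut` set).
#' @return `"W"`, `"N"` or `"R"`.
#' @export
score_window <- function(features, thr) {
  if (is.null(thr$emg_wake_cut))
    stop("thresholds not resolved; call resolve_thresholds() first")
  if (features$emg_tone > thr$emg_wake_cut) return("W")
  dr <- features$delta_power /
    (features$delta_power + features$theta_power)
  if (!is.finite(dr)) dr <- 1            # silent EEG defaults to NREM
  if (dr >= thr$delta_ratio_cut) return("N")
  if (features$theta_regularity >= thr$theta_reg_cut) return("R")
  "N"
}

# cumsum-based mean of v over second-windows [a_t, b_t) (1-based, inclusive
# start, exclusive end expressed as last index b_t - 1)
windowed_mean <- function(v, a, b) {
  cs <- c(0, cumsum(v))
  (cs[b] - cs[a]) / (b - a)
}

#' Per-second vigilance labels
#'
#' For each second `t` of the recording the 25-s window `[t-12, t+13)`
#' (clipped at the record boundaries) is scored and its state assigned
#' to that second.  Window features are the mean of 2-s Hann FFT
#' periodograms starting at each whole second inside the window
#' (delta/theta power, theta regularity) and the window RMS of the EMG.
#'
#' @param record A [signal_record()] of at least 25 s with >= 1 EEG and
#'   >= 1 EMG channel.
#' @param thr A [staging_thresholds()]; the wake cut is resolved on this
#'   record's tone distribution if not already set.
#' @param cfg A [study_config()].
#' @param window_s Staging window length in seconds (odd; default 25).
#' @return Character vector of `"W"/"N"/"R"`, one per whole second.
#' @export
per_second_labels <- function(record, thr = staging_thresholds(),
                              cfg = study_config(), window_s = 25) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$sampling_rate
  S <- floor(record_duration(record))
  if (S < window_s) stop("record shorter than one staging window (",
                         window_s, " s)")
  half_lo <- (window_s - 1) %/% 2
  half_hi <- window_s - half_lo            # window [t - half_lo, t + half_hi)

  eeg <- record$channels[[which(record$roles == "EEG")[1]]]
  if (!is.null(cfg$notch_hz)) eeg <- notch_filter(eeg, fs, cfg$notch_hz)
  emg <- record$channels[[which(record$roles == "EMG")[1]]]

  # per-second 2-s periodograms of the EEG, chunked
  nw <- cfg$fft_window_s * fs
  nseg <- S - cfg$fft_window_s + 1         # segments starting at 0..S-2
  f <- fs * (0:(nw %/% 2)) / nw
  dsel <- f >= cfg$swa_band[1] & f < cfg$swa_band[2]
  tsel <- f >= cfg$theta_band[1] & f < cfg$theta_band[2]
  d_seg <- numeric(nseg); th_seg <- numeric(nseg)
  tb_seg <- matrix(0, sum(tsel), nseg)
  chunk <- max(1, as.integer(4e6 %/% nw))
  for (from in seq(1, nseg, by = chunk)) {
    to <- min(from + chunk - 1, nseg)
    idx0 <- (from:to) - 1                  # segment start seconds (0-based)
    segs <- matrix(eeg[rep(idx0 * fs, each = nw) + seq_len(nw)], nrow = nw)
    P <- segment_periodograms(segs)
    d_seg[from:to] <- colSums(P[dsel, , drop = FALSE])
    th_seg[from:to] <- colSums(P[tsel, , drop = FALSE])
    tb_seg[, from:to] <- P[tsel, , drop = FALSE]
  }

  # window extents per second t = 0..S-1 (in seconds, half-open [a, b))
  t0 <- 0:(S - 1)
  a <- pmax(0, t0 - half_lo)
  b <- pmin(S, t0 + half_hi)
  # spectral segments fully inside [a, b): starts a .. b-2  -> 1-based a+1..b-1
  seg_a <- a + 1
  seg_b <- b - cfg$fft_window_s + 1
  d_win <- windowed_mean(d_seg, seg_a, seg_b + 1)
  th_win <- windowed_mean(th_seg, seg_a, seg_b + 1)
  tb_win <- t(apply(tb_seg, 1, function(v) windowed_mean(v, seg_a, seg_b + 1)))

  # theta regularity of the window-mean theta spectrum
  pk <- max.col(t(tb_win), ties.method = "first")
  nb_lo <- pmax(1, pk - 1); nb_hi <- pmin(nrow(tb_win), pk + 1)
  tot <- colSums(tb_win)
  peak3 <- vapply(seq_len(S), function(i)
    sum(tb_win[nb_lo[i]:nb_hi[i], i]), numeric(1))
  treg <- ifelse(tot > 0, pmin(1, peak3 / tot), 0)

  # EMG window RMS via per-second sums
  emg_s <- emg[seq_len(S * fs)]
  sec <- rep(seq_len(S), each = fs)
  sx <- rowsum(emg_s, sec)[, 1]
  sx2 <- rowsum(emg_s^2, sec)[, 1]
  nwin <- (b - a) * fs
  msum <- windowed_mean(sx, a + 1, b + 1) * (b - a)    # window sums
  m2sum <- windowed_mean(sx2, a + 1, b + 1) * (b - a)
  tone <- sqrt(pmax(m2sum / nwin - (msum / nwin)^2, 0))

  thr <- resolve_thresholds(thr, tone)
  dr <- d_win / (d_win + th_win)
  dr[!is.finite(dr)] <- 1
  unname(ifelse(tone > thr$emg_wake_cut, "W",
                ifelse(dr >= thr$delta_ratio_cut, "N",
                       ifelse(treg >= thr$theta_reg_cut, "R", "N"))))
}

#' Aggregate per-second labels to epochs
#'
#' Each epoch's label is the modal per-second label; ties are broken by
#' the fixed priority W > N > R.  A trailing partial epoch is truncated
#' with a warning.
#'
#' @param per_second Character vector of `"W"/"N"/"R"`.
#' @param epoch_s Epoch length in seconds.
#' @param start_zt,subject_id,genotype,sex,schedule Metadata for the
#'   resulting [hypnogram()].
#' @return A [hypnogram()].
#' @export
aggregate_epochs <- function(per_second, epoch_s = 10, start_zt = 0,
                             subject_id = "s1", genotype = "WT", sex = "M",
                             schedule = light_schedule()) {
  n <- length(per_second) %/% epoch_s
  if (n * epoch_s < length(per_second)) {
    warning("truncating ", length(per_second) - n * epoch_s,
            " trailing second(s) not filling an epoch")
    per_second <- per_second[seq_len(n * epoch_s)]
  }
  code <- match(per_second, state_levels())
  ep <- rep(seq_len(n), each = epoch_s)
  counts <- vapply(1:3, function(s) rowsum((code == s) + 0L, ep)[, 1],
                   numeric(n))
  lab <- state_levels()[max.col(matrix(counts, nrow = n), ties.method = "first")]
  hypnogram(lab, epoch_s = epoch_s, start_zt = start_zt,
            subject_id = subject_id, genotype = genotype, sex = sex,
            schedule = schedule)
}

#' Stage a whole recording
#'
#' Convenience wrapper: per-second labels then epoch aggregation, with
#' optional manual overrides (a data.frame of `epoch_index`, `label`)
#' applied last.
#'
#' @param record A [signal_record()].
#' @param thr A [staging_thresholds()].
#' @param cfg A [study_config()].
#' @param overrides Optional data.frame with columns `epoch_index`
#'   (0-based) and `label`.
#' @param ... Metadata passed to [aggregate_epochs()].
#' @return A [hypnogram()].
#' @export
stage_record <- function(record, thr = staging_thresholds(),
                         cfg = study_config(), overrides = NULL, ...) {
  sec <- per_second_labels(record, thr, cfg)
  hyp <- aggregate_epochs(sec, epoch_s = cfg$epoch_s,
                          start_zt = record$start_zt,
                          schedule = record$schedule, ...)
  if (!is.null(overrides)) {
    stopifnot(all(c("epoch_index", "label") %in% names(overrides)),
              all(overrides$label %in% state_levels()))
    idx <- overrides$epoch_index + 1L
    if (any(idx < 1 | idx > length(hyp$labels)))
      stop("override epoch_index out of range")
    hyp$labels[idx] <- overrides$label
  }
  hyp
}

#' Staging confusion matrix
#'
#' @param pred,truth [hypnogram()]s of equal length and epoching.
#' @return List with `matrix` (3x3 counts, rows = truth, columns =
#'   predicted), `recall` (per true state), and `accuracy`.
#' @export
staging_confusion <- function(pred, truth) {
  if (length(pred$labels) != length(truth$labels) ||
      pred$epoch_s != truth$epoch_s)
    stop("hypnograms differ in length or epoch size")
  lv <- state_levels()
  m <- table(factor(truth$labels, lv), factor(pred$labels, lv))
  m <- matrix(as.integer(m), 3, 3, dimnames = list(truth = lv, pred = lv))
  rec <- diag(m) / pmax(rowSums(m), 1)
  rec[rowSums(m) == 0] <- NA_real_
  list(matrix = m, recall = rec, accuracy = sum(diag(m)) / sum(m))
}
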