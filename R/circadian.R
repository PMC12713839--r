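## Locomotor-activity rhythm metrics: zeitgeber activity profiles,
## light/dark phase totals, the Sokolove-Bushell chi-square periodogram
## and actogram matrices.

activity_zt <- function(act) {
  (act$start_zt + (seq_along(act$counts) - 1) * act$bin_min / 60) %% 24
}

check_whole_days <- function(act) {
  n_day <- length(act$counts) * act$bin_min / 1440
  if (abs(n_day - round(n_day)) > 1e-9)
    stop("series must cover a whole number of days")
  as.integer(round(n_day))
}

#' Zeitgeber activity profile
#'
#' Mean counts per zeitgeber bin across recorded LD days.  The sum of
#' the bin means equals the mean daily total.
#'
#' @param act An LD [activity_series()] covering whole days.
#' @param bin_h Bin width in hours.
#' @return data.frame with columns `bin_start_zt`, `mean_counts`.
#' @export
activity_profile <- function(act, bin_h = 1) {
  stopifnot(inherits(act, "activity_series"))
  if (act$schedule$dd)
    stop("activity profiles are zeitgeber-referenced; DD data have no ZT")
  days <- check_whole_days(act)
  bins <- seq(0, 24 - bin_h, by = bin_h)
  bin <- floor(activity_zt(act) / bin_h) * bin_h
  s <- rowsum(act$counts, factor(bin, levels = bins))[, 1]
  data.frame(bin_start_zt = bins, mean_counts = unname(s) / days)
}

#' Light/dark phase activity totals
#'
#' Mean daily activity totals over 24 h and over the 12-h light and dark
#' phases; light + dark equals the total exactly.
#'
#' @param act An LD [activity_series()] covering whole days.
#' @return List with `total`, `light`, `dark` (mean counts per day).
#' @export
phase_totals <- function(act) {
  stopifnot(inherits(act, "activity_series"))
  if (act$schedule$dd) stop("phase totals require LD data")
  days <- check_whole_days(act)
  ph <- zt_phase(activity_zt(act), act$schedule)
  light <- sum(act$counts[ph == "light"]) / days
  dark <- sum(act$counts[ph == "dark"]) / days
  list(total = light + dark, light = light, dark = dark)
}

#' Chi-square periodogram
#'
#' Sokolove-Bushell chi-square periodogram over a candidate period grid
#' with one grid step per data bin.  For a candidate period of `K` bins
#' with `N` complete cycles (tail truncated), the statistic is
#' `Qp = N * sum_h (M_h - M)^2 / Var(x)`, where `M_h` are the K column
#' means of the folded series, `M` and `Var(x)` the mean and (population)
#' variance of the bins used.  Under the i.i.d. null Qp is approximately
#' chi-square with `K - 1` degrees of freedom, giving the per-candidate
#' significance threshold at level `alpha`.
#'
#' @param act An [activity_series()] (typically the DD segment).
#' @param p_min,p_max Candidate period range in hours.
#' @param alpha Significance level for the chi-square threshold.
#' @return An object of class `periodogram_result`: list with
#'   `periodogram` (data.frame: `period_h`, `k_bins`, `n_cycles`, `qp`,
#'   `threshold`), `best_period`, `best_qp`, `best_excess`
#'   (peak Qp minus its threshold), `alpha`.
#' @export
chi_square_periodogram <- function(act, p_min = 20, p_max = 28,
                                   alpha = 0.05) {
  stopifnot(inherits(act, "activity_series"), p_min > 0, p_min < p_max)
  x <- act$counts
  bin_h <- act$bin_min / 60
  k_min <- max(2L, as.integer(round(p_min / bin_h)))
  k_max <- as.integer(round(p_max / bin_h))
  if (length(x) < 2 * k_max)
    stop("need at least 2 complete cycles at the longest candidate period (",
         2 * k_max, " bins, have ", length(x), ")")
  ks <- k_min:k_max
  qp <- numeric(length(ks)); nc <- integer(length(ks))
  for (i in seq_along(ks)) {
    K <- ks[i]
    N <- length(x) %/% K
    nc[i] <- N
    xs <- x[seq_len(K * N)]
    Mh <- rowMeans(matrix(xs, nrow = K))
    Mbar <- mean(xs)
    v <- mean((xs - Mbar)^2)
    qp[i] <- if (v > 0) N * sum((Mh - Mbar)^2) / v else 0
  }
  thr <- stats::qchisq(1 - alpha, df = ks - 1)
  pg <- data.frame(period_h = ks * bin_h, k_bins = ks, n_cycles = nc,
                   qp = qp, threshold = thr)
  best <- which.max(qp)
  structure(list(periodogram = pg,
                 best_period = pg$period_h[best],
                 best_qp = qp[best],
                 best_excess = qp[best] - thr[best],
                 alpha = alpha),
            class = "periodogram_result")
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf("<periodogram_result> best period %.3f h, Qp %.1f (excess over %g%% threshold: %.1f)\n",
              x$best_period, x$best_qp, 100 * (1 - x$alpha), x$best_excess))
  invisible(x)
}

#' Actogram matrix
#'
#' Day-by-day raster of activity counts; double-plotted rows concatenate
#' day d with day d+1 (the last row's second half is NA).
#'
#' @param act An [activity_series()] covering whole days.
#' @param double_plot Logical.
#' @return Numeric matrix, days x (bins per 24 h, doubled if
#'   double-plotted).
#' @export
actogram_matrix <- function(act, double_plot = TRUE) {
  stopifnot(inherits(act, "activity_series"))
  days <- check_whole_days(act)
  bpd <- as.integer(1440 / act$bin_min)
  m <- matrix(act$counts, nrow = days, ncol = bpd, byrow = TRUE)
  if (!double_plot) return(m)
  nxt <- rbind(m[-1, , drop = FALSE], matrix(NA_real_, 1, bpd))
  cbind(m, nxt)
}

#' Daily activity onsets
#'
#' QC estimator of the daily activity onset: counts are smoothed with a
#' centred moving average, and the onset of day d is the first bin of
#' that day at or above 20% of the day's smoothed maximum that is
#' preceded by at least `min_low_h` hours below that level.  Used for
#' free-running drift checks, not headline metrics.
#'
#' @param act An [activity_series()] covering whole days.
#' @param smooth_bins Moving-average width in bins (odd).
#' @param thresh_frac Threshold as a fraction of the daily smoothed max.
#' @param min_low_h Required quiescent span before onset, hours.
#' @return data.frame with columns `day` (1-based), `onset_h` (hours
#'   since series start, NA if not found).
#' @export
activity_onsets <- function(act, smooth_bins = 29, thresh_frac = 0.2,
                            min_low_h = 4) {
  days <- check_whole_days(act)
  bpd <- as.integer(1440 / act$bin_min)
  sm <- as.numeric(stats::filter(act$counts, rep(1 / smooth_bins, smooth_bins),
                                 sides = 2))
  low_bins <- as.integer(min_low_h * 60 / act$bin_min)
  onset_h <- rep(NA_real_, days)
  for (d in seq_len(days)) {
    idx <- ((d - 1) * bpd + 1):(d * bpd)
    thr <- thresh_frac * max(sm[idx], na.rm = TRUE)
    for (i in idx) {
      if (is.na(sm[i]) || sm[i] < thr) next
      pre <- max(1, i - low_bins):(i - 1)
      if (length(pre) < low_bins / 2) next
      if (all(sm[pre] < thr, na.rm = TRUE)) {
        onset_h[d] <- (i - 1) * act$bin_min / 60
        break
      }
    }
  }
  data.frame(day = seq_len(days), onset_h = onset_h)
}
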