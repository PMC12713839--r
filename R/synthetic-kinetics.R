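## Generative vigilance-state kinetics: per-epoch first-order Markov
## chains with phase-switched transition matrices (light / dark, plus an
## optional mid-dark "nap" matrix).  Rows and columns follow the
## canonical state order W, N, R.

#' Vigilance-state kinetics
#'
#' Per-epoch 3x3 transition probability matrices, one per photic phase,
#' driving the hypnogram simulator.  `W -> R` transitions are
#' structurally excluded (they are vanishingly rare in rodents), so
#' `P["W","R"]` must be 0.
#'
#' @param light,dark 3x3 row-stochastic matrices (rows = from-state,
#'   order W, N, R).
#' @param nap Optional third matrix used during the nap window; `NULL`
#'   disables.
#' @param nap_zt Length-2 ZT window `c(from, to)` for the nap matrix.
#' @param pi0 Initial state distribution (length 3, sums to 1).
#' @return An object of class `vigilance_kinetics`.
#' @export
vigilance_kinetics <- function(light, dark, nap = NULL, nap_zt = c(19, 21),
                               pi0 = c(W = 0.5, N = 0.45, R = 0.05)) {
  check_kin_matrix <- function(P, what) {
    if (!is.matrix(P) || !all(dim(P) == c(3, 3)))
      stop(what, " must be a 3x3 matrix")
    if (any(P < 0)) stop(what, " has negative entries")
    if (any(abs(rowSums(P) - 1) > 1e-12))
      stop(what, " rows must sum to 1 (got ",
           paste(format(rowSums(P)), collapse = ", "), ")")
    if (P[1, 3] != 0)
      stop(what, ": direct W -> R transitions are excluded; P[W,R] must be 0")
    dimnames(P) <- list(from = state_levels(), to = state_levels())
    P
  }
  light <- check_kin_matrix(light, "light matrix")
  dark <- check_kin_matrix(dark, "dark matrix")
  if (!is.null(nap)) nap <- check_kin_matrix(nap, "nap matrix")
  stopifnot(length(pi0) == 3, abs(sum(pi0) - 1) < 1e-9, all(pi0 >= 0))
  structure(list(light = light, dark = dark, nap = nap, nap_zt = nap_zt,
                 pi0 = pi0),
            class = "vigilance_kinetics")
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the 3x3 per-epoch matrix for eigenvalue 1;
#' the long-run state occupancy if that matrix ran indefinitely.
#'
#' @param P A 3x3 row-stochastic matrix.
#' @return Named numeric vector over W, N, R summing to 1.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  stats::setNames(v / sum(v), state_levels())
}

#' Genotype presets for the synthetic cohort
#'
#' Numeric presets emulating a nocturnal wild-type mouse and a mutant
#' with attenuated circadian REM-sleep modulation: relative to WT the
#' mutant has a lower per-epoch `N -> R` rate in the light phase, a
#' higher one in the dark phase, reduced dark-phase wakefulness, and
#' lower, less front-loaded nocturnal locomotor activity with a slightly
#' shorter free-running period.  The WT preset includes a mid-dark nap
#' window (ZT19-21) scored with the light-phase matrix.
#'
#' @return Named list with elements `WT` and `MUT`, each a list of
#'   `kinetics` ([vigilance_kinetics()]) and `activity`
#'   ([activity_model()]).
#' @export
genotype_presets <- function() {
  m <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)
  wt_light <- m(0.920, 0.080, 0.000,
                0.045, 0.930, 0.025,
                0.050, 0.100, 0.850)
  wt_dark <- m(0.960, 0.040, 0.000,
               0.085, 0.907, 0.008,
               0.080, 0.120, 0.800)
  mut_light <- m(0.920, 0.080, 0.000,
                 0.045, 0.943, 0.012,
                 0.050, 0.100, 0.850)
  mut_dark <- m(0.945, 0.055, 0.000,
                0.075, 0.903, 0.022,
                0.080, 0.120, 0.800)
  list(
    WT = list(
      kinetics = vigilance_kinetics(wt_light, wt_dark, nap = wt_light),
      activity = activity_model(period_h = 23.75, mean_counts = 10,
                                dark_fraction = 0.85, early_peak_weight = 0.60,
                                dispersion = 3, days_ld = 7, days_dd = 10)
    ),
    MUT = list(
      kinetics = vigilance_kinetics(mut_light, mut_dark),
      activity = activity_model(period_h = 23.68, mean_counts = 6.5,
                                dark_fraction = 0.80, early_peak_weight = 0.42,
                                dispersion = 3, days_ld = 7, days_dd = 10)
    )
  )
}

#' Simulate a hypnogram from vigilance kinetics
#'
#' Steps a first-order Markov chain once per epoch, switching the
#' transition matrix with the photic phase of the epoch's onset ZT
#' (light, dark, or the optional nap window inside the dark phase).
#'
#' @param kin A [vigilance_kinetics()].
#' @param days Number of simulated 24-h days (>= 1, fractional allowed).
#' @param epoch_s Epoch length in seconds.
#' @param seed Integer seed (reproducible output).
#' @param start_zt Zeitgeber hour of epoch 0.
#' @param subject_id,genotype,sex Metadata copied into the hypnogram.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(kin, days = 1, epoch_s = 10, seed = 1,
                               start_zt = 0, subject_id = "sim",
                               genotype = "WT", sex = "M") {
  stopifnot(inherits(kin, "vigilance_kinetics"), days >= 1)
  n <- round(days * 86400 / epoch_s)
  zt <- (start_zt + (seq_len(n) - 1) * epoch_s / 3600) %% 24
  phase <- ifelse(zt < 12, 1L, 2L)                     # 1 light, 2 dark
  if (!is.null(kin$nap))
    phase[zt >= kin$nap_zt[1] & zt < kin$nap_zt[2]] <- 3L
  mats <- list(kin$light, kin$dark, if (!is.null(kin$nap)) kin$nap else kin$dark)
  # precompute cumulative rows for fast inverse-CDF stepping
  cum <- lapply(mats, function(P) t(apply(P, 1, cumsum)))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  u <- stats::runif(n)
  s <- integer(n)
  s0 <- findInterval(u[1], cumsum(kin$pi0)) + 1L
  s[1] <- min(s0, 3L)
  for (i in 2:n) {
    cr <- cum[[phase[i]]][s[i - 1L], ]
    s[i] <- if (u[i] <= cr[1]) 1L else if (u[i] <= cr[2]) 2L else 3L
  }
  hypnogram(state_levels()[s], epoch_s = epoch_s, start_zt = start_zt,
            subject_id = subject_id, genotype = genotype, sex = sex)
}
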