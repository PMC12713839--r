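## Group-comparison battery: unpaired t with Cohen's d, two-way
## fixed-effects ANOVA (Type III, effect coding), Sidak and Fisher-LSD
## post hoc, Shapiro-Wilk normality and Brown-Forsythe variance checks,
## mean +/- SEM summaries.

#' Unpaired two-tailed t-test with Cohen's d
#'
#' Pooled-variance Student t by default (matching the usual genotype
#' comparisons); if a Brown-Forsythe check on the two groups rejects at
#' `alpha` the result is additionally flagged and, when
#' `welch_fallback = TRUE`, the reported test switches to Welch.
#' Cohen's d is the mean difference over the pooled SD.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param alpha Level for the variance-homogeneity flag.
#' @param welch_fallback Switch to Welch when homogeneity is rejected.
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_diff`, `summary`
#'   (mean +/- SEM per group), `variance_flag`, `method`.
#' @export
unpaired_t <- function(group_a, group_b, alpha = 0.05,
                       welch_fallback = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  n1 <- length(group_a); n2 <- length(group_b)
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- if (sp2 > 0) (m1 - m2) / sqrt(sp2) else 0

  bf <- normality_and_variance(list(a = group_a, b = group_b))
  flag <- !is.na(bf$brown_forsythe$p) && bf$brown_forsythe$p < alpha

  if (sp2 == 0) {                       # degenerate: no variance anywhere
    tt <- list(statistic = c(t = 0), parameter = c(df = n1 + n2 - 2),
               p.value = if (m1 == m2) 1 else 0)
    method <- "pooled"
  } else if (flag && welch_fallback) {
    tt <- stats::t.test(group_a, group_b)
    method <- "welch"
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
    method <- "pooled"
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = d, mean_diff = m1 - m2,
       summary = group_summary(list(a = group_a, b = group_b)),
       variance_flag = flag, method = method)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `value ~ A * B` as a fixed-effects linear model with sum-to-zero
#' (effect) coding and reports Type III sums of squares, which handle
#' the unbalanced group sizes typical of animal cohorts.  Cell means,
#' SEMs and the residual mean square are returned for post-hoc tests.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Factors (coerced) with >= 2 levels each; all
#'   crossed cells must be non-empty.
#' @return List with `anova` (data.frame: effect, ss, df, f, p),
#'   `cells` (per-cell n, mean, sem), `mse`, `df_error`, `model_note`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b),
            nlevels(a) >= 2, nlevels(b) >= 2)
  tab <- table(a, b)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", levels(a)[empty[1]], " x ",
         levels(b)[empty[2]])
  }
  dat <- data.frame(y = values, A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = stats::contr.sum,
                                    B = stats::contr.sum))
  if (stats::var(values) == 0) {
    # degenerate constant response: every effect is exactly zero
    an <- data.frame(`Sum Sq` = rep(0, 4),
                     Df = c(nlevels(a) - 1, nlevels(b) - 1,
                            (nlevels(a) - 1) * (nlevels(b) - 1),
                            length(values) - nlevels(a) * nlevels(b)),
                     check.names = FALSE,
                     row.names = c("A", "B", "A:B", "Residuals"))
    f <- c(0, 0, 0, NA); p <- c(1, 1, 1, NA)
  } else {
    an <- car::Anova(fit, type = 3)
    an <- an[c("A", "B", "A:B", "Residuals"), ]
    f <- an[["F value"]]; p <- an[["Pr(>F)"]]
  }
  out <- data.frame(effect = c("A", "B", "A:B", "error"),
                    ss = an[["Sum Sq"]], df = an[["Df"]],
                    f = f, p = p)
  cells <- stats::aggregate(y ~ A + B, dat, function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_))
  cells <- do.call(data.frame, cells)
  names(cells) <- c("A", "B", "n", "mean", "sem")
  mse <- an["Residuals", "Sum Sq"] / an["Residuals", "Df"]
  list(anova = out, cells = cells, mse = mse,
       df_error = an["Residuals", "Df"],
       model_note = "fixed-effects two-way ANOVA, Type III SS (effect coding); not repeated-measures")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to 1.  The family size `m` defaults
#' to the number of p-values but may be larger (e.g. all time bins of a
#' profile).
#'
#' @param raw_p Numeric vector of p-values in [0, 1].
#' @param m Family size, `m >= length(raw_p) >= 1`.
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(raw_p, m = length(raw_p)) {
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(raw_p) || length(raw_p) < 1)
    stop("family size m must be >= length(raw_p) >= 1")
  pmin(1, 1 - (1 - raw_p)^m)
}

#' Fisher's LSD post-hoc test
#'
#' Unadjusted pairwise comparisons after an ANOVA:
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` with the
#' ANOVA's error degrees of freedom.
#'
#' @param means Named numeric vector of cell means.
#' @param ns Named integer vector of cell sizes (same names).
#' @param mse Residual mean square from the ANOVA.
#' @param df_error Error degrees of freedom.
#' @param pairs Two-column character matrix (or list of length-2
#'   vectors) of cell names to compare; default all pairs.
#' @return data.frame with columns `a`, `b`, `diff`, `t`, `p`.
#' @export
fisher_lsd <- function(means, ns, mse, df_error, pairs = NULL) {
  stopifnot(length(means) == length(ns), !is.null(names(means)),
            setequal(names(means), names(ns)), mse >= 0, df_error >= 1)
  ns <- ns[names(means)]
  if (is.null(pairs)) {
    cmb <- utils::combn(names(means), 2)
    pairs <- t(cmb)
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  bad <- !(pairs %in% names(means))
  if (any(bad))
    stop("unknown cell(s) in pairs: ", paste(unique(pairs[bad]), collapse = ", "))
  d <- means[pairs[, 1]] - means[pairs[, 2]]
  se <- sqrt(mse * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  t <- ifelse(se > 0, d / se, 0)
  data.frame(a = pairs[, 1], b = pairs[, 2], diff = unname(d),
             t = unname(t),
             p = unname(2 * stats::pt(-abs(t), df_error)),
             row.names = NULL)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group (skipped with a flag when n < 3 or the group
#' is constant) and the Brown-Forsythe test: a one-way ANOVA on the
#' absolute deviations from each group's median.
#'
#' @param groups Named list of numeric vectors.
#' @return List with `shapiro` (data.frame: group, n, w, p, skipped) and
#'   `brown_forsythe` (list: f, df1, df2, p).
#' @export
normality_and_variance <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sw <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 3 || stats::sd(x) == 0)
      return(data.frame(group = g, n = length(x), w = NA_real_,
                        p = NA_real_, skipped = TRUE))
    s <- stats::shapiro.test(x)
    data.frame(group = g, n = length(x), w = unname(s$statistic),
               p = s$p.value, skipped = FALSE)
  }))
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  f <- factor(rep(names(groups), lengths(groups)))
  df1 <- nlevels(f) - 1
  df2 <- length(z) - nlevels(f)
  gm <- tapply(z, f, mean)
  ssb <- sum(tabulate(f) * (gm - mean(z))^2)
  sse <- sum((z - gm[f])^2)
  sst <- ssb + sse
  bf <- if (sst > 0 && sse > 1e-12 * sst && df2 > 0) {
    fstat <- (ssb / df1) / (sse / df2)
    list(f = fstat, df1 = df1, df2 = df2,
         p = stats::pf(fstat, df1, df2, lower.tail = FALSE))
  } else list(f = if (sst > 0) Inf else 0, df1 = df1, df2 = df2,
              p = NA_real_)
  list(shapiro = sw, brown_forsythe = bf)
}

#' Mean +/- SEM summary per group
#'
#' @param groups Named list of numeric vectors (n >= 1 each).
#' @return data.frame with columns `group`, `n`, `mean`, `sem` (missing
#'   for n = 1).
#' @export
group_summary <- function(groups) {
  stopifnot(is.list(groups), all(lengths(groups) >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_)
  }))
}
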