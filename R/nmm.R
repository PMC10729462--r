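#' Empirical relative effect of one sample with respect to another
#'
#' The rank-based treatment-effect measure
#' `p = P(X1 < X2) + 1/2 P(X1 = X2)`: the probability that values in the
#' first sample fall below values in the second, with ties split.  Estimated
#' by the midrank plug-in, which equals the pair-counting estimate
#' `(#\{x1 < x2\} + 1/2 #\{x1 = x2\}) / (n1 n2)` exactly.  `p = 0.5` means no
#' tendency; `p(a, b) + p(b, a) = 1` always.
#'
#' @param sample1,sample2 Non-empty numeric vectors.
#' @return A scalar in [0, 1].
#' @export
#' @examples
#' relative_effect(c(1, 2), c(2, 3))  # 0.875
relative_effect <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 == 0 || n2 == 0) stop("samples must be non-empty", call. = FALSE)
  r <- rank(c(sample1, sample2))  # midranks
  (mean(r[(n1 + 1):(n1 + n2)]) - (n2 + 1) / 2) / n1
}

#' Per-cell relative effects for one treatment period
#'
#' Midranks are computed over all observations of the chosen period, and the
#' relative effect of each (treatment, time) cell against that pooled
#' reference is reported: `p_hat = (mean cell midrank - 1/2) / N`.  With
#' equal cell sizes the count-weighted mean of all eight cells is exactly
#' 0.5.
#'
#' @param data A trial data frame.
#' @param period Treatment period to analyse (1 or 2).
#' @param outcome Outcome column.
#' @return A tibble with columns `treatment`, `time`, `n`, `rel_effect`.
#' @export
relative_effect_table <- function(data, period,
                                  outcome = c("count", "vas", "binary")) {
  outcome <- match.arg(outcome)
  data <- as_trial_data(data)
  if (!period %in% 1:2) stop("unknown period: ", period, call. = FALSE)
  d <- data[data$period == period, ]
  N <- nrow(d)
  r <- rank(d[[outcome]])
  cell <- tapply(r, list(d$treatment, d$time), mean)
  cnt <- table(d$treatment, d$time)
  tibble::tibble(
    treatment = rep(rownames(cell), times = ncol(cell)),
    time = rep(as.integer(colnames(cell)), each = nrow(cell)),
    n = as.integer(cnt)[seq_along(cell)],
    rel_effect = (as.vector(cell) - 0.5) / N
  )
}

#' ANOVA-type statistic for the treatment-by-time interaction in one period
#'
#' Rank-based test of whether the longitudinal profiles of the two treatment
#' groups differ within one treatment period, where the groups are
#' independent (each subject appears in a period under exactly one
#' treatment, by sequence).  The design is a 2 x 4 layout with treatment as
#' the whole-plot factor and time as the repeated (sub-plot) factor.
#' Midranks over all observations of the period form subject-level rank
#' vectors; the ANOVA-type statistic is the quadratic form of the
#' interaction-contrasted cell mean ranks, normalised by the trace of the
#' contrasted empirical covariance of the rank vectors, and its null
#' distribution is approximated by an F distribution with box-type estimated
#' numerator degrees of freedom `f = tr(TV)^2 / tr(TVTV)` and (by default)
#' infinite denominator degrees of freedom.
#'
#' @inheritParams relative_effect_table
#' @param denominator `"infinite"` (default) for F(f, Inf), or
#'   `"estimated"` for a box-type finite denominator degrees of freedom.
#' @return An `ats_result`: `statistic`, `df1`, `df2`, `p_value`, `period`,
#'   and the per-cell relative-effect table.
#' @export
#' @examples
#' ats_interaction_test(generate_trial(seed = 1), period = 1, outcome = "count")
ats_interaction_test <- function(data, period,
                                 outcome = c("count", "vas", "binary"),
                                 denominator = c("infinite", "estimated")) {
  outcome <- match.arg(outcome)
  denominator <- match.arg(denominator)
  data <- as_trial_data(data)
  if (!period %in% 1:2) stop("unknown period: ", period, call. = FALSE)
  d <- data[data$period == period, ]
  d$.r <- rank(d[[outcome]])

  # canonical row order: each subject's 4 ranks are consecutive, times 1..4
  groups <- lapply(c("placebo", "verum"), function(g) {
    t(matrix(d$.r[d$treatment == g], nrow = 4L))
  })
  n_i <- vapply(groups, nrow, 0L)
  if (any(n_i < 2)) {
    stop("each treatment group needs at least 2 subjects in the period",
         call. = FALSE)
  }

  p_hat <- c(colMeans(groups[[1]]), colMeans(groups[[2]]))
  V <- matrix(0, 8, 8)
  V[1:4, 1:4] <- stats::cov(groups[[1]]) / n_i[1]
  V[5:8, 5:8] <- stats::cov(groups[[2]]) / n_i[2]

  centre <- function(a) diag(a) - 1 / a
  TT <- kronecker(centre(2), centre(4))  # interaction projection

  M <- TT %*% V
  tr1 <- sum(diag(M))
  if (tr1 <= .Machine$double.eps * 64) {
    stat <- 0; f1 <- 1; f2 <- Inf; p <- 1
  } else {
    stat <- drop(p_hat %*% TT %*% p_hat) / tr1
    f1 <- tr1^2 / sum(M * t(M))
    if (denominator == "infinite") {
      f2 <- Inf
      p <- stats::pchisq(stat * f1, df = f1, lower.tail = FALSE)
    } else {
      # box-type denominator df from the group-wise contributions
      contrib <- vapply(1:2, function(i) {
        Vi <- matrix(0, 8, 8)
        idx <- if (i == 1) 1:4 else 5:8
        Vi[idx, idx] <- V[idx, idx]
        Mi <- TT %*% Vi
        sum(Mi * t(Mi)) / (n_i[i] - 1)
      }, 0)
      f2 <- if (sum(contrib) > 0) tr1^2 / sum(contrib) else Inf
      p <- stats::pf(stat, f1, f2, lower.tail = FALSE)
    }
  }

  structure(list(
    statistic = stat, df1 = f1, df2 = f2, p_value = p,
    period = period, outcome = outcome, contrast = "interaction",
    n = stats::setNames(as.integer(n_i), c("placebo", "verum")),
    rel_effects = relative_effect_table(data, period, outcome)
  ), class = "ats_result")
}

#' Per-period interaction tests across a cross-over trial
#'
#' The marginal rank model handles the two treatment periods separately (it
#' cannot absorb the cross-over structure), so the interaction test is run
#' once per period and the two results combined by a chosen rule:
#' `"per_period"` reports both without combining (the default, matching how
#' the method is used in practice), `"bonferroni"` rejects when the smaller
#' p-value is below `alpha / 2`, and `"min_p"` is the liberal union rule
#' rejecting when the smaller p-value is below `alpha`.
#'
#' @inheritParams ats_interaction_test
#' @param rule Combination rule (see Details).
#' @param alpha Significance level for the combined decision.
#' @return An `nmm_result` holding both `ats_result`s, the rule and the
#'   combined decision (`NA` under `"per_period"`).
#' @export
nmm_crossover <- function(data, outcome = c("count", "vas", "binary"),
                          rule = c("per_period", "bonferroni", "min_p"),
                          alpha = 0.05,
                          denominator = c("infinite", "estimated")) {
  outcome <- match.arg(outcome)
  rule <- match.arg(rule)
  fits <- lapply(1:2, function(p)
    ats_interaction_test(data, p, outcome, denominator))
  p_min <- min(fits[[1]]$p_value, fits[[2]]$p_value)
  reject <- switch(rule,
    per_period = NA,
    bonferroni = p_min < alpha / 2,
    min_p = p_min < alpha
  )
  structure(list(periods = fits, rule = rule, alpha = alpha,
                 reject = reject, outcome = outcome),
            class = "nmm_result")
}

#' @export
print.ats_result <- function(x, ...) {
  cat("ANOVA-type interaction test (treatment x time), period ", x$period,
      ", outcome ", x$outcome, "\n", sep = "")
  cat(sprintf("  ATS = %0.4f, df = (%0.3f, %s), p = %0.4g\n",
              x$statistic, x$df1,
              if (is.finite(x$df2)) sprintf("%0.1f", x$df2) else "Inf",
              x$p_value))
  invisible(x)
}

#' @export
print.nmm_result <- function(x, ...) {
  cat("Nonparametric marginal model, per-period interaction tests (",
      x$outcome, ")\n", sep = "")
  for (f in x$periods) {
    cat(sprintf("  period %d: ATS = %0.4f, df1 = %0.3f, p = %0.4g\n",
                f$period, f$statistic, f$df1, f$p_value))
  }
  cat("  rule:", x$rule,
      if (!is.na(x$reject)) paste0("-> reject: ", x$reject) else "", "\n")
  invisible(x)
}
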