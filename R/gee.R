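#' Build the marginal-model design matrix for a cross-over trial
#'
#' The 13-parameter linear predictor of the marginal mean model: intercept;
#' treatment group indicator (verum = 1); period indicator (period 2 = 1);
#' three time dummies (times 2-4 against baseline); and the pairwise
#' group x period, group x time and period x time interactions.  Reference
#' cell: placebo, period 1, time 1.  Clusters are the subject-period blocks:
#' the between-period and within-period dependence structures are taken as
#' independent, so each period block is its own cluster (an optional
#' subject-fixed-effects extension absorbs between-period dependence
#' instead).
#'
#' The derived binary responder outcome is structurally zero at the baseline
#' visit (a responder is defined by reduction *from* baseline), so its
#' time-1 cell is not estimable on the logit scale; for `outcome =
#' "binary"` the design therefore drops the baseline rows and uses time 2
#' as the reference visit, giving a 10-parameter model of the same form.
#'
#' @param data A trial data frame.
#' @param outcome `"count"`, `"binary"` or `"vas"`.
#' @param subject_effects Add subject fixed effects (first subject as
#'   reference).  Off by default.
#' @return A list with the model matrix `X` (8n x 13 without subject
#'   effects; 6n x 10 for the binary outcome), response `y`, and the
#'   `cluster` factor.
#' @export
build_gee_design <- function(data, outcome = c("count", "binary", "vas"),
                             subject_effects = FALSE) {
  outcome <- match.arg(outcome)
  data <- as_trial_data(data)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not present", call. = FALSE)
  }
  times <- if (outcome == "binary") 2:4 else 1:4
  data <- data[data$time %in% times, ]
  G <- as.numeric(data$treatment == "verum")
  P <- as.numeric(data$period == 2)
  dummy_times <- times[-1]
  Td <- sapply(dummy_times, function(t) as.numeric(data$time == t))
  X <- cbind(1, G, P, Td, G * P, G * Td, P * Td)
  tn <- function(prefix) paste0(prefix, "time", dummy_times)
  colnames(X) <- c("(Intercept)", "group", "period2", tn(""),
                   "group:period2", tn("group:"), tn("period2:"))
  if (subject_effects) {
    S <- stats::model.matrix(~ subject_id, data = data)[, -1, drop = FALSE]
    X <- cbind(X, S)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("design matrix is rank deficient (rank ", qrX$rank, " < ",
            ncol(X), ")", call. = FALSE)
  }
  list(X = X, y = data[[outcome]],
       cluster = factor(paste(data$subject_id, data$period, sep = ":")))
}

#' Fit the GEE-type marginal model
#'
#' Solves the generalized estimating equations for the mean model of
#' [build_gee_design()] by iteratively reweighted updates, with a working
#' covariance that is either independence or exchangeable within the
#' subject-period clusters, and attaches the robust (sandwich) covariance.
#' For small numbers of clusters the Mancl-DeRouen leverage-adjusted
#' bias-corrected sandwich is available; the default switches it on for the
#' count outcome and off for the binary outcome, whose dichotomised variance
#' is close enough to homoscedastic that the correction is unnecessary.
#' Non-convergence and separation are flagged, never silently ignored.
#'
#' @param data A trial data frame.
#' @param outcome `"count"` (Poisson, log link), `"binary"` (Bernoulli,
#'   logit link) or `"vas"` (Gaussian, identity link -- a degenerate mode in
#'   which the independence fit reduces to ordinary least squares).
#' @param working Working correlation within clusters: `"independence"`
#'   or `"exchangeable"`.
#' @param correction Sandwich bias correction: `"bias_corrected"`
#'   (Mancl-DeRouen) or `"none"`; `NULL` picks the outcome default.
#' @param subject_effects Include subject fixed effects (see
#'   [build_gee_design()]).
#' @param max_iter,tol Iteration control for the estimating-equation solver.
#' @return A `gee_fit`: coefficient vector `beta`, robust covariance
#'   `vcov`, the naive model-based covariance, convergence information and
#'   the specification.
#' @export
#' @examples
#' fit <- fit_gee(generate_trial(seed = 1), "count")
#' tidy(fit)
fit_gee <- function(data, outcome = c("count", "binary", "vas"),
                    working = c("independence", "exchangeable"),
                    correction = NULL, subject_effects = FALSE,
                    max_iter = 50, tol = 1e-8) {
  outcome <- match.arg(outcome)
  working <- match.arg(working)
  stopifnot(tol > 0)
  family <- switch(outcome,
    count = stats::poisson("log"),
    binary = stats::binomial("logit"),
    vas = stats::gaussian("identity")
  )
  if (is.null(correction)) {
    correction <- if (outcome == "count") "bias_corrected" else "none"
  }
  correction <- match.arg(correction, c("bias_corrected", "none"))

  des <- build_gee_design(data, outcome, subject_effects)
  X <- des$X; y <- as.numeric(des$y); cl <- des$cluster
  p <- ncol(X)
  idx <- split(seq_along(y), cl)

  # initial value from the independence (GLM) fit
  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = family)$coefficients)
  if (anyNA(beta)) stop("design matrix not of full rank", call. = FALSE)

  alpha <- 0
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- family$linkinv(eta)
    dmu <- family$mu.eta(eta)
    vfun <- family$variance(mu)
    resid_p <- (y - mu) / sqrt(vfun)

    if (working == "exchangeable") {
      # moment estimator of the common within-cluster correlation
      num <- 0; den <- 0
      for (ix in idx) {
        r <- resid_p[ix]
        num <- num + sum(tcrossprod(r)) - sum(r^2)
        den <- den + length(r) * (length(r) - 1)
      }
      alpha <- max(min(num / den, 0.95), -0.3)
    }

    B <- matrix(0, p, p)   # sum D' V^-1 D
    U <- numeric(p)        # sum D' V^-1 (y - mu)
    for (ix in idx) {
      Dc <- X[ix, , drop = FALSE] * dmu[ix]
      sdv <- sqrt(vfun[ix])
      R <- if (working == "independence") diag(length(ix)) else {
        m <- matrix(alpha, length(ix), length(ix)); diag(m) <- 1; m
      }
      Vinv <- solve(R * tcrossprod(sdv))
      B <- B + crossprod(Dc, Vinv %*% Dc)
      U <- U + drop(crossprod(Dc, Vinv %*% (y[ix] - mu[ix])))
    }
    step <- solve(B, U)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("estimating equations did not converge in ", max_iter,
            " iterations", call. = FALSE)
  }
  separation <- family$family == "binomial" &&
    any(abs(drop(X %*% beta)) > 25)
  if (separation) {
    warning("fitted probabilities numerically 0/1: possible separation",
            call. = FALSE)
  }

  # sandwich pieces at the solution
  eta <- drop(X %*% beta)
  mu <- family$linkinv(eta)
  dmu <- family$mu.eta(eta)
  vfun <- family$variance(mu)
  B <- matrix(0, p, p)
  parts <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    ix <- idx[[j]]
    Dc <- X[ix, , drop = FALSE] * dmu[ix]
    sdv <- sqrt(vfun[ix])
    R <- if (working == "independence") diag(length(ix)) else {
      m <- matrix(alpha, length(ix), length(ix)); diag(m) <- 1; m
    }
    Vinv <- solve(R * tcrossprod(sdv))
    B <- B + crossprod(Dc, Vinv %*% Dc)
    parts[[j]] <- list(D = Dc, Vinv = Vinv, e = y[ix] - mu[ix])
  }
  Binv <- solve(B)
  meat <- matrix(0, p, p)
  for (pt in parts) {
    e <- pt$e
    if (correction == "bias_corrected") {
      H <- pt$D %*% Binv %*% t(pt$D) %*% pt$Vinv
      e <- solve(diag(length(e)) - H, e)
    }
    g <- drop(crossprod(pt$D, pt$Vinv %*% e))
    meat <- meat + tcrossprod(g)
  }
  vc <- Binv %*% meat %*% Binv
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(list(
    beta = stats::setNames(beta, colnames(X)), vcov = vc,
    vcov_naive = Binv, converged = converged, iterations = iter,
    separation = separation, alpha = if (working == "exchangeable") alpha,
    family = family$family, working = working, correction = correction,
    n_clusters = length(idx), n_obs = length(y), outcome = outcome,
    subject_effects = subject_effects
  ), class = "gee_fit")
}

#' Wald test of linear hypotheses on the marginal-model coefficients
#'
#' `W = (L b)' (L V L')^{-1} (L b)` with the robust covariance `V`,
#' referred to a chi-square distribution with `nrow(L)` degrees of freedom
#' (or an F distribution with `n_clusters - p` denominator degrees of
#' freedom for a small-sample variant).  The default contrast `"overall"`
#' tests all five coefficients involving the treatment-group indicator --
#' the overall treatment effect; `"main"` tests the group main effect alone.
#'
#' @param fit A `gee_fit`.
#' @param contrast `"overall"`, `"main"`, or a numeric matrix with one
#'   column per coefficient.
#' @param type `"chisq"` (default) or `"f"`.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`,
#'   `contrast`.
#' @export
wald_test <- function(fit, contrast = c("overall", "main"),
                      type = c("chisq", "f")) {
  stopifnot(inherits(fit, "gee_fit"))
  type <- match.arg(type)
  nm <- names(fit$beta)
  if (is.character(contrast)) {
    contrast <- match.arg(contrast)
    terms <- switch(contrast,
      overall = grep("^group($|:)", nm, value = TRUE),
      main = "group")
    L <- matrix(0, length(terms), length(nm),
                dimnames = list(terms, nm))
    L[cbind(seq_along(terms), match(terms, nm))] <- 1
    label <- contrast
  } else {
    L <- as.matrix(contrast)
    if (ncol(L) != length(nm)) {
      stop("contrast matrix must have one column per coefficient",
           call. = FALSE)
    }
    label <- "custom"
  }
  if (qr(L)$rank < nrow(L)) stop("contrast matrix not of full row rank",
                                 call. = FALSE)
  Lb <- drop(L %*% fit$beta)
  LVL <- L %*% fit$vcov %*% t(L)
  if (rcond(LVL) < .Machine$double.eps * 64) {
    stop("contrast covariance is singular", call. = FALSE)
  }
  W <- drop(Lb %*% solve(LVL, Lb))
  df1 <- nrow(L)
  if (type == "chisq") {
    tibble::tibble(statistic = W, df1 = df1, df2 = Inf,
                   p_value = stats::pchisq(W, df1, lower.tail = FALSE),
                   contrast = label, type = type)
  } else {
    df2 <- max(fit$n_clusters - length(nm), 1)
    Fstat <- W / df1
    tibble::tibble(statistic = Fstat, df1 = df1, df2 = df2,
                   p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                   contrast = label, type = type)
  }
}

#' Treatment effect on the outcome scale
#'
#' Back-transforms the treatment-group coefficient at the reference period
#' and time: the rate ratio for the count outcome (log link), the odds
#' ratio for the binary outcome (logit link), or the mean difference for
#' the Gaussian mode, with a robust Wald confidence interval.
#'
#' @param fit A converged `gee_fit`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `measure`, `estimate`, `conf_low`,
#'   `conf_high`.
#' @export
treatment_effect <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$converged) {
    stop("treatment effect undefined for an unconverged fit", call. = FALSE)
  }
  b <- fit$beta[["group"]]
  se <- sqrt(fit$vcov["group", "group"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- b + c(-1, 1) * z * se
  if (fit$family == "gaussian") {
    tibble::tibble(measure = "mean_difference", estimate = b,
                   conf_low = ci[1], conf_high = ci[2])
  } else {
    measure <- if (fit$family == "poisson") "rate_ratio" else "odds_ratio"
    tibble::tibble(measure = measure, estimate = exp(b),
                   conf_low = exp(ci[1]), conf_high = exp(ci[2]))
  }
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE-type marginal model (", x$family, ", working ", x$working,
      ", sandwich: ", x$correction, ")\n", sep = "")
  cat("  ", x$n_obs, " observations in ", x$n_clusters, " clusters; ",
      if (x$converged) paste0("converged in ", x$iterations, " iterations")
      else "DID NOT CONVERGE", "\n", sep = "")
  est <- cbind(estimate = x$beta, robust.se = sqrt(diag(x$vcov)))
  print(round(est, 4))
  invisible(x)
}
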