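#' Akaike weights for a pool of candidate models
#'
#' `w_q = exp(-AIC_q / 2) / sum_q' exp(-AIC_q' / 2)`, evaluated after
#' subtracting the minimum AIC (the weights are shift-invariant, so the
#' subtraction only stabilises the exponentials).  Non-finite AIC values
#' (failed fits) receive weight 0 with a warning; all-non-finite input is an
#' error.
#'
#' @param aic Numeric vector of AIC values (length >= 2).
#' @return Non-negative weights summing to 1, monotone decreasing in AIC.
#' @export
#' @examples
#' akaike_weights(c(10, 12, 14))
akaike_weights <- function(aic) {
  stopifnot(length(aic) >= 2)
  ok <- is.finite(aic)
  if (!any(ok)) stop("all AIC values are non-finite", call. = FALSE)
  if (!all(ok)) {
    warning(sum(!ok), " model(s) with non-finite AIC given weight 0",
            call. = FALSE)
  }
  w <- numeric(length(aic))
  rel <- exp(-(aic[ok] - min(aic[ok])) / 2)
  w[ok] <- rel / sum(rel)
  w
}

#' Default candidate model pool
#'
#' A predefined pool of marginal mean models for the chosen outcome, all
#' containing treatment and period main effects and differing in the count
#' family and the time structure: \{Poisson, negative binomial\} (counts) or
#' binomial (binary) crossed with \{categorical time + treatment x time,
#' linear time + treatment x time, categorical time main effects only\}.
#' Q = 6 for counts, Q = 3 for binary.
#'
#' @param outcome `"count"` or `"binary"`.
#' @return A tibble with columns `model_id`, `family`, `formula`.
#' @export
candidate_pool <- function(outcome = c("count", "binary")) {
  outcome <- match.arg(outcome)
  structures <- c(
    cat_ix = ".y ~ treatment + period_f + time_f + treatment:time_f",
    lin_ix = ".y ~ treatment + period_f + time_n + treatment:time_n",
    cat_main = ".y ~ treatment + period_f + time_f"
  )
  fams <- if (outcome == "count") c("poisson", "negbin") else "binomial"
  grid <- expand.grid(structure = names(structures), family = fams,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    model_id = paste(grid$family, grid$structure, sep = "_"),
    family = grid$family,
    formula = unname(structures[grid$structure])
  )
}

#' Fit every candidate model in a pool by maximum likelihood
#'
#' Candidates are ordinary likelihood fits (GLM; negative binomial via
#' [MASS::glm.nb()]) on the long data, with `AIC = 2k - 2 logLik`.  A failed
#' fit is recorded with a non-finite AIC rather than dropped.
#'
#' @param data A trial data frame.
#' @param outcome `"count"` or `"binary"` (the latter requires the derived
#'   `binary` column; see [dichotomize()]).
#' @param pool A [candidate_pool()]-shaped tibble; `NULL` uses the default
#'   pool for the outcome.
#' @return A list with `table` (pool tibble plus `aic`, `n_par`, `ok`) and
#'   `fits` (the fitted model objects, `NULL` where fitting failed).
#' @export
fit_pool <- function(data, outcome = c("count", "binary"), pool = NULL) {
  outcome <- match.arg(outcome)
  data <- as_trial_data(data)
  if (is.null(pool)) pool <- candidate_pool(outcome)
  if (nrow(pool) < 1) stop("empty candidate pool", call. = FALSE)
  md <- .ma_frame(data, outcome)

  fits <- vector("list", nrow(pool))
  aic <- rep(NA_real_, nrow(pool))
  n_par <- rep(NA_integer_, nrow(pool))
  for (q in seq_len(nrow(pool))) {
    f <- stats::as.formula(pool$formula[q])
    fit <- tryCatch(
      switch(pool$family[q],
        poisson = stats::glm(f, family = stats::poisson(), data = md),
        binomial = stats::glm(f, family = stats::binomial(), data = md),
        negbin = suppressWarnings(MASS::glm.nb(f, data = md)),
        stop("unknown family: ", pool$family[q])
      ),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      fits[[q]] <- fit
      aic[q] <- stats::AIC(fit)
      n_par[q] <- attr(stats::logLik(fit), "df")
    }
  }
  if (all(!is.finite(aic))) stop("every candidate fit failed", call. = FALSE)
  table <- pool
  table$aic <- aic
  table$n_par <- n_par
  table$ok <- is.finite(aic)
  list(table = table, fits = fits, frame = md, outcome = outcome)
}

.ma_frame <- function(data, outcome) {
  if (outcome == "binary") {
    if (!"binary" %in% names(data)) {
      stop("binary outcome not present; run dichotomize() first",
           call. = FALSE)
    }
    # responder status is structurally 0 at baseline; drop those rows so the
    # logit models stay estimable (the baseline cell proportions are 0)
    data <- data[data$time > 1, ]
  }
  y <- if (outcome == "count") data$count else data$binary
  data.frame(
    .y = y,
    treatment = factor(data$treatment, levels = c("placebo", "verum")),
    period_f = factor(data$period),
    time_f = factor(data$time),
    time_n = as.numeric(data$time),
    subject_id = data$subject_id
  )
}

#' Model-averaged treatment-effect measure
#'
#' Weighted combination of per-model effects over the candidate pool.
#' `"delta_delta"` is the difference-in-differences of model-predicted
#' (treatment, time) cell means: the verum-minus-placebo difference at the
#' post-treatment visit (time 3) minus the same difference at baseline --
#' for binary outcomes these cells are response proportions.
#' `"rate_ratio"` exponentiates the weighted mean of per-model log rate
#' ratios of predicted cell means at time 3.  Weights with zero mass (failed
#' fits) contribute nothing; the averaged effect is a convex combination,
#' bounded by the per-model extremes on the combining scale.
#'
#' @param pool_fit The result of [fit_pool()].
#' @param weights Weights from [akaike_weights()] on the pool's AICs;
#'   `NULL` recomputes them.
#' @param effect `"delta_delta"` or `"rate_ratio"`; `NULL` picks
#'   `"rate_ratio"` for counts and `"delta_delta"` for binary.
#' @return A scalar effect estimate.
#' @export
averaged_effect <- function(pool_fit, weights = NULL,
                            effect = c("delta_delta", "rate_ratio")) {
  if (is.null(effect)) {
    effect <- if (pool_fit$outcome == "count") "rate_ratio" else "delta_delta"
  }
  effect <- match.arg(effect)
  if (effect == "rate_ratio" && pool_fit$outcome == "binary") {
    stop("rate_ratio effect is defined for the count outcome", call. = FALSE)
  }
  if (is.null(weights)) weights <- akaike_weights(pool_fit$table$aic)
  stopifnot(length(weights) == length(pool_fit$fits))

  per_model <- vapply(seq_along(pool_fit$fits), function(q) {
    fit <- pool_fit$fits[[q]]
    if (is.null(fit) || weights[q] == 0) return(NA_real_)
    md <- pool_fit$frame
    mu <- stats::predict(fit, newdata = md, type = "response")
    cell <- tapply(mu, list(md$treatment, md$time_f), mean)
    if (effect == "delta_delta") {
      # baseline cells are structurally 0 for the binary outcome (rows
      # dropped at fitting time), so their difference contributes nothing
      d1 <- if ("1" %in% colnames(cell)) {
        cell["verum", "1"] - cell["placebo", "1"]
      } else 0
      (cell["verum", "3"] - cell["placebo", "3"]) - d1
    } else {
      if (cell["placebo", "3"] <= 0 || cell["verum", "3"] <= 0) {
        return(NA_real_)
      }
      log(cell["verum", "3"] / cell["placebo", "3"])
    }
  }, 0)
  if (any(is.na(per_model) & weights > 0)) {
    stop("effect undefined for a positively weighted model", call. = FALSE)
  }
  used <- weights > 0
  out <- sum(weights[used] * per_model[used])
  if (effect == "rate_ratio") exp(out) else out
}

#' Permutation test for the model-averaged treatment effect
#'
#' The reference distribution of the averaged effect under the null of no
#' treatment effect is built by the same within-subject label-swap engine as
#' the pairwise-comparison test: each subject's two period blocks exchange
#' treatment labels independently with probability 1/2, the pool is refit,
#' and the two-sided add-one p-value compares |effect| on the combining
#' scale (log scale for the rate ratio).  Exact enumeration of all `2^n`
#' swaps is used for small n.  If more than 10% of permutation refits fail
#' entirely the result is flagged.
#'
#' @param data A trial data frame.
#' @param outcome `"count"` or `"binary"`.
#' @param pool Candidate pool (default [candidate_pool()]).
#' @param effect Effect measure, as in [averaged_effect()].
#' @param n_perm Monte-Carlo permutations (default 500).
#' @param exact Enumerate all swaps; default `NULL` = exact when n <= 8.
#' @param seed Optional seed.
#' @return An `ma_result`: pool table with weights, the averaged effect,
#'   `p_value`, and a `flagged` indicator.
#' @export
#' @examples
#' \donttest{
#' ma_test(generate_trial(seed = 1), "count", n_perm = 99, seed = 2)
#' }
ma_test <- function(data, outcome = c("count", "binary"), pool = NULL,
                    effect = NULL, n_perm = 500, exact = NULL, seed = NULL) {
  outcome <- match.arg(outcome)
  data <- as_trial_data(data)
  if (is.null(effect)) {
    effect <- if (outcome == "count") "rate_ratio" else "delta_delta"
  }
  if (outcome == "binary" && !"binary" %in% names(data)) {
    data <- dichotomize(data)
  }

  obs_pool <- fit_pool(data, outcome, pool)
  weights <- akaike_weights(obs_pool$table$aic)
  eff_obs <- averaged_effect(obs_pool, weights, effect)
  stat_obs <- if (effect == "rate_ratio") abs(log(eff_obs)) else abs(eff_obs)

  subjects <- unique(data$subject_id)
  n <- length(subjects)
  if (is.null(exact)) exact <- n <= 8
  eff_stat_for <- function(swap) {
    d <- .swap_labels(data, subjects[swap == 1])
    pf <- tryCatch(suppressWarnings(fit_pool(d, outcome, pool)),
                   error = function(e) NULL)
    if (is.null(pf)) return(NA_real_)
    e <- tryCatch(
      averaged_effect(pf, suppressWarnings(akaike_weights(pf$table$aic)),
                      effect),
      error = function(e) NA_real_)
    if (is.na(e)) return(NA_real_)
    if (effect == "rate_ratio") abs(log(e)) else abs(e)
  }

  tol <- 1e-12
  if (exact) {
    swaps <- as.matrix(expand.grid(rep(list(0:1), n)))
    stars <- apply(swaps, 1, eff_stat_for)
    fail <- mean(is.na(stars))
    p <- mean(stars[!is.na(stars)] >= stat_obs - tol)
    n_used <- nrow(swaps)
  } else {
    stars <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        eff_stat_for(stats::rbinom(n, 1, 0.5))
      }, 0)
    })
    fail <- mean(is.na(stars))
    p <- (1 + sum(stars >= stat_obs - tol, na.rm = TRUE)) /
      (sum(!is.na(stars)) + 1)
    n_used <- n_perm
  }
  flagged <- fail > 0.10
  if (flagged) {
    warning(sprintf("%.0f%% of permutation refits failed", 100 * fail),
            call. = FALSE)
  }

  table <- obs_pool$table
  table$weight <- weights
  structure(list(
    table = table, effect_name = effect, effect = eff_obs,
    p_value = p, n_perm = n_used, outcome = outcome,
    failed_fraction = fail, flagged = flagged
  ), class = "ma_result")
}

.swap_labels <- function(data, swap_ids) {
  i <- data$subject_id %in% swap_ids
  data$treatment[i] <- ifelse(data$treatment[i] == "verum",
                              "placebo", "verum")
  data$sequence[i] <- ifelse(data$sequence[i] == "PV", "VP", "PV")
  as_trial_data(data)
}

#' @export
print.ma_result <- function(x, ...) {
  cat("AIC-weighted model averaging (", x$outcome, ")\n", sep = "")
  print(tibble::as_tibble(x$table[c("model_id", "aic", "weight")]))
  cat(sprintf("  averaged %s = %0.4f; permutation p = %0.4g (%d swaps)\n",
              x$effect_name, x$effect, x$p_value, x$n_perm))
  if (x$flagged) cat("  WARNING: >10% of permutation refits failed\n")
  invisible(x)
}
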