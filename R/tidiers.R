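#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GPC result
#'
#' @param x A `gpc_result`.
#' @param ... Unused.
#' @return One-row tibble: `delta`, `wins`, `losses`, `ties`, `n_pairs`,
#'   `p_value`.
#' @method tidy gpc_result
#' @export
tidy.gpc_result <- function(x, ...) {
  tibble::tibble(
    pairing = x$config$pairing, comparison = x$config$comparison,
    outcome = x$config$outcome,
    delta = x$delta, wins = x$wins, losses = x$losses, ties = x$ties,
    n_pairs = x$n_pairs,
    p_value = if (is.null(x$p_value)) NA_real_ else x$p_value
  )
}

#' @rdname tidy.gpc_result
#' @method glance gpc_result
#' @export
glance.gpc_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$config$n_subjects, test = x$test %||% NA_character_,
    n_perm = x$n_perm %||% NA_integer_,
    small_sample = x$small_sample
  )
}

#' Tidy an ANOVA-type statistic result
#'
#' @param x An `ats_result`.
#' @param ... Unused.
#' @return One-row tibble with the statistic, degrees of freedom and
#'   p-value.
#' @method tidy ats_result
#' @export
tidy.ats_result <- function(x, ...) {
  tibble::tibble(
    period = x$period, outcome = x$outcome, contrast = x$contrast,
    statistic = x$statistic, df1 = x$df1, df2 = x$df2, p_value = x$p_value
  )
}

#' Tidy a per-period marginal-model analysis
#'
#' @param x An `nmm_result`.
#' @param ... Unused.
#' @return One row per period.
#' @method tidy nmm_result
#' @export
tidy.nmm_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$periods, tidy))
}

#' @rdname tidy.nmm_result
#' @method glance nmm_result
#' @export
glance.nmm_result <- function(x, ...) {
  tibble::tibble(rule = x$rule, alpha = x$alpha, reject = x$reject,
                 min_p = min(vapply(x$periods, `[[`, 0, "p_value")))
}

#' Tidy a GEE-type marginal model fit
#'
#' @param x A `gee_fit`.
#' @param conf_level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return One row per coefficient with robust standard errors.
#' @method tidy gee_fit
#' @export
tidy.gee_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$beta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(se), statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(x$beta - q * se), conf.high = unname(x$beta + q * se)
  )
}

#' @rdname tidy.gee_fit
#' @method glance gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, working = x$working, correction = x$correction,
    converged = x$converged, iterations = x$iterations,
    n_obs = x$n_obs, n_clusters = x$n_clusters
  )
}

#' Tidy a model-averaging result
#'
#' @param x An `ma_result`.
#' @param ... Unused.
#' @return One row per candidate model with its AIC and weight.
#' @method tidy ma_result
#' @export
tidy.ma_result <- function(x, ...) {
  tibble::as_tibble(x$table)
}

#' @rdname tidy.ma_result
#' @method glance ma_result
#' @export
glance.ma_result <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, effect_name = x$effect_name, effect = x$effect,
    p_value = x$p_value, n_perm = x$n_perm, flagged = x$flagged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
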