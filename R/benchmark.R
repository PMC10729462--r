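#' @keywords internal
.method_registry <- function() {
  c("gpc_unmatched_prioritized", "gpc_unmatched_nonprioritized",
    "gpc_unmatched_univariate", "gpc_matched_prioritized",
    "gpc_matched_nonprioritized", "gpc_matched_univariate",
    "nmm", "gee", "ma")
}

# run one method on one dataset; returns a p-value or NA on failure
.run_method <- function(method, data, outcome, n_perm, seed, nmm_period = 1,
                        ma_n_perm = 200) {
  out <- tryCatch({
    if (grepl("^gpc_", method)) {
      parts <- strsplit(method, "_")[[1]]
      r <- gpc_test(data, outcome = outcome, pairing = parts[2],
                    comparison = parts[3], n_perm = n_perm,
                    exact = FALSE, seed = seed)
      r$p_value
    } else if (method == "nmm") {
      ats_interaction_test(data, period = nmm_period,
                           outcome = outcome)$p_value
    } else if (method == "gee") {
      fit <- suppressWarnings(
        fit_gee(data, outcome = if (outcome == "vas") "vas" else outcome))
      if (!fit$converged) NA_real_ else wald_test(fit, "overall")$p_value
    } else if (method == "ma") {
      suppressWarnings(
        ma_test(data, outcome = outcome, n_perm = ma_n_perm,
                exact = FALSE, seed = seed)$p_value)
    } else {
      stop("unknown method: ", method)
    }
  }, error = function(e) NA_real_)
  out
}

.check_methods <- function(methods) {
  bad <- setdiff(methods, .method_registry())
  if (length(bad) > 0) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "\n  valid methods: ", paste(.method_registry(), collapse = ", "),
         call. = FALSE)
  }
  methods
}

# outcomes an analysis method supports; rank-based methods take all three,
# the parametric/semiparametric ones are restricted to count and binary
.method_outcomes <- function(method, outcomes) {
  if (method %in% c("gee", "ma")) intersect(outcomes, c("count", "binary"))
  else outcomes
}

#' Empirical type-I error under the block-permutation null
#'
#' For each replicate a null dataset is produced (synthetic generation
#' followed by [block_permute()]), every requested method is run on the
#' *same* replicate (common random numbers, so paired method comparisons
#' are valid), and the rejection fraction at level `alpha` is aggregated
#' with its binomial Monte-Carlo standard error.  Method failures on a
#' replicate are counted and reported, never silently dropped.
#'
#' @param methods Character vector of method names; see the valid set in
#'   the error message of a misspelling, e.g. `"gpc_unmatched_prioritized"`,
#'   `"nmm"`, `"gee"`, `"ma"`.
#' @param outcomes Subset of `c("count", "binary", "vas")`.  The binary
#'   outcome is derived from the permuted counts via [dichotomize()].  The
#'   `gee` and `ma` methods only run on count and binary outcomes.
#' @param n_sim Number of simulation replicates.
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_perm Permutations per pairwise-comparison test.
#' @param seed Master seed; replicate sub-seeds are derived from it.
#' @param gen List of [generate_trial()] arguments for the data-generating
#'   conditions.
#' @param nmm_period Period analysed by the marginal-model interaction test
#'   (default 1).
#' @param ma_n_perm Permutations for the model-averaging test (kept
#'   smaller, each permutation refits the whole pool).
#' @return A `sim_report` tibble: one row per (method, outcome) with
#'   `rejections`, `failures`, `rate`, `mc_se`.
#' @export
#' @examples
#' estimate_type1("gpc_unmatched_prioritized", n_sim = 5, n_perm = 100,
#'                seed = 1)
estimate_type1 <- function(methods, outcomes = "count", n_sim = 1000,
                           alpha = 0.05, n_perm = 1000, seed = NULL,
                           gen = list(), nmm_period = 1, ma_n_perm = 200) {
  methods <- .check_methods(methods)
  stopifnot(n_sim >= 1, alpha > 0, alpha < 1)
  outcomes <- match.arg(outcomes, c("count", "binary", "vas"),
                        several.ok = TRUE)
  seeds <- .spawn_seeds(seed, n_sim)
  t0 <- Sys.time()

  grid <- .method_grid(methods, outcomes)
  rej <- fail <- stats::setNames(numeric(nrow(grid)),
                                 paste(grid$method, grid$outcome))
  for (r in seq_len(n_sim)) {
    d <- with_seed(seeds[r], {
      d0 <- do.call(generate_trial, gen)
      block_permute(d0)
    })
    if ("binary" %in% outcomes) d <- dichotomize(d)
    for (j in seq_len(nrow(grid))) {
      p <- .run_method(grid$method[j], d, grid$outcome[j], n_perm,
                       seed = seeds[r] %% 1000000L + j,
                       nmm_period = nmm_period, ma_n_perm = ma_n_perm)
      if (is.na(p)) fail[j] <- fail[j] + 1
      else if (p <= alpha) rej[j] <- rej[j] + 1
    }
  }
  .sim_report(grid, scenario = "null", delta = 0, n_sim, rej, fail, alpha,
              seed, t0)
}

#' Empirical power under the effect-injection scenarios
#'
#' Each replicate is generated, block-permuted to a null configuration, and
#' a treatment effect of mean `delta` is injected into the placebo arm
#' ([inject_effect()]): scenario `"S1"` at the post-treatment visit only,
#' `"S2"` additionally half the effect at follow-up.  All methods and all
#' (scenario, delta) conditions share replicate seeds, so power differences
#' between methods are paired comparisons.
#'
#' @inheritParams estimate_type1
#' @param scenarios Subset of `c("S1", "S2")`.
#' @param deltas Named list of effect-size grids per outcome, e.g.
#'   `list(count = c(1, 2, 4), vas = c(1, 2))`; the count grid is reused
#'   for the binary outcome, whose effect is injected on the source counts.
#'   The default grids are those values.
#' @param distribution Effect distribution passed to [inject_effect()]
#'   (`NULL` = outcome-appropriate default).
#' @return A `sim_report` tibble with one row per
#'   (method, outcome, scenario, delta).
#' @export
estimate_power <- function(methods, outcomes = "count",
                           scenarios = c("S1", "S2"), deltas = NULL,
                           n_sim = 1000, alpha = 0.05, n_perm = 1000,
                           seed = NULL, gen = list(), distribution = NULL,
                           nmm_period = 1, ma_n_perm = 200) {
  methods <- .check_methods(methods)
  stopifnot(n_sim >= 1)
  outcomes <- match.arg(outcomes, c("count", "binary", "vas"),
                        several.ok = TRUE)
  scenarios <- match.arg(scenarios, c("S1", "S2"), several.ok = TRUE)
  if (is.null(deltas)) deltas <- list(count = c(1, 2, 4), vas = c(1, 2))
  seeds <- .spawn_seeds(seed, n_sim)
  t0 <- Sys.time()

  grid <- .method_grid(methods, outcomes)
  cond <- do.call(rbind, lapply(scenarios, function(sc) {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
      dg <- if (grid$outcome[j] == "vas") deltas$vas else deltas$count
      data.frame(method = grid$method[j], outcome = grid$outcome[j],
                 scenario = sc, delta = dg)
    }))
  }))
  key <- paste(cond$method, cond$outcome, cond$scenario, cond$delta)
  rej <- fail <- stats::setNames(numeric(nrow(cond)), key)

  inj <- unique(cond[c("outcome", "scenario", "delta")])
  for (r in seq_len(n_sim)) {
    base <- with_seed(seeds[r], {
      d0 <- do.call(generate_trial, gen)
      block_permute(d0)
    })
    for (i in seq_len(nrow(inj))) {
      oc <- inj$outcome[i]
      d <- inject_effect(base, delta = inj$delta[i],
                         scenario = inj$scenario[i],
                         outcome = if (oc == "binary") "binary_source"
                                   else oc,
                         distribution = distribution,
                         seed = seeds[r] %% 900000L + i * 7L)
      rows <- which(cond$outcome == oc & cond$scenario == inj$scenario[i] &
                      cond$delta == inj$delta[i])
      for (j in rows) {
        p <- .run_method(cond$method[j], d, oc, n_perm,
                         seed = seeds[r] %% 1000000L + j,
                         nmm_period = nmm_period, ma_n_perm = ma_n_perm)
        if (is.na(p)) fail[j] <- fail[j] + 1
        else if (p <= alpha) rej[j] <- rej[j] + 1
      }
    }
  }
  .sim_report(cond, scenario = cond$scenario, delta = cond$delta,
              n_sim, rej, fail, alpha, seed, t0)
}

.method_grid <- function(methods, outcomes) {
  do.call(rbind, lapply(methods, function(m) {
    oc <- .method_outcomes(m, outcomes)
    if (length(oc) == 0) return(NULL)
    data.frame(method = m, outcome = oc)
  }))
}

.sim_report <- function(grid, scenario, delta, n_sim, rej, fail, alpha,
                        seed, t0) {
  rej <- unname(rej)
  fail <- unname(fail)
  out <- tibble::tibble(
    method = grid$method, outcome = grid$outcome,
    scenario = scenario, delta = delta,
    n_sim = n_sim, rejections = as.integer(rej),
    failures = as.integer(fail),
    rate = rej / n_sim,
    mc_se = sqrt((rej / n_sim) * (1 - rej / n_sim) / n_sim),
    alpha = alpha, seed = if (is.null(seed)) NA_integer_ else seed,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  class(out) <- c("sim_report", class(out))
  out
}

#' Run a configured benchmark and write report files
#'
#' Drives [estimate_type1()] and/or [estimate_power()] from a YAML
#' configuration (or an equivalent named list) and writes `results.csv`,
#' `config_echo.yaml` and `run.log` to `out_dir`.  Re-running with the same
#' configuration reproduces the report byte for byte.
#'
#' Configuration keys: `mode` (`"type1"`, `"power"` or `"both"`),
#' `methods`, `outcomes`, `scenarios`, `deltas` (named per-outcome lists),
#' `n_sim`, `n_perm`, `ma_n_perm`, `alpha`, `seed`, `generator` (arguments
#' to [generate_trial()]).
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @return The combined `sim_report`, invisibly when writing files.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "both", methods = "gpc_unmatched_prioritized",
                   outcomes = "count", scenarios = c("S1", "S2"),
                   deltas = NULL, n_sim = 1000, n_perm = 1000,
                   ma_n_perm = 200, alpha = 0.05, seed = 1,
                   generator = list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  cfg$methods <- .check_methods(unlist(cfg$methods))
  if (!cfg$mode %in% c("type1", "power", "both")) {
    stop("mode must be 'type1', 'power' or 'both'", call. = FALSE)
  }
  if (!is.null(cfg$deltas)) cfg$deltas <- lapply(cfg$deltas, unlist)

  reports <- list()
  if (cfg$mode %in% c("type1", "both")) {
    reports$type1 <- estimate_type1(
      cfg$methods, unlist(cfg$outcomes), n_sim = cfg$n_sim,
      alpha = cfg$alpha, n_perm = cfg$n_perm, seed = cfg$seed,
      gen = cfg$generator, ma_n_perm = cfg$ma_n_perm)
  }
  if (cfg$mode %in% c("power", "both")) {
    reports$power <- estimate_power(
      cfg$methods, unlist(cfg$outcomes), scenarios = unlist(cfg$scenarios),
      deltas = cfg$deltas, n_sim = cfg$n_sim, alpha = cfg$alpha,
      n_perm = cfg$n_perm, seed = cfg$seed, gen = cfg$generator,
      ma_n_perm = cfg$ma_n_perm)
  }
  report <- dplyr::bind_rows(reports)
  class(report) <- c("sim_report", class(tibble::tibble()))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    # runtime varies between runs; keep the CSV byte-identical under a seed
    readr::write_csv(tibble::as_tibble(report)[setdiff(names(report),
                                                       "runtime_s")],
                     file.path(out_dir, "results.csv"), progress = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
    writeLines(c(
      paste0("crossbench ", as.character(utils::packageVersion("crossbench"))),
      paste0("R ", R.version.string),
      paste0("seed: ", cfg$seed),
      paste0("rows: ", nrow(report))
    ), file.path(out_dir, "run.log"))
    return(invisible(report))
  }
  report
}

#' A small smoke-test benchmark configuration
#'
#' Reduced replication counts for a quick end-to-end run of the benchmark
#' machinery.
#'
#' @return A configuration list for [run_benchmark()].
#' @export
smoke_config <- function() {
  list(mode = "both",
       methods = c("gpc_unmatched_prioritized", "gpc_matched_prioritized",
                   "nmm"),
       outcomes = "count", scenarios = "S1",
       deltas = list(count = 4),
       n_sim = 50, n_perm = 200, alpha = 0.05, seed = 1)
}
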