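#' Block permutation of subject-period outcome blocks
#'
#' The simulation null: the 2n subject-period blocks of four consecutive
#' measurements are reassigned uniformly at random to the 2n (subject,
#' period) slots, jointly across all subjects and both treatment conditions.
#' Within-block time order travels intact, so the longitudinal dependence
#' structure of each block is preserved while any treatment, period or
#' subject effect is destroyed.  Design columns (sequence, period, treatment
#' labels) stay fixed; all outcome columns move together so a block's
#' derived binary values remain consistent with its own counts.
#'
#' @param data A complete trial data frame.
#' @param seed Optional seed for the permutation draw.
#' @return A trial data frame with permuted outcome blocks; the multiset of
#'   block value-vectors and hence every outcome total is invariant.
#' @export
#' @examples
#' d <- generate_trial(seed = 1)
#' p <- block_permute(d, seed = 2)
#' sum(p$count) == sum(d$count)
block_permute <- function(data, seed = NULL) {
  data <- as_trial_data(data)
  n_blocks <- nrow(data) / 4L
  if (n_blocks < 1) return(data)
  perm <- with_seed(seed, sample.int(n_blocks))
  src <- rep((perm - 1L) * 4L, each = 4L) + rep(1:4, times = n_blocks)
  out_cols <- intersect(c("count", "vas", "binary"), names(data))
  data[out_cols] <- data[src, out_cols]
  as_trial_data(data)
}

#' Inject a treatment effect for power simulation
#'
#' Starting from a null dataset (typically a [block_permute()] replicate),
#' adds random effects with mean `delta` to the *placebo* arm -- larger
#' counts and VAS scores are worse outcomes, so worsening placebo creates a
#' verum benefit.  Scenario `"S1"` adds the effect at the post-treatment
#' visit (time 3) only; scenario `"S2"` additionally adds half the effect
#' (`delta / 2`) at the follow-up visit (time 4).  Verum records are never
#' touched.
#'
#' Effect distributions: `"point_mass"` adds the constant `delta` (rounded
#' to an integer for counts, to the half-point grid for VAS);
#' `"poisson"` adds Poisson(`delta`) draws (counts); `"rounded_gaussian"`
#' adds N(`delta`, (`delta`/2)^2) draws rounded to the half-point grid
#' (VAS).  The default picks `"poisson"` for count-based outcomes and
#' `"rounded_gaussian"` for VAS.  Counts remain integers; VAS values are
#' clamped to [0, 10].
#'
#' `outcome = "binary_source"` injects on the counts and re-derives the
#' binary responder column with [dichotomize()], mirroring how the binary
#' endpoint is obtained from blister counts.
#'
#' @param data A trial data frame.
#' @param delta Mean added effect (>= 0) at time 3.
#' @param scenario `"S1"` (single affected time point) or `"S2"` (effect at
#'   times 3 and 4, halved at time 4).
#' @param outcome `"count"`, `"vas"` or `"binary_source"`.
#' @param distribution Effect distribution (see Details); `NULL` picks the
#'   outcome-appropriate default.
#' @param seed Optional seed for the effect draws.
#' @param threshold,baseline_time Passed to [dichotomize()] for
#'   `"binary_source"`.
#' @return The dataset with the effect added.
#' @export
inject_effect <- function(data, delta, scenario = c("S1", "S2"),
                          outcome = c("count", "vas", "binary_source"),
                          distribution = NULL, seed = NULL,
                          threshold = 0.4, baseline_time = 1) {
  scenario <- match.arg(scenario)
  outcome <- match.arg(outcome)
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0)
  data <- as_trial_data(data)
  target <- if (outcome == "vas") "vas" else "count"
  if (is.null(distribution)) {
    distribution <- if (target == "count") "poisson" else "rounded_gaussian"
  }
  distribution <- match.arg(distribution,
                            c("point_mass", "poisson", "rounded_gaussian"))

  data <- with_seed(seed, {
    d <- .add_effect(data, target, delta, time = 3L, distribution)
    if (scenario == "S2") {
      d <- .add_effect(d, target, delta / 2, time = 4L, distribution)
    }
    d
  })
  if (outcome == "binary_source") {
    data <- dichotomize(data, threshold = threshold,
                        baseline_time = baseline_time)
  }
  as_trial_data(data)
}

.add_effect <- function(data, target, mean_effect, time, distribution) {
  idx <- which(data$treatment == "placebo" & data$time == time)
  if (length(idx) == 0 || mean_effect == 0) return(data)
  add <- switch(distribution,
    point_mass = {
      if (target == "count") rep(round(mean_effect), length(idx))
      else rep(round(2 * mean_effect) / 2, length(idx))
    },
    poisson = stats::rpois(length(idx), mean_effect),
    rounded_gaussian = {
      draws <- stats::rnorm(length(idx), mean_effect, mean_effect / 2)
      round(2 * draws) / 2
    }
  )
  if (target == "count") {
    data$count[idx] <- as.integer(pmax(0L, data$count[idx] + as.integer(add)))
  } else {
    data$vas[idx] <- pmin(10, pmax(0, data$vas[idx] + add))
  }
  data
}

#' Generate a stream of block-permuted null replicates
#'
#' @param data A trial data frame acting as the template.
#' @param B Number of replicates (>= 1).
#' @param seed Master seed; each replicate gets its own derived sub-seed so
#'   the stream is reproducible as a whole.
#' @return A list of `B` trial data frames.
#' @export
null_replicates <- function(data, B, seed = NULL) {
  stopifnot(B >= 1)
  data <- as_trial_data(data)
  seeds <- .spawn_seeds(seed, B)
  lapply(seeds, function(s) block_permute(data, seed = s))
}
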