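#' Pairwise score of two outcome values
#'
#' The elementary generalized-pairwise-comparisons score: +1 when the verum
#' member of the pair does better, -1 when worse, 0 on a tie.  Blister
#' counts and VAS scores are harms, so the default orientation
#' `"lower_is_better"` scores `v1 < v2` as a win for verum and a positive
#' net benefit then means treatment benefit.  `"higher_is_better"` flips the
#' inequality (scoring `v1 > v2` as +1, the raw textbook orientation).
#'
#' @param v1 Value(s) under verum.
#' @param v2 Value(s) under placebo.
#' @param direction `"lower_is_better"` (default) or `"higher_is_better"`.
#' @return Integer score(s) in \{-1, 0, +1\}; vectorised over pairs.
#' @export
#' @examples
#' score_pair(3, 5)                          # +1: fewer blisters on verum
#' score_pair(5, 3, "higher_is_better")      # +1
score_pair <- function(v1, v2, direction = c("lower_is_better",
                                             "higher_is_better")) {
  direction <- match.arg(direction)
  s <- sign(v2 - v1)
  if (direction == "higher_is_better") s <- -s
  as.integer(s)
}

#' Prioritized score of two blocks of repeated measurements
#'
#' Compares two subject-period blocks time point by time point in order of
#' clinical priority: the pair is scored at the highest-priority time point,
#' and only if that comparison is a tie does the next time point on the
#' ladder decide, until the last rung; a pair tied everywhere scores 0.
#' The default ladder (3, 4, 2, 1) puts the post-treatment visit first and
#' the follow-up visit second.
#'
#' @param block1 Length-4 vector (verum block), ordered by time.
#' @param block2 Length-4 vector (placebo block).
#' @param priority_order Permutation of 1:4.
#' @inheritParams score_pair
#' @return Integer in \{-1, 0, +1\}.
#' @export
#' @examples
#' score_pair_prioritized(c(2, 4, 3, 3), c(5, 4, 3, 1))  # tie at t3, t4 decides
score_pair_prioritized <- function(block1, block2,
                                   priority_order = c(3, 4, 2, 1),
                                   direction = c("lower_is_better",
                                                 "higher_is_better")) {
  direction <- match.arg(direction)
  stopifnot(length(block1) == 4, length(block2) == 4,
            setequal(priority_order, 1:4))
  for (t in priority_order) {
    s <- score_pair(block1[t], block2[t], direction)
    if (s != 0L) return(s)
  }
  0L
}

#' Non-prioritized score of two blocks
#'
#' All four time points contribute symmetrically: the score is the mean of
#' the four per-time-point pairwise scores, a rational number in [-1, 1]
#' that reduces to the common value when all time points agree.
#'
#' @inheritParams score_pair_prioritized
#' @return Numeric in [-1, 1] (multiples of 1/4).
#' @export
score_pair_nonprioritized <- function(block1, block2,
                                      direction = c("lower_is_better",
                                                    "higher_is_better")) {
  direction <- match.arg(direction)
  stopifnot(length(block1) == 4, length(block2) == 4)
  mean(score_pair(block1, block2, direction))
}

# ---- internal scoring machinery -------------------------------------------

# sign-compare two value vectors across all pairs: S[k, l] = score(a[k], b[l])
.score_matrix_scalar <- function(a, b, direction) {
  s <- sign(matrix(b, length(a), length(b), byrow = TRUE) -
            matrix(a, length(a), length(b)))
  if (direction == "higher_is_better") -s else s
}

# pairwise scores of block rows A (na x 4) vs B (nb x 4); returns the score
# matrix plus elementary win/loss/tie counts (per pair, or per pair x time
# for the non-prioritized rule, whose score is a per-time average)
.score_blocks <- function(A, B, comparison, priority_order, direction,
                          summary) {
  na <- nrow(A); nb <- nrow(B)
  if (comparison == "univariate") {
    S <- .score_matrix_scalar(block_summary(A, summary),
                              block_summary(B, summary), direction)
    units <- 1L
  } else if (comparison == "prioritized") {
    S <- matrix(0, na, nb)
    for (t in priority_order) {
      D <- .score_matrix_scalar(A[, t], B[, t], direction)
      undecided <- S == 0
      S[undecided] <- D[undecided]
    }
    units <- 1L
  } else { # nonprioritized
    D <- lapply(1:4, function(t) .score_matrix_scalar(A[, t], B[, t],
                                                      direction))
    S <- Reduce(`+`, D) / 4
    units <- 4L
    wins <- sum(vapply(D, function(m) sum(m > 0), 0))
    losses <- sum(vapply(D, function(m) sum(m < 0), 0))
    n_units <- 4L * na * nb
    return(list(S = S, wins = wins, losses = losses,
                ties = n_units - wins - losses, n_pairs = n_units))
  }
  wins <- sum(S > 0); losses <- sum(S < 0)
  list(S = S, wins = wins, losses = losses,
       ties = na * nb - wins - losses, n_pairs = na * nb)
}

# per-subject block geometry: period-1/period-2 value matrices plus which
# period holds the verum block.  Relies on the canonical (subject, period,
# time) row order of a validated trial_df, so blocks reshape by indexing.
.gpc_blocks <- function(data, outcome) {
  data <- as_trial_data(data)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not present (run dichotomize()?)",
         call. = FALSE)
  }
  vals <- t(matrix(as.numeric(data[[outcome]]), nrow = 4L))
  head_rows <- seq(1L, nrow(data), by = 4L)
  odd <- seq(1L, nrow(vals), by = 2L)
  list(
    subjects = data$subject_id[head_rows][odd],
    P1 = vals[odd, , drop = FALSE],
    P2 = vals[odd + 1L, , drop = FALSE],
    verum_period = ifelse(data$treatment[head_rows][odd] == "verum", 1L, 2L)
  )
}

#' Net treatment benefit by generalized pairwise comparisons
#'
#' Scores verum-vs-placebo pairs of subject-period blocks and reports the
#' net treatment benefit: the mean pairwise score, i.e. the difference
#' between the probability that a random subject does better on verum and
#' the probability of the reverse, in [-1, +1].  The unmatched pairing
#' treats a subject's two periods as independent and scores all n x n
#' cross-arm pairs (each subject's own two periods included); the matched
#' pairing scores only the n within-subject pairs.
#'
#' @param data A trial data frame.
#' @param outcome `"count"`, `"vas"` or `"binary"`.
#' @param pairing `"unmatched"` (all cross-arm pairs) or `"matched"`
#'   (within-subject pairs only).
#' @param comparison `"prioritized"` (default), `"nonprioritized"` or
#'   `"univariate"` (blocks reduced by `summary` first).
#' @inheritParams score_pair_prioritized
#' @param summary Block summary for the univariate comparison; see
#'   [summarize_blocks()].
#' @return A `gpc_result` with `delta`, `wins`, `losses`, `ties`, `n_pairs`
#'   (no p-value; see [gpc_test()] for inference).  For the non-prioritized
#'   rule the accounting unit is the elementary pair x time-point
#'   comparison, so `delta == (wins - losses) / n_pairs` holds for every
#'   variant.
#' @export
#' @examples
#' gpc_net_benefit(generate_trial(seed = 1), "count")
gpc_net_benefit <- function(data, outcome = c("count", "vas", "binary"),
                            pairing = c("unmatched", "matched"),
                            comparison = c("prioritized", "nonprioritized",
                                           "univariate"),
                            priority_order = c(3, 4, 2, 1),
                            direction = c("lower_is_better",
                                          "higher_is_better"),
                            summary = "change_from_baseline_t3") {
  outcome <- match.arg(outcome)
  pairing <- match.arg(pairing)
  comparison <- match.arg(comparison)
  direction <- match.arg(direction)
  g <- .gpc_blocks(data, outcome)
  V <- rbind(g$P1[g$verum_period == 1L, , drop = FALSE],
             g$P2[g$verum_period == 2L, , drop = FALSE])
  P <- rbind(g$P1[g$verum_period == 2L, , drop = FALSE],
             g$P2[g$verum_period == 1L, , drop = FALSE])
  if (nrow(V) == 0 || nrow(P) == 0) stop("empty treatment arm", call. = FALSE)

  if (pairing == "unmatched") {
    sc <- .score_blocks(V, P, comparison, priority_order, direction, summary)
    delta <- mean(sc$S)
  } else {
    u <- .matched_scores(g, comparison, priority_order, direction, summary)
    sc <- .matched_counts(u, length(g$subjects), comparison, g,
                          priority_order, direction)
    delta <- mean(u)
  }
  .new_gpc_result(delta, sc, pairing, comparison, outcome, priority_order,
                  direction, summary, n_subjects = length(g$subjects))
}

# within-subject scores u_k = score(verum block, placebo block)
.matched_scores <- function(g, comparison, priority_order, direction,
                            summary) {
  n <- length(g$subjects)
  vapply(seq_len(n), function(k) {
    v <- if (g$verum_period[k] == 1L) g$P1[k, ] else g$P2[k, ]
    p <- if (g$verum_period[k] == 1L) g$P2[k, ] else g$P1[k, ]
    switch(comparison,
      prioritized = as.numeric(
        score_pair_prioritized(v, p, priority_order, direction)),
      nonprioritized = score_pair_nonprioritized(v, p, direction),
      univariate = as.numeric(
        score_pair(block_summary(v, summary), block_summary(p, summary),
                   direction))
    )
  }, 0)
}

.matched_counts <- function(u, n, comparison, g, priority_order, direction) {
  if (comparison == "nonprioritized") {
    # elementary per-time comparisons within subject
    per_time <- vapply(seq_len(n), function(k) {
      v <- if (g$verum_period[k] == 1L) g$P1[k, ] else g$P2[k, ]
      p <- if (g$verum_period[k] == 1L) g$P2[k, ] else g$P1[k, ]
      s <- score_pair(v, p, direction)
      c(sum(s > 0), sum(s < 0))
    }, c(0, 0))
    wins <- sum(per_time[1, ]); losses <- sum(per_time[2, ])
    list(wins = wins, losses = losses, ties = 4L * n - wins - losses,
         n_pairs = 4L * n)
  } else {
    wins <- sum(u > 0); losses <- sum(u < 0)
    list(wins = wins, losses = losses, ties = n - wins - losses, n_pairs = n)
  }
}

.new_gpc_result <- function(delta, counts, pairing, comparison, outcome,
                            priority_order, direction, summary, n_subjects,
                            p_value = NULL, test = NULL, n_perm = NULL,
                            small_sample = FALSE) {
  structure(list(
    delta = delta, wins = as.integer(counts$wins),
    losses = as.integer(counts$losses), ties = as.integer(counts$ties),
    n_pairs = as.integer(counts$n_pairs), p_value = p_value,
    test = test, n_perm = n_perm, small_sample = small_sample,
    config = list(pairing = pairing, comparison = comparison,
                  outcome = outcome, priority_order = priority_order,
                  direction = direction, summary = summary,
                  n_subjects = n_subjects)
  ), class = "gpc_result")
}

#' GPC hypothesis test for a 2x2 cross-over trial
#'
#' Inference for the net treatment benefit.  Unmatched variants use a
#' permutation test of the null of identical outcome distributions in the
#' two treatment arms: the reference distribution swaps, independently per
#' subject with probability 1/2, the treatment labels of that subject's two
#' period blocks (preserving all within-subject dependence), and the
#' two-sided p-value uses the add-one randomization estimator
#' `(1 + #\{|delta*| >= |delta_obs|\}) / (n_perm + 1)`.  With
#' `exact = TRUE` all `2^n` label swaps are enumerated instead and the
#' p-value is the exact proportion.  Matched variants use the conditional
#' sign test: conditioning on the `m` non-tied within-subject scores,
#' `p = min(1, 2 min(P(B <= b), P(B >= b)))` with `B ~ Binomial(m, 1/2)`
#' and `b` the number of wins; `m = 0` gives p = 1.  Matched results on
#' fewer than 15 subjects carry a `small_sample` flag, the sign test being
#' unreliable below that size.
#'
#' @inheritParams gpc_net_benefit
#' @param n_perm Number of Monte-Carlo label swaps (unmatched pairing).
#' @param exact Enumerate all `2^n` swaps (unmatched; requires n <= 20).
#'   Default `NULL` = exact when `n <= 10`.
#' @param seed Optional seed for the Monte-Carlo swaps.
#' @return A `gpc_result` with a `p_value`; see [gpc_net_benefit()] for the
#'   score accounting.
#' @export
#' @examples
#' gpc_test(generate_trial(seed = 1), "count", n_perm = 200, seed = 2)
gpc_test <- function(data, outcome = c("count", "vas", "binary"),
                     pairing = c("unmatched", "matched"),
                     comparison = c("prioritized", "nonprioritized",
                                    "univariate"),
                     priority_order = c(3, 4, 2, 1),
                     direction = c("lower_is_better", "higher_is_better"),
                     summary = "change_from_baseline_t3",
                     n_perm = 1000, exact = NULL, seed = NULL) {
  outcome <- match.arg(outcome)
  pairing <- match.arg(pairing)
  comparison <- match.arg(comparison)
  direction <- match.arg(direction)
  g <- .gpc_blocks(data, outcome)
  n <- length(g$subjects)

  if (pairing == "matched") {
    u <- .matched_scores(g, comparison, priority_order, direction, summary)
    counts <- .matched_counts(u, n, comparison, g, priority_order, direction)
    m <- sum(u != 0)
    b <- sum(u > 0)
    p <- if (m == 0) 1 else {
      min(1, 2 * min(stats::pbinom(b, m, 0.5),
                     stats::pbinom(b - 1, m, 0.5, lower.tail = FALSE)))
    }
    return(.new_gpc_result(mean(u), counts, pairing, comparison, outcome,
                           priority_order, direction, summary, n,
                           p_value = p, test = "conditional_sign",
                           small_sample = n < 15))
  }

  stopifnot(n_perm >= 1)
  if (is.null(exact)) exact <- n <= 10
  if (exact && n > 20) stop("exact enumeration limited to n <= 20",
                            call. = FALSE)

  # score matrices for every (verum role period a, placebo role period b)
  C <- lapply(1:2, function(a) lapply(1:2, function(b) {
    .score_blocks(if (a == 1) g$P1 else g$P2,
                  if (b == 1) g$P1 else g$P2,
                  comparison, priority_order, direction, summary)$S
  }))
  o <- as.numeric(g$verum_period == 1L)  # 1 if verum block is period 1
  delta_for <- function(A) {
    # A: m x n matrix of indicators a_k = 1 (verum is subject k's period-1
    # block); delta(s) decomposes into four bilinear forms in a and 1 - a
    Ac <- 1 - A
    (rowSums((A %*% C[[1]][[2]]) * A) +
     rowSums((A %*% C[[1]][[1]]) * Ac) +
     rowSums((Ac %*% C[[2]][[2]]) * A) +
     rowSums((Ac %*% C[[2]][[1]]) * Ac)) / (n * n)
  }
  delta_obs <- delta_for(matrix(o, nrow = 1))

  tol <- 1e-12
  if (exact) {
    swaps <- as.matrix(expand.grid(rep(list(0:1), n)))
    A <- abs(swaps - matrix(o, nrow(swaps), n, byrow = TRUE))  # XOR
    stars <- delta_for(A)
    p <- mean(abs(stars) >= abs(delta_obs) - tol)
    test <- "permutation_exact"
    n_used <- nrow(swaps)
  } else {
    A <- with_seed(seed, {
      swaps <- matrix(stats::rbinom(n_perm * n, 1, 0.5), n_perm, n)
      abs(swaps - matrix(o, n_perm, n, byrow = TRUE))
    })
    stars <- delta_for(A)
    p <- (1 + sum(abs(stars) >= abs(delta_obs) - tol)) / (n_perm + 1)
    test <- "permutation_mc"
    n_used <- n_perm
  }

  # observed accounting (wins/losses/ties on the observed assignment)
  V <- rbind(g$P1[g$verum_period == 1L, , drop = FALSE],
             g$P2[g$verum_period == 2L, , drop = FALSE])
  P <- rbind(g$P1[g$verum_period == 2L, , drop = FALSE],
             g$P2[g$verum_period == 1L, , drop = FALSE])
  counts <- .score_blocks(V, P, comparison, priority_order, direction,
                          summary)[c("wins", "losses", "ties", "n_pairs")]
  .new_gpc_result(delta_obs, counts, pairing, comparison, outcome,
                  priority_order, direction, summary, n,
                  p_value = p, test = test, n_perm = n_used)
}

#' Conditional sign test on within-subject pairwise scores
#'
#' Convenience wrapper: [gpc_test()] with matched pairing.
#'
#' @inheritParams gpc_test
#' @return A `gpc_result` with the exact conditional binomial p-value.
#' @export
conditional_sign_test <- function(data, outcome = c("count", "vas", "binary"),
                                  comparison = c("prioritized",
                                                 "nonprioritized",
                                                 "univariate"),
                                  priority_order = c(3, 4, 2, 1),
                                  direction = c("lower_is_better",
                                                "higher_is_better"),
                                  summary = "change_from_baseline_t3") {
  gpc_test(data, outcome, pairing = "matched", comparison = comparison,
           priority_order = priority_order, direction = direction,
           summary = summary)
}

#' @export
print.gpc_result <- function(x, ...) {
  cfg <- x$config
  cat("Generalized pairwise comparisons (", cfg$pairing, ", ",
      cfg$comparison, ", ", cfg$outcome, ")\n", sep = "")
  cat(sprintf("  net treatment benefit: %+0.4f  (wins %d, losses %d, ties %d of %d)\n",
              x$delta, x$wins, x$losses, x$ties, x$n_pairs))
  if (!is.null(x$p_value)) {
    cat(sprintf("  %s test: p = %0.4g\n", x$test, x$p_value))
  }
  if (isTRUE(x$small_sample)) {
    cat("  note: fewer than 15 matched subjects; sign test unreliable\n")
  }
  invisible(x)
}
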