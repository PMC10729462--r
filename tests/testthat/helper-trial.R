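# Build a small deterministic trial dataset from explicit count blocks.
# P1, P2: n x 4 integer matrices (period-1 / period-2 counts per subject).
# vas is derived as count/2 clamped to 10 so it sits on the half-point grid.
trial_from_blocks <- function(P1, P2, sequences = NULL) {
  n <- nrow(P1)
  stopifnot(nrow(P2) == n, ncol(P1) == 4, ncol(P2) == 4)
  if (is.null(sequences)) sequences <- rep(c("PV", "VP"), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    counts <- c(P1[i, ], P2[i, ])
    period <- rep(1:2, each = 4)
    treatment <- ifelse((sequences[i] == "PV") == (period == 1),
                        "placebo", "verum")
    data.frame(
      subject_id = sprintf("S%02d", i), sequence = sequences[i],
      period = period, treatment = treatment, time = rep(1:4, 2),
      count = as.integer(counts), vas = pmin(10, counts / 2)
    )
  })
  as_trial_data(do.call(rbind, rows))
}

# independent brute-force net treatment benefit over explicit block lists
# (verum_blocks, placebo_blocks: lists of length-4 vectors), plain loops
oracle_delta <- function(verum_blocks, placebo_blocks,
                         comparison = "prioritized",
                         priority_order = c(3, 4, 2, 1),
                         lower_is_better = TRUE,
                         summary_fun = function(b) b[3] - b[1]) {
  one <- function(v, p) {
    cmp <- function(a, b) {
      if (a == b) return(0)
      better <- if (lower_is_better) a < b else a > b
      if (better) 1 else -1
    }
    if (comparison == "univariate") return(cmp(summary_fun(v), summary_fun(p)))
    if (comparison == "nonprioritized") {
      return(mean(vapply(1:4, function(t) cmp(v[t], p[t]), 0)))
    }
    for (t in priority_order) {
      s <- cmp(v[t], p[t])
      if (s != 0) return(s)
    }
    0
  }
  scores <- c()
  for (v in verum_blocks) for (p in placebo_blocks) scores <- c(scores, one(v, p))
  mean(scores)
}

# exhaustive within-subject label-swap permutation p-value via oracle_delta
oracle_exact_p <- function(data, outcome = "count",
                           comparison = "prioritized", ...) {
  blocks <- period_blocks(data, outcome)
  n <- nrow(blocks) / 2
  subj <- unique(blocks$subject_id)
  delta_for <- function(verum_period) {
    vb <- list(); pb <- list()
    for (i in seq_len(n)) {
      b1 <- unlist(blocks[blocks$subject_id == subj[i] & blocks$period == 1,
                          c("t1", "t2", "t3", "t4")])
      b2 <- unlist(blocks[blocks$subject_id == subj[i] & blocks$period == 2,
                          c("t1", "t2", "t3", "t4")])
      if (verum_period[i] == 1) { vb[[i]] <- b1; pb[[i]] <- b2 }
      else { vb[[i]] <- b2; pb[[i]] <- b1 }
    }
    oracle_delta(vb, pb, comparison = comparison, ...)
  }
  obs <- vapply(subj, function(s) {
    blocks$period[blocks$subject_id == s & blocks$treatment == "verum"]
  }, 0L)
  d_obs <- delta_for(obs)
  swaps <- expand.grid(rep(list(0:1), n))
  stars <- apply(swaps, 1, function(s) delta_for(ifelse(s == 1, 3 - obs, obs)))
  list(delta = d_obs, p = mean(abs(stars) >= abs(d_obs) - 1e-12))
}
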