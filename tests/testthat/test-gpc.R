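test_that("pairwise scores follow the win/loss/tie rule in both orientations", {
  expect_identical(score_pair(5, 3, "higher_is_better"), 1L)
  expect_identical(score_pair(3, 5, "higher_is_better"), -1L)
  expect_identical(score_pair(4, 4), 0L)
  expect_identical(score_pair(3, 5, "lower_is_better"), 1L)
  expect_identical(score_pair(c(1, 2, 3), c(2, 2, 2)), c(1L, 0L, -1L))
})

test_that("the prioritized ladder descends only on ties", {
  # tie at t3, decided at t4 (fewer blisters on placebo there)
  expect_identical(
    score_pair_prioritized(c(2, 4, 3, 3), c(5, 4, 3, 1)), -1L)
  expect_identical(
    score_pair_prioritized(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0L)
  # blocks differing only at t1 are decided at the last rung
  expect_identical(
    score_pair_prioritized(c(9, 2, 3, 4), c(1, 2, 3, 4)), -1L)
  # a different ladder changes the answer
  expect_identical(
    score_pair_prioritized(c(2, 4, 3, 3), c(5, 4, 3, 1),
                           priority_order = c(1, 2, 3, 4)), 1L)
})

test_that("the non-prioritized score averages the four per-time scores", {
  expect_equal(score_pair_nonprioritized(c(1, 1, 1, 1), c(2, 2, 2, 2)), 1)
  expect_equal(score_pair_nonprioritized(c(1, 2, 9, 9), c(2, 1, 9, 9)), 0)
  expect_equal(score_pair_nonprioritized(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(score_pair_nonprioritized(c(1, 5, 5, 9), c(2, 4, 5, 8)),
               (1 - 1 + 0 - 1) / 4)
})

test_that("unmatched net benefit matches the hand-counted pair table", {
  # univariate summaries verum {3,5,7} vs placebo {5,6,2}: wins 3, losses 5
  P1 <- rbind(c(0, 0, 3, 0), c(0, 0, 5, 0), c(0, 0, 7, 0))
  P2 <- rbind(c(0, 0, 5, 0), c(0, 0, 6, 0), c(0, 0, 2, 0))
  seqs <- c("VP", "VP", "VP")  # period 1 = verum
  d <- trial_from_blocks(P1, P2, sequences = seqs)
  r <- gpc_net_benefit(d, "count", pairing = "unmatched",
                       comparison = "univariate",
                       summary = "change_from_baseline_t3")
  expect_equal(r$delta, -2 / 9)
  expect_identical(c(r$wins, r$losses, r$ties, r$n_pairs), c(3L, 5L, 1L, 9L))
})

test_that("net benefit hits its range endpoints and flips with the arms", {
  # verum dominant everywhere (lower counts): delta = +1
  P1 <- matrix(1L, 3, 4); P2 <- matrix(9L, 3, 4)
  d <- trial_from_blocks(P1, P2, sequences = c("VP", "VP", "VP"))
  for (cmp in c("prioritized", "nonprioritized", "univariate")) {
    r <- gpc_net_benefit(d, "count", comparison = cmp, summary = "total")
    expect_equal(r$delta, 1)
  }
  # swapping the arms negates delta
  d_sw <- trial_from_blocks(P1, P2, sequences = c("PV", "PV", "PV"))
  r1 <- gpc_net_benefit(d, "count")
  r2 <- gpc_net_benefit(d_sw, "count")
  expect_equal(r1$delta, -r2$delta)
  # identical arms: delta = 0
  same <- trial_from_blocks(P2, P2)
  expect_equal(gpc_net_benefit(same, "count")$delta, 0)
})

test_that("score accounting and range invariants hold on random data", {
  for (s in 1:10) {
    d <- generate_trial(seed = 600 + s)
    for (cmp in c("prioritized", "nonprioritized", "univariate")) {
      for (pr in c("unmatched", "matched")) {
        r <- gpc_net_benefit(d, "count", pairing = pr, comparison = cmp)
        expect_identical(r$wins + r$losses + r$ties, r$n_pairs)
        expect_equal(r$delta, (r$wins - r$losses) / r$n_pairs)
        expect_true(r$delta >= -1 && r$delta <= 1)
      }
    }
  }
})

test_that("univariate unmatched GPC is a linear transform of Mann-Whitney", {
  for (s in 1:25) {
    d <- generate_trial(n_subjects = 8, sequence_split = c(4, 4),
                        seed = 1000 + s)
    r <- gpc_net_benefit(d, "count", pairing = "unmatched",
                         comparison = "univariate",
                         direction = "higher_is_better",
                         summary = "change_from_baseline_t3")
    sm <- summarize_blocks(d, "count", "change_from_baseline_t3")
    v <- sm$value[sm$treatment == "verum"]
    p <- sm$value[sm$treatment == "placebo"]
    U <- suppressWarnings(
      wilcox.test(v, p, exact = FALSE)$statistic)  # ties counted half
    expect_equal(r$delta, unname(2 * U / (length(v) * length(p)) - 1))
  }
})

test_that("exact permutation p-values match exhaustive enumeration", {
  for (s in 1:6) {
    n <- sample(2:4, 1)
    d <- generate_trial(n_subjects = n,
                        sequence_split = c(ceiling(n / 2), floor(n / 2)),
                        seed = 1400 + s)
    for (cmp in c("prioritized", "univariate")) {
      got <- gpc_test(d, "count", comparison = cmp, exact = TRUE)
      want <- oracle_exact_p(d, "count", comparison = cmp)
      expect_equal(got$delta, want$delta)
      expect_equal(got$p_value, want$p)
    }
  }
})

test_that("degenerate all-identical data yield delta 0 and p 1", {
  d <- trial_from_blocks(matrix(4L, 5, 4), matrix(4L, 5, 4))
  r <- gpc_test(d, "count", n_perm = 200, seed = 1)
  expect_equal(r$delta, 0)
  expect_equal(r$p_value, 1)
  rm <- gpc_test(d, "count", pairing = "matched")
  expect_equal(rm$p_value, 1)
})

test_that("Monte-Carlo permutation p-values are reproducible under a seed", {
  d <- generate_trial(seed = 55)
  a <- gpc_test(d, "count", n_perm = 300, exact = FALSE, seed = 42)
  b <- gpc_test(d, "count", n_perm = 300, exact = FALSE, seed = 42)
  expect_identical(a$p_value, b$p_value)
})

test_that("the conditional sign test matches binomial enumeration", {
  # scores (+1,+1,+1,0,-1,0): m = 4, b = 3 -> p = 2 P(B >= 3) = 10/16
  P1 <- rbind(c(9, 9, 5, 9), c(9, 9, 5, 9), c(9, 9, 5, 9),
              c(9, 9, 5, 9), c(9, 9, 5, 9), c(9, 9, 5, 9))
  P2 <- rbind(c(9, 9, 7, 9), c(9, 9, 7, 9), c(9, 9, 7, 9),
              c(9, 9, 5, 9), c(9, 9, 3, 9), c(9, 9, 5, 9))
  # verum = period 1 for all subjects
  d <- trial_from_blocks(P1, P2, sequences = rep("VP", 6))
  r <- gpc_test(d, "count", pairing = "matched", comparison = "prioritized")
  expect_identical(c(r$wins, r$losses, r$ties), c(3L, 1L, 2L))
  expect_equal(r$p_value, 10 / 16)
  expect_true(r$small_sample)

  # all wins over m = 15: p = 2 * (1/2)^15
  d15 <- trial_from_blocks(matrix(1L, 15, 4), matrix(5L, 15, 4),
                           sequences = rep("VP", 15))
  r15 <- gpc_test(d15, "count", pairing = "matched")
  expect_equal(r15$p_value, 2 * 0.5^15)
  expect_false(r15$small_sample)
})

test_that("matched ties are conditioned away entirely", {
  d <- trial_from_blocks(matrix(2L, 4, 4), matrix(2L, 4, 4))
  r <- gpc_test(d, "count", pairing = "matched")
  expect_equal(r$p_value, 1)
  expect_equal(r$delta, 0)
})

test_that("permutation p-values are super-uniform under the null generator", {
  hits <- 0
  n_rep <- 200
  for (s in 1:n_rep) {
    d <- block_permute(generate_trial(seed = 3000 + s), seed = 3000 + s)
    p <- gpc_test(d, "count", n_perm = 200, exact = FALSE,
                  seed = s)$p_value
    if (p <= 0.1) hits <- hits + 1
  }
  expect_lt(hits / n_rep, 0.1 + 3 * sqrt(0.1 * 0.9 / n_rep))
})
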