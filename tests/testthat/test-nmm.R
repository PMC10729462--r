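test_that("the relative effect equals pair counting with half-weighted ties", {
  expect_equal(relative_effect(c(1, 2), c(2, 3)), 0.875)
  expect_equal(relative_effect(c(5, 5, 5), c(5, 5, 5)), 0.5)
  expect_equal(relative_effect(c(1, 2), c(3, 4)), 1)
  expect_equal(relative_effect(c(3, 4), c(1, 2)), 0)
  # brute-force pair counting on random tied samples
  for (s in 1:20) {
    set.seed(s)
    a <- sample(0:5, 7, replace = TRUE)
    b <- sample(0:5, 9, replace = TRUE)
    brute <- (sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))) /
      (length(a) * length(b))
    expect_equal(relative_effect(a, b), brute)
  }
})

test_that("relative effects are complementary and rank-invariant", {
  for (s in 1:10) {
    set.seed(100 + s)
    a <- rpois(8, 5); b <- rpois(6, 7)
    expect_equal(relative_effect(a, b) + relative_effect(b, a), 1)
    mono <- function(x) exp(x / 2) + x  # strictly increasing
    expect_equal(relative_effect(mono(a), mono(b)), relative_effect(a, b))
  }
})

test_that("per-cell relative effects average to one half with equal cells", {
  d <- generate_trial(n_subjects = 8, sequence_split = c(4, 4), seed = 12)
  tab <- relative_effect_table(d, 1, "count")
  expect_identical(nrow(tab), 8L)
  expect_true(all(tab$rel_effect >= 0 & tab$rel_effect <= 1))
  expect_equal(sum(tab$rel_effect * tab$n) / sum(tab$n), 0.5)
})

test_that("identical group data drive the interaction statistic to zero", {
  m <- rbind(c(1, 5, 3, 2), c(4, 4, 4, 4), c(0, 2, 8, 1), c(1, 5, 3, 2))
  # period 1: placebo = PV subjects, verum = VP subjects, identical matrices
  d <- trial_from_blocks(rbind(m, m), rbind(m, m)[, c(1, 2, 3, 4)],
                         sequences = c(rep("PV", 4), rep("VP", 4)))
  r <- ats_interaction_test(d, 1, "count")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("the ATS quadratic form matches a direct matrix evaluation", {
  for (s in 1:5) {
    d <- generate_trial(n_subjects = 6, sequence_split = c(3, 3),
                        seed = 1500 + s)
    got <- ats_interaction_test(d, 1, "count")

    # independent reconstruction from first principles
    sub <- d[d$period == 1, ]
    r <- rank(sub$count)
    R1 <- do.call(rbind, lapply(unique(sub$subject_id[sub$treatment == "placebo"]),
      function(id) r[sub$subject_id == id & sub$treatment == "placebo"]))
    R2 <- do.call(rbind, lapply(unique(sub$subject_id[sub$treatment == "verum"]),
      function(id) r[sub$subject_id == id & sub$treatment == "verum"]))
    phat <- c(colMeans(R1), colMeans(R2))
    P2 <- diag(2) - matrix(1 / 2, 2, 2)
    P4 <- diag(4) - matrix(1 / 4, 4, 4)
    TT <- kronecker(P2, P4)
    V <- rbind(cbind(cov(R1) / nrow(R1), matrix(0, 4, 4)),
               cbind(matrix(0, 4, 4), cov(R2) / nrow(R2)))
    stat <- drop(t(phat) %*% TT %*% phat) / sum(diag(TT %*% V))
    f1 <- sum(diag(TT %*% V))^2 / sum(diag(TT %*% V %*% TT %*% V))
    expect_equal(got$statistic, stat)
    expect_equal(got$df1, f1)
    expect_equal(got$p_value, pchisq(stat * f1, f1, lower.tail = FALSE))
  }
})

test_that("the ATS is invariant under joint monotone transforms", {
  d <- generate_trial(seed = 91)
  a <- ats_interaction_test(d, 2, "count")
  d2 <- d
  d2$count <- as.integer(d$count^2)  # strictly monotone on non-negative ints
  b <- ats_interaction_test(d2, 2, "count")
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("interaction testing demands enough subjects and a known period", {
  d <- generate_trial(n_subjects = 3, sequence_split = c(2, 1), seed = 7)
  expect_error(ats_interaction_test(d, 1, "count"), "at least 2 subjects")
  d2 <- generate_trial(seed = 7)
  expect_error(ats_interaction_test(d2, 3, "count"), "unknown period")
})

test_that("cross-over combination rules act on the per-period p-values", {
  d <- generate_trial(seed = 14)
  r <- nmm_crossover(d, "count", rule = "per_period")
  expect_true(is.na(r$reject))
  expect_identical(nrow(tidy(r)), 2L)

  # rule arithmetic on p = (0.03, 0.20) at alpha 0.05
  fake <- r
  fake$periods[[1]]$p_value <- 0.03
  fake$periods[[2]]$p_value <- 0.20
  pmin_ <- min(0.03, 0.20)
  expect_false(pmin_ < 0.05 / 2)  # bonferroni would not reject
  expect_true(pmin_ < 0.05)       # min_p rejects
  expect_true(nmm_crossover(d, "count", rule = "min_p",
                            alpha = 1)$reject)   # any p below alpha = 1
})

test_that("the min-p union rule rejects more often than either period alone", {
  n_rep <- 150
  rej_minp <- rej_per <- 0
  for (s in 1:n_rep) {
    d <- block_permute(generate_trial(seed = 5000 + s), seed = 5000 + s)
    r <- nmm_crossover(d, "count", rule = "min_p", alpha = 0.05)
    p1 <- r$periods[[1]]$p_value
    if (r$reject) rej_minp <- rej_minp + 1
    if (p1 < 0.05) rej_per <- rej_per + 1
  }
  expect_gte(rej_minp, rej_per)
})
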