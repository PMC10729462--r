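test_that("Akaike weights match direct evaluation and its symmetries", {
  w <- akaike_weights(c(10, 12, 14))
  direct <- exp(-c(10, 12, 14) / 2) / sum(exp(-c(10, 12, 14) / 2))
  expect_equal(w, direct)
  expect_equal(w, c(0.6652, 0.2447, 0.0900), tolerance = 1e-3)

  # equal AICs: uniform weights at any pool size
  for (q in c(2, 5, 9)) {
    expect_equal(akaike_weights(rep(3.7, q)), rep(1 / q, q))
  }

  # shift invariance (Akaike weights depend only on AIC differences)
  a <- c(100.2, 101.7, 99.3, 104.0)
  expect_equal(akaike_weights(a), akaike_weights(a + 1000))

  # monotone decreasing in AIC, non-negative, sum to one
  for (s in 1:5) {
    set.seed(s)
    a <- sort(rnorm(6, 50, 10))
    w <- akaike_weights(a)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    expect_true(all(diff(w) <= 1e-12))
  }
})

test_that("non-finite AICs lose their weight; all-failed pools are an error", {
  expect_warning(w <- akaike_weights(c(10, Inf, 12)), "non-finite")
  expect_equal(w[2], 0)
  expect_equal(sum(w), 1)
  expect_error(akaike_weights(c(Inf, NA)), "non-finite")
})

test_that("pool fitting is deterministic and records candidate metadata", {
  d <- generate_trial(seed = 61)
  p1 <- fit_pool(d, "count")
  p2 <- fit_pool(d, "count")
  expect_equal(p1$table$aic, p2$table$aic)
  expect_identical(nrow(p1$table), 6L)  # {poisson, negbin} x 3 structures
  expect_true(all(p1$table$ok))

  db <- dichotomize(d)
  pb <- fit_pool(db, "binary")
  expect_identical(nrow(pb$table), 3L)
})

test_that("a degenerate single-model pool returns that model's effect", {
  d <- generate_trial(seed = 62)
  pool <- candidate_pool("count")[1, ]
  pool2 <- rbind(pool, pool)  # duplicate so Q >= 2 for the weights
  pf <- fit_pool(d, "count", pool2)
  w <- akaike_weights(pf$table$aic)
  expect_equal(w, c(0.5, 0.5))
  avg <- averaged_effect(pf, w, "rate_ratio")
  single <- averaged_effect(list(table = pf$table[1, ],
                                 fits = pf$fits[1], frame = pf$frame,
                                 outcome = "count"),
                            1, "rate_ratio")
  expect_equal(avg, single)
})

test_that("the averaged effect is a convex combination of per-model effects", {
  d <- generate_trial(seed = 63)
  pf <- fit_pool(d, "count")
  w <- akaike_weights(pf$table$aic)
  per <- vapply(seq_along(pf$fits), function(q) {
    sub <- list(table = pf$table[q, ], fits = pf$fits[q],
                frame = pf$frame, outcome = "count")
    log(averaged_effect(sub, 1, "rate_ratio"))
  }, 0)
  avg <- log(averaged_effect(pf, w, "rate_ratio"))
  expect_gte(avg, min(per) - 1e-12)
  expect_lte(avg, max(per) + 1e-12)
})

test_that("identical arms give an averaged effect at the null and p = 1", {
  P <- rbind(c(5, 6, 4, 4), c(9, 7, 8, 6), c(2, 2, 3, 1), c(4, 4, 4, 4))
  d <- trial_from_blocks(P, P)
  r <- ma_test(d, "count", n_perm = 30, seed = 1)
  expect_equal(r$effect, 1)   # rate ratio on identical arms
  expect_equal(r$p_value, 1)
})

test_that("the exact MA permutation matches brute-force enumeration at n = 2", {
  d <- trial_from_blocks(rbind(c(3, 5, 2, 4), c(7, 6, 9, 4)),
                         rbind(c(6, 4, 7, 5), c(5, 8, 3, 6)))
  pool <- candidate_pool("count")[c(1, 3), ]  # two Poisson candidates
  got <- ma_test(d, "count", pool = pool, exact = TRUE)

  # brute force: all 4 within-subject label swaps, effect recomputed per swap
  eff_of <- function(swap) {
    dd <- d
    for (i in which(swap == 1)) {
      id <- sprintf("S%02d", i)
      sel <- dd$subject_id == id
      dd$treatment[sel] <- ifelse(dd$treatment[sel] == "verum",
                                  "placebo", "verum")
      dd$sequence[sel] <- ifelse(dd$sequence[sel] == "PV", "VP", "PV")
    }
    dd <- as_trial_data(tibble::as_tibble(dd), revalidate = TRUE)
    pf <- fit_pool(dd, "count", pool)
    abs(log(averaged_effect(pf, akaike_weights(pf$table$aic), "rate_ratio")))
  }
  stars <- apply(expand.grid(0:1, 0:1), 1, eff_of)
  obs <- eff_of(c(0, 0))
  expect_equal(got$p_value, mean(stars >= obs - 1e-12))
})

test_that("binary delta-delta is centred and its test is reproducible", {
  d <- dichotomize(generate_trial(seed = 64))
  r1 <- ma_test(d, "binary", n_perm = 60, exact = FALSE, seed = 5)
  r2 <- ma_test(d, "binary", n_perm = 60, exact = FALSE, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_identical(r1$effect_name, "delta_delta")
  expect_true(abs(r1$effect) <= 1)
})
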