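test_that("the diff statistic has the documented sign convention", {
  sp <- fx_space()
  tr <- fx_trials()[[7]]
  sep <- dissim(tr$test, tr$transformed_test, sp)
  r_test <- trial_diff(tr$test, tr, sp)
  expect_equal(r_test$diff, sep, tolerance = 1e-12)
  expect_equal(r_test$diff, r_test$d_transformed - r_test$d_test)
  r_tt <- trial_diff(tr$transformed_test, tr, sp)
  expect_equal(r_tt$diff, -sep, tolerance = 1e-12)
  expect_true(r_test$valid && r_tt$valid)
})

test_that("an equidistant drawing constructed by root finding has diff zero", {
  sp <- fx_space()
  tr <- fx_trials()[[9]]
  blend_diff <- function(w) {
    d <- contour((1 - w) * unclass(tr$test)[, 1:2] +
                   w * unclass(tr$transformed_test)[, 1:2])
    trial_diff(d, tr, sp)$diff
  }
  lo <- 0; hi <- 1
  stopifnot(blend_diff(0) > 0, blend_diff(1) < 0)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    v <- blend_diff(mid)
    if (abs(v) < 1e-8) break
    if (v > 0) lo <- mid else hi <- mid
  }
  d_eq <- contour((1 - mid) * unclass(tr$test)[, 1:2] +
                    mid * unclass(tr$transformed_test)[, 1:2])
  expect_lt(abs(trial_diff(d_eq, tr, sp)$diff), 1e-6)
})

# synthetic results table with the canonical balanced layout:
# 5 types x 2 magnitudes x 3 similarities, 2 per cell, 11 participants
fake_results <- function(seed = 1) {
  des <- sample_design(enumerate_design(8L), 60L, "cells", seed = 3L)
  res <- do.call(rbind, lapply(1:11, function(p) {
    data.frame(trial_id = seq_len(60L), participant_id = p,
               type = des$type, magnitude_level = des$magnitude,
               similarity_level = des$similarity,
               d_test = NA_real_, d_transformed = NA_real_,
               diff = NA_real_, valid = TRUE)
  }))
  set.seed(seed)
  res$diff <- rnorm(nrow(res), mean = -0.2, sd = 0.3)
  res$d_test <- runif(nrow(res), 0.5, 1.5)
  res$d_transformed <- res$d_test + res$diff
  res
}

test_that("aggregation reproduces the canonical degrees-of-freedom pattern", {
  res <- fake_results()
  ov <- aggregate_diffs(res, "overall")
  expect_equal(ov$groups$n, 660L)
  expect_equal(ov$groups$df, 659)

  ty <- aggregate_diffs(res, "by_type")
  expect_equal(ty$omnibus$df1, 4)
  expect_equal(ty$omnibus$df2, 655)
  expect_true(all(ty$groups$df == 131))

  si <- aggregate_diffs(res, "by_similarity")
  expect_equal(si$omnibus$df1, 2)
  expect_equal(si$omnibus$df2, 657)
  expect_true(all(si$groups$df == 219))

  mg <- aggregate_diffs(res, "by_magnitude")
  expect_true(all(mg$groups$df == 329))
  expect_equal(mg$omnibus$test, "two-sample t (Welch)")
  mg2 <- aggregate_diffs(res, "by_magnitude", var_equal = TRUE)
  expect_equal(mg2$omnibus$df, 658)
  expect_equal(mg2$omnibus$test, "two-sample t (pooled)")
})

test_that("aggregation output matches direct t.test and oneway.test oracles", {
  res <- fake_results(seed = 5)
  ov <- aggregate_diffs(res, "overall")
  tt <- t.test(res$diff)
  expect_equal(ov$groups$t, unname(tt$statistic))
  expect_equal(ov$groups$p, tt$p.value)
  expect_equal(c(ov$groups$ci_lo, ov$groups$ci_hi), unname(tt$conf.int),
               ignore_attr = TRUE)

  ty <- aggregate_diffs(res, "by_type")
  f <- oneway.test(diff ~ type, data = res, var.equal = TRUE)
  expect_equal(ty$omnibus$F, unname(f$statistic))
  expect_equal(ty$omnibus$p, f$p.value)
  expect_true(all(ty$groups$p_holm >= ty$groups$p))
})

test_that("aggregation is order invariant and guards degenerate input", {
  res <- fake_results(seed = 2)
  shuf <- res[sample(nrow(res)), ]
  a <- aggregate_diffs(res, "by_type")$groups
  b <- aggregate_diffs(shuf, "by_type")$groups
  expect_equal(a, b)

  const <- res[1:20, ]
  const$diff <- 0.4
  expect_error(aggregate_diffs(const, "overall"), "degenerate variance")

  res$valid[1:5] <- FALSE
  expect_warning(ov <- aggregate_diffs(res, "overall"), "invalid")
  expect_equal(ov$groups$n, 655L)
})

test_that("fidelity recovery orders mean diff monotonically in lambda", {
  sp <- fx_space()
  trials <- fx_trials()[1:20]
  rec <- recovery_experiment(c(0, 0.5, 1), panel_size = 2L, trials, sp,
                             sigma = 0.01, seed = 77L)
  expect_equal(rec$lambda, c(0, 0.5, 1))
  expect_true(all(diff(rec$mean_diff) < 0))
  expect_gt(rec$mean_diff[1], 0)
  expect_lt(rec$mean_diff[3], 0)
  expect_equal(rec$n, rep(40L, 3))
})
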