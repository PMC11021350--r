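# backing matrix whose column means equal `means` exactly
backing_for <- function(means, np = 12, sd = 0.1, seed = 1) {
  set.seed(seed)
  e <- matrix(rnorm(np * length(means), 0, sd), np)
  e <- sweep(e, 2, colMeans(e))
  sweep(e, 2, means, "+")
}

test_that("jointly monotone data give p = 1 in every mode and for any seed", {
  means_x <- c(.1, .3, .5, .7, .9)
  means_y <- c(.2, .4, .5, .8, .85)
  st <- state_trace(means_x, means_y,
                    backing_x = backing_for(means_x, seed = 1),
                    backing_y = backing_for(means_y, seed = 2))
  for (mode in c("participant_resample", "parametric_normal")) {
    for (seed in c(3, 99)) {
      r <- cmr_test(st, n_boot = 59, seed = seed, mode = mode)
      expect_equal(r$observed_stat, 0)
      expect_equal(r$p_value, 1)
    }
  }
})

test_that("results are bit-for-bit reproducible given (seed, n_boot, mode)", {
  means_x <- c(.1, .5, .3, .9, .6)
  means_y <- c(.4, .2, .6, .7, .9)
  st <- state_trace(means_x, means_y,
                    backing_x = backing_for(means_x, sd = 0.15, seed = 3),
                    backing_y = backing_for(means_y, sd = 0.15, seed = 4))
  for (mode in c("participant_resample", "parametric_normal")) {
    r1 <- cmr_test(st, n_boot = 99, seed = 42, mode = mode)
    r2 <- cmr_test(st, n_boot = 99, seed = 42, mode = mode)
    expect_identical(r1$boot_stats, r2$boot_stats)
    expect_identical(r1$p_value, r2$p_value)
    r3 <- cmr_test(st, n_boot = 99, seed = 43, mode = mode)
    expect_false(identical(r1$boot_stats, r3$boot_stats))
  }
})

test_that("the p-value obeys the add-one formula and its bounds", {
  means_x <- c(.1, .5, .3, .9, .6)
  means_y <- c(.4, .2, .6, .7, .9)
  st <- state_trace(means_x, means_y,
                    backing_x = backing_for(means_x, sd = 0.2, seed = 5),
                    backing_y = backing_for(means_y, sd = 0.2, seed = 6))
  r <- cmr_test(st, n_boot = 199, seed = 7)
  expect_equal(r$p_value,
               (1 + sum(r$boot_stats >= r$observed_stat)) / (r$n_boot + 1))
  expect_gte(r$p_value, 1 / (r$n_boot + 1))
  expect_lte(r$p_value, 1)
  expect_true(all(r$boot_stats >= 0))
  expect_equal(r$observed_stat, r$model$fit_stat)
})

test_that("participant resampling requires backing data", {
  st <- state_trace(c(0, 1), c(1, 0))
  expect_error(cmr_test(st, n_boot = 9, mode = "participant_resample"),
               "backing")
  expect_error(cmr_test(st, n_boot = 0), "positive integer")
})

test_that("summary-statistics mode: monotone means give zero misfit and p = 1", {
  # two groups, identical means on both variables
  inp <- data.frame(condition = rep(c("A", "B"), each = 2),
                    dv = rep(c("c", "a"), 2),
                    mean = c(.5, .6, .5, .6), sd = .2, n = 20)
  r <- cmr_from_summary(inp, n_boot = 39, seed = 1)
  expect_equal(r$observed_stat, 0)
  expect_equal(r$p_value, 1)

  # five groups, jointly monotone means
  inp5 <- data.frame(condition = rep(paste0("G", 1:5), each = 2),
                     dv = rep(c("c", "a"), 5),
                     mean = c(t(cbind(seq(.3, .9, length.out = 5),
                                      seq(.2, .8, length.out = 5)))),
                     sd = 1, n = 20)
  r5 <- cmr_from_summary(inp5, n_boot = 39, seed = 2)
  expect_equal(r5$observed_stat, 0)
  expect_equal(r5$p_value, 1)
})

test_that("a dissociation buried in large SDs is not significant", {
  # one group depressed on one variable only, SD large relative to the dip
  m_cog <- c(.80, .78, .76, .74, .72)
  m_aff <- c(.80, .78, .40, .74, .72)   # group 3 selectively impaired
  inp <- data.frame(condition = rep(paste0("G", 1:5), each = 2),
                    dv = rep(c("cog", "aff"), 5),
                    mean = c(t(cbind(m_cog, m_aff))),
                    sd = 1.5, n = 12)
  r <- cmr_from_summary(inp, n_boot = 199, seed = 3)
  expect_gt(r$p_value, 0.05)
  # self-consistency: a longer independent run agrees on the conclusion
  r2 <- cmr_from_summary(inp, n_boot = 1999, seed = 101)
  expect_gt(r2$p_value, 0.05)
  expect_lt(abs(r2$p_value - r$p_value), 0.2)
})

test_that("summary-statistics input is validated", {
  bad <- data.frame(condition = c("A", "A"), dv = c("x", "y"),
                    mean = c(.5, .6), sd = c(0, .1), n = c(10, 10))
  expect_error(cmr_from_summary(bad, n_boot = 9), "positive")
  bad2 <- data.frame(condition = c("A", "A"), dv = c("x", "y"),
                     mean = c(.5, .6), sd = c(.1, .1), n = c(1, 10))
  expect_error(cmr_from_summary(bad2, n_boot = 9), ">= 2")
  bad3 <- data.frame(condition = c("A", "B"), dv = c("x", "x"),
                     mean = c(.5, .6), sd = .1, n = 10)
  expect_error(cmr_from_summary(bad3, n_boot = 9), "two dependent")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), 3), c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(0.5, 3), 1)
  expect_equal(adjust_pvalues(c(3e-4, 1e-4, 2e-4), 3), c(9e-4, 3e-4, 6e-4))
  expect_true(all(adjust_pvalues(c(3e-4, 1e-4, 2e-4), 3) < 0.001))
  expect_error(adjust_pvalues(0, 3), "0, 1")
  expect_error(adjust_pvalues(1.2, 3), "0, 1")
  expect_error(adjust_pvalues(0.5, 0), "positive")
})
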