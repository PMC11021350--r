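test_that("jointly monotone data fit perfectly", {
  st <- state_trace(c(.2, .5, .9), c(.1, .4, .8))
  f <- cmr(st)
  expect_equal(f$fit_stat, 0)
  expect_equal(f$x_fitted, st$x_means)
  expect_equal(f$y_fitted, st$y_means)
  expect_true(f$exact)
  # fitted values are weakly nondecreasing along the common order
  expect_true(all(diff(f$x_fitted[f$order]) >= -1e-12))
  expect_true(all(diff(f$y_fitted[f$order]) >= -1e-12))
})

test_that("a forced crossing pools one variable's two points", {
  st <- state_trace(c(0, 1), c(1, 0))
  f <- cmr(st)
  expect_equal(f$fit_stat, 0.5)
})

test_that("four-point crossing matches the brute-force enumeration oracle", {
  x <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(0.2, 0.8, 0.3, 0.7)
  st <- state_trace(x, y)
  ref <- cmr_ref(x, rep(1, 4), y, rep(1, 4))
  f <- cmr(st, method = "exhaustive")
  expect_equal(f$fit_stat, ref$sse, tolerance = 1e-10)
  expect_gt(f$fit_stat, 0)
  # the reported statistic decomposes as the two isotonic SSEs under the order
  sse_parts <- isotonic_fit(x, order = f$order)$sse +
    isotonic_fit(y, order = f$order)$sse
  expect_equal(f$fit_stat, sse_parts, tolerance = 1e-12)
})

test_that("swapping the two dependent variables leaves fit_stat unchanged", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:7, 1)
    x <- runif(n); y <- runif(n)
    wx <- runif(n, .5, 2); wy <- runif(n, .5, 2)
    f1 <- cmr(state_trace(x, y, wx, wy), method = "exhaustive")
    f2 <- cmr(state_trace(y, x, wy, wx), method = "exhaustive")
    expect_equal(f1$fit_stat, f2$fit_stat, tolerance = 1e-10)
  }
})

test_that("strictly increasing transforms of one variable preserve a zero fit", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    theta <- sort(runif(n))
    x <- plogis(2 * theta - 1)
    y <- theta^2
    perm <- sample(n)  # condition labelling should not matter
    st <- state_trace(x[perm], y[perm])
    expect_equal(cmr(st)$fit_stat, 0)
    # a strictly increasing transform of y keeps the data jointly monotone
    st2 <- state_trace(x[perm], exp(3 * y[perm]))
    expect_equal(cmr(st2)$fit_stat, 0)
  }
})

test_that("fit_stat is zero exactly when some common order sorts both variables", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- sample(0:3, n, replace = TRUE) / 3  # ties are likely
    y <- sample(0:3, n, replace = TRUE) / 3
    f <- cmr(state_trace(x, y), method = "exhaustive")
    zero_order_exists <- any(vapply(perms_of(n), function(ord) {
      all(diff(x[ord]) >= 0) && all(diff(y[ord]) >= 0)
    }, logical(1)))
    expect_identical(f$fit_stat <= 1e-12, zero_order_exists)
  }
})

test_that("branch-and-bound equals exhaustive enumeration on random instances", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    x <- runif(n); y <- runif(n)
    wx <- runif(n, .3, 3); wy <- runif(n, .3, 3)
    st <- state_trace(x, y, wx, wy)
    ex <- cmr(st, method = "exhaustive")
    bb <- cmr(st, method = "branch_and_bound")
    expect_equal(bb$fit_stat, ex$fit_stat, tolerance = 1e-9)
    expect_true(bb$exact)
  }
})

test_that("the multistart heuristic is near-exact on moderate designs", {
  set.seed(15)
  worst <- 0
  for (i in 1:15) {
    n <- 10
    x <- runif(n); y <- runif(n)
    st <- state_trace(x, y)
    bb <- cmr(st, method = "branch_and_bound")
    ms <- cmr(st, method = "multistart")
    expect_false(ms$exact)
    expect_gte(ms$fit_stat, bb$fit_stat - 1e-12)
    worst <- max(worst, ms$fit_stat - bb$fit_stat)
  }
  expect_lt(worst, 1e-6)
})

test_that("guards reject degenerate or oversized requests", {
  expect_error(state_trace(0.5, 0.5), "at least 2")
  big <- state_trace(runif(9), runif(9))
  expect_error(cmr(big, method = "exhaustive"), "limited to 8")
  expect_error(state_trace(c(0, 1), c(1, 0), x_weights = c(0, 1)), "positive")
  bx <- matrix(c(0, 1, 0, 1), 2)
  expect_error(state_trace(c(0.9, 0.5), c(0, 1), backing_x = bx), "reproduce")
})

test_that("accessor methods return consistent views of the fit", {
  st <- state_trace(c(.1, .5, .3, .9), c(.2, .6, .5, .8),
                    dv_names = c("think", "feel"))
  f <- cmr(st)
  cf <- coef(f)
  expect_identical(dim(cf), c(4L, 2L))
  expect_identical(colnames(cf), c("think_fitted", "feel_fitted"))
  expect_equal(unname(cf[, 1]), f$x_fitted)
  res <- residuals(f)
  expect_equal(unname(res[, 1]), st$x_means - f$x_fitted)
  expect_equal(f$fit_stat,
               sum(st$x_weights * res[, 1]^2) + sum(st$y_weights * res[, 2]^2),
               tolerance = 1e-12)
  expect_output(print(summary(f)), "fitted common order")
})
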