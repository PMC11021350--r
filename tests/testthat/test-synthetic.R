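test_that("grid layout emits the expected row counts", {
  # scored rows per participant: 5 exchange x 2 item x 3 DV x items_per_cell
  cfg <- synth_config(n_participants = 4, items_per_cell = 1, seed = 1,
                      include_say = FALSE, dont_know_rate = 0)
  d <- sample_dataset(cfg)
  expect_equal(nrow(d$responses), 4 * 5 * 2 * 3 * 1)
  cfg2 <- synth_config(n_participants = 4, items_per_cell = 2, seed = 1)
  d2 <- sample_dataset(cfg2)
  expect_equal(sum(d2$responses$question_type != "say"), 4 * 5 * 2 * 3 * 2)
  expect_equal(nrow(d2$responses), 4 * 5 * 2 * 4 * 2)
})

test_that("tasit layout reproduces the instrument's structure", {
  d <- sample_dataset(synth_config(n_participants = 4, seed = 2),
                      layout = "tasit")
  per <- split(d$responses, d$responses$participant_id)
  for (p in per) {
    expect_equal(nrow(p), 124)                       # 31 scenes x 4 questions
    expect_equal(sum(p$question_type != "say"), 93)  # 31 scenes x 3 scored
    expect_equal(length(unique(p$scene_id)), 31)
    expect_equal(sum(p$part == "two") / 4, 15)
    expect_equal(sum(p$part == "three") / 4, 16)
  }
  # every exchange x question x item cell is populated
  sc <- d$responses[d$responses$question_type != "say" &
                      d$responses$participant_id == "P001", ]
  counts <- table(sc$exchange_type, sc$question_type, sc$item_type)
  expect_true(all(counts >= 1))
})

test_that("generation is deterministic and files are byte-identical", {
  cfg <- synth_config(n_participants = 6, seed = 33)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(sample_dataset(cfg), f1)
  write_responses(sample_dataset(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- sample_dataset(synth_config(n_participants = 6, seed = 34))
  expect_false(identical(readLines(f1), {
    f3 <- withr::local_tempfile(fileext = ".csv")
    write_responses(d3, f3); readLines(f3)
  }))
})

test_that("two_latent with delta = 0 reduces exactly to one_latent", {
  d1 <- sample_dataset(synth_config("one_latent", n_participants = 8, seed = 9))
  d2 <- sample_dataset(synth_config("two_latent", delta = 0,
                                    n_participants = 8, seed = 9))
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$ep_scores, d2$ep_scores)
  s1 <- sample_summary_dataset(synth_config("one_latent", seed = 9))
  s2 <- sample_summary_dataset(synth_config("two_latent", delta = 0, seed = 9))
  expect_identical(s1, s2)
})

test_that("logistic link maps a zero latent value to probability one half", {
  cfg <- synth_config(theta = rep(0, 20),
                      link_params = data.frame(dv = c("think", "do", "feel"),
                                               slope = 1, intercept = 0))
  p <- cell_probabilities(cfg)
  expect_true(all(p$probability == 0.5))
})

test_that("one-latent population means are jointly monotone, two-latent are not", {
  for (seed in 1:3) {
    cfg <- synth_config("one_latent", seed = seed)
    for (pair in list(c("think", "feel"), c("do", "feel"), c("think", "do"))) {
      st <- population_state_trace(cfg, pair)
      # exact check on a subsample of 8 conditions
      sub <- seq(1, 20, length.out = 8)
      st8 <- state_trace(st$x_means[sub], st$y_means[sub])
      expect_equal(cmr(st8, method = "exhaustive")$fit_stat, 0)
      # heuristic check on the full 20-condition grid
      set.seed(1)
      expect_equal(cmr(st, method = "multistart")$fit_stat, 0)
    }
  }
  cfg2 <- synth_config("two_latent", delta = "large")
  for (pair in list(c("think", "feel"), c("do", "feel"), c("think", "do"))) {
    st <- population_state_trace(cfg2, pair)
    set.seed(1)
    expect_gt(cmr(st, method = "multistart")$fit_stat, 1e-4)
  }
})

test_that("emitted files round-trip through the reader without errors", {
  for (layout in c("grid", "tasit")) {
    d <- sample_dataset(synth_config(n_participants = 8, seed = 13,
                                     dont_know_rate = 0.05), layout = layout)
    path <- withr::local_tempfile(fileext = ".csv")
    write_responses(d, path)
    got <- read_responses(path)
    expect_equal(nrow(got), nrow(d$responses))
    ep <- withr::local_tempfile(fileext = ".csv")
    write_ep_scores(d, ep)
    expect_identical(read_ep_scores(ep), d$ep_scores)
  }
})

test_that("summary generator emits a valid two-DV table", {
  s <- sample_summary_dataset(synth_config(seed = 3), n_groups = 5,
                              n_per_group = 30)
  expect_equal(nrow(s), 10)
  expect_true(all(s$sd > 0))
  expect_true(all(s$n == 30))
  r <- cmr_from_summary(s, n_boot = 19, seed = 1)
  expect_s3_class(r, "cmr_test")
})

test_that("configuration validation rejects bad inputs", {
  expect_error(synth_config(n_participants = 2), ">= 4")
  expect_error(synth_config(items_per_cell = 0), ">= 1")
  expect_error(synth_config(theta = 1:5), "20")
  expect_error(synth_config(delta = -1, model = "two_latent"), "nonnegative")
  expect_error(synth_config(delta = "huge", model = "two_latent"), "preset")
  lp <- data.frame(dv = c("think", "do", "feel"), slope = c(1, -1, 1),
                   intercept = 0)
  expect_error(synth_config(link_params = lp), "positive")
})
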