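test_that("d-prime applies the extreme-rate adjustment and quantile difference", {
  r <- dprime(20, 0, 0, 20)
  expect_equal(r$hit_rate, 0.99)
  expect_equal(r$fa_rate, 0.01)
  expect_equal(r$dprime, qnorm(0.99) - qnorm(0.01), tolerance = 1e-12)
  expect_equal(round(r$dprime, 4), 4.6527)
  expect_equal(dprime(10, 10, 10, 10)$dprime, 0)
  expect_equal(dprime(16, 4, 4, 16)$dprime, 2 * qnorm(0.8), tolerance = 1e-12)
  expect_equal(round(dprime(16, 4, 4, 16)$dprime, 4), 1.6832)
  expect_error(dprime(0, 0, 3, 7), "signal")
})

test_that("d-prime is antisymmetric under swapping hit and false-alarm counts", {
  set.seed(2)
  for (i in 1:20) {
    h <- sample(0:30, 1)
    f <- sample(0:30, 1)
    a <- dprime(h, 30 - h, f, 30 - f)
    b <- dprime(f, 30 - f, h, 30 - h)
    expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
  }
})

long_fixture <- function(props, n_trials = 4L) {
  # one cell; one participant per element of props with that prop correct
  do.call(rbind, lapply(seq_along(props), function(i) {
    k <- round(props[i] * n_trials)
    data.frame(participant_id = paste0("p", i), group = "g1",
               task = "single_cue", condition = "deterministic",
               phase = "early",
               correct = rep(c(TRUE, FALSE), c(k, n_trials - k)))
  }))
}

test_that("accuracy cells aggregate participant proportions correctly", {
  tab <- accuracy_table(long_fixture(c(0.75, 0.25)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$mean, 0.5)
  expect_equal(tab$sd, sqrt(2) * 0.25, tolerance = 1e-4)  # 0.3536
  expect_equal(tab$n, 2L)
  perfect <- long_fixture(c(1, 1, 1))
  expect_equal(accuracy_table(perfect)$mean, 1)
})

test_that("accuracy cell means are invariant to trial order", {
  long <- long_fixture(c(0.75, 0.5, 0.25), n_trials = 8L)
  shuf <- long[sample(nrow(long)), ]
  expect_equal(accuracy_table(shuf)$mean, accuracy_table(long)$mean)
})

test_that("chance-level cohorts rarely flag above-chance performance", {
  set.seed(77)
  sig <- vapply(1:20, function(r) {
    long <- do.call(rbind, lapply(1:12, function(i) {
      data.frame(participant_id = paste0("p", i), group = "g1",
                 task = "bandit", condition = NA_character_, phase = "early",
                 correct = sample(c(TRUE, FALSE), 40, replace = TRUE))
    }))
    accuracy_table(long)$p_chance < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.8)
})

test_that("the pooled t-test matches its closed form and the design df", {
  tt <- independent_ttest(c(1, 2, 3), c(2, 3, 4))
  sp <- sqrt(((2 * 1 + 2 * 1) / 4) * (1 / 3 + 1 / 3))
  expect_equal(tt$t, (2 - 3) / sp, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  same <- independent_ttest(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(3)
  a <- rnorm(52, 0.39, 0.05)
  b <- rnorm(52, 0.34, 0.06)
  expect_equal(independent_ttest(a, b)$df, 102)
  # antisymmetry
  ab <- independent_ttest(a, b)
  ba <- independent_ttest(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_error(independent_ttest(rep(1, 5), rep(1, 5)), "pooled variance")
  expect_error(independent_ttest(1, c(1, 2)), "at least 2")
})

test_that("the outlier rule flags only points beyond median +/- 1.5 IQR", {
  expect_equal(outlier_flag(c(0.3, 0.31, 0.32, 0.33)), rep(FALSE, 4))
  expect_equal(outlier_flag(c(0.3, 0.31, 0.32, 0.9)),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(outlier_flag(rep(0.4, 6)), rep(FALSE, 6))
  expect_error(outlier_flag(c(1, 2, 3)), "at least 4")
})

test_that("the long trial table restores conditions after a CSV round trip", {
  spec <- cohort_spec(n_per_group = 2L, tasks = c("bandit", "single_cue",
                                                  "multi_cue"), seed = 42)
  cohort <- simulate_cohort(spec)
  long <- trials_long(cohort)
  expect_setequal(unique(long$condition[long$task == "single_cue"]),
                  c("deterministic", "probabilistic"))
  expect_setequal(unique(long$condition[long$task == "multi_cue"]),
                  c("ambiguous", "unambiguous"))
  dir <- tempfile()
  dir.create(dir)
  write_cohort_csv(cohort, dir)
  trials <- file.path(dir, "trials.csv")
  sessions <- rwlearn:::read_trials_csv(trials)
  long2 <- trials_long(sessions, cohort$roster)
  key <- function(d) d[order(d$participant_id, d$task, d$trial_index),
                       c("participant_id", "task", "condition", "correct")]
  expect_equal(key(long2), key(long), ignore_attr = TRUE)
})
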