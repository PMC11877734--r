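test_that("multi-cue sessions match the printed design and are seed-reproducible", {
  s <- generate_multicue_session(seed = 7)
  expect_s3_class(s, "rl_session")
  expect_equal(sum(!s$is_catch), 128L)
  expect_equal(sum(s$is_catch), 8L)
  # blocked by set: every block of 16 experimental trials shows all stimuli
  exp_rows <- s[!s$is_catch, ]
  for (b in unique(exp_rows$block)) {
    expect_setequal(exp_rows$stimulus_id[exp_rows$block == b], 1:16)
  }
  expect_identical(as.data.frame(generate_multicue_session(seed = 7)),
                   as.data.frame(s))
  expect_false(identical(as.data.frame(generate_multicue_session(seed = 8)),
                         as.data.frame(s)))
})

test_that("a stimulus with p_high forced to 1 is always rated high", {
  stub <- build_multicue_stimuli()
  stub$p_high <- 1
  s <- generate_multicue_session(seed = 3, stimuli = stub)
  expect_true(all(s$outcome[!s$is_catch] == "high"))
})

test_that("multi-cue outcomes follow the stated random-number rule", {
  # empirical high-rating frequency for one ambiguous stimulus over many sets
  s <- generate_multicue_session(seed = 41, n_repeats = 200L, n_catch = 0L)
  rows <- s[s$stimulus_id == 5 & !s$is_catch, ]
  p <- mean(rows$outcome == "high")
  se <- sqrt(0.4 * 0.6 / nrow(rows))
  expect_lt(abs(p - 0.400), 3 * se)
})

test_that("single-cue sessions have 100 trials, 50 per period", {
  for (cond in c("deterministic", "probabilistic")) {
    s <- generate_singlecue_session(cond, seed = 5)
    expect_equal(sum(!s$is_catch), 100L)
    expect_equal(sum(s$is_catch), 8L)
    expect_equal(unname(table(s$outcome[!s$is_catch])), c(50L, 50L),
                 ignore_attr = TRUE)
  }
  expect_error(generate_singlecue_session("nope", seed = 1))
})

singlecue_congruent_count <- function(s) {
  d <- session_design(s)
  rows <- s[!s$is_catch, ]
  bits <- do.call(rbind, strsplit(rows$cue_levels, "|", fixed = TRUE))
  lvl <- bits[, d$target_slot]
  sum(unlist(d$level_period[lvl]) == rows$outcome)
}

test_that("single-cue predictive strength is exact in both conditions", {
  for (seed in c(1, 23, 99)) {
    det <- generate_singlecue_session("deterministic", seed = seed)
    expect_equal(singlecue_congruent_count(det), 100L)
    prob <- generate_singlecue_session("probabilistic", seed = seed)
    expect_equal(singlecue_congruent_count(prob), 75L)
  }
})

test_that("bandit sessions have 20 experimental + 2 catch trials, one reward per trial", {
  s <- generate_bandit_session(seed = 2)
  expect_equal(sum(!s$is_catch), 20L)
  expect_equal(sum(s$is_catch), 2L)
  expect_true(all(s$outcome[!s$is_catch] %in% c("A", "B")))
  d <- session_design(s)
  expect_true(d$better_option %in% c("A", "B"))
  # degenerate contingency: better option rewarded on every trial
  s1 <- generate_bandit_session(seed = 9, p_contingency = 1)
  expect_true(all(s1$outcome[!s1$is_catch] ==
                    session_design(s1)$better_option))
})

test_that("phase halves experimental trials and ignores catch trials", {
  s <- generate_multicue_session(seed = 13)
  exp_rows <- s[!s$is_catch, ]
  expect_equal(sum(exp_rows$phase == "early"), 64L)
  expect_equal(sum(exp_rows$phase == "late"), 64L)
  expect_true(all(which(exp_rows$phase == "early") <= 64))
  expect_true(all(is.na(s$phase[s$is_catch])))
  sc <- generate_singlecue_session("deterministic", seed = 13)
  expect_equal(sum(sc$phase == "early", na.rm = TRUE), 50L)
})

test_that("session CSV round trip preserves records and is byte-stable", {
  s <- played_bandit(seed = 31)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_session_csv(s, f1)
  write_session_csv(s, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_session_csv(f1)
  expect_equal(as.data.frame(back), as.data.frame(s))
  expect_equal(session_design(back)$better_option,
               session_design(s)$better_option)
  expect_true(file.exists(sub("\\.csv$", ".meta.json", f1)))
})
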