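test_that("the default cohort has 52 participants per group, all with bandit sessions", {
  spec <- cohort_spec(seed = 1)
  expect_equal(spec$n_per_group, 52L)
  expect_equal(spec$alpha_mean, c(0.39, 0.34))
  expect_equal(spec$alpha_sd, c(0.05, 0.06))
  cohort <- simulate_cohort(spec)
  expect_equal(nrow(cohort$roster), 104L)
  expect_equal(unname(table(cohort$roster$group)), c(52L, 52L),
               ignore_attr = TRUE)
  bandit <- cohort_sessions(cohort, "bandit")
  expect_length(bandit, 104L)
  expect_true(all(vapply(bandit, function(s) sum(!s$is_catch) == 20L,
                         logical(1))))
  expect_error(cohort_spec(n_per_group = 5), "seed")
})

test_that("cohort generation is deterministic and respects degenerate spreads", {
  s1 <- simulate_cohort(cohort_spec(n_per_group = 3, seed = 9))
  s2 <- simulate_cohort(cohort_spec(n_per_group = 3, seed = 9))
  expect_identical(s1$roster, s2$roster)
  expect_identical(lapply(s1$sessions, as.data.frame),
                   lapply(s2$sessions, as.data.frame))
  flat <- simulate_cohort(cohort_spec(n_per_group = 4, alpha_sd = c(0, 0.06),
                                      seed = 2))
  g1 <- flat$roster$alpha[flat$roster$group == "autistic"]
  expect_equal(g1, rep(0.39, 4))
})

test_that("drawn learning rates match the group distribution", {
  draws <- unlist(lapply(1:10, function(i) {
    co <- simulate_cohort(cohort_spec(n_per_group = 52, seed = 100 + i))
    co$roster$alpha[co$roster$group == "autistic"]
  }))
  se <- 0.05 / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 0.39), 3 * se)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("an indifferent agent chooses both options equally often", {
  des <- generate_bandit_session(seed = 5, n_trials = 10000L, n_catch = 0L)
  par <- agent_params("simple", alpha = 0.5, beta = 0)
  played <- simulate_agent(par, des, seed = 6)
  p <- mean(played$response == "A")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a greedy agent locks onto the better option once rewarded", {
  sticks <- vapply(1:10, function(i) {
    des <- generate_bandit_session(seed = 700 + i, p_contingency = 1,
                                   n_trials = 40L, n_catch = 0L)
    par <- agent_params("counterfactual", alpha = 0.5, beta = 10)
    played <- simulate_agent(par, des, seed = 800 + i)
    better <- session_design(des)$better_option
    first_informative <- 1L  # every trial is informative at contingency 1
    mean(played$response[-first_informative] == better)
  }, numeric(1))
  expect_true(all(sticks >= 0.95))
})

test_that("response noise is injected as specified", {
  des <- generate_bandit_session(seed = 3)
  par <- agent_params("simple", alpha = 0.3, beta = 2)
  all_to <- simulate_agent(par, des, seed = 4, timeout_prob = 1)
  expect_true(all(all_to$response == "timeout"))
  wrong_catch <- simulate_agent(par, des, seed = 4, catch_error_prob = 1)
  cc <- wrong_catch[wrong_catch$is_catch, ]
  expect_true(all(cc$response != cc$outcome))
  # determinism of the response stream
  a <- simulate_agent(par, des, seed = 11, timeout_prob = 0.1)
  b <- simulate_agent(par, des, seed = 11, timeout_prob = 0.1)
  expect_identical(a$response, b$response)
})

test_that("agents and tasks must match", {
  par <- agent_params("simple", alpha = 0.3, beta = 2)
  mc <- generate_multicue_session(seed = 1)
  expect_error(simulate_agent(par, mc, seed = 1), "cueweight")
  des <- generate_bandit_session(seed = 1)
  expect_error(simulate_agent(cueweight_params(), des, seed = 1),
               "agent_params")
})

test_that("the cue-weight responder learns the multi-cue structure above chance", {
  acc <- vapply(1:5, function(i) {
    des <- generate_multicue_session(seed = 900 + i)
    played <- simulate_agent(cueweight_params(), des, seed = 950 + i)
    mean(played$correct[!played$is_catch])
  }, numeric(1))
  expect_gt(mean(acc), 0.55)
})

test_that("a zero-replicate recovery request yields an empty report", {
  spec <- cohort_spec(n_per_group = 3, seed = 1)
  rep <- recovery_experiment(spec, n_replicates = 0)
  expect_s3_class(rep, "recovery_report")
  expect_length(rep$replicates, 0)
  expect_equal(nrow(rep$summary), 0L)
})

test_that("recovery correlation rises with trials per session", {
  corr_at <- function(n_trials, seed0 = 1000) {
    set.seed(seed0)
    alphas <- pmin(pmax(rnorm(20, 0.39, 0.08), 0.05), 0.95)
    est <- vapply(seq_along(alphas), function(i) {
      des <- generate_bandit_session(seed0 + i, n_trials = n_trials)
      pl <- simulate_agent(agent_params("counterfactual", alpha = alphas[i],
                                        beta = 3),
                           des, seed = seed0 + 500 + i)
      fit_rw_mle(pl, "counterfactual", n_restarts = 2,
                 seed = i)$estimate[["alpha"]]
    }, numeric(1))
    cor(alphas, est)
  }
  cors <- vapply(c(20, 100, 400), corr_at, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("identical group distributions reject at about the nominal rate", {
  spec <- cohort_spec(n_per_group = 10, alpha_mean = c(0.36, 0.36),
                      alpha_sd = c(0.06, 0.06), timeout_prob = 0,
                      catch_error_prob = 0, n_trials = 20, seed = 314)
  rep <- recovery_experiment(spec, models = "counterfactual",
                             n_replicates = 40, method = "mle")
  expect_lte(rep$summary$ttest_rejection_rate, 0.15)
  expect_equal(rep$summary$n_failed, 0L)
})
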