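test_that("the simple delta rule updates only with the scaled prediction error", {
  u <- update_simple(0, 1, 0.5)
  expect_equal(u$delta, 1)
  expect_equal(u$value, 0.5)
  # learning-rate limits
  expect_equal(update_simple(0.3, 1, 1e-9)$value, 0.3, tolerance = 1e-8)
  expect_equal(update_simple(0.3, 1, 1 - 1e-9)$value, 1, tolerance = 1e-8)
  expect_error(update_simple(0, 1, 0), "alpha")
  expect_error(update_simple(0, 1, 1), "alpha")
})

test_that("the dual-rate rule branches on the prediction error sign, ties to alpha_pos", {
  up <- update_posneg(0.5, 1, 0.2, 0.8)
  expect_equal(up$delta, 0.5)
  expect_equal(up$value, 0.6)
  dn <- update_posneg(0.5, -1, 0.2, 0.8)
  expect_equal(dn$delta, -1.5)
  expect_equal(dn$value, -0.7)
  # zero prediction error: no movement whatever the rates
  z <- update_posneg(1, 1, 0.2, 0.8)
  expect_equal(z$delta, 0)
  expect_equal(z$value, 1)
})

test_that("counterfactual updating moves both options, preserving anti-symmetry", {
  u <- update_counterfactual(0, 0, 1, 0.5)
  expect_equal(u$v_chosen, 0.5)
  expect_equal(u$v_unchosen, -0.5)
  expect_equal(update_counterfactual(0, 0, 0, 0.5)$v_chosen, 0)
  # algebraic identity: v_nc = -v_c is invariant under the update
  set.seed(11)
  for (i in 1:200) {
    vc <- runif(1, -1, 1)
    a <- runif(1, 0.05, 0.95)
    r <- sample(c(-1, 1), 1)
    u <- update_counterfactual(vc, -vc, r, a)
    expect_equal(u$v_unchosen, -u$v_chosen, tolerance = 1e-12)
  }
})

test_that("softmax choice rule behaves at its landmarks", {
  expect_equal(choice_prob(0.3, 0.3, 5), 0.5)
  expect_equal(choice_prob(0.9, -0.9, 0), 0.5)
  expect_gte(choice_prob(1, -1, 10), 0.999)
  p <- choice_prob(0.2, -0.4, 2.5)
  expect_equal(p + choice_prob(-0.4, 0.2, 2.5), 1)
  expect_error(choice_prob(0, 0, -1), "beta")
})

test_that("values stay in [-1, 1] for any +/-1 reward sequence (all models)", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 50
    rewards <- sample(c(-1, 1), n, replace = TRUE)
    chosen <- sample(1:2, n, replace = TRUE)
    a <- runif(1, 0.05, 0.95)
    ap <- runif(1, 0.05, 0.95)
    an <- runif(1, 0.05, 0.95)
    v_s <- c(0, 0)
    v_p <- c(0, 0)
    v_c <- c(0, 0)
    for (t in 1:n) {
      k <- chosen[t]
      j <- 3 - k
      v_s[k] <- update_simple(v_s[k], rewards[t], a)$value
      v_p[k] <- update_posneg(v_p[k], rewards[t], ap, an)$value
      u <- update_counterfactual(v_c[k], v_c[j], rewards[t], a)
      v_c[k] <- u$v_chosen
      v_c[j] <- u$v_unchosen
      expect_true(all(abs(c(v_s, v_p, v_c)) <= 1 + 1e-12))
    }
  }
})

test_that("posneg with equal rates reproduces the simple model exactly", {
  set.seed(5)
  v1 <- 0
  v2 <- 0
  for (t in 1:100) {
    r <- sample(c(-1, 1), 1)
    a <- 0.37
    v1 <- update_simple(v1, r, a)$value
    v2 <- update_posneg(v2, r, a, a)$value
    expect_identical(v1, v2)
  }
  s <- played_bandit(seed = 77, n_trials = 50)
  ll_simple <- session_loglik(agent_params("simple", alpha = 0.37, beta = 2.2), s)
  ll_posneg <- session_loglik(agent_params("posneg", alpha_pos = 0.37,
                                           alpha_neg = 0.37, beta = 2.2), s)
  expect_equal(ll_posneg$pointwise, ll_simple$pointwise, tolerance = 1e-12)
})

test_that("session log-likelihood handles degenerate cases", {
  s <- played_bandit(seed = 15)
  ll <- session_loglik(agent_params("simple", alpha = 0.5, beta = 0), s)
  expect_equal(ll$total, 20 * log(0.5))
  expect_equal(ll$n, 20L)
  # all timeouts: no data, zero likelihood contribution
  s2 <- s
  s2$response <- "timeout"
  ll2 <- session_loglik(agent_params("simple", alpha = 0.5, beta = 2), s2)
  expect_equal(ll2$total, 0)
  expect_length(ll2$pointwise, 0)
  # non-bandit sessions are refused
  mc <- generate_multicue_session(seed = 1)
  expect_error(session_loglik(agent_params("simple", alpha = 0.5, beta = 1), mc),
               "bandit")
})

test_that("session log-likelihood matches an independent oracle to 1e-10", {
  set.seed(99)
  for (model in c("simple", "posneg", "counterfactual")) {
    for (rep in 1:5) {
      s <- played_bandit(seed = 100 * rep + match(model, c("simple", "posneg",
                                                           "counterfactual")),
                         alpha = runif(1, 0.1, 0.9), beta = runif(1, 0.5, 6),
                         model = model, timeout_prob = 0.1)
      a <- runif(1, 0.05, 0.95)
      ap <- runif(1, 0.05, 0.95)
      an <- runif(1, 0.05, 0.95)
      b <- runif(1, 0, 8)
      par <- if (model == "posneg") {
        agent_params("posneg", alpha_pos = ap, alpha_neg = an, beta = b)
      } else {
        agent_params(model, alpha = a, beta = b)
      }
      got <- session_loglik(par, s)
      want <- oracle_bandit_loglik(model, a, b, s, alpha_pos = ap, alpha_neg = an)
      expect_equal(got$total, want$total, tolerance = 1e-10)
      expect_equal(got$pointwise, want$pointwise, tolerance = 1e-10)
    }
  }
})

test_that("log-likelihood is invariant to consistent option relabelling", {
  s <- played_bandit(seed = 55)
  swap <- function(x) chartr("AB", "BA", x)
  s2 <- s
  s2$response <- ifelse(s$response == "timeout", "timeout", swap(s$response))
  s2$outcome <- swap(s$outcome)
  attr(s2, "design")$options <- c("A", "B")
  attr(s2, "design")$better_option <- swap(session_design(s)$better_option)
  par <- agent_params("counterfactual", alpha = 0.33, beta = 2.8)
  expect_equal(session_loglik(par, s2)$total, session_loglik(par, s)$total,
               tolerance = 1e-12)
})
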