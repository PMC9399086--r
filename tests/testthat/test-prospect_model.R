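# valuation equations, softmax choice rule, social composition

test_that("gamble utility matches hand-computed values", {
  expect_equal(gamble_utility(10, -5, rho = 1, lam = 1), 2.5)
  expect_equal(gamble_utility(10, -5, rho = 1, lam = 2), 0)
  # 0.5 * 12^0.9 - 0.5 * 1.5 * 6^0.9
  expect_equal(gamble_utility(12, -6, rho = 0.9, lam = 1.5),
               0.5 * 12^0.9 - 0.75 * 6^0.9, tolerance = 1e-12)
  # gain-only: zero branch contributes exactly 0
  expect_equal(gamble_utility(8, 0, rho = 0.7, lam = 3), 0.5 * 8^0.7)
  expect_error(gamble_utility(10, -5, rho = 0, lam = 1), "positive")
  expect_error(gamble_utility(10, -5, rho = 1, lam = -1), "positive")
  expect_error(gamble_utility(10, 5, rho = 1, lam = 1), "loss")
})

test_that("at rho = lam = 1 gamble utility equals expected value exactly", {
  set.seed(41)
  gain <- round(runif(200, 2, 12), 2)
  loss <- -round(runif(200, 0.5, 24), 2)
  expect_identical(gamble_utility(gain, loss, 1, 1), 0.5 * gain + 0.5 * loss)
})

test_that("guaranteed utility is amount^rho with 0 mapped to 0", {
  expect_equal(guaranteed_utility(0, 0.8), 0)
  expect_equal(guaranteed_utility(5, 1), 5)
  expect_equal(guaranteed_utility(5, 0.8), 5^0.8)
  expect_error(guaranteed_utility(-1, 1), ">= 0")
})

test_that("softmax probability is symmetric, bounded, and monotone", {
  expect_equal(choice_probability(2.25, 1, mu = 1), plogis(1.25))
  expect_equal(choice_probability(3, 3, mu = 10), 0.5)
  expect_equal(choice_probability(7, -2, mu = 0), 0.5)
  expect_error(choice_probability(1, 0, mu = -1), ">= 0")
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(1, 0, 5); b <- rnorm(1, 0, 5); m <- rexp(1, 1 / 10)
    expect_equal(choice_probability(a, b, m) + choice_probability(b, a, m), 1)
  }
  # strictly increasing in u_gamble; deterministic limit as mu -> Inf
  u <- seq(-2, 2, 0.25)
  expect_true(all(diff(choice_probability(u, 0, 3)) > 0))
  expect_equal(choice_probability(1.5, 1, mu = 1e6), 1)
  expect_equal(choice_probability(1, 1.5, mu = 1e6), 0)
  # numerically stable: extreme arguments stay inside [0, 1] and finite on
  # the log scale via trial_loglik
  expect_true(is.finite(trial_loglik(1, 10, -1, 0, 1, 1, mu = 500)))
})

test_that("social composition is exponential-additive with exact self identity", {
  base <- parameter_set(rho = 1.07, lam = 1.78, mu = 18.0)
  eff <- social_effects(d_rho_other = -0.11, d_lam_other = 0.06,
                        d_mu_other = 0.45)
  p <- compose_trial_parameters(base, eff, other = 1, sharing = 0,
                                identity = 0)
  # the published implied 'other' means (inputs printed to 2 decimals)
  expect_equal(p$rho, 0.96, tolerance = 0.02 / 0.96)
  expect_equal(p$lam, 1.90, tolerance = 0.02 / 1.90)
  expect_equal(p$mu, 28.3, tolerance = 0.2 / 28.3)
  # self trials return the baseline exactly
  p0 <- compose_trial_parameters(base, eff, 0, 0, 0)
  expect_identical(c(p0$rho, p0$lam, p0$mu), c(base$rho, base$lam, base$mu))
  # zero-delta composition is the identity for any indicator pattern
  set.seed(11)
  for (i in 1:25) {
    ind <- encode_social_indicators(sample(c("self", "other", "shared"), 1),
                                    sample(c("friend", "stranger"), 1))
    pz <- compose_trial_parameters(base, social_effects(),
                                   ind$other, ind$sharing, ind$identity)
    expect_equal(c(pz$rho, pz$lam, pz$mu), c(base$rho, base$lam, base$mu))
  }
})

test_that("parameter_set enforces one scale and positivity", {
  expect_error(parameter_set(rho = 1, lam = 1, mu = 1, log_rho = 0), "both")
  expect_error(parameter_set(rho = -1, lam = 1, mu = 1), "> 0")
  ps <- parameter_set(log_rho = 0.2, log_lam = -0.1, log_mu = 3)
  expect_equal(ps$rho, exp(0.2))
  expect_equal(ps$mu, exp(3))
})

test_that("trial log-likelihood matches the softmax and sums over trials", {
  expect_equal(trial_loglik(1, 10, -10, 0, 1, 1, mu = 5), log(0.5))
  expect_equal(trial_loglik(0, 10, -10, 0, 1, 1, mu = 5), log(0.5))
  # gamble accepted at p = logistic(1.25)
  expect_equal(trial_loglik(1, 4.5, 0, 2.25 - 1.25, 1, 1, mu = 1),
               log(plogis(1.25)), tolerance = 1e-12)
  expect_error(trial_loglik(NA, 10, -5, 0, 1, 1, 1), "choice")
})

test_that("vectorized dataset log-likelihood equals a scalar loop oracle", {
  set.seed(99)
  n <- 1000
  mixed <- runif(n) < 0.6
  trials <- data.frame(
    participant_id = sample(sprintf("p%02d", 1:10), n, replace = TRUE),
    gain = round(runif(n, 2, 12), 2),
    loss = ifelse(mixed, -round(runif(n, 1, 20), 2), 0),
    guaranteed = ifelse(mixed, 0, round(runif(n, 1, 2.9), 2)),
    other = 0L, sharing = 0L, identity = 0L,
    choice = rbinom(n, 1, 0.5))
  ind <- encode_social_indicators(
    sample(c("self", "other", "shared"), n, replace = TRUE),
    sample(c("friend", "stranger"), n, replace = TRUE))
  trials[c("other", "sharing", "identity")] <- ind
  ids <- sort(unique(trials$participant_id))
  params <- parameter_set(log_rho = rnorm(10, 0, 0.2),
                          log_lam = rnorm(10, 0.5, 0.3),
                          log_mu = rnorm(10, 2, 0.4))
  eff <- social_effects(d_rho_other = -0.1, d_rho_sharing = 0.02,
                        d_rho_identity = -0.05, d_lam_other = 0.06,
                        d_mu_other = 0.4, d_mu_identity = -0.2)
  vec <- dataset_loglik(trials, params, eff)
  # scalar per-trial loop, composed by hand
  loop <- vapply(seq_len(n), function(t) {
    s <- match(trials$participant_id[t], ids)
    lr <- params$log_rho[s] + trials$other[t] * eff[["d_rho_other"]] +
      trials$sharing[t] * eff[["d_rho_sharing"]] +
      trials$identity[t] * eff[["d_rho_identity"]]
    ll <- params$log_lam[s] + trials$other[t] * eff[["d_lam_other"]]
    lm <- params$log_mu[s] + trials$other[t] * eff[["d_mu_other"]] +
      trials$identity[t] * eff[["d_mu_identity"]]
    u_g <- 0.5 * trials$gain[t]^exp(lr) -
      (if (trials$loss[t] < 0) 0.5 * exp(ll) * (-trials$loss[t])^exp(lr) else 0)
    u_s <- if (trials$guaranteed[t] > 0) trials$guaranteed[t]^exp(lr) else 0
    # stable log logistic: log p = -log(1 + exp(-x)) without over/underflow
    x <- exp(lm) * (u_g - u_s)
    if (trials$choice[t] == 0) x <- -x
    if (x > 0) -log1p(exp(-x)) else x - log1p(exp(x))
  }, numeric(1))
  expect_equal(vec$pointwise, loop, tolerance = 1e-10)
  expect_equal(vec$total, sum(loop), tolerance = 1e-10)
})
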