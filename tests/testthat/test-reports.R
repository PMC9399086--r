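# implied condition means, recovery reports, trait correlations

test_that("implied condition means reproduce the published table cells", {
  base <- parameter_set(rho = 1.07, lam = 1.78, mu = 18.0)
  # all deltas zero: every cell equals the baselines
  cm0 <- implied_condition_means(base, social_effects())
  expect_true(all(abs(cm0$rho - 1.07) < 1e-12))
  expect_true(all(abs(cm0$mu - 18.0) < 1e-12))
  # published point estimates for all nine deltas (unprinted ones zero)
  eff <- social_effects(d_rho_other = -0.11, d_rho_sharing = 0.016,
                        d_rho_identity = -0.05,
                        d_lam_other = 0.06, d_lam_identity = 0.02,
                        d_mu_other = 0.45, d_mu_identity = -0.18)
  cm <- implied_condition_means(base, eff)
  expect_equal(cm$condition, c("self", "other", "other", "shared", "shared"))
  self_row <- cm[cm$condition == "self", ]
  expect_equal(self_row$rho, 1.07)
  # other-only x stranger vs friend rho cells: 0.92 / 1.03 within the
  # rounding of two-decimal printed inputs
  o_str <- cm[cm$condition == "other" & cm$identity_group == "stranger", ]
  o_fri <- cm[cm$condition == "other" & cm$identity_group == "friend", ]
  expect_equal(o_str$rho, 0.92, tolerance = 0.01 / 0.92)
  expect_equal(o_fri$rho, 1.03, tolerance = 0.01 / 1.03)
})

test_that("draw-wise composition exposes the Jensen gap", {
  set.seed(3)
  n <- 4000
  draws <- cbind(mu_log_rho = rnorm(n, log(1.07), 0.02),
                 mu_log_lam = rnorm(n, log(1.78), 0.02),
                 mu_log_mu = rnorm(n, log(18), 0.5),
                 d_mu_other = rnorm(n, 0.45, 0.02))
  cm <- implied_condition_means(draws = draws)
  point <- implied_condition_means(
    parameter_set(rho = 1.07, lam = 1.78, mu = 18.0),
    social_effects(d_mu_other = 0.45))
  o <- cm$condition == "other" & cm$identity_group == "stranger"
  # wide draw spread on log mu: draw-wise mean exceeds exp-of-mean by
  # roughly exp(sd^2/2)
  expect_gt(cm$mu[o] / point$mu[o][1], 1.08)
  # narrow spread on log rho: the two compositions agree closely
  expect_equal(cm$rho[o], point$rho[point$condition == "other" &
                                      point$identity_group == "stranger"],
               tolerance = 0.005)
  expect_true(all(cm$rho_lower <= cm$rho & cm$rho <= cm$rho_upper))
})

test_that("recovery report scores collapsed and mis-scaled posteriors", {
  cfg <- tiny_config(n_stranger = 2, n_friend = 2, seed = 5)
  ag <- draw_population(cfg)
  truth <- c(mu_log_rho = unname(cfg$group_log_means[1]),
             mu_log_lam = unname(cfg$group_log_means[2]),
             mu_log_mu = unname(cfg$group_log_means[3]),
             sigma_log_rho = 0.3, sigma_log_lam = 0.5, sigma_log_mu = 0.6,
             d_rho_other = -0.11, d_rho_sharing = 0.016,
             d_rho_identity = -0.05, d_lam_other = 0.06,
             d_lam_sharing = 0, d_lam_identity = 0.02,
             d_mu_other = 0.45, d_mu_sharing = 0, d_mu_identity = -0.18)
  # posterior collapsed exactly at truth: zero bias, full coverage
  fit <- constant_fit(truth, ag$participant_id)
  rec <- recovery_report(ag, fit, cfg)
  expect_equal(rec$coverage, 1)
  expect_true(all(rec$table$bias == 0))
  # truth deliberately outside every HDI: zero coverage
  fit_off <- constant_fit(truth + 5, ag$participant_id)
  rec_off <- recovery_report(ag, fit_off, cfg)
  expect_equal(rec_off$coverage, 0)
  expect_error(recovery_report(ag[-1, ], fit, cfg), "participants")
})

test_that("trait correlations handle exact and degenerate cases", {
  eff <- data.frame(participant_id = sprintf("p%02d", 1:20),
                    d_lam_other = seq(-1, 1, length.out = 20))
  tr <- data.frame(participant_id = eff$participant_id,
                   t_same = eff$d_lam_other,
                   t_orth = 0)
  # orthogonalize t_orth against the effect exactly
  z <- rnorm(20)
  tr$t_orth <- z - eff$d_lam_other *
    sum(z * eff$d_lam_other) / sum(eff$d_lam_other^2)
  out <- trait_correlations(eff, tr)
  expect_equal(out$r[out$trait == "t_same"], 1)
  expect_lt(abs(out$r[out$trait == "t_orth"]), 1e-10)
  expect_equal(out$n, c(20, 20))
  expect_true(all(abs(out$r) <= 1))
  # zero-variance trait is an error
  tr$t_orth <- 1
  expect_error(trait_correlations(eff, tr), "zero-variance")
  # missing traits dropped pairwise
  tr$t_orth <- c(NA, NA, z[-(1:2)])
  out2 <- trait_correlations(eff, tr)
  expect_equal(out2$n[out2$trait == "t_orth"], 18)
})

test_that("permuted trait labels are null-calibrated", {
  # under label permutation |r| should fall below the alpha = 0.01
  # critical value in ~99% of draws; assert >= 98% (3 binomial SDs slack)
  set.seed(17)
  n <- 57
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n, 0, sqrt(1 - 0.09))
  r_crit <- sqrt(qf(0.99, 1, n - 2) / (qf(0.99, 1, n - 2) + n - 2))
  r_perm <- replicate(1000, abs(cor(x, sample(y))))
  expect_gte(mean(r_perm < r_crit), 0.98)
})

test_that("cohorts generated at a target correlation recover it", {
  cfg <- population_config(seed = 7)   # 57 agents, target r = 0.30
  ag <- draw_population(cfg)
  out <- trait_correlations(
    ag[c("participant_id", "d_lam_other")],
    ag[c("participant_id", "dospert_social")])
  ci <- tanh(atanh(0.30) + c(-1, 1) * qnorm(0.975) / sqrt(nrow(ag) - 3))
  expect_gt(out$r, ci[1])
  expect_lt(out$r, ci[2])
})

test_that("friend-vs-stranger comparison runs on subject effects", {
  cfg <- tiny_config(n_stranger = 10, n_friend = 10, seed = 23)
  ag <- draw_population(cfg)
  cmp <- group_effect_comparison(
    ag[c("participant_id", "d_rho_other", "d_lam_other", "d_mu_other")],
    ag[c("participant_id", "group")])
  expect_equal(nrow(cmp), 3)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  # generating process is group-symmetric, so huge t values would be a bug
  expect_true(all(abs(cmp$t) < 6))
})
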