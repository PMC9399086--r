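# HDI, WAIC, convergence diagnostics, and the MCMC engine

test_that("hdi handles degenerate inputs and known distributions", {
  expect_equal(unname(hdi(rep(3.5, 10))), c(3.5, 3.5), ignore_attr = TRUE)
  x <- rnorm(50)
  expect_equal(unname(hdi(x, mass = 1)), range(x), ignore_attr = TRUE)
  expect_error(hdi(numeric(0)), "samples")
  expect_error(hdi(1:5, mass = 0), "mass")
  # closed-form oracles: N(0,1) central interval, Exp(1) upper tail
  set.seed(31)
  h <- hdi(rnorm(1e5))
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05 / 1.96,
               ignore_attr = TRUE)
  h2 <- hdi(rexp(1e5), mass = 0.95)
  expect_lt(h2[["lower"]], 0.05)
  expect_equal(h2[["upper"]], -log(0.05), tolerance = 0.1)
})

test_that("waic identities hold", {
  set.seed(12)
  ll <- matrix(rnorm(40 * 25, -1, 0.3), 40, 25)
  w <- waic(ll)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic))
  expect_gte(w$p_waic, 0)
  # identical models give identical WAIC; permuting trials leaves it
  # unchanged
  expect_equal(waic(ll)$waic, waic(ll)$waic)
  perm <- sample(ncol(ll))
  expect_equal(waic(ll[, perm])$waic, w$waic)
  expect_equal(waic(ll[, perm])$se_waic, w$se_waic)
  # constant log-likelihood across draws: p_waic = 0, waic = -2 sum(ll)
  llc <- matrix(rep(rnorm(25, -1, 0.5), each = 40), 40, 25)
  wc <- waic(llc)
  expect_equal(wc$p_waic, 0)
  expect_equal(wc$waic, -2 * sum(llc[1, ]))
  expect_error(waic(ll[1, , drop = FALSE]), "draws")
  d <- compare_waic(w, wc)
  expect_equal(d$d_waic, w$waic - wc$waic)
})

test_that("convergence diagnostics flag broken chains and bound ESS", {
  set.seed(9)
  mk_fit <- function(draws_by_chain) {
    d <- do.call(rbind, draws_by_chain)
    structure(list(model = "M0", draws = d,
                   chain = rep(seq_along(draws_by_chain),
                               vapply(draws_by_chain, nrow, 1L)),
                   participants = "p1", data = list(n_trials = 0)),
              class = "spt_fit")
  }
  iid <- lapply(1:4, function(i) {
    matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "a"))
  })
  conv <- check_convergence(mk_fit(iid))
  expect_lt(abs(conv$rhat - 1), 0.01)
  expect_false(conv$flagged)
  expect_lte(conv$ess, 2000)
  # one chain offset by a large constant must be flagged
  off <- iid
  off[[2]] <- off[[2]] + 50
  conv2 <- check_convergence(mk_fit(off))
  expect_gt(conv2$rhat, 1.05)
  expect_true(conv2$flagged)
  # single chain: warning, rhat NA
  expect_warning(conv3 <- check_convergence(mk_fit(iid[1])), "one chain")
  expect_true(is.na(conv3$rhat))
})

test_that("the sampler likelihood equals the standalone oracle", {
  sim <- tiny_cohort(n_stranger = 3, n_friend = 3, seed = 55,
                     trials_per_condition = 30L)
  tr <- sim$trials[order(sim$trials$participant_id), ]
  ids <- sort(unique(tr$participant_id))
  set.seed(14)
  for (rep in 1:5) {
    theta <- cbind(rnorm(6, 0, 0.3), rnorm(6, 0.5, 0.3), rnorm(6, 2.5, 0.5))
    delta <- rnorm(9, 0, 0.1)
    internal <- model_loglik(tr, theta, delta, "M1")
    oracle <- dataset_loglik(
      tr, parameter_set(log_rho = theta[, 1], log_lam = theta[, 2],
                        log_mu = theta[, 3]),
      structure(stats::setNames(delta, social_effect_names()),
                class = "social_effects"))$pointwise
    expect_lt(max(abs(internal - oracle)), 1e-8)
  }
  # nesting: M1 with all deltas zero defines the same likelihood as M0
  theta <- cbind(rnorm(6, 0, 0.3), rnorm(6, 0.5, 0.3), rnorm(6, 2.5, 0.5))
  expect_equal(model_loglik(tr, theta, rep(0, 9), "M1"),
               model_loglik(tr, theta, rep(0, 9), "M0"))
})

test_that("M0 recovers the group level on data without social effects", {
  cfg <- population_config(n_stranger = 6, n_friend = 6,
                           true_social_effects = social_effects(),
                           subject_effect_sd = 0, seed = 19)
  sim <- simulate_cohort(cfg, trials_per_condition = 90L)
  fit <- fit_model(sim$trials, model = "M0", chains = 2, warmup = 600,
                   draws = 300, seed = 29, keep_loglik = FALSE)
  rec <- recovery_report(sim$agents, fit, cfg)
  means <- rec$table[rec$table$parameter %in%
                       c("mu_log_rho", "mu_log_lam", "mu_log_mu"), ]
  expect_true(all(means$covered))
  # a subject with near-deterministic behavior lands above the group mean
  # in consistency
  det_id <- sim$agents$participant_id[which.max(sim$agents$log_mu)]
  expect_gt(mean(fit$draws[, paste0("log_mu[", det_id, "]")]),
            mean(fit$draws[, "mu_log_mu"]))
})

test_that("fit_model validates inputs", {
  sim <- tiny_cohort(n_stranger = 2, n_friend = 1, seed = 2)
  expect_error(fit_model(sim$trials[, -1]), "participant_id")
  bad <- sim$trials
  bad$choice[5] <- NA
  expect_error(fit_model(bad), "choice")
})

test_that("simulate-then-fit HDIs are calibrated (scaled-down study)", {
  # 20 replicates at reduced size/draws; group log-mean coverage must be
  # >= 80% (loose bound so the default suite stays fast)
  hits <- 0; total <- 0
  for (r in 1:20) {
    cfg <- population_config(n_stranger = 5, n_friend = 5,
                             true_social_effects = social_effects(),
                             subject_effect_sd = 0, seed = 1000 + r)
    sim <- simulate_cohort(cfg, trials_per_condition = 30L)
    fit <- fit_model(sim$trials, model = "M0", chains = 2, warmup = 400,
                     draws = 200, seed = 2000 + r, keep_loglik = FALSE)
    rec <- recovery_report(sim$agents, fit, cfg)
    means <- rec$table[rec$table$parameter %in%
                         c("mu_log_rho", "mu_log_lam", "mu_log_mu"), ]
    hits <- hits + sum(means$covered)
    total <- total + nrow(means)
  }
  expect_gte(hits / total, 0.80)
})

test_that("M2 fits run and recover subject-level risk/loss effects", {
  cfg <- population_config(n_stranger = 8, n_friend = 8, seed = 61)
  sim <- simulate_cohort(cfg, "model2_mixed", trials_per_condition = 90L)
  fit <- fit_model(sim$trials, model = "M2", chains = 2, warmup = 500,
                   draws = 250, seed = 62, keep_loglik = FALSE)
  expect_true(all(c("mu_d_rho_other_s", "sigma_d_rho_other_s",
                    "d_rho_sharing") %in% colnames(fit$draws)))
  expect_false(any(c("d_rho_identity", "d_rho_other") %in%
                     colnames(fit$draws)))
  se <- subject_effect_estimates(fit)
  m <- merge(se, sim$agents, by = "participant_id",
             suffixes = c("_est", "_true"))
  # rho/lambda subject effects are identified; mu's are weak (documented)
  expect_gt(cor(m$d_rho_other_est, m$d_rho_other_true), 0.3)
  expect_gt(cor(m$d_lam_other_est, m$d_lam_other_true), 0.3)
})
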