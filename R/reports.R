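#' Implied per-condition parameter means
#'
#' Reconstructs the "implied mean parameter" table: natural-scale rho,
#' lambda, mu for the self condition and for each cell of
#' {other-only, shared} x {stranger, friend}, obtained by composing the
#' baseline log-scale means with the social deltas under that cell's
#' indicator triple and exponentiating.
#'
#' When posterior `draws` are supplied (a matrix with named columns
#' containing `mu_log_rho`, `mu_log_lam`, `mu_log_mu` and the nine delta
#' columns present in the model), the composition is applied draw-wise and
#' each cell additionally carries a 95% HDI; cell means are then posterior
#' means of the composed natural-scale quantity (not the exponential of the
#' mean — see the Jensen-gap note in the methods vignette).
#'
#' @param baselines A [parameter_set()] of group-level means (used when
#'   `draws` is NULL).
#' @param effects A [social_effects()] vector of posterior-mean deltas (used
#'   when `draws` is NULL).
#' @param draws Optional posterior draws matrix (e.g. `fit$draws` from an M1
#'   [fit_model()] run).
#' @param mass HDI mass for draw-wise cells.
#' @return Data.frame with columns `condition`, `identity_group`, `other`,
#'   `sharing`, `identity`, `rho`, `lam`, `mu` (and HDI columns when draws
#'   are given).
#' @examples
#' implied_condition_means(parameter_set(rho = 1.07, lam = 1.78, mu = 18),
#'                         social_effects(d_rho_other = -0.11,
#'                                        d_lam_other = 0.06,
#'                                        d_mu_other = 0.45))
#' @export
implied_condition_means <- function(baselines = NULL, effects = NULL,
                                    draws = NULL, mass = 0.95) {
  cells <- data.frame(
    condition = c("self", "other", "other", "shared", "shared"),
    identity_group = c(NA, "stranger", "friend", "stranger", "friend"))
  ind <- rbind(data.frame(other = 0L, sharing = 0L, identity = 0L),
               encode_social_indicators(cells$condition[-1],
                                        cells$identity_group[-1]))
  out <- cbind(cells, ind)
  if (is.null(draws)) {
    stopifnot(inherits(baselines, "parameter_set"))
    p <- compose_trial_parameters(baselines, effects, out$other, out$sharing,
                                  out$identity)
    out$rho <- p$rho; out$lam <- p$lam; out$mu <- p$mu
    return(out)
  }
  base_cols <- c("mu_log_rho", "mu_log_lam", "mu_log_mu")
  if (!all(base_cols %in% colnames(draws))) {
    stop("draws must contain the group-level baseline columns", call. = FALSE)
  }
  dn <- social_effect_names()
  eff_draws <- matrix(0, nrow(draws), 9, dimnames = list(NULL, dn))
  present <- intersect(dn, colnames(draws))
  eff_draws[, present] <- draws[, present]
  for (par in c("rho", "lam", "mu")) {
    idx <- DELTA_IDX[[switch(par, rho = "rho", lam = "lam", mu = "mu")]]
    comp <- exp(draws[, paste0("mu_log_", par)] +
                  outer(eff_draws[, idx[1]], out$other) +
                  outer(eff_draws[, idx[2]], out$sharing) +
                  outer(eff_draws[, idx[3]], out$identity))
    out[[par]] <- colMeans(comp)
    h <- apply(comp, 2, hdi, mass = mass)
    out[[paste0(par, "_lower")]] <- h[1, ]
    out[[paste0(par, "_upper")]] <- h[2, ]
  }
  out
}

#' Parameter-recovery report
#'
#' Compares a fit against the ground truth of the synthetic cohort that
#' generated its data: per-parameter truth, posterior mean, bias, absolute
#' error, and whether the 95% HDI covers the truth.
#'
#' Group-level rows cover the three baselines (as group log-means) and the
#' generating fixed deltas present in the model; for M2 fits, subject-level
#' 'other' deltas are additionally scored against each agent's true deltas.
#'
#' @param agents Ground-truth agent table from [draw_population()].
#' @param fit An `spt_fit` whose data came from those agents.
#' @param config The generating [population_config()] (for group-level
#'   truth).
#' @param mass HDI mass (default 0.95).
#' @return List with `table` (per-parameter data.frame: `parameter`,
#'   `truth`, `posterior_mean`, `bias`, `abs_error`, `hdi_lower`,
#'   `hdi_upper`, `covered`) and `coverage` (aggregate coverage rate).
#' @export
recovery_report <- function(agents, fit, config, mass = 0.95) {
  stopifnot(inherits(fit, "spt_fit"), inherits(config, "population_config"))
  if (!setequal(agents$participant_id, fit$participants)) {
    stop("agents and fit cover different participants", call. = FALSE)
  }
  truth <- c(mu_log_rho = unname(config$group_log_means[1]),
             mu_log_lam = unname(config$group_log_means[2]),
             mu_log_mu = unname(config$group_log_means[3]),
             sigma_log_rho = unname(config$group_log_sds[1]),
             sigma_log_lam = unname(config$group_log_sds[2]),
             sigma_log_mu = unname(config$group_log_sds[3]))
  eff <- config$true_social_effects
  act <- intersect(social_effect_names(), colnames(fit$draws))
  truth <- c(truth, stats::setNames(as.numeric(eff)[match(act, names(eff))],
                                    act))
  # subject-level truths
  if (fit$model == "M2") {
    for (p in c("d_rho_other", "d_lam_other", "d_mu_other")) {
      cols <- paste0(p, "_s[", agents$participant_id, "]")
      keep <- cols %in% colnames(fit$draws)
      truth <- c(truth, stats::setNames(agents[[p]][keep], cols[keep]))
    }
  }
  truth <- truth[names(truth) %in% colnames(fit$draws)]
  d <- fit$draws[, names(truth), drop = FALSE]
  h <- apply(d, 2, hdi, mass = mass)
  tab <- data.frame(parameter = names(truth), truth = unname(truth),
                    posterior_mean = colMeans(d),
                    hdi_lower = h[1, ], hdi_upper = h[2, ])
  tab$bias <- tab$posterior_mean - tab$truth
  tab$abs_error <- abs(tab$bias)
  tab$covered <- tab$truth >= tab$hdi_lower & tab$truth <= tab$hdi_upper
  rownames(tab) <- NULL
  list(table = tab, coverage = mean(tab$covered))
}

#' Correlations between subject-level social effects and trait scores
#'
#' Pearson correlations (two-sided, df = n - 2) between per-subject point
#' estimates of the 'other' deltas and trait covariates, with pairwise
#' deletion of missing traits. A Benjamini-Hochberg adjusted p-value column
#' is included alongside the unadjusted values.
#'
#' @param subject_effects Data.frame with `participant_id` and one column
#'   per effect (e.g. posterior means of `d_rho_other_s`, or the true
#'   deltas of a synthetic cohort).
#' @param traits Data.frame with `participant_id` and one column per trait.
#' @param effect_cols,trait_cols Column selections; default all non-id
#'   numeric columns.
#' @return Data.frame with columns `trait`, `effect`, `r`, `p`, `p_bh`, `n`.
#' @export
trait_correlations <- function(subject_effects, traits,
                               effect_cols = NULL, trait_cols = NULL) {
  if (is.null(effect_cols)) {
    effect_cols <- setdiff(names(subject_effects)[vapply(subject_effects,
                                                         is.numeric, TRUE)],
                           "participant_id")
  }
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          "participant_id")
  }
  m <- merge(subject_effects, traits, by = "participant_id")
  out <- expand.grid(trait = trait_cols, effect = effect_cols,
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    x <- m[[out$trait[i]]]; y <- m[[out$effect[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) {
      stop("fewer than 3 complete pairs for ", out$trait[i], " vs ",
           out$effect[i], call. = FALSE)
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      stop("zero-variance vector in ", out$trait[i], " vs ", out$effect[i],
           call. = FALSE)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  res <- do.call(rbind, res)
  out$r <- res[, "r"]; out$p <- res[, "p"]; out$n <- res[, "n"]
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out[c("trait", "effect", "r", "p", "p_bh", "n")]
}

#' Subject-level 'other' effect point estimates from an M2 fit
#'
#' Posterior means (or medians) of each subject's 'other' deltas, the point
#' estimates fed into [trait_correlations()] and the friend-vs-stranger
#' comparison.
#'
#' @param fit An M2 `spt_fit`.
#' @param point `"mean"` (default) or `"median"`.
#' @return Data.frame: `participant_id`, `d_rho_other`, `d_lam_other`,
#'   `d_mu_other`.
#' @export
subject_effect_estimates <- function(fit, point = c("mean", "median")) {
  stopifnot(inherits(fit, "spt_fit"))
  if (fit$model != "M2") {
    stop("subject-level 'other' effects exist only in M2 fits", call. = FALSE)
  }
  point <- match.arg(point)
  f <- if (point == "mean") colMeans else
    function(m) apply(m, 2, stats::median)
  out <- data.frame(participant_id = fit$participants)
  for (p in c("d_rho_other", "d_lam_other", "d_mu_other")) {
    cols <- paste0(p, "_s[", fit$participants, "]")
    out[[p]] <- f(fit$draws[, cols, drop = FALSE])
  }
  out
}

#' Friend-vs-stranger comparison of subject-level 'other' effects
#'
#' Two-sample Welch t-tests of per-subject point estimates between the two
#' partner-identity groups, mirroring the between-group follow-up used with
#' mixed-effects fits.
#'
#' @param subject_effects Output of [subject_effect_estimates()] (or the
#'   true deltas of a synthetic cohort).
#' @param groups Data.frame with `participant_id` and `group`
#'   (friend/stranger).
#' @return Data.frame: `effect`, `mean_friend`, `mean_stranger`, `t`, `df`,
#'   `p`.
#' @export
group_effect_comparison <- function(subject_effects, groups) {
  m <- merge(subject_effects, groups[c("participant_id", "group")],
             by = "participant_id")
  effects <- setdiff(names(subject_effects), "participant_id")
  res <- lapply(effects, function(e) {
    tt <- stats::t.test(m[[e]][m$group == "friend"],
                        m[[e]][m$group == "stranger"])
    data.frame(effect = e,
               mean_friend = mean(m[[e]][m$group == "friend"]),
               mean_stranger = mean(m[[e]][m$group == "stranger"]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
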