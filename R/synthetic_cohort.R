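#' Configuration of the synthetic population
#'
#' Describes the generative world the hierarchical model assumes: subject
#' log-scale baselines drawn around group log-means, additive social effects
#' (fixed group values, optionally with subject-level spread on the 'other'
#' deltas), and trait covariates with specified correlations to chosen
#' subject-level deltas.
#'
#' Defaults are the published group-level estimates (baselines rho = 1.07,
#' lambda = 1.78, mu = 18.0; the reliable social deltas on the log scale),
#' so simulations exercise the realistic regime. Group log-scale SDs and the
#' subject-level 'other'-delta SD are not reported at the group level in the
#' source study; the defaults (0.3 / 0.5 / 0.6 and 0.2) are package choices,
#' documented in the methods vignette, not published values.
#'
#' @param group_log_means Named numeric length 3: group means of
#'   (log rho, log lam, log mu).
#' @param group_log_sds Positive numeric length 3: group SDs on the log
#'   scale.
#' @param true_social_effects A [social_effects()] vector of generating
#'   fixed-effect deltas.
#' @param subject_effect_sd Positive numeric (length 1 or 3): SD of
#'   subject-level 'other' deltas around the group deltas (used when
#'   simulating in `"model2_mixed"` mode).
#' @param trait_spec List of trait definitions; each a list with fields
#'   `name`, `with` (one of the nine delta names, must be an 'other' delta),
#'   `target_r` (|r| < 1), `mean`, `sd`.
#' @param n_stranger,n_friend Group sizes (defaults 29 / 28).
#' @param seed Master seed for the cohort.
#' @return A list of class `population_config`.
#' @export
population_config <- function(
    group_log_means = c(log_rho = log(1.07), log_lam = log(1.78),
                        log_mu = log(18.0)),
    group_log_sds = c(log_rho = 0.3, log_lam = 0.5, log_mu = 0.6),
    true_social_effects = social_effects(
      d_rho_other = -0.11, d_rho_sharing = 0.016, d_rho_identity = -0.05,
      d_lam_other = 0.06, d_lam_identity = 0.02,
      d_mu_other = 0.45, d_mu_identity = -0.18),
    subject_effect_sd = 0.2,
    trait_spec = list(
      list(name = "dospert_social", with = "d_lam_other", target_r = 0.30,
           mean = 25, sd = 7),
      list(name = "iri", with = "d_rho_other", target_r = -0.25,
           mean = 60, sd = 12)),
    n_stranger = 29, n_friend = 28, seed = 1L) {
  if (any(group_log_sds < 0)) {
    stop("group_log_sds must be non-negative", call. = FALSE)
  }
  if (any(subject_effect_sd < 0)) {
    stop("subject_effect_sd must be non-negative", call. = FALSE)
  }
  if (n_stranger < 0 || n_friend < 0) {
    stop("group sizes must be non-negative", call. = FALSE)
  }
  for (tr in trait_spec) {
    if (abs(tr$target_r) >= 1) {
      stop("trait target correlations must satisfy |r| < 1", call. = FALSE)
    }
    if (!tr$with %in% c("d_rho_other", "d_lam_other", "d_mu_other")) {
      stop("traits correlate with subject-level 'other' deltas only",
           call. = FALSE)
    }
  }
  structure(list(group_log_means = group_log_means,
                 group_log_sds = rep_len(group_log_sds, 3),
                 true_social_effects = true_social_effects,
                 subject_effect_sd = rep_len(subject_effect_sd, 3),
                 trait_spec = trait_spec,
                 n_stranger = n_stranger, n_friend = n_friend,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Draw a synthetic population of agents
#'
#' Samples per-subject ground truth: log-scale baselines
#' `Normal(group_log_means, group_log_sds)`, subject-level 'other' deltas
#' `Normal(group other deltas, subject_effect_sd)`, and trait scores built
#' jointly with a chosen delta so that the population correlation equals the
#' trait's `target_r` (trait = `r * z(delta) + sqrt(1 - r^2) * noise`,
#' affine-mapped to the questionnaire scale).
#'
#' @param config A [population_config()].
#' @return A data.frame of agents (one row each) with columns
#'   `participant_id`, `group`, true log-scale baselines `log_rho`,
#'   `log_lam`, `log_mu`, subject 'other' deltas `d_rho_other`,
#'   `d_lam_other`, `d_mu_other`, and one column per trait.
#' @export
draw_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_stranger + config$n_friend
  ids <- c(if (config$n_stranger > 0) sprintf("s%02d", seq_len(config$n_stranger)),
           if (config$n_friend > 0) sprintf("f%02d", seq_len(config$n_friend)))
  groups <- c(rep("stranger", config$n_stranger),
              rep("friend", config$n_friend))
  local_rng(split_seed(config$seed, "population", 0))
  m <- config$group_log_means
  s <- config$group_log_sds
  agents <- data.frame(
    participant_id = ids, group = groups,
    log_rho = stats::rnorm(n, m[1], s[1]),
    log_lam = stats::rnorm(n, m[2], s[2]),
    log_mu = stats::rnorm(n, m[3], s[3]))
  eff <- config$true_social_effects
  sd_d <- config$subject_effect_sd
  agents$d_rho_other <- stats::rnorm(n, eff[["d_rho_other"]], sd_d[1])
  agents$d_lam_other <- stats::rnorm(n, eff[["d_lam_other"]], sd_d[2])
  agents$d_mu_other <- stats::rnorm(n, eff[["d_mu_other"]], sd_d[3])
  for (tr in config$trait_spec) {
    d <- agents[[tr$with]]
    z <- if (stats::sd(d) > 0) (d - mean(d)) / stats::sd(d) else numeric(n)
    r <- tr$target_r
    zt <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    agents[[tr$name]] <- tr$mean + tr$sd * zt
  }
  agents
}

#' Simulate one agent's choices over a session
#'
#' Composes per-trial natural-scale parameters from the agent's baselines
#' and the social effects, evaluates the softmax gamble probability, and
#' draws one Bernoulli accept/reject per trial. In `"model1_fixed"` mode the
#' generating deltas are the group-level fixed effects; in `"model2_mixed"`
#' mode the 'other' deltas are the agent's subject-level values (sharing
#' deltas remain the fixed group values; identity deltas are not applied,
#' mirroring the mixed-effects model variant, which has no identity factor).
#'
#' @param session A session table from [build_session()] (or the rows of one
#'   participant from [build_cohort()]).
#' @param agent One row of [draw_population()] output.
#' @param effects A [social_effects()] vector of group-level deltas.
#' @param effects_mode `"model1_fixed"` or `"model2_mixed"`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return The session table with extra columns `true_p` (the generating
#'   gamble-choice probability) and `choice` (1 = gamble accepted).
#' @export
simulate_choices <- function(session, agent, effects,
                             effects_mode = c("model1_fixed", "model2_mixed"),
                             seed = 1L) {
  effects_mode <- match.arg(effects_mode)
  if (!is.null(agent$group) && !is.null(session$group) &&
      !all(session$group == agent$group)) {
    stop("session and agent belong to different groups", call. = FALSE)
  }
  eff <- as.numeric(effects)
  names(eff) <- names(effects)
  if (effects_mode == "model2_mixed") {
    eff[["d_rho_other"]] <- agent$d_rho_other
    eff[["d_lam_other"]] <- agent$d_lam_other
    eff[["d_mu_other"]] <- agent$d_mu_other
    eff[c("d_rho_identity", "d_lam_identity", "d_mu_identity")] <- 0
  }
  base <- parameter_set(log_rho = agent$log_rho, log_lam = agent$log_lam,
                        log_mu = agent$log_mu)
  p <- compose_trial_parameters(base, structure(eff, class = "social_effects"),
                                session$other, session$sharing,
                                session$identity)
  u_g <- gamble_utility(session$gain, session$loss, p$rho, p$lam,
                        session$p_gain)
  u_s <- guaranteed_utility(session$guaranteed, p$rho)
  prob <- choice_probability(u_g, u_s, p$mu)
  local_rng(seed)
  session$true_p <- prob
  session$choice <- as.integer(stats::runif(nrow(session)) < prob)
  session
}

#' Simulate a full synthetic cohort
#'
#' End-to-end generator: builds the cohort design ([build_cohort()]), draws
#' agents ([draw_population()]), and simulates every agent's choices
#' ([simulate_choices()]). All per-stage seeds derive from `config$seed` via
#' [split_seed()], so the output is exactly reproducible and any single
#' agent can be re-simulated in isolation.
#'
#' @param config A [population_config()].
#' @param effects_mode Passed to [simulate_choices()].
#' @param choice_set Optional fixed choice set (defaults to the standard
#'   90-gamble set derived from the master seed).
#' @param trials_per_condition Per-condition trial count (default 90).
#' @return List with `trials` (long choice table, one row per trial) and
#'   `agents` (the ground-truth agent table).
#' @export
simulate_cohort <- function(config = population_config(),
                            effects_mode = c("model1_fixed", "model2_mixed"),
                            choice_set = NULL,
                            trials_per_condition = 90L) {
  effects_mode <- match.arg(effects_mode)
  agents <- draw_population(config)
  design <- build_cohort(config$n_stranger, config$n_friend,
                         choice_set = choice_set, seed = config$seed,
                         trials_per_condition = trials_per_condition)
  trials <- lapply(seq_len(nrow(agents)), function(i) {
    session <- design[design$participant_id == agents$participant_id[i], ,
                      drop = FALSE]
    simulate_choices(session, agents[i, ], config$true_social_effects,
                     effects_mode,
                     seed = split_seed(config$seed, "choices", i))
  })
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  list(trials = trials, agents = agents)
}
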