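# shared fixture builders: everything is generated in code at test time

# a reduced cohort (fewer subjects, 30 gambles per condition) for fast fits
tiny_config <- function(n_stranger = 5, n_friend = 5, seed = 1L, ...) {
  population_config(n_stranger = n_stranger, n_friend = n_friend,
                    seed = seed, ...)
}

tiny_cohort <- function(n_stranger = 5, n_friend = 5, seed = 1L,
                        trials_per_condition = 30L,
                        effects_mode = "model1_fixed", ...) {
  simulate_cohort(tiny_config(n_stranger, n_friend, seed, ...),
                  effects_mode = effects_mode,
                  trials_per_condition = trials_per_condition)
}

# a hand-rolled session where every gamble strictly dominates the safe
# option at rho = lam = 1 (used for deterministic-limit checks)
dominant_session <- function(n = 200) {
  data.frame(participant_id = "p1", group = "friend", condition = "self",
             block = 1L, trial_index = seq_len(n), trial_type = "mixed",
             gain = 10, loss = -1, guaranteed = 0, p_gain = 0.5,
             other = 0L, sharing = 0L, identity = 0L)
}

# minimal spt_fit stand-in with draws pinned at given values (for report
# plumbing tests that do not need a real sampler run)
constant_fit <- function(values, participants, model = "M1", n = 50) {
  draws <- matrix(rep(values, each = n), n, length(values),
                  dimnames = list(NULL, names(values)))
  structure(list(model = model, draws = draws,
                 chain = rep(1:2, each = n / 2), n_chains = 2,
                 n_warmup = 0, n_draws = n / 2, loglik = NULL,
                 participants = participants,
                 acceptance = NULL, priors = default_priors_stub(),
                 seed = 1, warnings = character(0),
                 data = list(n_trials = 0)),
            class = "spt_fit")
}

default_priors_stub <- function() list()
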