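#' Encode the social indicator variables for a condition/group cell
#'
#' Maps the five distinct (condition, partner-group) cells of the design onto
#' the signed indicator triple used by the additive social-modulation model:
#' `other` (0 self, +1 another person involved), `sharing` (+1 other-only,
#' -1 shared, 0 self) and `identity` (+1 stranger, -1 friend, 0 self).
#' Self trials are all-zero regardless of group.
#'
#' @param condition Character vector in `c("self", "other", "shared")`.
#' @param group Character vector in `c("friend", "stranger")` (recycled).
#' @return A data.frame with integer columns `other`, `sharing`, `identity`.
#' @examples
#' encode_social_indicators("other", "stranger")   # (1, +1, +1)
#' encode_social_indicators("shared", "friend")    # (1, -1, -1)
#' @export
encode_social_indicators <- function(condition, group) {
  n <- max(length(condition), length(group))
  condition <- rep_len(condition, n)
  group <- rep_len(group, n)
  if (!all(condition %in% c("self", "other", "shared"))) {
    stop("condition must be one of 'self', 'other', 'shared'", call. = FALSE)
  }
  if (!all(group %in% c("friend", "stranger"))) {
    stop("group must be one of 'friend', 'stranger'", call. = FALSE)
  }
  social <- condition != "self"
  data.frame(
    other = as.integer(social),
    sharing = as.integer(ifelse(!social, 0L,
                                ifelse(condition == "other", 1L, -1L))),
    identity = as.integer(ifelse(!social, 0L,
                                 ifelse(group == "stranger", 1L, -1L)))
  )
}

#' Generate the gamble choice set
#'
#' Builds the per-condition choice set: mixed gambles (50% gain / 50% loss vs
#' a guaranteed $0) and gain-only gambles (50% gain / 50% $0 vs a smaller
#' guaranteed gain). Mixed-trial gains are drawn from the fixed task grid
#' `{2, 4, 5, 6, 8, 9, 10, 12}` and losses are `gain * m` with multipliers
#' `m` evenly spaced over `loss_mult_range`; the gain/multiplier pairing is
#' shuffled deterministically by `seed`. Gain-only risky gains are evenly
#' spaced over `gain_only_range` and guaranteed amounts are the risky gain
#' times a fraction cycled from `guaranteed_frac`. All dollar amounts are
#' rounded to whole cents.
#'
#' @param n_mixed,n_gain_only Trial counts (defaults 54 + 36 = 90 per
#'   condition).
#' @param gains_mixed Gain grid for mixed gambles.
#' @param loss_mult_range Length-2 range of loss multipliers, within
#'   `[-2, -0.25]`.
#' @param gain_only_range Length-2 range of risky gains on gain-only trials,
#'   within `[3.25, 30]`.
#' @param guaranteed_frac Fractions in (0, 1) mapping a risky gain to its
#'   guaranteed alternative.
#' @param seed Integer seed; the set is deterministic given the seed.
#' @return A data.frame with one row per gamble and columns `trial_type`
#'   ("mixed"/"gain_only"), `gain`, `loss`, `guaranteed`, `p_gain`.
#' @export
generate_choice_set <- function(n_mixed = 54, n_gain_only = 36,
                                gains_mixed = c(2, 4, 5, 6, 8, 9, 10, 12),
                                loss_mult_range = c(-0.25, -2),
                                gain_only_range = c(3.25, 30),
                                guaranteed_frac = c(0.3, 0.4, 0.5, 0.6, 0.7),
                                seed = 1L) {
  if (n_mixed < 0 || n_gain_only < 0) {
    stop("trial counts must be non-negative", call. = FALSE)
  }
  if (any(loss_mult_range < -2) || any(loss_mult_range > -0.25)) {
    stop("loss multipliers must lie within [-2, -0.25]", call. = FALSE)
  }
  if (any(gain_only_range < 3.25) || any(gain_only_range > 30) ||
      diff(gain_only_range) < 0) {
    stop("gain-only risky gains must lie within [3.25, 30]", call. = FALSE)
  }
  if (any(guaranteed_frac <= 0) || any(guaranteed_frac >= 1)) {
    stop("guaranteed fractions must lie in (0, 1)", call. = FALSE)
  }
  local_rng(seed)
  mixed <- NULL
  if (n_mixed > 0) {
    mult <- seq(loss_mult_range[1], loss_mult_range[2], length.out = n_mixed)
    gains <- rep_len(gains_mixed, n_mixed)
    # shuffle the gain/multiplier pairing so the crossing is not degenerate
    gains <- gains[sample.int(n_mixed)]
    mixed <- data.frame(trial_type = "mixed", gain = gains,
                        loss = round(gains * mult, 2), guaranteed = 0)
  }
  gonly <- NULL
  if (n_gain_only > 0) {
    risky <- round(seq(gain_only_range[1], gain_only_range[2],
                       length.out = n_gain_only), 2)
    guar <- round(risky * rep_len(guaranteed_frac, n_gain_only), 2)
    gonly <- data.frame(trial_type = "gain_only", gain = risky, loss = 0,
                        guaranteed = guar)
  }
  out <- rbind(mixed, gonly)
  out$p_gain <- 0.5
  rownames(out) <- NULL
  out
}

#' Build one participant's session
#'
#' Arranges the shared choice set into the three-condition session structure:
#' the self condition always comes first; the two social conditions follow in
#' the order given by `counterbalance` ("AB" = other then shared, "BA" =
#' shared then other). The identical gamble set is repeated in each
#' condition, independently shuffled by `seed`, and split into mini-blocks of
#' 30 trials. Social indicators are attached via
#' [encode_social_indicators()].
#'
#' @param participant_id Identifier (kept as given).
#' @param group `"friend"` or `"stranger"`.
#' @param counterbalance `"AB"` or `"BA"`.
#' @param choice_set A choice set from [generate_choice_set()]; 90 rows by
#'   default, configurable through `trials_per_condition`.
#' @param seed Integer seed controlling within-condition trial order.
#' @param trials_per_condition Expected choice-set size (design check).
#' @return A long data.frame with one row per trial (3 x nrow(choice_set))
#'   and columns `participant_id`, `group`, `condition`, `block`,
#'   `trial_index`, the gamble columns, and `other`/`sharing`/`identity`.
#' @export
build_session <- function(participant_id, group,
                          counterbalance = c("AB", "BA"),
                          choice_set, seed = 1L,
                          trials_per_condition = 90L) {
  counterbalance <- match.arg(counterbalance)
  if (nrow(choice_set) != trials_per_condition) {
    stop(sprintf("choice_set has %d gambles but the design expects %d per condition",
                 nrow(choice_set), trials_per_condition), call. = FALSE)
  }
  conditions <- c("self",
                  if (counterbalance == "AB") c("other", "shared")
                  else c("shared", "other"))
  local_rng(seed)
  blocks <- lapply(seq_along(conditions), function(k) {
    cond <- conditions[k]
    ord <- sample.int(nrow(choice_set))
    b <- choice_set[ord, , drop = FALSE]
    b$condition <- cond
    b$block <- ceiling(seq_len(nrow(b)) / 30)
    b
  })
  out <- do.call(rbind, blocks)
  out$participant_id <- participant_id
  out$group <- group
  out$trial_index <- seq_len(nrow(out))
  ind <- encode_social_indicators(out$condition, out$group)
  out <- cbind(out[c("participant_id", "group", "condition", "block",
                     "trial_index", "trial_type", "gain", "loss",
                     "guaranteed", "p_gain")], ind)
  rownames(out) <- NULL
  out
}

#' Build the full cohort design
#'
#' Stacks one session per participant: `n_stranger` stranger-group and
#' `n_friend` friend-group decision-makers (defaults 29 + 28 = 57), all
#' facing the same choice set, with the other/shared condition order
#' counterbalanced within each group (alternating AB/BA). Per-session
#' shuffling seeds are derived from `seed` by the package's seed-splitting
#' rule (see [split_seed()]).
#'
#' @param n_stranger,n_friend Group sizes.
#' @param choice_set Optional choice set; defaults to
#'   [generate_choice_set()] with `seed`.
#' @param seed Master integer seed.
#' @param trials_per_condition Per-condition trial count (default 90).
#' @return Long data.frame of all trials (57 x 270 = 15,390 rows at the
#'   default design), participant ids `"s01"..` (stranger) and `"f01"..`
#'   (friend).
#' @export
build_cohort <- function(n_stranger = 29, n_friend = 28, choice_set = NULL,
                         seed = 1L, trials_per_condition = 90L) {
  if (is.null(choice_set)) {
    n_go <- round(0.4 * trials_per_condition)   # default 54 mixed + 36 gain-only
    choice_set <- generate_choice_set(
      n_mixed = trials_per_condition - n_go, n_gain_only = n_go,
      seed = split_seed(seed, "choice_set", 0))
  }
  ids <- c(if (n_stranger > 0) sprintf("s%02d", seq_len(n_stranger)),
           if (n_friend > 0) sprintf("f%02d", seq_len(n_friend)))
  groups <- c(rep("stranger", n_stranger), rep("friend", n_friend))
  # alternate counterbalancing within each group
  flags <- unlist(lapply(c(n_stranger, n_friend), function(n) {
    rep_len(c("AB", "BA"), n)
  }))
  sessions <- lapply(seq_along(ids), function(i) {
    build_session(ids[i], groups[i], flags[i], choice_set,
                  seed = split_seed(seed, "session", i),
                  trials_per_condition = trials_per_condition)
  })
  out <- do.call(rbind, sessions)
  rownames(out) <- NULL
  out
}
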