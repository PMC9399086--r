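#' Construct a prospect-theory parameter set
#'
#' Bundles the three valuation/choice parameters on both the natural and the
#' unconstrained (log) scale. The natural-scale parameters are strictly
#' positive by construction: `rho` (risk attitude; 1 = risk neutral), `lam`
#' (loss aversion; 1 = gain-loss neutral) and `mu` (softmax choice
#' consistency; larger = more deterministic).
#'
#' Exactly one of the two scales must be supplied; the other is derived via
#' the exponential map used throughout the package for parameter bounding.
#'
#' @param rho,lam,mu Natural-scale parameters (all > 0).
#' @param log_rho,log_lam,log_mu Unconstrained log-scale parameters.
#' @return An object of class `parameter_set`: a list with fields `rho`,
#'   `lam`, `mu`, `log_rho`, `log_lam`, `log_mu`.
#' @examples
#' parameter_set(rho = 1.07, lam = 1.78, mu = 18.0)
#' parameter_set(log_rho = 0, log_lam = 0, log_mu = log(10))
#' @export
parameter_set <- function(rho = NULL, lam = NULL, mu = NULL,
                          log_rho = NULL, log_lam = NULL, log_mu = NULL) {
  natural <- !is.null(rho) || !is.null(lam) || !is.null(mu)
  logged <- !is.null(log_rho) || !is.null(log_lam) || !is.null(log_mu)
  if (natural && logged) {
    stop("supply parameters on the natural scale or the log scale, not both",
         call. = FALSE)
  }
  if (natural) {
    if (is.null(rho) || is.null(lam) || is.null(mu)) {
      stop("all of rho, lam, mu must be supplied", call. = FALSE)
    }
    if (any(c(rho, lam) <= 0) || any(mu < 0)) {
      stop("rho and lam must be > 0 and mu >= 0", call. = FALSE)
    }
    log_rho <- log(rho); log_lam <- log(lam); log_mu <- log(mu)
  } else {
    if (is.null(log_rho) || is.null(log_lam) || is.null(log_mu)) {
      stop("all of log_rho, log_lam, log_mu must be supplied", call. = FALSE)
    }
    rho <- exp(log_rho); lam <- exp(log_lam); mu <- exp(log_mu)
  }
  structure(list(rho = rho, lam = lam, mu = mu,
                 log_rho = log_rho, log_lam = log_lam, log_mu = log_mu),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  rho = %.4g  lam = %.4g  mu = %.4g\n",
              x$rho[1], x$lam[1], x$mu[1]))
  invisible(x)
}

#' Construct the vector of additive social-modulation effects
#'
#' The nine additive deltas acting on the unconstrained (log) scale of the
#' three choice parameters, one per social factor (`other`, `sharing`,
#' `identity`). Unspecified deltas default to zero, which makes all social
#' conditions behaviourally identical to the self condition.
#'
#' @param d_rho_other,d_rho_sharing,d_rho_identity Deltas on log(rho).
#' @param d_lam_other,d_lam_sharing,d_lam_identity Deltas on log(lambda).
#' @param d_mu_other,d_mu_sharing,d_mu_identity Deltas on log(mu).
#' @return A named numeric vector of length 9 with class `social_effects`.
#' @examples
#' # the published group-level fixed-effect estimates
#' social_effects(d_rho_other = -0.11, d_lam_other = 0.06, d_mu_other = 0.45)
#' @export
social_effects <- function(d_rho_other = 0, d_rho_sharing = 0, d_rho_identity = 0,
                           d_lam_other = 0, d_lam_sharing = 0, d_lam_identity = 0,
                           d_mu_other = 0, d_mu_sharing = 0, d_mu_identity = 0) {
  x <- c(d_rho_other = d_rho_other, d_rho_sharing = d_rho_sharing,
         d_rho_identity = d_rho_identity,
         d_lam_other = d_lam_other, d_lam_sharing = d_lam_sharing,
         d_lam_identity = d_lam_identity,
         d_mu_other = d_mu_other, d_mu_sharing = d_mu_sharing,
         d_mu_identity = d_mu_identity)
  if (any(!is.finite(x))) stop("social effects must be finite", call. = FALSE)
  structure(x, class = c("social_effects", "numeric"))
}

#' Names of the nine social-effect parameters
#' @return Character vector of length 9.
#' @export
social_effect_names <- function() names(social_effects())

#' Utility of a 50/50 gamble
#'
#' Computes the prospect-theory utility of a two-branch gamble. The gain
#' branch contributes `p_gain * gain^rho`; a loss branch contributes
#' `-p_loss * lam * |loss|^rho` (the exponent is shared between gains and
#' losses; the loss sign is carried outside the power so a negative amount is
#' never raised to a real exponent). A zero branch (gain-only gambles)
#' contributes exactly 0.
#'
#' All arguments are vectorized and recycled.
#'
#' @param gain Gamble gain amount(s), > 0 (USD).
#' @param loss Gamble loss amount(s), <= 0 (USD); 0 denotes the zero branch
#'   of a gain-only gamble.
#' @param rho Risk attitude, > 0.
#' @param lam Loss aversion, > 0.
#' @param p_gain Probability of the gain branch (default 0.5, as in the
#'   task); the complementary branch has probability `1 - p_gain`.
#' @return Numeric utility vector.
#' @examples
#' gamble_utility(10, -5, rho = 1, lam = 1)   # expected value: 2.5
#' gamble_utility(10, -5, rho = 1, lam = 2)   # doubled losses cancel: 0
#' @export
gamble_utility <- function(gain, loss, rho, lam, p_gain = 0.5) {
  if (any(rho <= 0) || any(lam <= 0)) {
    stop("rho and lam must be strictly positive", call. = FALSE)
  }
  if (any(gain <= 0)) stop("gain must be strictly positive", call. = FALSE)
  if (any(loss > 0)) stop("loss must be <= 0", call. = FALSE)
  n <- max(length(gain), length(loss), length(rho), length(lam), length(p_gain))
  gain <- rep_len(gain, n); loss <- rep_len(loss, n)
  rho <- rep_len(rho, n); lam <- rep_len(lam, n); p_gain <- rep_len(p_gain, n)
  u_gain <- p_gain * gain^rho
  u_loss <- numeric(n)
  has_loss <- loss < 0
  if (any(has_loss)) {
    u_loss[has_loss] <- -(1 - p_gain[has_loss]) * lam[has_loss] *
      (-loss[has_loss])^rho[has_loss]
  }
  u_gain + u_loss
}

#' Utility of a guaranteed amount
#'
#' `amount^rho`, with `0^rho` defined as 0 (the guaranteed $0 alternative of
#' mixed gambles).
#'
#' @param amount Guaranteed amount(s), >= 0 (USD).
#' @param rho Risk attitude, > 0.
#' @return Numeric utility vector.
#' @export
guaranteed_utility <- function(amount, rho) {
  if (any(amount < 0)) stop("guaranteed amount must be >= 0", call. = FALSE)
  if (any(rho <= 0)) stop("rho must be strictly positive", call. = FALSE)
  n <- max(length(amount), length(rho))
  amount <- rep_len(amount, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  pos <- amount > 0
  out[pos] <- amount[pos]^rho[pos]
  out
}

#' Softmax probability of choosing the gamble
#'
#' Logistic choice rule `1 / (1 + exp(-mu * (u_gamble - u_guaranteed)))`,
#' evaluated through [stats::plogis()] so it is numerically stable for large
#' `|mu * delta_u|`. At `mu = 0` or equal utilities the probability is 0.5.
#'
#' @param u_gamble,u_guaranteed Utilities of the two options.
#' @param mu Choice consistency (inverse temperature), >= 0.
#' @return Probability vector in (0, 1).
#' @examples
#' choice_probability(2.25, 1, mu = 1)  # logistic(1.25) ~ 0.777
#' @export
choice_probability <- function(u_gamble, u_guaranteed, mu) {
  if (any(mu < 0)) stop("mu must be >= 0", call. = FALSE)
  stats::plogis(mu * (u_gamble - u_guaranteed))
}

#' Compose per-trial parameters from baselines and social effects
#'
#' Applies the additive social-modulation model on the unconstrained scale:
#' for each parameter `theta` in (rho, lam, mu),
#' `theta_trial = exp(log theta_baseline + other * d_theta_other +
#' sharing * d_theta_sharing + identity * d_theta_identity)`.
#' Self trials (all-zero indicators) return the baseline exactly.
#'
#' The indicators follow the task coding: `other` 0 self / +1 another person
#' involved; `sharing` +1 other-only / -1 shared / 0 self; `identity`
#' +1 stranger / -1 friend / 0 self.
#'
#' @param baseline A [parameter_set()] (its log-scale fields are used);
#'   fields may be vectors (e.g. one entry per subject or per trial).
#' @param effects A [social_effects()] vector.
#' @param other,sharing,identity Integer indicator vectors (recycled).
#' @return A `parameter_set` whose fields are vectors over trials.
#' @examples
#' base <- parameter_set(rho = 1.07, lam = 1.78, mu = 18.0)
#' eff <- social_effects(d_rho_other = -0.11, d_lam_other = 0.06,
#'                       d_mu_other = 0.45)
#' p <- compose_trial_parameters(base, eff, other = 1, sharing = 0, identity = 0)
#' round(c(p$rho, p$lam, p$mu), 2)  # ~ 0.96 1.90 28.23
#' @export
compose_trial_parameters <- function(baseline, effects, other, sharing, identity) {
  stopifnot(inherits(baseline, "parameter_set"))
  e <- as.numeric(effects)
  names(e) <- names(effects)
  if (!all(social_effect_names() %in% names(e))) {
    stop("effects must carry the nine named social deltas", call. = FALSE)
  }
  n <- max(length(other), length(sharing), length(identity),
           length(baseline$log_rho))
  other <- rep_len(other, n); sharing <- rep_len(sharing, n)
  identity <- rep_len(identity, n)
  sh_r <- other * e[["d_rho_other"]] + sharing * e[["d_rho_sharing"]] +
    identity * e[["d_rho_identity"]]
  sh_l <- other * e[["d_lam_other"]] + sharing * e[["d_lam_sharing"]] +
    identity * e[["d_lam_identity"]]
  sh_m <- other * e[["d_mu_other"]] + sharing * e[["d_mu_sharing"]] +
    identity * e[["d_mu_identity"]]
  # multiply on the natural scale (exp(0) == 1, so self trials return the
  # baseline bit-for-bit)
  structure(list(rho = rep_len(baseline$rho, n) * exp(sh_r),
                 lam = rep_len(baseline$lam, n) * exp(sh_l),
                 mu = rep_len(baseline$mu, n) * exp(sh_m),
                 log_rho = rep_len(baseline$log_rho, n) + sh_r,
                 log_lam = rep_len(baseline$log_lam, n) + sh_l,
                 log_mu = rep_len(baseline$log_mu, n) + sh_m),
            class = "parameter_set")
}

#' Per-trial Bernoulli log-likelihood of observed choices
#'
#' `log p` when the gamble was accepted, `log(1 - p)` when rejected, with
#' `p` from [choice_probability()]. Computed on the log scale via
#' `plogis(..., log.p = TRUE)` so extreme consistency does not underflow.
#'
#' All trial-level arguments are vectorized; parameters may be scalars or
#' per-trial vectors.
#'
#' @param choice 1 = gamble accepted, 0 = guaranteed option taken.
#' @param gain,loss,guaranteed Trial option values (USD); `loss = 0` and
#'   `guaranteed > 0` on gain-only trials, `guaranteed = 0` on mixed trials.
#' @param rho,lam,mu Natural-scale parameters.
#' @param p_gain Gain-branch probability (default 0.5).
#' @return Numeric vector of per-trial log-likelihood contributions (<= 0).
#'   The dataset log-likelihood is their sum (trials are independent).
#' @export
trial_loglik <- function(choice, gain, loss, guaranteed, rho, lam, mu,
                         p_gain = 0.5) {
  if (anyNA(choice) || !all(choice %in% c(0, 1))) {
    stop("choice must be 0/1 with no missing values", call. = FALSE)
  }
  u_g <- gamble_utility(gain, loss, rho, lam, p_gain)
  u_s <- guaranteed_utility(guaranteed, rho)
  x <- mu * (u_g - u_s)
  n <- max(length(choice), length(x))
  choice <- rep_len(choice, n); x <- rep_len(x, n)
  sgn <- ifelse(choice == 1, 1, -1)
  stats::plogis(sgn * x, log.p = TRUE)
}

#' Dataset log-likelihood of a trial table under given parameters
#'
#' Convenience wrapper evaluating [trial_loglik()] over a long trial table,
#' composing per-trial parameters from per-subject baselines plus social
#' effects. Used as the reference ("oracle") likelihood the MCMC machinery is
#' tested against.
#'
#' @param trials Trial table with columns `participant_id`, `gain`, `loss`,
#'   `guaranteed`, `other`, `sharing`, `identity`, `choice`.
#' @param subject_params A `parameter_set` whose fields are vectors indexed
#'   by subject (in the order of `sort(unique(trials$participant_id))`), or a
#'   scalar set applied to all subjects.
#' @param effects A [social_effects()] vector (defaults to all-zero).
#' @return List with `total` (scalar log-likelihood) and `pointwise`
#'   (per-trial vector, in the row order of `trials`).
#' @export
dataset_loglik <- function(trials, subject_params, effects = social_effects()) {
  ids <- sort(unique(trials$participant_id))
  idx <- match(trials$participant_id, ids)
  base <- parameter_set(
    log_rho = rep_len(subject_params$log_rho, length(ids))[idx],
    log_lam = rep_len(subject_params$log_lam, length(ids))[idx],
    log_mu = rep_len(subject_params$log_mu, length(ids))[idx])
  p <- compose_trial_parameters(base, effects, trials$other, trials$sharing,
                                trials$identity)
  ll <- trial_loglik(trials$choice, trials$gain, trials$loss,
                     trials$guaranteed, p$rho, p$lam, p$mu)
  list(total = sum(ll), pointwise = ll)
}
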