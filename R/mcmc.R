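#' Model variants
#'
#' * `M0`: hierarchical baselines only (no social terms).
#' * `M1`: nine fixed-effect social deltas (other/sharing/identity on each of
#'   log rho, log lambda, log mu).
#' * `M2`: the 'other' deltas become mixed effects (group mean + SD with
#'   subject-level values); sharing deltas stay fixed effects; identity is
#'   not modelled.
#' @name model_variants
#' @keywords internal
NULL

# full-9 delta vector index helpers (order of social_effect_names())
DELTA_IDX <- list(rho = 1:3, lam = 4:6, mu = 7:9)

# active fixed-effect delta positions per model
active_delta <- function(model) {
  switch(model,
         M0 = integer(0),
         M1 = 1:9,
         M2 = c(2L, 5L, 8L))  # sharing terms only
}

# subject-level column labels per model
theta_cols <- function(model) {
  base <- c("log_rho", "log_lam", "log_mu")
  if (model == "M2") c(base, "d_rho_other_s", "d_lam_other_s", "d_mu_other_s")
  else base
}

# prepare the trial table for fast likelihood evaluation
prep_data <- function(trials) {
  required <- c("participant_id", "gain", "loss", "guaranteed", "other",
                "sharing", "identity", "choice")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(trials$choice) || !all(trials$choice %in% c(0, 1))) {
    stop("choice must be 0/1 with no missing values", call. = FALSE)
  }
  ord <- order(trials$participant_id)
  trials <- trials[ord, , drop = FALSE]
  ids <- unique(trials$participant_id)
  subj <- match(trials$participant_id, ids)
  pg <- if ("p_gain" %in% names(trials)) trials$p_gain else 0.5
  pg <- rep_len(pg, nrow(trials))
  # per-subject identity sign on social trials (0 if the subject has none)
  soc <- trials$other != 0
  subj_identity <- vapply(
    split(trials$identity[soc], factor(subj[soc], levels = seq_along(ids))),
    function(v) if (length(v)) v[1] else 0, numeric(1))
  list(ids = ids, n_subj = length(ids), n_trials = nrow(trials),
       subj = subj, row_order = ord, subj_identity = unname(subj_identity),
       other = as.numeric(trials$other), sharing = as.numeric(trials$sharing),
       identity = as.numeric(trials$identity),
       pg = pg, pl = 1 - pg,
       lg = log(trials$gain),
       has_loss = as.numeric(trials$loss < 0),
       llo = ifelse(trials$loss < 0, log(-trials$loss), 0),
       has_guar = as.numeric(trials$guaranteed > 0),
       lgu = ifelse(trials$guaranteed > 0, log(trials$guaranteed), 0),
       sgn = ifelse(trials$choice == 1, 1, -1),
       trials = trials)
}

# extract a row-subset "view" of the prepared data
data_view <- function(data, idx) {
  list(subj = data$subj[idx], other = data$other[idx],
       sharing = data$sharing[idx], identity = data$identity[idx],
       pg = data$pg[idx], pl = data$pl[idx], lg = data$lg[idx],
       has_loss = data$has_loss[idx], llo = data$llo[idx],
       has_guar = data$has_guar[idx], lgu = data$lgu[idx],
       sgn = data$sgn[idx])
}

# likelihood closure factory. The returned function evaluates the per-trial
# Bernoulli log-likelihood over one of three row sets: "all", "self"
# (all-zero indicators: no delta dependence) or "social", returning
# per-subject sums (length n_subj). Deltas and (for M2) the subject-level
# 'other' columns enter only through social rows, which is what makes the
# partial evaluations in the sampler cheap and exact.
make_loglik <- function(data, model) {
  views <- list(all = data_view(data, seq_len(data$n_trials)),
                self = data_view(data, which(data$other == 0)),
                social = data_view(data, which(data$other != 0)))
  n_subj <- data$n_subj
  function(theta, delta, part = "all", pointwise = FALSE) {
    v <- views[[part]]
    s <- v$subj
    if (part == "self") {
      lr <- theta[s, 1]; lla <- theta[s, 2]; lmu <- theta[s, 3]
    } else if (model == "M2") {
      lr <- theta[s, 1] + v$other * theta[s, 4] + v$sharing * delta[2]
      lla <- theta[s, 2] + v$other * theta[s, 5] + v$sharing * delta[5]
      lmu <- theta[s, 3] + v$other * theta[s, 6] + v$sharing * delta[8]
    } else {
      lr <- theta[s, 1] + v$other * delta[1] + v$sharing * delta[2] +
        v$identity * delta[3]
      lla <- theta[s, 2] + v$other * delta[4] + v$sharing * delta[5] +
        v$identity * delta[6]
      lmu <- theta[s, 3] + v$other * delta[7] + v$sharing * delta[8] +
        v$identity * delta[9]
    }
    rho <- exp(lr); lam <- exp(lla); mu <- exp(lmu)
    u <- v$pg * exp(rho * v$lg) -
      v$pl * lam * (v$has_loss * exp(rho * v$llo))
    us <- v$has_guar * exp(rho * v$lgu)
    x <- v$sgn * (mu * (u - us))
    llt <- stats::plogis(x, log.p = TRUE)
    llt[!is.finite(llt)] <- -Inf
    rs <- rowsum(llt, s, reorder = TRUE)
    subj_ll <- numeric(n_subj)
    subj_ll[as.integer(rownames(rs))] <- rs
    list(subj = subj_ll, total = sum(subj_ll),
         pointwise = if (pointwise) llt else NULL)
  }
}

#' Pointwise log-likelihood as evaluated inside the sampler
#'
#' Exposes the inference engine's internal likelihood at fixed parameter
#' values so it can be checked against the standalone [trial_loglik()]
#' oracle (dual-route check) and so model nesting (M1 with zero deltas vs
#' M0) can be verified at fixed parameters.
#'
#' @param trials Trial table (long format, with `choice`).
#' @param theta Matrix `n_subjects x K` of subject-level parameters on the
#'   unconstrained scale, rows ordered by `sort(unique(participant_id))`;
#'   `K = 3` (log rho, log lam, log mu) for M0/M1, `K = 6` for M2 (plus the
#'   subject 'other' deltas).
#' @param delta Full 9-vector of fixed-effect deltas in the order of
#'   [social_effect_names()] (entries outside the model's active set must be
#'   zero).
#' @param model `"M0"`, `"M1"` or `"M2"`.
#' @return Per-trial log-likelihood vector in the sampler's internal row
#'   order (trials sorted by participant).
#' @export
model_loglik <- function(trials, theta, delta = rep(0, 9), model = "M1") {
  model <- match.arg(model, c("M0", "M1", "M2"))
  data <- prep_data(trials)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = data$n_subj,
                                         ncol = length(theta), byrow = TRUE)
  make_loglik(data, model)(theta, delta, pointwise = TRUE)$pointwise
}

default_priors <- function(model) {
  k <- length(theta_cols(model))
  hm <- c(0, 0, log(10))           # exp ~ 1 for rho/lam, ~10 for mu
  hs <- c(1, 1, 1)
  if (model == "M2") {
    hm <- c(hm, 0, 0, 0)
    hs <- c(hs, 0.5, 0.5, 0.5)
  }
  list(hyper_mean_mean = hm,       # Normal priors on group-level means
       hyper_mean_sd = hs,
       hyper_sd_scale = rep(1, k), # half-Normal scale on group-level SDs
       delta_sd = 0.5)             # Normal(0, 0.5) on fixed social deltas
}

#' Fit a hierarchical prospect-theory model by MCMC
#'
#' Estimates subject-level log-scale parameters partially pooled under
#' group-level means and SDs, plus the social-modulation deltas of the
#' chosen model variant, from a long trial table. Sampling is an adaptive
#' Metropolis-within-Gibbs scheme:
#' * per-subject joint random-walk updates, vectorized across subjects
#'   (conditionally independent given the group level), with proposal SDs
#'   estimated online during warmup;
#' * conjugate Gibbs draws for group-level means and log-scale random-walk
#'   updates for group-level SDs;
#' * for the fixed deltas, a Haario-style adaptive multivariate block update
#'   plus a componentwise sweep (deltas touch only social-condition trials,
#'   so these use partial likelihood evaluations);
#' * "translation" moves that slide along the posterior ridges created by
#'   weakly identified baseline/delta splits: the 'other' effect of each
#'   parameter against all subject baselines, and (M1) the identity effect
#'   against the group-signed baselines. These leave social-trial likelihood
#'   exactly invariant and re-evaluate self trials only.
#'
#' All adaptation happens during warmup only; the post-warmup kernel is
#' fixed, so retained draws form a valid Markov chain.
#'
#' @param trials Long trial table with columns `participant_id`, `gain`,
#'   `loss`, `guaranteed`, `other`, `sharing`, `identity`, `choice`.
#' @param model `"M0"` (no social terms), `"M1"` (nine fixed deltas) or
#'   `"M2"` ('other' deltas mixed effects, sharing fixed, no identity).
#' @param chains Number of chains (default 4).
#' @param warmup Adaptation iterations per chain, discarded (default 1000).
#' @param draws Retained iterations per chain (default 500; the published
#'   budget of 10,000 retained across 4 chains corresponds to
#'   `draws = 2500`).
#' @param seed Master seed; per-chain seeds are derived via [split_seed()].
#' @param priors Optional list overriding [default_priors] entries.
#' @param keep_loglik Keep the draws x trials pointwise log-likelihood
#'   matrix (needed for [waic()]; default TRUE, costs memory).
#' @param progress Print per-chain progress lines.
#' @return An object of class `spt_fit`: list with `draws` (total retained
#'   draws x parameters matrix, named columns), `chain` (chain index per
#'   row), `loglik` (matrix or NULL), `model`, `participants`, `acceptance`
#'   rates, `priors`, `seed`, and the prepared internal data (`data`).
#' @export
fit_model <- function(trials, model = c("M1", "M0", "M2"), chains = 4,
                      warmup = 1000, draws = 500, seed = 1L, priors = NULL,
                      keep_loglik = TRUE, progress = FALSE) {
  model <- match.arg(model)
  data <- prep_data(trials)
  pr <- default_priors(model)
  if (!is.null(priors)) pr[names(priors)] <- priors
  loglik <- make_loglik(data, model)
  k <- length(theta_cols(model))
  act <- active_delta(model)
  s_n <- data$n_subj
  par_names <- c(paste0("mu_", theta_cols(model)),
                 paste0("sigma_", theta_cols(model)),
                 if (length(act)) social_effect_names()[act],
                 as.vector(t(outer(theta_cols(model), data$ids,
                                   function(a, b) paste0(a, "[", b, "]")))))
  n_par <- length(par_names)
  total <- chains * draws
  all_draws <- matrix(NA_real_, total, n_par,
                      dimnames = list(NULL, par_names))
  chain_id <- rep(seq_len(chains), each = draws)
  ll_mat <- if (keep_loglik) matrix(NA_real_, total, data$n_trials) else NULL
  acc_report <- vector("list", chains)

  for (ch in seq_len(chains)) {
    local_rng(split_seed(seed, "chain", ch))
    # --- initialization ---
    hyper_mu <- pr$hyper_mean_mean + stats::rnorm(k, 0, 0.2)
    hyper_sd <- abs(stats::rnorm(k, 0.3, 0.1)) + 0.05
    theta <- matrix(rep(hyper_mu, each = s_n), s_n, k) +
      matrix(stats::rnorm(s_n * k, 0, 0.15), s_n, k)
    delta <- rep(0, 9)
    if (length(act)) delta[act] <- stats::rnorm(length(act), 0, 0.02)
    cur_self <- loglik(theta, delta, "self")$subj
    cur_social <- loglik(theta, delta, "social")$subj
    if (!all(is.finite(cur_self + cur_social))) {
      stop("non-finite likelihood at initialization (chain ", ch, ")",
           call. = FALSE)
    }
    # subject proposal scales: per-subject scalar (acceptance-tuned) times
    # per-parameter SDs estimated online during warmup (Welford)
    base_rel <- matrix(rep(c(0.04, 0.08, 0.15,
                             0.08, 0.08, 0.15)[seq_len(k)], each = s_n),
                       s_n, k)
    tune_theta <- rep(1, s_n)
    sd_est <- base_rel
    n_w <- 0
    mean_w <- matrix(0, s_n, k)
    m2_w <- matrix(0, s_n, k)
    step_sd <- rep(0.2, k)
    # delta block + componentwise scales
    delta_scale <- 0.02
    step_d <- rep(0.02, length(act))
    d_hist <- if (length(act)) matrix(NA_real_, max(warmup, 1), length(act))
    d_chol <- if (length(act)) diag(length(act))
    # translation-move scales
    step_tr <- rep(0.1, 3)
    step_tr_id <- rep(0.05, 3)
    step_st <- rep(0.1, k)
    id_sign <- ifelse(data$subj_identity >= 0, 1, -1)
    acc_theta <- 0; acc_delta <- 0; acc_n <- 0

    theta_prior <- function(th) {
      rowSums(stats::dnorm(th, rep(hyper_mu, each = s_n),
                           rep(hyper_sd, each = s_n), log = TRUE))
    }
    delta_prior <- function(d) {
      sum(stats::dnorm(d[act], 0, pr$delta_sd, log = TRUE))
    }

    n_iter <- warmup + draws
    for (it in seq_len(n_iter)) {
      gain <- 0.5 / sqrt(it)
      adapting <- it <= warmup
      # 1. subject blocks (joint K-dim RW per subject, vectorized)
      prop <- theta + matrix(stats::rnorm(s_n * k), s_n, k) *
        (tune_theta * sd_est)
      new_self <- loglik(prop, delta, "self")$subj
      new_social <- loglik(prop, delta, "social")$subj
      lp_cur <- cur_self + cur_social + theta_prior(theta)
      lp_new <- new_self + new_social + theta_prior(prop)
      lp_new[!is.finite(lp_new)] <- -Inf
      acc <- log(stats::runif(s_n)) < (lp_new - lp_cur)
      if (any(acc)) {
        theta[acc, ] <- prop[acc, , drop = FALSE]
        cur_self[acc] <- new_self[acc]
        cur_social[acc] <- new_social[acc]
      }
      if (adapting) {
        tune_theta <- tune_theta * exp(gain * (as.numeric(acc) - 0.30))
        n_w <- n_w + 1
        d1 <- theta - mean_w
        mean_w <- mean_w + d1 / n_w
        m2_w <- m2_w + d1 * (theta - mean_w)
        if (n_w > 50) {
          sd_est <- pmax(sqrt(m2_w / (n_w - 1)), 0.25 * base_rel)
        }
      } else {
        acc_theta <- acc_theta + mean(acc)
      }
      # 2. group means: conjugate Gibbs given theta and hyper_sd
      prec <- s_n / hyper_sd^2 + 1 / pr$hyper_mean_sd^2
      mean_post <- (colSums(theta) / hyper_sd^2 +
                      pr$hyper_mean_mean / pr$hyper_mean_sd^2) / prec
      hyper_mu <- stats::rnorm(k, mean_post, sqrt(1 / prec))
      # 3. group SDs: RW on log sd, half-Normal prior (+ Jacobian)
      for (j in seq_len(k)) {
        sd_new <- hyper_sd[j] * exp(stats::rnorm(1, 0, step_sd[j]))
        lt_cur <- sum(stats::dnorm(theta[, j], hyper_mu[j], hyper_sd[j],
                                   log = TRUE)) +
          stats::dnorm(hyper_sd[j], 0, pr$hyper_sd_scale[j], log = TRUE) +
          log(hyper_sd[j])
        lt_new <- sum(stats::dnorm(theta[, j], hyper_mu[j], sd_new,
                                   log = TRUE)) +
          stats::dnorm(sd_new, 0, pr$hyper_sd_scale[j], log = TRUE) +
          log(sd_new)
        a <- is.finite(lt_new) && log(stats::runif(1)) < (lt_new - lt_cur)
        if (a) hyper_sd[j] <- sd_new
        if (adapting) step_sd[j] <- step_sd[j] * exp(gain * (as.numeric(a) - 0.44))
      }
      if (length(act)) {
        # 4a. fixed-delta block (adaptive multivariate RW, social rows only)
        eps <- as.vector(d_chol %*% stats::rnorm(length(act))) * delta_scale
        delta_new <- delta
        delta_new[act] <- delta[act] + eps
        new_social <- loglik(theta, delta_new, "social")$subj
        lp_n <- sum(new_social) + delta_prior(delta_new)
        lp_c <- sum(cur_social) + delta_prior(delta)
        a <- is.finite(lp_n) && log(stats::runif(1)) < (lp_n - lp_c)
        if (a) {
          delta <- delta_new
          cur_social <- new_social
        }
        if (adapting) {
          delta_scale <- delta_scale * exp(gain * (as.numeric(a) - 0.25))
          d_hist[it, ] <- delta[act]
          if (it >= 150 && it %% 50 == 0) {
            cv <- stats::cov(d_hist[seq_len(it), , drop = FALSE])
            d_chol <- tryCatch(
              t(chol(cv + diag(1e-10, length(act))) * 2.38 /
                  sqrt(length(act))),
              error = function(e) d_chol)
          }
        } else {
          acc_delta <- acc_delta + as.numeric(a)
        }
        # 4b. componentwise delta sweep (guards against frozen dimensions
        # the block covariance cannot escape)
        for (jj in seq_along(act)) {
          dj <- act[jj]
          delta_new <- delta
          delta_new[dj] <- delta[dj] + stats::rnorm(1, 0, step_d[jj])
          new_social <- loglik(theta, delta_new, "social")$subj
          lp_n <- sum(new_social) + delta_prior(delta_new)
          lp_c <- sum(cur_social) + delta_prior(delta)
          a <- is.finite(lp_n) && log(stats::runif(1)) < (lp_n - lp_c)
          if (a) {
            delta <- delta_new
            cur_social <- new_social
          }
          if (adapting) {
            step_d[jj] <- step_d[jj] * exp(gain * (as.numeric(a) - 0.44))
          }
        }
      }
      # 5. 'other' translation moves: shift the 'other' effect of parameter
      # j by +e and every subject baseline (and group mean) by -e. Social
      # trials see theta - e + (delta + e): exactly invariant, so only self
      # trials are re-evaluated. Frees the weakly identified baseline/delta
      # split (notably for mu).
      if (model != "M0") {
        for (j in 1:3) {
          e <- stats::rnorm(1, 0, step_tr[j])
          theta_new <- theta
          theta_new[, j] <- theta[, j] - e
          mu_new <- hyper_mu
          mu_new[j] <- hyper_mu[j] - e
          delta_new <- delta
          if (model == "M1") {
            dj <- DELTA_IDX[[j]][1]   # the 'other' slot of parameter j
            delta_new[dj] <- delta[dj] + e
            lp_shift <-
              stats::dnorm(delta_new[dj], 0, pr$delta_sd, log = TRUE) -
              stats::dnorm(delta[dj], 0, pr$delta_sd, log = TRUE)
          } else {            # M2: subject-level other deltas live in theta
            theta_new[, 3 + j] <- theta[, 3 + j] + e
            mu_new[3 + j] <- hyper_mu[3 + j] + e
            lp_shift <-
              stats::dnorm(mu_new[3 + j], pr$hyper_mean_mean[3 + j],
                           pr$hyper_mean_sd[3 + j], log = TRUE) -
              stats::dnorm(hyper_mu[3 + j], pr$hyper_mean_mean[3 + j],
                           pr$hyper_mean_sd[3 + j], log = TRUE)
          }
          lp_shift <- lp_shift +
            stats::dnorm(mu_new[j], pr$hyper_mean_mean[j],
                         pr$hyper_mean_sd[j], log = TRUE) -
            stats::dnorm(hyper_mu[j], pr$hyper_mean_mean[j],
                         pr$hyper_mean_sd[j], log = TRUE)
          new_self <- loglik(theta_new, delta_new, "self")$subj
          lp_n <- sum(new_self) + lp_shift
          a <- is.finite(lp_n) && log(stats::runif(1)) < (lp_n - sum(cur_self))
          if (a) {
            theta <- theta_new
            hyper_mu <- mu_new
            delta <- delta_new
            cur_self <- new_self
          }
          if (adapting) {
            step_tr[j] <- step_tr[j] * exp(gain * (as.numeric(a) - 0.44))
          }
        }
      }
      # 6. identity translation (M1 only): the identity contrast is
      # constant within participant (+1 stranger-group, -1 friend-group),
      # so it rides a between-group ridge with the subject baselines;
      # shifting it and the group-signed baselines together again leaves
      # social trials exactly invariant
      if (model == "M1") {
        for (j in 1:3) {
          e <- stats::rnorm(1, 0, step_tr_id[j])
          dj <- DELTA_IDX[[j]][3]   # the 'identity' slot of parameter j
          delta_new <- delta
          delta_new[dj] <- delta[dj] + e
          theta_new <- theta
          theta_new[, j] <- theta[, j] - e * id_sign
          lp_shift <-
            stats::dnorm(delta_new[dj], 0, pr$delta_sd, log = TRUE) -
            stats::dnorm(delta[dj], 0, pr$delta_sd, log = TRUE) +
            sum(stats::dnorm(theta_new[, j], hyper_mu[j], hyper_sd[j],
                             log = TRUE)) -
            sum(stats::dnorm(theta[, j], hyper_mu[j], hyper_sd[j],
                             log = TRUE))
          new_self <- loglik(theta_new, delta_new, "self")$subj
          lp_n <- sum(new_self) + lp_shift
          a <- is.finite(lp_n) && log(stats::runif(1)) < (lp_n - sum(cur_self))
          if (a) {
            theta <- theta_new
            delta <- delta_new
            cur_self <- new_self
          }
          if (adapting) {
            step_tr_id[j] <- step_tr_id[j] * exp(gain * (as.numeric(a) - 0.44))
          }
        }
      }
      # 7. stretch moves: rescale one theta column around its group mean
      # together with the group SD (theta' = m + c(theta - m),
      # sigma' = c sigma). The group SD of a weakly identified column
      # (log mu) otherwise only moves as fast as the whole column's spread
      # can drift. Jacobian is (S + 1) log c.
      for (j in seq_len(k)) {
        e <- stats::rnorm(1, 0, step_st[j])
        cc <- exp(e)
        sd_new_j <- cc * hyper_sd[j]
        theta_new <- theta
        theta_new[, j] <- hyper_mu[j] + cc * (theta[, j] - hyper_mu[j])
        new_social <- loglik(theta_new, delta, "social")$subj
        if (j <= 3) {
          new_self <- loglik(theta_new, delta, "self")$subj
        } else {
          new_self <- cur_self    # M2 subject-delta columns: self invariant
        }
        lp_shift <-
          sum(stats::dnorm(theta_new[, j], hyper_mu[j], sd_new_j,
                           log = TRUE)) -
          sum(stats::dnorm(theta[, j], hyper_mu[j], hyper_sd[j],
                           log = TRUE)) +
          stats::dnorm(sd_new_j, 0, pr$hyper_sd_scale[j], log = TRUE) -
          stats::dnorm(hyper_sd[j], 0, pr$hyper_sd_scale[j], log = TRUE) +
          (s_n + 1) * e
        lp_n <- sum(new_self) + sum(new_social) + lp_shift
        a <- is.finite(lp_n) &&
          log(stats::runif(1)) < (lp_n - sum(cur_self) - sum(cur_social))
        if (a) {
          theta <- theta_new
          hyper_sd[j] <- sd_new_j
          cur_self <- new_self
          cur_social <- new_social
        }
        if (adapting) {
          step_st[j] <- step_st[j] * exp(gain * (as.numeric(a) - 0.44))
        }
      }
      # store retained draw
      if (!adapting) {
        acc_n <- acc_n + 1
        row <- (ch - 1) * draws + (it - warmup)
        all_draws[row, ] <- c(hyper_mu, hyper_sd, delta[act],
                              as.vector(theta))
        if (keep_loglik) {
          ll_mat[row, ] <- loglik(theta, delta, "all",
                                  pointwise = TRUE)$pointwise
        }
      }
    }
    acc_report[[ch]] <- c(theta = acc_theta / max(acc_n, 1),
                          delta = if (length(act)) acc_delta / max(acc_n, 1)
                                  else NA_real_)
    if (progress) {
      message(sprintf("chain %d done (subject acc %.2f, delta acc %.2f)",
                      ch, acc_report[[ch]]["theta"],
                      acc_report[[ch]]["delta"]))
    }
  }
  acc_mat <- do.call(rbind, acc_report)
  warn <- character(0)
  if (mean(acc_mat[, "theta"]) < 0.05) {
    warn <- c(warn, "subject-block acceptance below 0.05: poor mixing")
  }
  if (length(act) && mean(acc_mat[, "delta"], na.rm = TRUE) < 0.02) {
    warn <- c(warn, "delta-block acceptance below 0.02: poor mixing")
  }
  for (w in warn) warning(w, call. = FALSE)
  structure(list(model = model, draws = all_draws, chain = chain_id,
                 n_chains = chains, n_warmup = warmup, n_draws = draws,
                 loglik = ll_mat, participants = data$ids,
                 acceptance = acc_mat, priors = pr, seed = seed,
                 warnings = warn, data = data),
            class = "spt_fit")
}

#' @export
print.spt_fit <- function(x, ...) {
  cat(sprintf("<spt_fit> model %s: %d chains x %d retained draws, %d subjects, %d trials\n",
              x$model, x$n_chains, x$n_draws, length(x$participants),
              x$data$n_trials))
  cat("group-level parameters:\n")
  print(utils::head(posterior_summary(x, group_only = TRUE), 15))
  invisible(x)
}

#' Posterior summary table
#'
#' Means, SDs and 95% HDIs per parameter, with split R-hat and effective
#' sample size.
#'
#' @param fit An `spt_fit`.
#' @param mass HDI mass (default 0.95).
#' @param group_only Drop subject-level parameters from the table.
#' @return Data.frame with one row per parameter.
#' @export
posterior_summary <- function(fit, mass = 0.95, group_only = FALSE) {
  stopifnot(inherits(fit, "spt_fit"))
  d <- fit$draws
  if (group_only) d <- d[, !grepl("\\[", colnames(d)), drop = FALSE]
  h <- apply(d, 2, hdi, mass = mass)
  out <- data.frame(parameter = colnames(d),
                    mean = colMeans(d),
                    sd = apply(d, 2, stats::sd),
                    hdi_lower = h[1, ], hdi_upper = h[2, ])
  conv <- check_convergence(fit)
  out <- merge(out, conv[c("parameter", "rhat", "ess")], by = "parameter",
               sort = FALSE)
  rownames(out) <- NULL
  out[match(colnames(d), out$parameter), ]
}
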