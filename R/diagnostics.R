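#' Highest density interval of a sample
#'
#' Shortest interval containing at least `mass` of the draws, computed by
#' the sorted sliding-window method: among all windows of
#' `ceiling(mass * n)` consecutive order statistics, the narrowest is
#' returned. Assumes a unimodal marginal (adequate for the posteriors this
#' package produces).
#'
#' @param samples Numeric vector of draws (>= 2 finite values unless
#'   `mass = 1` or all values equal).
#' @param mass Probability mass (default 0.95).
#' @return Numeric vector `c(lower, upper)` with attribute `mass`.
#' @examples
#' hdi(rnorm(1e4))  # roughly c(-1.96, 1.96)
#' @export
hdi <- function(samples, mass = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n == 0) stop("no finite samples supplied", call. = FALSE)
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]", call. = FALSE)
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) {
    out <- c(x[1], x[n])
  } else {
    starts <- seq_len(n - k + 1)
    widths <- x[starts + k - 1] - x[starts]
    i <- which.min(widths)
    out <- c(x[i], x[i + k - 1])
  }
  names(out) <- c("lower", "upper")
  attr(out, "mass") <- mass
  out
}

#' Widely applicable information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_i log mean_s exp(ll[s, i])` (evaluated stably via the
#' log-sum-exp trick), `p_waic = sum_i var_s(ll[s, i])`,
#' `waic = -2 * (lppd - p_waic)`. The standard error comes from the
#' trial-wise WAIC contributions.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws x trials.
#' @return An object of class `waic_result`: list with `lppd`, `p_waic`,
#'   `waic`, `se_waic`, `n_trials`, and the `pointwise` per-trial
#'   contributions (columns `lppd`, `p_waic`, `waic`).
#' @export
waic <- function(loglik) {
  if (!is.matrix(loglik) || nrow(loglik) < 2) {
    stop("loglik must be a draws x trials matrix with >= 2 draws",
         call. = FALSE)
  }
  if (any(!is.finite(loglik))) {
    stop("loglik contains non-finite values", call. = FALSE)
  }
  s <- nrow(loglik)
  mx <- apply(loglik, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx, "-"))))
  m1 <- colMeans(loglik)
  p_i <- colSums((loglik - rep(m1, each = s))^2) / (s - 1)
  waic_i <- -2 * (lppd_i - p_i)
  n <- length(lppd_i)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
                 se_waic = sqrt(n * stats::var(waic_i)), n_trials = n,
                 pointwise = data.frame(lppd = lppd_i, p_waic = p_i,
                                        waic = waic_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.1f (SE %.1f); lppd = %.1f, p_waic = %.1f, n = %d\n",
              x$waic, x$se_waic, x$lppd, x$p_waic, x$n_trials))
  invisible(x)
}

#' Compare two models by WAIC with a paired trial-wise standard error
#'
#' @param a,b `waic_result` objects computed on the same trials (same order).
#' @return List with `d_waic` (`a$waic - b$waic`; negative favours `a`) and
#'   `se_d_waic` from the paired per-trial differences.
#' @export
compare_waic <- function(a, b) {
  stopifnot(inherits(a, "waic_result"), inherits(b, "waic_result"))
  if (a$n_trials != b$n_trials) {
    stop("WAIC comparison requires the same trials", call. = FALSE)
  }
  d_i <- a$pointwise$waic - b$pointwise$waic
  list(d_waic = sum(d_i),
       se_d_waic = sqrt(length(d_i) * stats::var(d_i)))
}

# split-chain potential scale reduction factor; x is an iterations x chains
# matrix of one parameter's draws
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size by Geyer's initial monotone positive sequence,
# combined across chains
ess_mean <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  w <- mean(vars)
  means <- colMeans(x)
  var_plus <- (n - 1) / n * w + (if (m > 1) stats::var(means) else 0)
  if (var_plus == 0) return(n * m)
  lag_max <- min(n - 2, 1000)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(x[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  acov <- if (is.matrix(acov)) rowMeans(acov) else acov
  rho <- 1 - (w - acov[-1]) / var_plus
  # sum consecutive pairs while positive (initial positive sequence)
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  min(n * m, n * m / tau)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size per parameter, flagging parameters
#' with R-hat above the threshold. With a single chain R-hat cannot be
#' computed (a warning is raised and `NA` returned).
#'
#' @param fit An `spt_fit` from [fit_model()].
#' @param rhat_threshold Flagging threshold (default 1.05).
#' @return Data.frame with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
check_convergence <- function(fit, rhat_threshold = 1.05) {
  stopifnot(inherits(fit, "spt_fit"))
  chains <- sort(unique(fit$chain))
  single <- length(chains) < 2
  if (single) {
    warning("only one chain: R-hat omitted", call. = FALSE)
  }
  params <- colnames(fit$draws)
  per_chain <- lapply(chains, function(c) fit$draws[fit$chain == c, ,
                                                    drop = FALSE])
  res <- lapply(seq_along(params), function(j) {
    x <- sapply(per_chain, function(d) d[, j])
    if (!is.matrix(x)) x <- matrix(x, ncol = length(chains))
    data.frame(parameter = params[j],
               rhat = if (single) NA_real_ else split_rhat(x),
               ess = ess_mean(x))
  })
  out <- do.call(rbind, res)
  out$flagged <- !is.na(out$rhat) & out$rhat > rhat_threshold
  rownames(out) <- NULL
  out
}
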