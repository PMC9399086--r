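#' Write a trial table to comma-separated text
#'
#' Money columns are serialized with exactly two decimals, indicators as
#' signed integers; no locale-dependent formatting.
#'
#' @param trials Long trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(trials, path) {
  out <- trials
  for (col in intersect(c("gain", "loss", "guaranteed"), names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a trial table
#'
#' Reads a comma-separated long trial table, type-checks every column, and
#' rejects illegal indicator codes, malformed choices, or duplicate
#' (participant, trial) keys with row-level error messages.
#'
#' @param path Path to a CSV with header; required columns
#'   `participant_id`, `gain`, `loss`, `guaranteed`, `other`, `sharing`,
#'   `identity`; optional `choice` (0/1), `condition`, `block`,
#'   `trial_index`, `group`, `trial_type`, `p_gain`, `true_p`.
#' @return Validated data.frame; the reported row count is attached as
#'   attribute `n_rows`.
#' @export
load_choice_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "gain", "loss", "guaranteed", "other",
                "sharing", "identity")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s (first offending row: %d)", what, which(!ok)[1]),
           call. = FALSE)
    }
  }
  for (col in c("gain", "loss", "guaranteed")) {
    bad_row(is.finite(x[[col]]), paste0("non-numeric ", col))
    x[[col]] <- round_money(x[[col]])
  }
  bad_row(x$gain > 0, "gain must be > 0")
  bad_row(x$loss <= 0, "loss must be <= 0")
  bad_row(x$guaranteed >= 0, "guaranteed must be >= 0")
  bad_row(x$other %in% c(0, 1), "illegal 'other' indicator")
  bad_row(x$sharing %in% c(-1, 0, 1), "illegal 'sharing' indicator")
  bad_row(x$identity %in% c(-1, 0, 1), "illegal 'identity' indicator")
  bad_row((x$other == 0) == (x$sharing == 0) &
            (x$other == 0) == (x$identity == 0),
          "self trials must have all-zero indicators")
  if ("choice" %in% names(x)) {
    bad_row(x$choice %in% c(0, 1), "choice must be 0/1")
  }
  if ("trial_index" %in% names(x)) {
    key <- paste(x$participant_id, x$trial_index)
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate (participant, trial) key at row %d",
                   anyDuplicated(key)), call. = FALSE)
    }
  }
  attr(x, "n_rows") <- nrow(x)
  x
}

#' Default run configuration
#'
#' Full configuration of an end-to-end run: design sizes, generating
#' population, MCMC settings, and report options. Serialized as JSON into
#' the output directory for provenance.
#'
#' @param seed Master seed (flows to every stage via [split_seed()]).
#' @param n_stranger,n_friend Cohort sizes.
#' @param trials_per_condition Choice-set size per condition.
#' @param model Model variant to fit.
#' @param chains,warmup,draws MCMC budget.
#' @param effects_mode Generative mode for the synthetic cohort.
#' @param population Optional [population_config()] override.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_stranger = 29, n_friend = 28,
                       trials_per_condition = 90L, model = "M1",
                       chains = 4, warmup = 1000, draws = 500,
                       effects_mode = "model1_fixed", population = NULL) {
  if (is.null(population)) {
    population <- population_config(n_stranger = n_stranger,
                                    n_friend = n_friend, seed = seed)
  }
  stopifnot(inherits(population, "population_config"),
            model %in% c("M0", "M1", "M2"),
            effects_mode %in% c("model1_fixed", "model2_mixed"),
            chains >= 1, warmup >= 0, draws >= 2)
  structure(list(seed = as.integer(seed), n_stranger = n_stranger,
                 n_friend = n_friend,
                 trials_per_condition = trials_per_condition,
                 model = model, chains = chains, warmup = warmup,
                 draws = draws, effects_mode = effects_mode,
                 population = population),
            class = "run_config")
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$population <- unclass(x$population)
  x$population$true_social_effects <-
    as.list(unclass(x$population$true_social_effects))
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Generation -> simulation -> fitting -> reporting, writing every stage's
#' outputs (and the serialized configuration, seeds, and a log) into
#' `out_dir`. Rerunning with the same configuration reproduces the
#' simulation outputs exactly and the posterior summaries up to sampler
#' tolerance.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param progress Print stage progress.
#' @return Invisibly, a list with `trials`, `agents`, `fit`, `recovery`,
#'   `condition_means`, `correlations` and the output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
    if (progress) message(sprintf(...))
  }
  stage <- "configure"
  result <- tryCatch({
    cfg_json <- serialize_config(config)
    writeLines(cfg_json, file.path(out_dir, "config.json"))
    log_line("config hash %s seed %d",
             substr(digest_string(cfg_json), 1, 12), config$seed)

    stage <- "simulate"
    sim <- simulate_cohort(config$population, config$effects_mode,
                           trials_per_condition = config$trials_per_condition)
    write_choice_table(sim$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(sim$agents, file.path(out_dir, "agents.csv"),
                     row.names = FALSE)
    log_line("simulated %d trials for %d agents", nrow(sim$trials),
             nrow(sim$agents))

    stage <- "fit"
    fit <- fit_model(sim$trials, model = config$model,
                     chains = config$chains, warmup = config$warmup,
                     draws = config$draws,
                     seed = split_seed(config$seed, "fit", 0),
                     progress = progress)
    summ <- posterior_summary(fit)
    utils::write.csv(summ, file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    draws_long <- data.frame(chain = rep(fit$chain, ncol(fit$draws)),
                             iteration = rep(seq_len(fit$n_draws),
                                             fit$n_chains * ncol(fit$draws)),
                             parameter = rep(colnames(fit$draws),
                                             each = nrow(fit$draws)),
                             value = as.vector(fit$draws))
    utils::write.csv(draws_long, file.path(out_dir, "posterior_draws.csv"),
                     row.names = FALSE)
    log_line("fitted %s: %d chains x %d draws", config$model,
             config$chains, config$draws)

    stage <- "report"
    recov <- recovery_report(sim$agents, fit, config$population)
    utils::write.csv(recov$table, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    cm <- if (config$model == "M1") {
      implied_condition_means(draws = fit$draws)
    } else {
      implied_condition_means(
        parameter_set(log_rho = mean(fit$draws[, "mu_log_rho"]),
                      log_lam = mean(fit$draws[, "mu_log_lam"]),
                      log_mu = mean(fit$draws[, "mu_log_mu"])),
        config$population$true_social_effects * 0)
    }
    utils::write.csv(cm, file.path(out_dir, "condition_means.csv"),
                     row.names = FALSE)
    writeLines(condition_means_markdown(cm),
               file.path(out_dir, "condition_means.md"))
    corr <- if (config$model == "M2") {
      trait_names <- vapply(config$population$trait_spec, `[[`, "", "name")
      trait_correlations(subject_effect_estimates(fit),
                         sim$agents[c("participant_id", trait_names)])
    } else NULL
    if (!is.null(corr)) {
      utils::write.csv(corr, file.path(out_dir, "trait_correlations.csv"),
                       row.names = FALSE)
    }
    summary_json <- list(
      seed = config$seed, model = config$model,
      coverage = recov$coverage,
      waic = if (!is.null(fit$loglik)) unclass(waic(fit$loglik))[
        c("lppd", "p_waic", "waic", "se_waic")] else NULL)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("reports written; HDI coverage %.2f", recov$coverage)
    list(trials = sim$trials, agents = sim$agents, fit = fit,
         recovery = recov, condition_means = cm, correlations = corr,
         out_dir = out_dir)
  }, error = function(e) {
    log_line("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

# small dependency-free polynomial string hash (hex) for config provenance
digest_string <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x%04x", as.integer(h), length(bytes) %% 65536)
}

# render the implied-condition-means table as markdown
condition_means_markdown <- function(cm) {
  fmt <- function(v, lo, hi) {
    if (is.null(lo)) sprintf("%.2f", v)
    else sprintf("%.2f [%.2f, %.2f]", v, lo, hi)
  }
  rows <- vapply(seq_len(nrow(cm)), function(i) {
    has_hdi <- "rho_lower" %in% names(cm)
    sprintf("| %s | %s | %s | %s | %s |",
            cm$condition[i],
            ifelse(is.na(cm$identity_group[i]), "-", cm$identity_group[i]),
            fmt(cm$rho[i], if (has_hdi) cm$rho_lower[i], if (has_hdi) cm$rho_upper[i]),
            fmt(cm$lam[i], if (has_hdi) cm$lam_lower[i], if (has_hdi) cm$lam_upper[i]),
            fmt(cm$mu[i], if (has_hdi) cm$mu_lower[i], if (has_hdi) cm$mu_upper[i]))
  }, "")
  c("| condition | partner | rho | lambda | mu |",
    "|---|---|---|---|---|", rows)
}
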