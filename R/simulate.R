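# Synthetic dose-response generator and Monte-Carlo harnesses. The default
# scenario mirrors a replicated geometric dose series with an untreated
# control: CRS truth (c = 0, d = 100, b = 2, e = 10, f = 50, a = 1), doses
# {0, 0.1, 0.3, 1, 3, 10, 30, 100}, 5 replicates, Gaussian noise with
# per-dose SD proportional to the mean (5% of the control mean, floored at
# 1% of it) so that the inverse-SD weighting is exercised meaningfully.

#' Default simulation truth
#'
#' @return Named list: `family`, `params`, `doses`, `replicates`.
#' @export
sim_default_truth <- function() {
  list(family = "cedergreen",
       params = c(b = 2, c = 0, d = 100, e = 10, f = 50, a = 1),
       doses = c(0, 0.1, 0.3, 1, 3, 10, 30, 100),
       replicates = 5)
}

#' Generate a synthetic dose-response data set
#'
#' Draws `replicates` Gaussian observations per dose around the truth mean
#' curve. The per-dose SD is either supplied explicitly (`sd`, recycled over
#' dose levels) or proportional to the local mean (`cv` times the mean,
#' floored at `sd_floor_frac` of the control mean). Negative draws are
#' truncated to 0 — the measurement floor of a length endpoint — and
#' counted in the `truncated` attribute (a warning is raised if more than
#' 1% of observations were truncated).
#'
#' @param family,params Truth mean function, see [hm_mean()].
#' @param doses Dose levels; must include 0.
#' @param replicates Replicates per dose (>= 2 for inverse-SD weighting).
#' @param sd Optional explicit per-dose SD vector.
#' @param cv Proportionality constant of the SD to the local mean.
#' @param sd_floor_frac SD floor as a fraction of the control mean.
#' @param seed Optional integer seed for reproducibility.
#' @return A `dose_response` tibble with attribute `truncated`.
#' @export
#' @examples
#' d <- simulate_dose_response(seed = 1)
#' dose_summaries(d)
simulate_dose_response <- function(family = "cedergreen",
                                   params = c(b = 2, c = 0, d = 100, e = 10,
                                              f = 50, a = 1),
                                   doses = c(0, 0.1, 0.3, 1, 3, 10, 30, 100),
                                   replicates = 5,
                                   sd = NULL, cv = 0.05,
                                   sd_floor_frac = 0.01, seed = NULL) {
  if (!0 %in% doses) {
    hf_abort("The dose design must include an untreated control (dose 0).",
             "config_error")
  }
  if (replicates < 1) hf_abort("Need at least 1 replicate.", "config_error")
  if (!is.null(seed)) set.seed(seed)
  mu <- hm_mean(family, params, doses)
  d0 <- mu[doses == 0][1]
  sds <- if (!is.null(sd)) {
    rep_len(as.numeric(sd), length(doses))
  } else {
    pmax(cv * mu, sd_floor_frac * d0)
  }
  if (any(sds < 0)) hf_abort("Per-dose SDs must be >= 0.", "config_error")
  long <- tibble(
    dose = rep(doses, each = replicates),
    mu = rep(mu, each = replicates),
    sd = rep(sds, each = replicates),
    replicate = as.character(rep(seq_len(replicates), times = length(doses))))
  y <- rnorm(nrow(long), mean = long$mu, sd = long$sd)
  n_trunc <- sum(y < 0)
  y[y < 0] <- 0
  if (n_trunc > 0.01 * length(y)) {
    rlang::warn(sprintf("%d of %d observations truncated at 0 (> 1%%).",
                        n_trunc, length(y)))
  }
  out <- dose_response(tibble(dose = long$dose, response = y,
                              replicate = long$replicate),
                       replicate = "replicate")
  attr(out, "truncated") <- n_trunc
  out
}

# per-simulation seed scheme: base seed plus the simulation counter, kept
# inside the 32-bit integer range
hf_sim_seed <- function(seed, i) (as.integer(seed) + i) %% .Machine$integer.max

#' Coverage experiment for a reparameterized effective-dose estimate
#'
#' For each simulated data set: generate from the truth, attach weights,
#' fit the natural model, refit the reparameterized model for the target
#' quantity, and record whether its t confidence interval covers the true
#' functional (computed once from the truth parameters by the numeric
#' oracle) along with the relative estimation error. Simulations whose fits
#' fail are dropped and counted; more than 20% failures invalidates the
#' experiment.
#'
#' @param n_sims Number of simulated data sets.
#' @param quantity `"ED_K"`, `"LDS"` or `"M"`.
#' @param K Percent inhibition for `ED_K`.
#' @param level Confidence level.
#' @param truth Truth scenario, see [sim_default_truth()].
#' @param scheme Weighting scheme, see [compute_weights()].
#' @param a CRS shape handling for the fits (default: fixed at the truth
#'   value when the truth family is CRS, otherwise free).
#' @param cv,sd_floor_frac Noise settings of [simulate_dose_response()].
#' @param seed Base seed; simulation i uses `seed + i`.
#' @return List: `coverage` (fraction), `coverage_ci` (binomial 95% CI),
#'   `bias` (summary tibble of relative errors), `n_used`, `n_failed`,
#'   `truth_value`, `results` (per-simulation tibble).
#' @export
coverage_experiment <- function(n_sims = 300, quantity = "ED_K", K = 50,
                                level = 0.95, truth = sim_default_truth(),
                                scheme = "inverse_sd", a = NULL,
                                cv = 0.05, sd_floor_frac = 0.01, seed = 1) {
  quantity <- match.arg(quantity, c("ED_K", "LDS", "M"))
  if (quantity %in% c("M", "LDS") &&
      (truth$family == "loglogistic4" ||
         !isTRUE(unname(truth$params["f"]) > 0))) {
    hf_abort("M/LDS are undefined for a non-hormetic truth.", "no_hormesis")
  }
  tg <- if (quantity == "ED_K") target_quantity("ED_K", K = K) else
    target_quantity(quantity)
  truth_fun <- effective_doses_numeric(truth$family, truth$params,
                                       K = if (quantity == "ED_K") K else
                                         numeric(0))
  truth_value <- if (quantity == "ED_K") {
    truth_fun$value[truth_fun$quantity == "ED_K"]
  } else truth_fun$value[truth_fun$quantity == quantity]
  if (is.null(a)) {
    a <- if (truth$family == "cedergreen") unname(truth$params["a"]) else
      "auto"
  }
  spec <- build_reparam_model(truth$family, tg)
  tname <- tail(spec$par_names, 1)

  one <- function(i) {
    d <- simulate_dose_response(truth$family, truth$params, truth$doses,
                                truth$replicates, cv = cv,
                                sd_floor_frac = sd_floor_frac,
                                seed = hf_sim_seed(seed, i))
    d <- compute_weights(d, scheme = scheme)
    nat <- fit_hormesis(d, truth$family, a = a)
    fun <- effective_doses_numeric(truth$family, hm_natural_params(nat),
                                   K = if (quantity == "ED_K") K else
                                     numeric(0))
    start_val <- if (quantity == "ED_K") {
      fun$value[fun$quantity == "ED_K"]
    } else fun$value[fun$quantity == quantity]
    np <- hm_natural_params(nat)
    start <- c(np[setdiff(spec$par_names, tname)],
               setNames(start_val, tname))
    refit <- fit_hormesis(d, spec, start = start, a = a)
    ci <- wald_ci(refit, tname, level = level)
    tibble(sim = i, estimate = ci$estimate, se = ci$se,
           lower = ci$lower, upper = ci$upper,
           covered = ci$lower <= truth_value & truth_value <= ci$upper,
           rel_error = (ci$estimate - truth_value) / truth_value)
  }
  results <- purrr::map(seq_len(n_sims), function(i) {
    tryCatch(suppressWarnings(suppressMessages(one(i))),
             error = function(e) NULL)
  })
  failed <- sum(vapply(results, is.null, logical(1)))
  if (failed > 0.2 * n_sims) {
    hf_abort(sprintf("Experiment invalid: %d/%d fits failed.", failed,
                     n_sims), "experiment_invalid")
  }
  results <- dplyr::bind_rows(results)
  n_used <- nrow(results)
  cov <- mean(results$covered)
  ci <- as.numeric(stats::binom.test(sum(results$covered), n_used)$conf.int)
  list(coverage = cov, coverage_ci = ci,
       bias = tibble(median_rel_error = median(results$rel_error),
                     median_abs_rel_error = median(abs(results$rel_error)),
                     mean_rel_error = mean(results$rel_error)),
       n_used = n_used, n_failed = failed, truth_value = truth_value,
       results = results)
}

#' Type-I error of the hormesis test under a monotone truth
#'
#' Simulates from a monotone log-logistic truth (f = 0), fits a hormetic
#' family with free `f`, and records how often the CI-excludes-zero rule
#' declares hormesis. The Brain-Cousens family is the default vehicle: its
#' `f` stays identifiable when the true value is 0, whereas the CRS shape
#' exponent does not.
#'
#' @param n_sims Number of simulations.
#' @param fit_family Hormetic family fitted to each data set.
#' @param truth Monotone truth; default is the standard scenario with f
#'   removed (a four-parameter log-logistic).
#' @param level Confidence level of the test.
#' @inheritParams coverage_experiment
#' @return List: `rejection_rate`, `n_used`, `n_failed`, `results`.
#' @export
type1_experiment <- function(n_sims = 500, fit_family = "brain_cousens",
                             truth = NULL, level = 0.95,
                             scheme = "inverse_sd",
                             cv = 0.05, sd_floor_frac = 0.01, seed = 1) {
  if (is.null(truth)) {
    base <- sim_default_truth()
    truth <- list(family = "loglogistic4",
                  params = base$params[c("b", "c", "d", "e")],
                  doses = base$doses, replicates = base$replicates)
  }
  one <- function(i) {
    d <- simulate_dose_response(truth$family, truth$params, truth$doses,
                                truth$replicates, cv = cv,
                                sd_floor_frac = sd_floor_frac,
                                seed = hf_sim_seed(seed, i))
    d <- compute_weights(d, scheme = scheme)
    fit <- fit_hormesis(d, fit_family, a = 1)
    t <- hormesis_test(fit, level = level)
    tibble(sim = i, f = t$f_estimate, significant = t$significant)
  }
  results <- purrr::map(seq_len(n_sims), function(i) {
    tryCatch(suppressWarnings(suppressMessages(one(i))),
             error = function(e) NULL)
  })
  failed <- sum(vapply(results, is.null, logical(1)))
  if (failed > 0.2 * n_sims) {
    hf_abort(sprintf("Experiment invalid: %d/%d fits failed.", failed,
                     n_sims), "experiment_invalid")
  }
  results <- dplyr::bind_rows(results)
  list(rejection_rate = mean(results$significant),
       n_used = nrow(results), n_failed = failed, results = results)
}

#' Misspecification bias experiment
#'
#' Generates data from one hormetic family and fits the other, then
#' compares the fitted model's effective doses (extracted by the numeric
#' oracle) with the truth functionals. The qualitative pattern of interest:
#' bias concentrates on the hormetic-zone quantities (M, LDS) rather than
#' ED_50, and is largest when a broad-hormesis CRS truth (small shape
#' exponent a, wide M-LDS span) is forced through the Brain-Cousens form.
#'
#' @param n_sims Number of simulations.
#' @param truth Truth scenario (list with family, params, doses,
#'   replicates); default is a broad-hormesis CRS curve (a = 0.25).
#' @param fit_family Family fitted to each data set.
#' @param K ED_K level, default 50.
#' @inheritParams coverage_experiment
#' @return List: `summary` (median absolute relative bias per quantity),
#'   `results` (per-simulation tibble), `truth_values`, `n_failed`.
#' @export
misspecification_experiment <- function(n_sims = 100, truth = NULL,
                                        fit_family = "brain_cousens",
                                        K = 50, scheme = "inverse_sd",
                                        cv = 0.05, sd_floor_frac = 0.01,
                                        seed = 1) {
  if (is.null(truth)) {
    truth <- sim_default_truth()
    truth$params["a"] <- 0.25
  }
  if (n_sims == 0) {
    return(list(summary = tibble(quantity = character(), K = numeric(),
                                 median_abs_bias_pct = numeric()),
                results = tibble(), truth_values = NULL, n_failed = 0L))
  }
  truth_fun <- effective_doses_numeric(truth$family, truth$params, K = K)
  one <- function(i) {
    d <- simulate_dose_response(truth$family, truth$params, truth$doses,
                                truth$replicates, cv = cv,
                                sd_floor_frac = sd_floor_frac,
                                seed = hf_sim_seed(seed, i))
    d <- compute_weights(d, scheme = scheme)
    fit <- fit_hormesis(d, fit_family,
                        a = if (fit_family == "cedergreen") "auto" else
                          "free")
    fun <- effective_doses_numeric(fit_family, hm_natural_params(fit), K = K)
    key <- paste(truth_fun$quantity, truth_fun$K)
    m <- match(paste(fun$quantity, fun$K), key)
    tibble(sim = i, quantity = fun$quantity, K = fun$K,
           estimate = fun$value, truth = truth_fun$value[m],
           bias_pct = 100 * (fun$value - truth_fun$value[m]) /
             truth_fun$value[m])
  }
  results <- purrr::map(seq_len(n_sims), function(i) {
    tryCatch(suppressWarnings(suppressMessages(one(i))),
             error = function(e) NULL)
  })
  failed <- sum(vapply(results, is.null, logical(1)))
  if (failed > 0.2 * n_sims) {
    hf_abort(sprintf("Experiment invalid: %d/%d fits failed.", failed,
                     n_sims), "experiment_invalid")
  }
  results <- dplyr::bind_rows(results)
  summary <- results |>
    dplyr::group_by(.data$quantity, .data$K) |>
    dplyr::summarise(median_abs_bias_pct = median(abs(.data$bias_pct)),
                     median_bias_pct = median(.data$bias_pct),
                     .groups = "drop")
  list(summary = summary, results = results, truth_values = truth_fun,
       n_failed = failed)
}
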