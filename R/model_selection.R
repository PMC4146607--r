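# Model selection over the tree ensemble: fit the three candidate models on
# every tree, compute per-tree delta AICc relative to that tree's best
# model, and aggregate deltas, lambda, effect sizes and coefficients across
# trees. Coefficient CIs follow the estimate +/- 1.96 * SE convention, with
# SEs and estimates averaged over trees; a percentile alternative over
# per-tree estimates is available.

#' Run the three-model set over a tree ensemble
#'
#' For each tree, fits the null, mass-only and mass-by-environment
#' interaction models with ML lambda, computes AICc, and the per-tree
#' delta AICc (AICc minus the tree's best model's AICc; ties within 1e-12
#' broken towards the model with fewest parameters). Aggregates across
#' trees: per-model mean delta AICc and its 2.5/97.5 percentile interval,
#' mean lambda and mean likelihood-ratio effect size; per-coefficient mean
#' estimate, mean SE and 1.96-SE confidence interval; environment-specific
#' regression lines from the interaction model's aggregated coefficients.
#' Single-tree fit failures are recorded and excluded with a warning; more
#' than 5% failures is an error.
#'
#' @param table a `trait_table`.
#' @param ensemble a `multiPhylo` (or single `phylo`) sharing the table's
#'   species as tips.
#' @param response `"min"`, `"max"` or `"range"`.
#' @param effect_r_method passed to [fit_pgls()].
#' @param coef_ci `"se"` (mean estimate +/- 1.96 * mean SE, default) or
#'   `"percentile"` (2.5/97.5 percentiles of per-tree estimates).
#' @return object of class `ensemble_summary` with elements `models`
#'   (data.frame: model, delta_aicc_mean, delta CI, lambda_mean,
#'   effect_r_mean, equally_supported), `coefficients` (per-model
#'   data.frame: term, estimate, se, ci_low, ci_high), `lines`
#'   (environment, slope, intercept), `slope_diff_ci`, `intercept_diff_ci`,
#'   `best_model`, `fits` (per-tree log), `n_trees`, `n_failed`.
#' @export
run_model_set <- function(table, ensemble, response = "min",
                          effect_r_method = c("lr", "t"),
                          coef_ci = c("se", "percentile")) {
  effect_r_method <- match.arg(effect_r_method)
  coef_ci <- match.arg(coef_ci)
  if (inherits(ensemble, "phylo")) {
    ensemble <- structure(list(ensemble), class = "multiPhylo")
  }
  n_trees <- length(ensemble)
  if (n_trees < 1) stop("ensemble is empty")

  models <- .model_names  # null, mass_only, interaction
  fits <- vector("list", n_trees)
  failed <- logical(n_trees)
  for (i in seq_len(n_trees)) {
    fits[[i]] <- tryCatch({
      f0 <- fit_pgls(table, ensemble[[i]], response, "null", lambda = "ml")
      f1 <- fit_pgls(table, ensemble[[i]], response, "mass_only", lambda = "ml",
                     null_loglik = f0$loglik, effect_r_method = effect_r_method)
      f2 <- fit_pgls(table, ensemble[[i]], response, "interaction", lambda = "ml",
                     null_loglik = f0$loglik, effect_r_method = effect_r_method)
      list(null = f0, mass_only = f1, interaction = f2)
    }, error = function(e) e)
    failed[i] <- inherits(fits[[i]], "error")
  }
  if (any(failed)) {
    msgs <- vapply(fits[failed], conditionMessage, character(1))
    if (mean(failed) > 0.05)
      stop(sprintf("%d/%d tree fits failed (> 5%%); first error: %s",
                   sum(failed), n_trees, msgs[1]))
    warning(sprintf("%d/%d tree fits failed and were excluded; first error: %s",
                    sum(failed), n_trees, msgs[1]))
    fits <- fits[!failed]
  }
  n_used <- length(fits)

  per_tree <- do.call(rbind, lapply(seq_along(fits), function(i) {
    fl <- fits[[i]]
    ic <- vapply(fl, `[[`, numeric(1), "aicc")
    kv <- vapply(fl, `[[`, numeric(1), "k")
    best_ic <- min(ic)
    # tie-break: among models within 1e-12 of the minimum, fewest parameters
    tied <- ic - best_ic < 1e-12
    best <- names(fl)[tied][which.min(kv[tied])]
    data.frame(tree = i, model = names(fl),
               loglik = vapply(fl, `[[`, numeric(1), "loglik"),
               aicc = ic, delta_aicc = ic - best_ic,
               lambda = vapply(fl, `[[`, numeric(1), "lambda"),
               effect_r = vapply(fl, `[[`, numeric(1), "effect_r"),
               best = names(fl) == best,
               row.names = NULL)
  }))

  model_summ <- do.call(rbind, lapply(models, function(m) {
    d <- per_tree[per_tree$model == m, ]
    ci <- quantile(d$delta_aicc, c(0.025, 0.975), names = FALSE)
    data.frame(model = m,
               delta_aicc_mean = mean(d$delta_aicc),
               delta_aicc_ci_low = ci[1], delta_aicc_ci_high = ci[2],
               lambda_mean = mean(d$lambda),
               effect_r_mean = if (m == "null") NA_real_ else mean(d$effect_r),
               row.names = NULL)
  }))
  best_model <- model_summ$model[which.min(model_summ$delta_aicc_mean)]
  model_summ$equally_supported <-
    model_summ$delta_aicc_mean - min(model_summ$delta_aicc_mean) < 2

  coefs <- lapply(setNames(models, models), function(m) {
    B <- do.call(rbind, lapply(fits, function(fl) fl[[m]]$beta))
    S <- do.call(rbind, lapply(fits, function(fl) fl[[m]]$se))
    est <- colMeans(B)
    sem <- colMeans(S)
    if (coef_ci == "se") {
      lo <- est - 1.96 * sem
      hi <- est + 1.96 * sem
    } else {
      lo <- apply(B, 2, quantile, 0.025, names = FALSE)
      hi <- apply(B, 2, quantile, 0.975, names = FALSE)
    }
    data.frame(term = colnames(B), estimate = est, se = sem,
               ci_low = lo, ci_high = hi, row.names = NULL)
  })

  bi <- coefs$interaction
  est <- setNames(bi$estimate, bi$term)
  lines <- data.frame(
    environment = c("aquatic", "terrestrial"),
    slope = c(est[["log_mass"]],
              est[["log_mass"]] + est[["log_mass:env_terrestrial"]]),
    intercept = c(est[["(Intercept)"]],
                  est[["(Intercept)"]] + est[["env_terrestrial"]]))
  slope_row <- bi[bi$term == "log_mass:env_terrestrial", ]
  int_row <- bi[bi$term == "env_terrestrial", ]

  structure(list(response = response, models = model_summ,
                 best_model = best_model, coefficients = coefs,
                 lines = lines,
                 slope_diff_ci = c(low = slope_row$ci_low, high = slope_row$ci_high),
                 intercept_diff_ci = c(low = int_row$ci_low, high = int_row$ci_high),
                 fits = per_tree, n_trees = n_trees, n_failed = sum(failed)),
            class = "ensemble_summary")
}

#' Environment-specific regression lines from an interaction fit
#'
#' Under the aquatic = 0 / terrestrial = 1 coding, the aquatic line is
#' `(slope, intercept) = (b_mass, b_0)` and the terrestrial line
#' `(b_mass + b_interaction, b_0 + b_environment)`.
#'
#' @param fit a `pgls_fit` from the interaction model.
#' @return data.frame with columns `environment`, `slope`, `intercept`.
#' @export
environment_lines <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (fit$model != "interaction")
    stop("environment_lines() requires an interaction-model fit, got '",
         fit$model, "'")
  b <- fit$beta
  data.frame(
    environment = c("aquatic", "terrestrial"),
    slope = c(b[["log_mass"]], b[["log_mass"]] + b[["log_mass:env_terrestrial"]]),
    intercept = c(b[["(Intercept)"]], b[["(Intercept)"]] + b[["env_terrestrial"]]))
}

#' Confidence interval of the terrestrial-minus-aquatic slope difference
#'
#' The interaction coefficient's CI; environments differ significantly in
#' slope when the interval excludes 0. For an `ensemble_summary` the
#' aggregated CI is returned; for a single `pgls_fit` it is
#' `estimate +/- 1.96 * SE`.
#'
#' @param x an `ensemble_summary` or an interaction-model `pgls_fit`.
#' @return named numeric `c(low, high)` with attribute `significant`.
#' @export
slope_difference_ci <- function(x) {
  if (inherits(x, "ensemble_summary")) {
    ci <- x$slope_diff_ci
  } else if (inherits(x, "pgls_fit")) {
    if (x$model != "interaction")
      stop("slope_difference_ci() requires the interaction model")
    b <- x$beta[["log_mass:env_terrestrial"]]
    s <- x$se[["log_mass:env_terrestrial"]]
    ci <- c(low = b - 1.96 * s, high = b + 1.96 * s)
  } else stop("x must be an ensemble_summary or pgls_fit")
  attr(ci, "significant") <- ci[["low"]] > 0 || ci[["high"]] < 0
  ci
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("PGLS model set, response '%s', %d trees (%d failed)\n",
              x$response, x$n_trees, x$n_failed))
  df <- x$models
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(df, row.names = FALSE)
  cat(sprintf("best model: %s\n", x$best_model))
  cat("environment lines (interaction model):\n")
  print(transform(x$lines, slope = round(slope, 3),
                  intercept = round(intercept, 3)), row.names = FALSE)
  ci <- x$slope_diff_ci
  cat(sprintf("slope difference (terrestrial - aquatic) CI: (%.3f, %.3f)\n",
              ci[["low"]], ci[["high"]]))
  invisible(x)
}
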