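# Taxonomic variance-components decomposition: how much of the variance in
# (log10) prey mass is attributable to order, family, genus, predator mass
# and environment.
#
# Random intercepts for the nested taxonomic levels are estimated by ML
# with lme4; the two fixed covariates contribute Nakagawa-Schielzeth-style
# components, i.e. the variance over species of the term's fitted
# contribution (coefficient x covariate). The residual is computed and
# reported; percentages are over the model-based total
# (components + residual), optionally renormalized to the five named
# sources to mirror presentations that omit the residual row.

#' Decompose trait variance into taxonomic and ecological components
#'
#' Fits, by maximum likelihood, a linear mixed model with nested random
#' intercepts for order, family and genus and fixed effects of log10
#' predator mass and environment, then reports each source's variance
#' component and percent of total. Taxonomic nesting (each family within
#' one order, each genus within one family) is validated from the data.
#' Factors with a single level contribute 0 with a warning. A constant
#' response returns an all-zero decomposition.
#'
#' @param table a `trait_table`.
#' @param response `"min"`, `"max"` or `"range"`.
#' @param renormalize if `TRUE`, percentages are renormalized over the five
#'   named sources (order, family, genus, mass, environment), excluding the
#'   residual; components themselves are unchanged.
#' @return object of class `variance_decomposition`: `response`,
#'   `total_variance` (sum of components + residual), `components` (named
#'   numeric: order, family, genus, mass, environment, residual),
#'   `percents` (same names minus residual when renormalized).
#' @export
decompose_variance <- function(table, response = "min", renormalize = FALSE) {
  stopifnot(inherits(table, "trait_table"))
  col <- .response_col(response)
  keep <- is.finite(table[[col]])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " species with undefined ", col)
    table <- table[keep, , drop = FALSE]
  }
  y <- table[[col]]
  dat <- data.frame(
    y = y,
    log_mass = table$log_mass,
    env01 = as.numeric(table$environment == "terrestrial"),
    order = factor(table$order),
    family = factor(table$family),
    genus = factor(table$genus))

  # nesting must hold in the labels themselves (labels are globally unique
  # per level, so plain random intercepts encode the nested design)
  fam_orders <- tapply(as.character(dat$order), dat$family,
                       function(v) length(unique(v)))
  if (any(fam_orders > 1))
    stop("taxonomic nesting violated: family in more than one order: ",
         paste(names(fam_orders)[fam_orders > 1], collapse = ", "))
  gen_fams <- tapply(as.character(dat$family), dat$genus,
                     function(v) length(unique(v)))
  if (any(gen_fams > 1))
    stop("taxonomic nesting violated: genus in more than one family: ",
         paste(names(gen_fams)[gen_fams > 1], collapse = ", "))

  sources <- c("order", "family", "genus", "mass", "environment")
  comp <- setNames(numeric(6), c(sources, "residual"))
  if (var(y) == 0) {
    pct <- setNames(numeric(length(sources) + !renormalize),
                    if (renormalize) sources else names(comp))
    return(structure(list(response = response, total_variance = 0,
                          components = comp, percents = pct,
                          renormalized = renormalize),
                     class = "variance_decomposition"))
  }

  ranef_terms <- character(0)
  for (f in c("order", "family", "genus")) {
    if (nlevels(dat[[f]]) >= 2) {
      ranef_terms <- c(ranef_terms, sprintf("(1 | %s)", f))
    } else {
      warning("factor '", f, "' has a single level; its component is 0")
    }
  }
  fixed_terms <- c("log_mass")
  if (length(unique(dat$env01)) >= 2) {
    fixed_terms <- c(fixed_terms, "env01")
  } else {
    warning("environment has a single level; its component is 0")
  }
  if (length(ranef_terms) == 0)
    stop("no taxonomic factor has >= 2 levels; nothing to decompose")

  form <- stats::as.formula(paste("y ~", paste(c(fixed_terms, ranef_terms),
                                               collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(
    form, data = dat, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  for (f in c("order", "family", "genus")) {
    row <- vc$grp == f
    if (any(row)) comp[f] <- vc$vcov[row]
  }
  comp["residual"] <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  comp["mass"] <- var(fe[["log_mass"]] * dat$log_mass)
  if ("env01" %in% names(fe))
    comp["environment"] <- var(fe[["env01"]] * dat$env01)

  total <- sum(comp)
  pct <- if (renormalize) {
    100 * comp[sources] / sum(comp[sources])
  } else {
    100 * comp / total
  }
  structure(list(response = response, total_variance = total,
                 components = comp, percents = pct,
                 renormalized = renormalize),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance decomposition, response '%s' (total %.4f)\n",
              x$response, x$total_variance))
  df <- data.frame(source = names(x$components),
                   component = round(x$components, 4))
  df$percent <- round(x$percents[match(df$source, names(x$percents))], 2)
  print(df, row.names = FALSE)
  if (x$renormalized)
    cat("(percentages renormalized over the five named sources)\n")
  invisible(x)
}

#' Variance decompositions for several responses as one table
#'
#' @param table a `trait_table`.
#' @param responses subset of `c("min", "max", "range")`.
#' @inheritParams decompose_variance
#' @return long data.frame: response, source, component, percent.
#' @export
variance_table <- function(table, responses = c("min", "max", "range"),
                           renormalize = FALSE) {
  do.call(rbind, lapply(responses, function(r) {
    d <- decompose_variance(table, r, renormalize)
    src <- names(d$percents)
    data.frame(response = r, source = src,
               component = unname(d$components[src]),
               percent = unname(d$percents),
               total_variance = d$total_variance, row.names = NULL)
  }))
}
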