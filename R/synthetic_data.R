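# Synthetic-data generator: birth-death trees with optional soft
# polytomies, and trait tables drawn from the lambda-transformed Brownian
# regression model the analysis assumes, with taxonomy carved out of the
# tree itself. Defaults state the world of the reference analysis: 108
# species, a phylogenetically clustered aquatic clade (57/108 aquatic), a
# positive terrestrial and flat aquatic mass-prey slope, lambda 0.62, unit
# residual rate on a unit-height tree.

#' Simulation configuration
#'
#' Collects every knob of the generator with the defaults used throughout
#' the package's recovery tests.
#'
#' @param n_species number of tips.
#' @param birth,death birth-death rates per lineage per unit time.
#' @param polytomy_fraction share of non-root internal nodes collapsed into
#'   soft polytomies.
#' @param tree_scale root height the simulated tree is rescaled to; with
#'   height 1, `sigma2` is the residual trait variance accumulated
#'   root-to-tip.
#' @param beta0,beta_mass,beta_env,beta_interaction generative coefficients
#'   of `log_prey_min` on `[1, log_mass, env, log_mass x env]` with
#'   aquatic = 0 / terrestrial = 1.
#' @param lambda_true generative Pagel's lambda in `[0, 1]`.
#' @param sigma2 residual Brownian rate (> 0).
#' @param mass_mean,mass_sd mean/SD of log10 predator mass (log10 kg).
#' @param aquatic_fraction target share of aquatic species.
#' @param env_assignment `"clade"` (default; the clade whose size best
#'   matches `aquatic_fraction` is marked aquatic, mimicking cetaceans +
#'   pinnipeds being clades) or `"random"` (iid Bernoulli).
#' @param tax_cut_rel node ages (as fractions of tree height) at which the
#'   tree is sliced to define order/family/genus labels.
#' @param offset_a,offset_b,offset_sd,offset_floor the positive log10
#'   offset `log_prey_max - log_prey_min` is
#'   `max(offset_floor, offset_a + offset_b * log_mass + N(0, offset_sd))`,
#'   guaranteeing `prey_max > prey_min`.
#' @param seed master integer seed.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 108, birth = 1, death = 0.5,
                       polytomy_fraction = 0.15, tree_scale = 1,
                       beta0 = -2.96, beta_mass = -0.03, beta_env = -0.34,
                       beta_interaction = 1.16, lambda_true = 0.62,
                       sigma2 = 1, mass_mean = 1, mass_sd = 1.25,
                       aquatic_fraction = 57 / 108,
                       env_assignment = c("clade", "random"),
                       tax_cut_rel = c(order = 0.75, family = 0.5, genus = 0.25),
                       offset_a = 0.5, offset_b = 0.15, offset_sd = 0.25,
                       offset_floor = 0.05, seed = 1L) {
  env_assignment <- match.arg(env_assignment)
  stopifnot(n_species >= 3, birth >= 0, death >= 0, birth > 0,
            polytomy_fraction >= 0, polytomy_fraction <= 1,
            tree_scale > 0, lambda_true >= 0, lambda_true <= 1, sigma2 > 0,
            mass_sd > 0, aquatic_fraction > 0, aquatic_fraction < 1,
            length(tax_cut_rel) == 3, all(tax_cut_rel > 0),
            all(tax_cut_rel < 1), all(diff(tax_cut_rel) < 0),
            offset_sd >= 0, offset_floor > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a dated tree with optional soft polytomies
#'
#' Draws a birth-death tree conditioned on `n_species` surviving tips,
#' rescales it to root height `tree_scale`, then collapses
#' `polytomy_fraction` of its non-root internal nodes into their parents
#' (tip depths preserved) to create soft polytomies. Complete extinction
#' or a degenerate draw is retried with an incremented seed (at most 20
#' times).
#'
#' @param config a [sim_config()].
#' @return ultrametric `phylo`, binary iff `polytomy_fraction` selected no
#'   node.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- NULL
  for (try in 0:20) {
    set.seed(as.integer(config$seed) + try)
    tr <- tryCatch(ape::rphylo(config$n_species, config$birth, config$death),
                   error = function(e) NULL)
    if (!is.null(tr)) break
  }
  if (is.null(tr)) stop("tree simulation failed after 20 retries")
  tr$edge.length <- tr$edge.length * config$tree_scale / tree_height(tr)
  if (config$polytomy_fraction > 0)
    tr <- collapse_to_polytomies(tr, config$polytomy_fraction)
  tr
}

# clade-based environment assignment: mark as aquatic the clade whose tip
# count is closest to the target fraction (ties towards the larger clade)
.assign_env_clade <- function(tree, fraction) {
  ntip <- length(tree$tip.label)
  target <- fraction * ntip
  clades <- ape::prop.part(tree)
  sizes <- lengths(clades)
  inner <- which(sizes < ntip)  # exclude the root clade (all tips)
  if (!length(inner)) return(sample(ntip, round(target)))
  best <- inner[order(abs(sizes[inner] - target), -sizes[inner])][1]
  clades[[best]]
}

# taxonomy from the tree: a tip's label at a cut age is the child node of
# the branch crossing that age on its root path
.cut_groups <- function(tree, cut_age) {
  ntip <- length(tree$tip.label)
  age <- node_ages(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(ntip), function(t) {
    v <- t
    while (parent[v] != 0 && age[parent[v]] < cut_age) v <- parent[v]
    if (parent[v] == 0) v else v  # root reached: its own group
  }, integer(1))
}

#' Simulate a trait table on a tree
#'
#' Draws log10 predator mass iid normal, assigns environment (clade-based
#' by default), slices the tree at the configured relative ages to obtain
#' nested order/family/genus labels, and generates
#' `y = log_prey_min = X beta + e` with
#' `e ~ MVN(0, sigma2 * V(lambda_true))` on (a random binary resolution of)
#' the tree. `log_prey_max` is `y` plus a strictly positive mass-dependent
#' offset. Species are named `Gen<k>_sp<i>` so the genus equals the first
#' name token; the returned table carries the relabeled tree as attribute
#' `"phylogeny"` (and its binary resolution as `"phylogeny_binary"`).
#'
#' @param tree a `phylo` from [simulate_tree()] (or any ultrametric tree
#'   with `n_species` tips).
#' @param config a [sim_config()].
#' @return a `trait_table` with attributes `phylogeny`, `phylogeny_binary`
#'   and `generative` (the true beta/lambda/sigma2 used).
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  tree_b <- if (nrow(find_polytomies(tree)) > 0)
    resolve_polytomies(tree, 1, seed = as.integer(config$seed) + 1000L)[[1]]
  else tree
  set.seed(as.integer(config$seed) + 2000L)

  log_mass <- rnorm(n, config$mass_mean, config$mass_sd)
  aq_tips <- if (config$env_assignment == "clade")
    .assign_env_clade(tree_b, config$aquatic_fraction)
  else which(as.logical(rbinom(n, 1, config$aquatic_fraction)))
  if (length(aq_tips) == 0 || length(aq_tips) == n)
    aq_tips <- sample(n, max(1, round(config$aquatic_fraction * n)))
  env <- rep("terrestrial", n)
  env[aq_tips] <- "aquatic"

  # nested taxonomy labels from cuts of the binary tree (order: oldest cut)
  h <- tree_height(tree_b)
  grp <- lapply(config$tax_cut_rel * h, .cut_groups, tree = tree_b)
  ord_id <- as.integer(factor(grp[[1]], levels = unique(grp[[1]])))
  fam_id <- as.integer(factor(grp[[2]], levels = unique(grp[[2]])))
  gen_id <- as.integer(factor(grp[[3]], levels = unique(grp[[3]])))
  genus <- sprintf("Gen%d", gen_id)
  sp_idx <- stats::ave(gen_id, gen_id, FUN = seq_along)
  species <- sprintf("%s_sp%d", genus, sp_idx)

  env01 <- as.numeric(env == "terrestrial")
  X <- cbind(1, log_mass, env01, log_mass * env01)
  beta <- c(config$beta0, config$beta_mass, config$beta_env,
            config$beta_interaction)
  V <- phylo_covariance(tree_b)  # tip-label order
  Vl <- apply_lambda(V, config$lambda_true)
  e <- drop(crossprod(chol(config$sigma2 * Vl), rnorm(n)))
  y <- drop(X %*% beta) + e

  offset <- pmax(config$offset_floor,
                 config$offset_a + config$offset_b * log_mass +
                   rnorm(n, 0, config$offset_sd))
  df <- data.frame(
    species = species,
    order = sprintf("Ord%d", ord_id),
    family = sprintf("Fam%d", fam_id),
    genus = genus,
    environment = env,
    predator_mass = 10^log_mass,
    prey_min = 10^y,
    prey_max = 10^(y + offset))

  relabel <- function(tr) {
    tr$tip.label <- species[match(tr$tip.label, tree_b$tip.label)]
    tr
  }
  tree_out <- tree
  tree_out$tip.label <- species[match(tree_out$tip.label, tree_b$tip.label)]
  tab <- trait_table(df)
  attr(tab, "phylogeny") <- tree_out
  attr(tab, "phylogeny_binary") <- relabel(tree_b)
  attr(tab, "generative") <- list(beta = beta, lambda = config$lambda_true,
                                  sigma2 = config$sigma2,
                                  residuals = e, design = X)
  tab
}

#' Simulate a complete dataset (tree + traits)
#'
#' Convenience wrapper: [simulate_tree()] then [simulate_traits()], tips
#' and species names consistent.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (possibly polytomous, species-labeled),
#'   `tree_binary`, `traits` (a `trait_table`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tr <- simulate_tree(config)
  tab <- simulate_traits(tr, config)
  list(tree = attr(tab, "phylogeny"),
       tree_binary = attr(tab, "phylogeny_binary"),
       traits = tab, config = config)
}
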