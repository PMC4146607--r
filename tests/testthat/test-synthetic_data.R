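test_that("simulated trees are dated, sized and optionally polytomous", {
  cfg <- sim_config(n_species = 40, polytomy_fraction = 0, seed = 41)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 40)
  expect_true(ape::is.binary(tr))
  expect_equal(tr$Nnode, 39)  # n - 1 internal nodes when binary
  expect_true(is_ultrametric(tr, 1e-8))
  expect_equal(tree_height(tr), 1, tolerance = 1e-10)
  # Yule case
  tr_y <- simulate_tree(sim_config(n_species = 25, death = 0, seed = 42,
                                   polytomy_fraction = 0))
  expect_gt(tree_height(tr_y), 0)
  expect_true(is_ultrametric(tr_y, 1e-8))
  # polytomies appear when requested
  tr_p <- simulate_tree(sim_config(n_species = 40, polytomy_fraction = 0.3,
                                   seed = 43))
  expect_gt(nrow(find_polytomies(tr_p)), 0)
})

test_that("noise-free traits lie exactly on the generating plane", {
  cfg <- sim_config(n_species = 30, sigma2 = 1e-14, polytomy_fraction = 0,
                    seed = 44)
  d <- simulate_dataset(cfg)
  gen <- attr(d$traits, "generative")
  fitted <- drop(gen$design %*% gen$beta)
  expect_lt(max(abs(d$traits$log_prey_min - fitted)), 1e-6)
  expect_true(all(d$traits$prey_max > d$traits$prey_min))
})

test_that("same config gives identical output; taxonomy is nested", {
  cfg <- sim_config(n_species = 35, seed = 45, polytomy_fraction = 0.2)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1$traits), as.data.frame(d2$traits))
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  tab <- d1$traits
  # each family within one order, each genus within one family
  expect_true(all(tapply(tab$order, tab$family,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(tab$family, tab$genus,
                         function(v) length(unique(v))) == 1))
  # both environments present; aquatic species form a clade by default
  expect_setequal(unique(tab$environment), c("aquatic", "terrestrial"))
  aq <- tab$species[tab$environment == "aquatic"]
  expect_true(ape::is.monophyletic(d1$tree_binary, aq))
})

test_that("replicate residuals reproduce sigma2 * V(lambda) on a fixed tree", {
  base <- sim_config(n_species = 10, polytomy_fraction = 0, seed = 50,
                     lambda_true = 0.6, sigma2 = 0.5)
  tr <- simulate_tree(base)
  nrep <- 2000
  E <- matrix(NA_real_, nrep, 10)
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_species = 10, polytomy_fraction = 0,
                      seed = 100000 + i, lambda_true = 0.6, sigma2 = 0.5)
    E[i, ] <- attr(simulate_traits(tr, cfg), "generative")$residuals
  }
  target <- apply_lambda(0.5 * phylo_covariance(tr), 0.6)
  emp <- crossprod(E) / nrep
  mc_se <- sqrt((outer(diag(target), diag(target)) + target^2) / nrep)
  expect_true(all(abs(emp - target) <= 3.5 * mc_se))
})

test_that("lambda 0 gives phylogeny-free residuals (sister pairs uncorrelated)", {
  base <- sim_config(n_species = 12, polytomy_fraction = 0, seed = 60,
                     lambda_true = 0, sigma2 = 1)
  tr <- simulate_tree(base)
  # find one sister tip pair
  V <- phylo_covariance(tr)
  nrep <- 800
  r1 <- numeric(nrep)
  r2 <- numeric(nrep)
  pair <- which(V == max(V - diag(diag(V))), arr.ind = TRUE)[1, ]
  for (i in seq_len(nrep)) {
    cfg <- sim_config(n_species = 12, polytomy_fraction = 0,
                      seed = 200000 + i, lambda_true = 0, sigma2 = 1)
    e <- attr(simulate_traits(tr, cfg), "generative")$residuals
    r1[i] <- e[pair[1]]
    r2[i] <- e[pair[2]]
  }
  expect_lt(abs(cor(r1, r2)), 3.5 / sqrt(nrep))
})

test_that("random environment assignment is available", {
  cfg <- sim_config(n_species = 40, env_assignment = "random", seed = 61)
  tab <- simulate_dataset(cfg)$traits
  expect_setequal(unique(tab$environment), c("aquatic", "terrestrial"))
})
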