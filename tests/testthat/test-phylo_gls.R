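test_that("phylo_covariance matches the MRCA-depth definition", {
  V <- phylo_covariance(tree3(), c("A", "B", "C"))
  expect_equal(unname(V), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  # star tree: d * I
  Vs <- phylo_covariance(star_tree(4, d = 3))
  expect_equal(unname(Vs), diag(3, 4))
  # independent MRCA-depth oracle on a random tree
  set.seed(2)
  tr <- ape::rcoal(12)
  V2 <- phylo_covariance(tr)
  depth <- ape::node.depth.edgelength(tr)
  for (pair in list(c(1, 5), c(2, 9), c(3, 3), c(7, 12))) {
    i <- pair[1]; j <- pair[2]
    m <- if (i == j) i else ape::getMRCA(tr, c(i, j))
    expect_equal(V2[tr$tip.label[i], tr$tip.label[j]], depth[m],
                 tolerance = 1e-12)
  }
  # row order follows species_order
  ord <- rev(tr$tip.label)
  expect_equal(phylo_covariance(tr, ord), V2[ord, ord])
  expect_error(phylo_covariance(tr, c(tr$tip.label[-1], "nope")), "nope")
})

test_that("lambda transform scales off-diagonals only and validates input", {
  V <- rbind(c(2, 1), c(1, 2))
  expect_equal(apply_lambda(V, 1), V)
  expect_equal(apply_lambda(V, 0), diag(c(2, 2)))
  expect_equal(apply_lambda(V, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_error(apply_lambda(V, -0.1), "lambda")
  expect_error(apply_lambda(V, 1.5), "lambda")
})

test_that("gls_fit matches closed-form and dense-solve oracles", {
  # intercept-only hand example: beta0 = 2, ML sigma2 = 2/3
  f <- gls_fit(c(1, 2, 3), matrix(1, 3, 1), diag(3))
  expect_equal(unname(f$beta), 2)
  expect_equal(f$sigma2, 2 / 3)
  # random problems against the independent dense-solve oracle
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n)
    A <- matrix(rnorm(n * n), n)
    V <- crossprod(A) + diag(n)
    f <- gls_fit(y, X, V)
    o <- gls_oracle(y, X, V)
    expect_equal(f$beta, o$beta, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(f$se, o$se, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(f$loglik, o$loglik, tolerance = 1e-9)
  }
  expect_error(gls_fit(rnorm(5), cbind(1, rep(2, 5)), diag(5)),
               "rank deficient")
})

test_that("GLS with identity covariance reduces exactly to OLS", {
  set.seed(3)
  n <- 50
  X <- cbind(1, rnorm(n), runif(n))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  f <- gls_fit(drop(y), X, diag(n))
  ols <- lm.fit(X, y)
  expect_lt(max(abs(f$beta - ols$coefficients) / abs(ols$coefficients)), 1e-8)
})

test_that("AICc follows the closed form", {
  expect_equal(aicc(-5, 3, 10), 16 + 24 / 6)  # AIC 16, correction 4
  expect_equal(aicc(0, 2, 100), 4 + 12 / 97)
  expect_error(aicc(0, 9, 10), "undefined")
})

test_that("ML lambda attains the profile maximum (1001-point grid oracle)", {
  d <- quick_sim(n = 30, seed = 21, lambda_true = 0.6)
  fit <- fit_pgls(d$traits, d$tree_binary, "min", "interaction")
  tab <- d$traits
  y <- tab$log_prey_min
  X <- preyscale:::design_matrix(tab, "interaction")
  V <- phylo_covariance(d$tree_binary, tab$species)
  grid_ll <- vapply(seq(0, 1, length.out = 1001),
                    function(l) gls_fit(y, X, apply_lambda(V, l))$loglik,
                    numeric(1))
  expect_gte(fit$loglik, max(grid_ll) - 1e-3)
  expect_true(fit$lambda >= 0 && fit$lambda <= 1)
})

test_that("on a star tree lambda has no effect on the fit", {
  set.seed(8)
  star <- star_tree(20, d = 1)
  df <- data.frame(
    species = paste0("Gt", 1:20), order = "O1", family = "F1",
    genus = "Gt", environment = rep(c("aquatic", "terrestrial"), 10),
    predator_mass = 10^rnorm(20), prey_min = 10^rnorm(20),
    prey_max = 10^(rnorm(20) + 3))
  df$species <- paste0("Gt_", 1:20)  # genus token must match
  df$genus <- "Gt"
  tab <- trait_table(df)
  star$tip.label <- tab$species
  f0 <- fit_pgls(tab, star, "min", "mass_only", lambda = 0)
  f1 <- fit_pgls(tab, star, "min", "mass_only", lambda = 1)
  expect_equal(f0$beta, f1$beta, tolerance = 1e-8)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("nested models never lose likelihood at a common fixed lambda", {
  d <- quick_sim(n = 35, seed = 4)
  for (lam in c(0, 0.5, 1)) {
    ll <- vapply(c("null", "mass_only", "interaction"), function(m)
      fit_pgls(d$traits, d$tree_binary, "min", m, lambda = lam)$loglik,
      numeric(1))
    expect_true(ll["interaction"] >= ll["mass_only"] - 1e-9)
    expect_true(ll["mass_only"] >= ll["null"] - 1e-9)
  }
})

test_that("k convention and effect size conventions are applied", {
  d <- quick_sim(n = 30, seed = 5)
  f_ml <- fit_pgls(d$traits, d$tree_binary, "min", "interaction")
  expect_equal(f_ml$k, 4 + 1 + 1)
  f_fix <- fit_pgls(d$traits, d$tree_binary, "min", "interaction", lambda = 0.5)
  expect_equal(f_fix$k, 4 + 1)
  expect_equal(f_ml$aicc, aicc(f_ml$loglik, f_ml$k, f_ml$n))
  # lr-based effect size needs the null loglik; t-based does not
  f0 <- fit_pgls(d$traits, d$tree_binary, "min", "null")
  f_lr <- fit_pgls(d$traits, d$tree_binary, "min", "mass_only",
                   null_loglik = f0$loglik)
  expect_equal(f_lr$effect_r,
               sqrt(1 - exp((2 / f_lr$n) * (f0$loglik - f_lr$loglik))))
  f_t <- fit_pgls(d$traits, d$tree_binary, "min", "mass_only",
                  effect_r_method = "t")
  tstat <- f_t$beta[["log_mass"]] / f_t$se[["log_mass"]]
  expect_equal(f_t$effect_r, sqrt(tstat^2 / (tstat^2 + f_t$n - 2)))
})

test_that("rows with undefined log range are dropped with the tree pruned", {
  d <- quick_sim(n = 12, seed = 22)
  df <- as.data.frame(d$traits)[, preyscale:::.raw_cols]
  df$prey_max[1] <- df$prey_min[1]
  tab <- suppressWarnings(trait_table(df))
  expect_message(f <- fit_pgls(tab, d$tree_binary, "range", "mass_only"),
                 "dropping 1")
  expect_equal(f$n, 11)
})
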