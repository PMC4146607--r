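# Shared fixtures: a small hand-written trait table, tiny Newick trees, and
# an independent dense-algebra GLS oracle used to cross-check the Cholesky
# fitting path.

make_traits_df <- function() {
  data.frame(
    species = c("Canis_lupus", "Canis_latrans", "Felis_catus",
                "Orcinus_orca", "Phoca_vitulina", "Balaena_mysticetus"),
    order = c("Carnivora", "Carnivora", "Carnivora",
              "Cetacea", "Carnivora", "Cetacea"),
    family = c("Canidae", "Canidae", "Felidae",
               "Delphinidae", "Phocidae", "Balaenidae"),
    genus = c("Canis", "Canis", "Felis", "Orcinus", "Phoca", "Balaena"),
    environment = c("terrestrial", "terrestrial", "terrestrial",
                    "aquatic", "aquatic", "aquatic"),
    predator_mass = c(40, 13, 4, 4000, 90, 80000),
    prey_min = c(0.5, 0.02, 0.005, 1, 0.05, 0.0005),
    prey_max = c(500, 20, 1, 2000, 5, 0.005),
    stringsAsFactors = FALSE)
}

make_traits <- function() suppressWarnings(trait_table(make_traits_df()))

# ((A:1,B:1):1,C:2); — the canonical 3-tip dated tree of the examples
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# star tree on k tips, depth d
star_tree <- function(k = 5, d = 1) {
  ape::read.tree(text = paste0(
    "(", paste0("t", seq_len(k), ":", d, collapse = ","), ");"))
}

# dense-solve GLS oracle, independent of the package's Cholesky path
gls_oracle <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- drop(solve(XtViX, t(X) %*% Vi %*% y))
  e <- y - X %*% beta
  quad <- drop(t(e) %*% Vi %*% e)
  sigma2 <- quad / n
  loglik <- -(n / 2) * log(2 * pi * sigma2) -
    as.numeric(determinant(V, logarithm = TRUE)$modulus) / 2 - n / 2
  se <- sqrt(quad / (n - ncol(X)) * diag(solve(XtViX)))
  list(beta = beta, se = se, sigma2 = sigma2, loglik = loglik)
}

# quick simulated dataset for tests, small by default
quick_sim <- function(n = 40, seed = 1, ...) {
  simulate_dataset(sim_config(n_species = n, seed = seed, ...))
}
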