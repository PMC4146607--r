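# Dated-tree handling: Newick I/O, pruning, polytomy detection and
# stochastic resolution into ensembles of binary dated trees.
#
# Trees are ape "phylo" objects throughout; ensembles are "multiPhylo" with a
# "seeds" attribute recording the per-tree RNG seed. The source trees are
# dated (branch lengths in time), so every operation is required to preserve
# ultrametricity within a relative tolerance: published supertrees carry
# rounding error, hence the default tau = 1e-6 * tree height.

#' Read trees from a Newick file
#'
#' One tree per line; a single-tree file yields a `phylo`, a multi-tree file
#' a `multiPhylo`. Internal node labels are kept if present.
#'
#' @param path path to a Newick file.
#' @return `phylo` or `multiPhylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("no trees could be parsed from ", path)
  tr
}

#' Write trees to a Newick file
#'
#' @param tree `phylo` or `multiPhylo`.
#' @param path output path; multi-tree input is written one tree per line.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Tree height (maximum root-to-tip path length)
#' @param tree a `phylo`.
#' @return numeric scalar.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

# node ages measured from the tips (height - depth from root)
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_along(tree$tip.label)]) - depth
}

#' Check ultrametricity within a relative tolerance
#'
#' @param tree a `phylo` with branch lengths.
#' @param tol_rel tolerance as a fraction of tree height (default `1e-6`).
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree, tol_rel = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  h <- max(d)
  if (h <= 0) return(TRUE)
  (max(d) - min(d)) <= tol_rel * h
}

#' Validate a dated phylogeny
#'
#' Checks rootedness, branch lengths, unique tip labels and ultrametricity
#' within `tol_rel`. Zero-length terminal branches are permitted but
#' reported via message.
#'
#' @inheritParams is_ultrametric
#' @return the tree, invisibly; errors describe the violated invariant.
#' @export
validate_phylogeny <- function(tree, tol_rel = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  # ape calls a tree with a basal multifurcation unrooted; for dated trees a
  # basal soft polytomy is a legitimate root, so accept it when ultrametric
  if (!ape::is.rooted(tree) && !is_ultrametric(tree, tol_rel))
    stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths present")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is_ultrametric(tree, tol_rel))
    stop("tree is not ultrametric within tolerance ", tol_rel, " * height")
  term <- tree$edge[, 2] <= length(tree$tip.label)
  nz <- tree$edge.length[term] == 0
  if (any(nz))
    message(sum(nz), " zero-length terminal branch(es) present")
  invisible(tree)
}

#' Prune a phylogeny to a species set
#'
#' Keeps exactly the `keep` tips; internal nodes left with a single child
#' are suppressed with their branch lengths summed, so root-to-tip depths of
#' retained tips are unchanged.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain (normalized with
#'   [normalize_species()]).
#' @return pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  keep <- normalize_species(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, keep)
}

#' Find polytomies
#'
#' @param tree a `phylo`.
#' @return data.frame with columns `node` (internal node id) and `degree`
#'   (number of children, > 2); zero rows for a binary tree.
#' @export
find_polytomies <- function(tree) {
  cnt <- tabulate(tree$edge[, 1], nbins = length(tree$tip.label) + tree$Nnode)
  nodes <- which(cnt > 2)
  data.frame(node = nodes, degree = cnt[nodes])
}

# one random dated resolution: within each polytomy, repeatedly join two
# children chosen uniformly at random at an age drawn uniformly between the
# older child's age and the polytomy node's age. Ages of pre-existing nodes
# are untouched, so ultrametricity and tip depths are preserved.
resolve_once <- function(tree) {
  ntip <- length(tree$tip.label)
  age <- node_ages(tree)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(list(str = tree$tip.label[v], age = age[v]))
    items <- lapply(ch, rec)
    while (length(items) > 2L) {
      pick <- sample.int(length(items), 2L)
      a <- items[[pick[1]]]
      b <- items[[pick[2]]]
      lo <- max(a$age, b$age)
      u <- if (age[v] > lo) runif(1, lo, age[v]) else lo
      s <- paste0("(", a$str, ":", fmt(u - a$age), ",",
                  b$str, ":", fmt(u - b$age), ")")
      items <- c(items[-pick], list(list(str = s, age = u)))
    }
    s <- paste0("(",
                paste0(vapply(items, function(it)
                  paste0(it$str, ":", fmt(age[v] - it$age)), character(1)),
                  collapse = ","),
                ")")
    list(str = s, age = age[v])
  }
  ape::read.tree(text = paste0(rec(root)$str, ";"))
}

#' Resolve polytomies into an ensemble of binary dated trees
#'
#' Each ensemble member independently randomizes both the local topology
#' within every polytomy (sequential random joins, uniform over pairs) and
#' the ages of the inserted nodes (uniform between the older joined child's
#' age and the polytomy's age), so the resolved subtrees remain dated and no
#' branch is negative. Tip set and ages of all pre-existing nodes are
#' preserved. A binary input yields `n_trees` identical copies.
#'
#' @param tree a rooted ultrametric `phylo` (tolerance `tol_rel`).
#' @param n_trees ensemble size (>= 1); the reference analysis used 1,000.
#' @param seed integer seed; member i uses seed `seed + i - 1`, recorded in
#'   the `seeds` attribute. Same seed, bit-identical Newick output.
#' @param tol_rel ultrametricity tolerance passed to [validate_phylogeny()].
#' @return `multiPhylo` of binary ultrametric trees with attribute `seeds`.
#' @export
resolve_polytomies <- function(tree, n_trees, seed = 1L, tol_rel = 1e-6) {
  if (!is.numeric(n_trees) || length(n_trees) != 1 || n_trees < 1)
    stop("n_trees must be a single integer >= 1")
  n_trees <- as.integer(n_trees)
  validate_phylogeny(tree, tol_rel)
  seeds <- as.integer(seed) + seq_len(n_trees) - 1L
  poly <- find_polytomies(tree)
  trees <- if (nrow(poly) == 0L) {
    rep(list(tree), n_trees)
  } else {
    lapply(seeds, function(s) {
      set.seed(s)
      resolve_once(tree)
    })
  }
  class(trees) <- "multiPhylo"
  attr(trees, "seeds") <- seeds
  trees
}

#' Collapse random internal nodes into soft polytomies
#'
#' Each selected non-root internal node is contracted into its parent: its
#' children are reattached to the parent with their branch lengths increased
#' by the removed edge's length, preserving all tip depths. Used by the
#' simulator to emulate the soft polytomies of published supertrees. Uses
#' the current RNG state.
#'
#' @param tree a binary `phylo`.
#' @param fraction share of non-root internal nodes to collapse, in `[0, 1]`.
#' @return a `phylo`, polytomous if `fraction > 0` selected any node.
#' @export
collapse_to_polytomies <- function(tree, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cand <- setdiff((ntip + 1L):(ntip + tree$Nnode), root)
  k <- round(fraction * length(cand))
  if (k == 0L) return(tree)
  sel <- sample(cand, k)
  depth <- ape::node.depth.edgelength(tree)
  sel <- sel[order(depth[sel])]  # contract top-down so nested picks compose
  edge <- tree$edge
  el <- tree$edge.length
  for (v in sel) {
    epar <- which(edge[, 2] == v)
    ce <- which(edge[, 1] == v)
    el[ce] <- el[ce] + el[epar]
    el[epar] <- 0
  }
  tree$edge.length <- el
  ape::di2multi(tree, tol = tree_height(tree) * 1e-12)
}
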