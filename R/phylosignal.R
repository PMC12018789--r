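#' @title Blomberg's K phylogenetic signal with a randomization test
#'
#' @description Blomberg's K compares the variance structure of a trait on a
#'   phylogeny with its Brownian-motion expectation: K = 1 matches Brownian
#'   motion, K > 1 indicates stronger-than-expected conservation, K near 0 a
#'   weak signal. Significance is assessed by shuffling trait values across
#'   tips. Tree utilities cover Newick I/O, pruning, tip renaming and
#'   genus-level tip addition for species missing from a dated reference
#'   tree (branch lengths in million years).
#'
#' @name phylosignal
NULL

#' Read a Newick tree with branch lengths
#'
#' @param source Newick text or a file path
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(source) {
  phy <- if (file.exists(source)) ape::read.tree(source)
  else ape::read.tree(text = source)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  phy
}

#' Prune a tree to a tip set
#'
#' Retains exactly the requested tips, collapsing unary nodes and summing
#' branch lengths, so patristic distances among retained tips are preserved.
#'
#' @param phy an [ape::phylo] tree
#' @param tips character vector of tip labels to keep
#' @return pruned tree
#' @export
prune_tree <- function(phy, tips) {
  missing <- setdiff(tips, phy$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(phy, tips)
}

#' Rename tips via an explicit map
#'
#' @param phy an [ape::phylo] tree
#' @param map named character vector, `old_label = "new_label"`
#' @return relabelled tree
#' @export
rename_tips <- function(phy, map) {
  hit <- phy$tip.label %in% names(map)
  phy$tip.label[hit] <- unname(map[phy$tip.label[hit]])
  if (anyDuplicated(phy$tip.label)) stop("renaming created duplicate tips")
  phy
}

.genus_of <- function(labels) vapply(strsplit(labels, "[ _]"), `[`, "", 1)

#' Add a species to a tree at the genus level
#'
#' Attaches a new tip for `species` at the root node of its genus clade
#' (with two or more congeners) or at the midpoint of the single congener's
#' terminal branch, choosing the new terminal branch length so the new tip
#' reaches the depth of its sister group; on ultrametric inputs the tree
#' stays ultrametric. The genus is the first whitespace- or
#' underscore-delimited token of the tip label.
#'
#' @param phy an [ape::phylo] tree
#' @param species binomial label of the species to add
#' @return tree with the extra tip; unchanged if the species is present
#' @export
add_tip_to_genus <- function(phy, species) {
  if (species %in% phy$tip.label) return(phy)
  genus <- .genus_of(species)
  cong <- which(.genus_of(phy$tip.label) == genus)
  if (length(cong) == 0)
    stop("no congeneric tip in tree for species: ", species)
  tip_tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = species, edge.length = 0,
                             Nnode = 1L), class = "phylo")
  depths <- ape::node.depth.edgelength(phy)
  if (length(cong) == 1) {
    e <- which(phy$edge[, 2] == cong)
    half <- phy$edge.length[e] / 2
    tip_tree$edge.length <- half
    out <- ape::bind.tree(phy, tip_tree, where = cong, position = half)
  } else {
    node <- ape::getMRCA(phy, phy$tip.label[cong])
    tip_tree$edge.length <- mean(depths[cong]) - depths[node]
    out <- ape::bind.tree(phy, tip_tree, where = node, position = 0)
  }
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' `V[i, j]` is the branch length shared by the root-to-tip paths of tips i
#' and j (the depth of their most recent common ancestor); the diagonal
#' holds tip depths.
#'
#' Any tree is interpreted as rooted at its root node, so star phylogenies
#' (a basal polytomy joining all tips) are valid input.
#'
#' @param phy an [ape::phylo] tree with branch lengths
#' @return symmetric positive semi-definite matrix with tip labels as
#'   dimnames
#' @export
phylo_vcv <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  n <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  anc <- ape::mrca(phy)                   # n x n matrix of MRCA node ids
  V <- matrix(depths[anc], n, n, dimnames = list(phy$tip.label, phy$tip.label))
  diag(V) <- depths[seq_len(n)]
  V
}

# K statistic given precomputed pieces; x must be ordered like V
.k_stat <- function(x, Vi, expected_ratio, n) {
  ahat <- sum(Vi %*% x) / sum(Vi)
  dev <- x - ahat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(t(dev) %*% Vi %*% dev) / (n - 1)
  (mse0 / mse) / expected_ratio
}

#' Blomberg's K
#'
#' Observed over expected ratio of the trait mean squared error (about the
#' phylogenetically corrected mean) to the phylogenetically corrected mean
#' squared error:
#' `K = (MSE0 / MSE) / ((trace(V) - n / sum(V^-1)) / (n - 1))`, with the
#' phylogenetic mean `ahat = (1' V^-1 1)^-1 1' V^-1 x`. Equals 1 exactly on
#' any star phylogeny and on average for Brownian-motion traits.
#'
#' @param phy a rooted tree with branch lengths
#' @param trait named numeric vector over the tips (names matched to tip
#'   labels)
#' @return the K statistic (numeric scalar)
#' @export
blombergs_k <- function(phy, trait) {
  V <- phylo_vcv(phy)
  n <- nrow(V)
  if (is.null(names(trait))) {
    if (length(trait) != n) stop("trait length must match number of tips")
    names(trait) <- rownames(V)
  }
  if (!all(rownames(V) %in% names(trait)))
    stop("trait missing for some tips")
  x <- trait[rownames(V)]
  if (var(x) == 0) stop("constant trait")
  Vi <- solve(V)
  expected_ratio <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  .k_stat(x, Vi, expected_ratio, n)
}

#' Randomization test for Blomberg's K
#'
#' Shuffles trait values across tips `n_perm` times and reports
#' `p = (1 + #(K_perm >= K_obs)) / (n_perm + 1)`, a one-sided test for the
#' presence of phylogenetic signal.
#'
#' @inheritParams blombergs_k
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed recorded in the result
#' @return object of class `ifc_kresult`: `k_observed`, `p_value`,
#'   `n_permutations`, `perm_summary` (mean and quantiles of the permuted
#'   K), `seed`
#' @export
#' @examples
#' tr <- ape::rcoal(20)
#' x <- simulate_bm_trait(tr, 1, seed = 2)
#' k_randomization_test(tr, x, n_perm = 99, seed = 3)
k_randomization_test <- function(phy, trait, n_perm = 1000, seed = 1) {
  V <- phylo_vcv(phy)
  n <- nrow(V)
  if (is.null(names(trait))) {
    if (length(trait) != n) stop("trait length must match number of tips")
    names(trait) <- rownames(V)
  }
  x <- trait[rownames(V)]
  if (var(x) == 0) stop("constant trait")
  Vi <- solve(V)
  expected_ratio <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  k_obs <- .k_stat(x, Vi, expected_ratio, n)
  set.seed(seed)
  k_perm <- vapply(seq_len(n_perm), function(i)
    .k_stat(sample(x), Vi, expected_ratio, n), 0)
  p <- (1 + sum(k_perm >= k_obs)) / (n_perm + 1)
  structure(list(k_observed = k_obs, p_value = p, n_permutations = n_perm,
                 perm_summary = c(mean = mean(k_perm),
                                  quantile(k_perm, c(0.5, 0.95, 0.99))),
                 seed = seed), class = "ifc_kresult")
}

#' @export
print.ifc_kresult <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$k_observed, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
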