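# Edge-by-tip incidence of a tree: E[e, t] is TRUE when tip t descends from
# edge e. Built once per (pruned) tree; every branch-length classification is
# then a matrix product. The root stem (tree$root.edge), if any, is not part
# of the edge matrix and is therefore dropped, per the PhyloSor convention.
edge_tip_incidence <- function(tree) {
  tre <- stats::reorder(tree, "postorder")
  n_tip <- length(tre$tip.label)
  n_edge <- nrow(tre$edge)
  desc <- vector("list", n_tip + tre$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  E <- matrix(0, n_edge, n_tip, dimnames = list(NULL, tre$tip.label))
  for (k in seq_len(n_edge)) { # postorder: children resolved before parents
    par <- tre$edge[k, 1L]
    ch <- tre$edge[k, 2L]
    E[k, desc[[ch]]] <- 1
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  list(E = E, lengths = tre$edge.length, tips = tre$tip.label)
}

#' Shared and unique branch lengths of a site pair
#'
#' Classifies each branch of the tree by whether at least one descendant tip
#' belongs to each community, and sums branch lengths into the phylogenetic
#' matching components: `a` on the root-to-tip paths of both communities,
#' `b` of the first only, `c` of the second only. The tree should already be
#' pruned to the regional species pool; tips outside both communities simply
#' contribute no exclusive branches.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param comm1,comm2 character vectors of species (tree tips).
#' @return named numeric vector `c(a =, b =, c =)` in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' branch_components(tr, c("A", "B"), c("C", "D"))  # a=0 b=3 c=3
#' @export
branch_components <- function(tree, comm1, comm2) {
  tree <- validate_tree(tree, allow_basal_polytomy = TRUE)
  missing <- setdiff(c(comm1, comm2), tree$tip.label)
  if (length(missing))
    stop(sprintf("species not on the tree: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  inc <- edge_tip_incidence(tree)
  in1 <- (inc$E %*% (inc$tips %in% comm1)) > 0
  in2 <- (inc$E %*% (inc$tips %in% comm2)) > 0
  c(a = sum(inc$lengths[in1 & in2]),
    b = sum(inc$lengths[in1 & !in2]),
    c = sum(inc$lengths[!in1 & in2]))
}

# Edge-presence matrix (edges x sites) for a community matrix on the pooled
# tree, plus per-site total path lengths. Shared by the observed computation
# and the label-shuffle null (which only permutes the tip -> species map).
phylo_presence <- function(inc, m, tip_species) {
  P <- (inc$E %*% t(m[, tip_species, drop = FALSE]) > 0) * 1
  P
}

phylo_triplets <- function(inc, P) {
  wP <- P * inc$lengths
  A <- crossprod(wP, P) # A[i,j] = summed length of branches present at both
  tot <- colSums(wP)
  idx <- pair_index(ncol(P))
  a <- A[idx]
  sorensen_triplet(a, tot[idx[, 1L]] - a, tot[idx[, 2L]] - a)
}

# Prune the tree to the regional pool (union of species over all sites).
pool_tree <- function(cm, tree, drop_unmatched = FALSE) {
  cm <- match_species_pool(cm, tree$tip.label, "tree tip", drop_unmatched)
  pool <- species(cm)[colSums(cm) > 0]
  if (length(pool) < 2L)
    stop("need at least 2 species present somewhere to prune the tree",
         call. = FALSE)
  list(cm = cm, tree = ape::keep.tip(tree, pool))
}

#' Pairwise phylogenetic beta-diversity table
#'
#' The PhyloSor-family analogue of [beta_matrix_taxonomic()]: matching
#' components are shared/unique branch lengths on the tree pruned to the
#' regional pool (every species present at one or more sites), fed through
#' the same turnover/nestedness decomposition.
#'
#' @param cm a [community_matrix].
#' @param tree rooted `phylo` with branch lengths covering every species
#'   present in `cm`.
#' @param empty_pair policy for pairs with one empty assemblage, as in
#'   [beta_matrix_taxonomic()].
#' @param drop_unmatched prune species missing from the tree (with a logged
#'   list) instead of erroring.
#' @return `pairwise_beta` data.frame with branch-length components
#'   `a_bl, b_bl, c_bl`.
#' @export
beta_matrix_phylo <- function(cm, tree, empty_pair = c("exclude", "as_one"),
                              drop_unmatched = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  pt <- pool_tree(cm, validate_tree(tree, allow_basal_polytomy = TRUE),
                  drop_unmatched)
  m <- unclass(pt$cm)
  inc <- edge_tip_incidence(pt$tree)
  P <- phylo_presence(inc, m, inc$tips)
  wP <- P * inc$lengths
  A <- crossprod(wP, P)
  tot <- colSums(wP)
  idx <- pair_index(nrow(m))
  a <- A[idx]
  b <- tot[idx[, 1L]] - a
  c <- tot[idx[, 2L]] - a
  trip <- sorensen_triplet(a, b, c)
  r <- rowSums(m)
  assemble_beta_table(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]],
                      list(a, b, c), c("a_bl", "b_bl", "c_bl"), trip,
                      empty_i = r[idx[, 1L]] == 0, empty_j = r[idx[, 2L]] == 0,
                      empty_pair = empty_pair, dimension = "phylogenetic")
}

#' Average phylogenetic beta-diversity over a tree distribution
#'
#' For analyses based on a posterior or pseudo-posterior sample of trees
#' (identical tip sets), computes the pairwise table on every tree and
#' returns per-pair arithmetic means of each index plus across-tree standard
#' deviations (`beta_*_sd`). With a single tree this degenerates to
#' [beta_matrix_phylo()] with zero sd columns.
#'
#' @param cm a [community_matrix].
#' @param trees list of rooted `phylo` objects with identical tip sets.
#' @inheritParams beta_matrix_phylo
#' @return `pairwise_beta` data.frame (components averaged as well).
#' @export
multi_tree_summary <- function(cm, trees, empty_pair = c("exclude", "as_one"),
                               drop_unmatched = FALSE) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  tips <- sort(trees[[1L]]$tip.label)
  for (tr in trees[-1L])
    if (!identical(sort(tr$tip.label), tips))
      stop("trees must share an identical tip set", call. = FALSE)
  tabs <- lapply(trees, function(tr)
    beta_matrix_phylo(cm, tr, empty_pair = empty_pair,
                      drop_unmatched = drop_unmatched))
  out <- tabs[[1L]]
  cols <- c("a_bl", "b_bl", "c_bl", "beta_sim", "beta_sne", "beta_sor")
  stacks <- lapply(cols, function(cl)
    sapply(tabs, function(tb) tb[[cl]]))
  names(stacks) <- cols
  for (cl in cols) out[[cl]] <- rowMeans(as.matrix(stacks[[cl]]))
  for (cl in c("beta_sim", "beta_sne", "beta_sor")) {
    s <- as.matrix(stacks[[cl]])
    out[[paste0(cl, "_sd")]] <-
      if (ncol(s) == 1L) ifelse(is.na(s[, 1L]), NA_real_, 0)
      else apply(s, 1L, stats::sd)
  }
  attr(out, "n_trees") <- length(trees)
  out
}

#' Blomberg's K phylogenetic signal
#'
#' K compares the observed ratio of trait variance (around the phylogenetic
#' mean) to its Brownian-motion contrast variance against the ratio expected
#' under BM on the given tree; K = 1 matches the BM expectation, K < 1
#' indicates weaker signal. Significance comes from permuting trait values
#' across tips.
#'
#' With trait vector x, phylogenetic variance-covariance matrix V (shared
#' branch length to the root) and phylogenetic mean
#' a = (1'V^-1 x)/(1'V^-1 1):
#' `MSE0 = (x-a)'(x-a)/(n-1)`, `MSE = (x-a)'V^-1(x-a)/(n-1)`,
#' `K = (MSE0/MSE) / E[MSE0/MSE]` with
#' `E[MSE0/MSE] = (tr(V) - n/(1'V^-1 1))/(n-1)`.
#'
#' @param tree rooted `phylo` with branch lengths, >= 4 tips.
#' @param trait named numeric vector, one value per tip.
#' @param n_perm number of tip permutations for the p-value (0 skips the
#'   permutation test).
#' @param seed optional seed for the permutations.
#' @return list of class `blomberg_k`: `K`, `p` (proportion of permutations
#'   with an observed-variance ratio at least as large, `(1+count)/(1+n_perm)`),
#'   `n_perm`, `obs_ratio`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  tree <- validate_tree(tree, allow_basal_polytomy = TRUE)
  n <- length(tree$tip.label)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips", call. = FALSE)
  if (is.null(names(trait)))
    stop("trait vector must be named by tip label", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop(sprintf("trait missing for tip(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  x <- trait[tree$tip.label]
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e)
    stop(paste0("tree variance-covariance matrix is singular (zero-length ",
                "cherries collapse tips); resolve or minimally extend ",
                "zero-length branches"), call. = FALSE))
  ones <- rep(1, n)
  denom <- sum(Vi)
  ratio <- function(x) {
    ahat <- sum(Vi %*% x) / denom
    d <- x - ahat
    sum(d * d) / drop(crossprod(d, Vi %*% d))
  }
  obs <- ratio(x)
  expected <- (sum(diag(V)) - n / denom) / (n - 1)
  K <- obs / expected
  p <- NA_real_
  if (n_perm > 0) {
    perm_fn <- function() {
      hits <- 0L
      for (i in seq_len(n_perm)) if (ratio(sample(x)) >= obs) hits <- hits + 1L
      hits
    }
    hits <- if (is.null(seed)) perm_fn() else withr::with_seed(seed, perm_fn())
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(K = K, p = p, n_perm = n_perm, obs_ratio = obs, n_tips = n),
            class = "blomberg_k")
}

#' @export
print.blomberg_k <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f (%d tips)", x$K, x$n_tips))
  if (!is.na(x$p)) cat(sprintf(", permutation p = %.4g (%d permutations)",
                               x$p, x$n_perm))
  cat("\n")
  invisible(x)
}
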