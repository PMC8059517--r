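# All randomizations are performed on a canonically ordered copy of the
# input (sites and species sorted by id) and mapped back, so that identical
# seeds give identical draws regardless of the row/column order of the
# matrix the user happens to pass in.
canonical_order <- function(cm) {
  list(site = order(rownames(cm)), sp = order(colnames(cm)))
}

# One or several richness-preserving draws: each site keeps its richness and
# fills it with species drawn equiprobably without replacement from the pool.
draw_richness_preserving <- function(ms) {
  out <- matrix(0, nrow(ms), ncol(ms), dimnames = dimnames(ms))
  ns <- ncol(ms)
  r <- rowSums(ms)
  for (i in seq_len(nrow(ms)))
    if (r[i] > 0) out[i, sample.int(ns, r[i])] <- 1
  out
}

has_checkerboard <- function(m) {
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- m[i, ] > m[j, ]
    v <- m[j, ] > m[i, ]
    if (any(u) && any(v)) return(TRUE)
  }
  FALSE
}

#' Null-model randomization of community data
#'
#' Three schemes feed the standardized-effect-size machinery:
#' \describe{
#'   \item{`richness_preserving_draw`}{each site keeps its observed richness;
#'     species are drawn equiprobably without replacement from the pool.}
#'   \item{`fixed_fixed_swap`}{sequential 2x2 checkerboard swaps preserving
#'     both row (richness) and column (occupancy) sums, via
#'     `vegan::nullmodel(, "swap")`; defaults 10000 burn-in swaps then one
#'     matrix every 1000 swaps. Margin preservation is asserted on every
#'     returned matrix.}
#'   \item{`label_shuffle`}{the community matrix is untouched; the species
#'     labels of the phylogeny's tips, or the species-to-coordinate
#'     assignment of a trait space, are permuted (within the species that
#'     actually carry tips/coordinates).}
#' }
#' Draws are taken in a canonical (sorted) site/species order and mapped
#' back, so results are invariant to the input ordering.
#'
#' @param cm a [community_matrix].
#' @param scheme randomization scheme id.
#' @param seed mandatory integer seed.
#' @param n number of randomizations to return.
#' @param burnin,thin swap-scheme burn-in and thinning (in swaps).
#' @param tree,trait_space the object to relabel under `label_shuffle`.
#' @return for the matrix schemes, a `community_matrix` (or list of them
#'   when `n > 1`); for `label_shuffle`, the relabeled tree / trait space
#'   (or list of them).
#' @export
randomize <- function(cm, scheme = c("richness_preserving_draw",
                                     "fixed_fixed_swap", "label_shuffle"),
                      seed, n = 1, burnin = 10000, thin = 1000,
                      tree = NULL, trait_space = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cm, "community_matrix"), is.numeric(seed))
  ord <- canonical_order(cm)
  ms <- unclass(cm)[ord$site, ord$sp, drop = FALSE]
  back_site <- order(ord$site)
  back_sp <- order(ord$sp)
  wrap <- function(x) community_matrix(x[back_site, back_sp, drop = FALSE])

  if (scheme == "richness_preserving_draw") {
    res <- withr::with_seed(seed,
      lapply(seq_len(n), function(i) draw_richness_preserving(ms)))
    res <- lapply(res, wrap)
    return(if (n == 1L) res[[1L]] else res)
  }

  if (scheme == "fixed_fixed_swap") {
    if (!has_checkerboard(ms))
      stop("matrix has no swappable 2x2 checkerboard submatrix", call. = FALSE)
    sim <- stats::simulate(vegan::nullmodel(ms, "swap"), nsim = n,
                           thin = thin, burnin = burnin, seed = seed)
    res <- lapply(seq_len(n), function(k) {
      mk <- sim[, , k]
      dimnames(mk) <- dimnames(ms)
      stopifnot(identical(rowSums(mk), rowSums(ms)),
                identical(colSums(mk), colSums(ms)))
      wrap(mk)
    })
    return(if (n == 1L) res[[1L]] else res)
  }

  # label_shuffle
  if (is.null(tree) && is.null(trait_space))
    stop("label_shuffle needs a `tree` or a `trait_space` to relabel",
         call. = FALSE)
  if (!is.null(tree)) {
    tree <- validate_tree(tree, allow_basal_polytomy = TRUE)
    pool <- sort(intersect(tree$tip.label, colnames(ms)))
  } else {
    pool <- sort(intersect(rownames(trait_space$scores), colnames(ms)))
  }
  if (length(pool) < 2L) stop("fewer than 2 shuffleable species", call. = FALSE)
  perms <- withr::with_seed(seed,
    lapply(seq_len(n), function(i) stats::setNames(sample(pool), pool)))
  res <- lapply(perms, function(pm) {
    if (!is.null(tree)) {
      tr2 <- tree
      hit <- tr2$tip.label %in% pool
      tr2$tip.label[hit] <- unname(pm[tr2$tip.label[hit]])
      tr2
    } else {
      ts2 <- trait_space
      rn <- rownames(ts2$scores)
      hit <- rn %in% pool
      rn[hit] <- unname(pm[rn[hit]])
      rownames(ts2$scores) <- rn
      ts2
    }
  })
  if (n == 1L) res[[1L]] else res
}

#' Standardized effect sizes of pairwise beta-diversity
#'
#' For every computable site pair and every member of the decomposition
#' (`sim`, `sne`, `sor`), compares the observed dissimilarity with its
#' distribution over `n_rand` null randomizations:
#' `SES = (observed - null mean) / null sd`. Negative SES means less
#' dissimilar than expected under the null (an environmental-filtering
#' signature); positive means more (limiting similarity).
#'
#' Default schemes: the taxonomic null is `fixed_fixed_swap` (conserves both
#' richness and occupancy, the conservative community null); phylogenetic
#' and functional nulls are `label_shuffle` with the community matrix fixed,
#' isolating tree/trait structure. The scheme used is recorded in every
#' output row and is freely overridable.
#'
#' @param cm a [community_matrix].
#' @param dimension which beta-diversity dimension to standardize.
#' @param n_rand number of randomizations (>= 99).
#' @param scheme randomization scheme; `NULL` picks the dimension default.
#' @param seed mandatory integer seed; the run is fully reproducible from
#'   `(scheme, seed, n_rand)`.
#' @param tree rooted `phylo` (phylogenetic dimension).
#' @param trait_space a [build_trait_space()] result (functional dimension).
#' @param min_richness functional minimum community size (see
#'   [beta_matrix_functional()]).
#' @param burnin,thin swap-scheme tuning, passed to [randomize()].
#' @return data.frame of class `ses_table` with columns `site_i, site_j,
#'   index, observed, null_mean, null_sd, ses, n_rand, scheme, seed` and a
#'   `dimension` attribute. Pairs whose null sd is 0 keep `ses = NA`
#'   (flagged, not dropped).
#' @export
ses_beta <- function(cm, dimension = c("taxonomic", "phylogenetic", "functional"),
                     n_rand = 999, scheme = NULL, seed,
                     tree = NULL, trait_space = NULL, min_richness = 3,
                     burnin = 10000, thin = 1000) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(cm, "community_matrix"), is.numeric(seed))
  if (n_rand < 99) stop("n_rand must be >= 99", call. = FALSE)
  scheme <- scheme %||% switch(dimension,
                               taxonomic = "fixed_fixed_swap",
                               "label_shuffle")
  scheme <- match.arg(scheme, c("richness_preserving_draw", "fixed_fixed_swap",
                                "label_shuffle"))

  ord <- canonical_order(cm)
  ms <- unclass(cm)[ord$site, ord$sp, drop = FALSE]

  # observed + per-randomization triplets via the dimension's engine
  if (dimension == "taxonomic") {
    obs <- tax_triplets(ms)
    engine <- function(mat) tax_triplets(mat)
  } else if (dimension == "phylogenetic") {
    if (is.null(tree)) stop("phylogenetic SES needs `tree`", call. = FALSE)
    pt <- pool_tree(community_matrix(ms), tree)
    ms <- unclass(pt$cm)
    tree <- pt$tree # shuffles permute labels within the pooled tree's tips
    inc <- edge_tip_incidence(tree)
    obs <- phylo_triplets(inc, phylo_presence(inc, ms, inc$tips))
    engine <- function(x) { # x: relabeled pooled tree or randomized matrix
      if (inherits(x, "phylo"))
        # same topology and edge order: only the tip -> species map moved
        phylo_triplets(inc, phylo_presence(inc, ms, x$tip.label))
      else phylo_triplets(inc, phylo_presence(inc, x, inc$tips))
    }
  } else {
    if (is.null(trait_space)) stop("functional SES needs `trait_space`", call. = FALSE)
    cm2 <- match_species_pool(community_matrix(ms), rownames(trait_space$scores),
                              "trait-space coordinate")
    ms <- unclass(cm2)
    ftrip <- function(scores, mat) {
      ft <- func_triplets(site_hulls(mat, scores, min_richness))
      sorensen_triplet(ft$a, ft$b, ft$c)
    }
    obs <- ftrip(trait_space$scores, ms)
    engine <- function(x) {
      if (inherits(x, "trait_space")) ftrip(x$scores, ms)
      else ftrip(trait_space$scores, x)
    }
  }
  idx <- pair_index(nrow(ms))
  site_i <- rownames(ms)[idx[, 1L]]
  site_j <- rownames(ms)[idx[, 2L]]

  draws <- randomize(community_matrix(ms), scheme = scheme, seed = seed,
                     n = n_rand, burnin = burnin, thin = thin,
                     tree = if (dimension == "phylogenetic") tree,
                     trait_space = if (dimension == "functional") trait_space)

  np <- nrow(idx)
  indices <- c("sim", "sne", "sor")
  s1 <- s2 <- cnt <- matrix(0, np, 3L, dimnames = list(NULL, indices))
  for (r in seq_len(n_rand)) {
    tr <- engine(if (inherits(draws[[r]], "community_matrix"))
                   unclass(draws[[r]]) else draws[[r]])
    vals <- cbind(tr$beta_sim, tr$beta_sne, tr$beta_sor)
    ok <- is.finite(vals)
    vals[!ok] <- 0
    s1 <- s1 + vals
    s2 <- s2 + vals^2
    cnt <- cnt + ok
  }
  null_mean <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  null_var <- ifelse(cnt > 1, (s2 - cnt * null_mean^2) / (cnt - 1), NA_real_)
  null_sd <- sqrt(pmax(null_var, 0))

  obs_m <- cbind(sim = obs$beta_sim, sne = obs$beta_sne, sor = obs$beta_sor)
  ses <- (obs_m - null_mean) / null_sd
  ses[!is.finite(ses)] <- NA_real_

  computable <- is.finite(obs_m)
  if (all(null_sd[computable] == 0, na.rm = TRUE))
    stop("degenerate null: every pair's null distribution is constant",
         call. = FALSE)

  out <- data.frame(
    site_i = rep(site_i, 3L), site_j = rep(site_j, 3L),
    index = rep(indices, each = np),
    observed = as.vector(obs_m), null_mean = as.vector(null_mean),
    null_sd = as.vector(null_sd), ses = as.vector(ses),
    n_rand = n_rand, scheme = scheme, seed = as.integer(seed),
    stringsAsFactors = FALSE)
  out <- out[is.finite(out$observed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dimension") <- dimension
  class(out) <- c("ses_table", "data.frame")
  out
}

#' @export
print.ses_table <- function(x, ...) {
  cat(sprintf("ses_table (%s, scheme %s, %d randomizations): %d rows\n",
              attr(x, "dimension"), x$scheme[1L], x$n_rand[1L], nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  invisible(x)
}
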