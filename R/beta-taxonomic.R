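#' Matching components of a site pair
#'
#' Counts the components underlying every incidence-based Sorensen-family
#' index: `a` species shared, `b` unique to the first assemblage, `c` unique
#' to the second.
#'
#' @param comm1,comm2 character vectors of species present at each site.
#' @return named integer vector `c(a =, b =, c =)`.
#' @examples
#' pair_counts(c("A", "B", "C"), c("B", "C", "D", "E"))  # a=2 b=1 c=2
#' @export
pair_counts <- function(comm1, comm2) {
  comm1 <- unique(as.character(comm1))
  comm2 <- unique(as.character(comm2))
  a <- length(intersect(comm1, comm2))
  c(a = a, b = length(comm1) - a, c = length(comm2) - a)
}

# Vectorised decomposition core. a, b, c may be counts, branch lengths or
# hull areas; division happens once per index so that beta_sor is exactly
# beta_sim + beta_sne in floating point (sne is computed as the difference).
sorensen_triplet <- function(a, b, c) {
  denom <- 2 * a + b + c
  sor <- (b + c) / denom
  m <- pmin(b, c)
  sim <- ifelse(a + m == 0, NaN, m / (a + m)) # NaN: one assemblage empty
  list(beta_sim = sim, beta_sne = sor - sim, beta_sor = sor)
}

#' Decompose a pair's matching components into turnover and nestedness
#'
#' The additive partition of total Sorensen dissimilarity:
#' `beta_sor = (b+c)/(2a+b+c)`, turnover `beta_sim = min(b,c)/(a+min(b,c))`
#' (Simpson dissimilarity), and the nestedness-resultant component
#' `beta_sne = beta_sor - beta_sim`.
#'
#' @param a shared component (count, branch length or hull area), or the
#'   3-vector returned by [pair_counts()].
#' @param b,c unique components; omit when `a` is a 3-vector.
#' @return named numeric vector `c(beta_sim =, beta_sne =, beta_sor =)`.
#'   For a pair with exactly one empty assemblage `beta_sor` is 1 and the
#'   components are `NaN` (0/0); matrix-level functions exclude such pairs
#'   under the default policy.
#' @examples
#' decompose_pair(pair_counts(c("A", "B", "C"), c("B", "C", "D", "E")))
#' @export
decompose_pair <- function(a, b = NULL, c = NULL) {
  if (is.null(b) && length(a) == 3L) {
    b <- a[[2L]]; c <- a[[3L]]; a <- a[[1L]]
  }
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (any(c(a, b, c) < 0)) stop("components must be non-negative", call. = FALSE)
  if (a == 0 && b == 0 && c == 0)
    stop("both assemblages empty: dissimilarity undefined", call. = FALSE)
  t <- sorensen_triplet(a, b, c)
  c(beta_sim = t$beta_sim, beta_sne = t$beta_sne, beta_sor = t$beta_sor)
}

# Shared scaffolding for the three pairwise tables: pair index in
# column-major upper-triangle order, i.e. (1,2), (1,3), (2,3), ...
pair_index <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

new_pairwise_beta <- function(df, dimension) {
  rownames(df) <- NULL
  attr(df, "dimension") <- dimension
  class(df) <- c("pairwise_beta", "data.frame")
  df
}

#' @export
print.pairwise_beta <- function(x, ...) {
  cat(sprintf("pairwise_beta (%s): %d pairs, %d excluded\n",
              attr(x, "dimension"), nrow(x), sum(x$excluded)))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat(sprintf("... %d more pairs\n", nrow(x) - 6L))
  invisible(x)
}

# Apply the empty-assemblage policy and assemble the output table.
assemble_beta_table <- function(site_i, site_j, comp, comp_names, trip,
                                empty_i, empty_j, extra_excluded = NULL,
                                empty_pair = c("exclude", "as_one"),
                                dimension) {
  empty_pair <- match.arg(empty_pair)
  excluded <- logical(length(site_i))
  reason <- character(length(site_i))
  both <- empty_i & empty_j
  one <- xor(empty_i, empty_j)
  excluded[both] <- TRUE
  reason[both] <- "empty pair"
  if (empty_pair == "exclude") {
    excluded[one] <- TRUE
    reason[one] <- "empty assemblage"
  } else { # as_one: total dissimilarity recorded as 1, components undefined
    trip$beta_sim[one] <- NA_real_
    trip$beta_sne[one] <- NA_real_
    trip$beta_sor[one] <- 1
    reason[one] <- "one empty assemblage; components undefined"
  }
  if (!is.null(extra_excluded)) {
    excluded[extra_excluded$which] <- TRUE
    reason[extra_excluded$which] <- extra_excluded$reason[extra_excluded$which]
  }
  for (nm in c("beta_sim", "beta_sne", "beta_sor")) trip[[nm]][excluded] <- NA_real_
  df <- data.frame(site_i = site_i, site_j = site_j,
                   as.data.frame(stats::setNames(comp, comp_names)),
                   beta_sim = trip$beta_sim, beta_sne = trip$beta_sne,
                   beta_sor = trip$beta_sor,
                   excluded = excluded, reason = reason,
                   stringsAsFactors = FALSE)
  new_pairwise_beta(df, dimension)
}

# Fast path used by the null engines: triplets for all pairs of a binary
# matrix, no data.frame overhead.
tax_triplets <- function(m) {
  A <- tcrossprod(m)
  r <- rowSums(m)
  idx <- pair_index(nrow(m))
  a <- A[idx]
  sorensen_triplet(a, r[idx[, 1L]] - a, r[idx[, 2L]] - a)
}

#' Pairwise taxonomic beta-diversity table
#'
#' Computes `a`, `b`, `c` and the decomposed Sorensen triplet for every
#' unordered site pair of a community matrix. Pairs involving an empty
#' assemblage are excluded and flagged under the default policy (the
#' turnover index is 0/0 there); `empty_pair = "as_one"` instead records
#' total dissimilarity 1 with undefined components.
#'
#' @param cm a [community_matrix].
#' @param empty_pair policy for pairs with exactly one empty assemblage.
#' @return a `pairwise_beta` data.frame with one row per unordered pair
#'   (n(n-1)/2 rows), columns `site_i, site_j, a, b, c, beta_sim, beta_sne,
#'   beta_sor, excluded, reason`.
#' @examples
#' m <- matrix(c(1,1,1,0,0, 0,1,1,1,1, 0,0,1,1,0), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), paste0("sp", 1:5)))
#' beta_matrix_taxonomic(community_matrix(m))
#' @export
beta_matrix_taxonomic <- function(cm, empty_pair = c("exclude", "as_one")) {
  stopifnot(inherits(cm, "community_matrix"))
  m <- unclass(cm)
  idx <- pair_index(nrow(m))
  A <- tcrossprod(m)
  r <- rowSums(m)
  a <- A[idx]
  b <- r[idx[, 1L]] - a
  c <- r[idx[, 2L]] - a
  trip <- sorensen_triplet(a, b, c)
  assemble_beta_table(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]],
                      list(a, b, c), c("a", "b", "c"), trip,
                      empty_i = r[idx[, 1L]] == 0, empty_j = r[idx[, 2L]] == 0,
                      empty_pair = empty_pair, dimension = "taxonomic")
}
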