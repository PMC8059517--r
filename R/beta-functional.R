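#' Build a 2-D trait space from positive size measurements
#'
#' Each trait is natural-log transformed then z-scored (so the PCA is
#' correlation-based), and the principal components are extracted by singular
#' value decomposition of the centred matrix. Axis signs are fixed so that
#' each axis's largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param traits numeric matrix or data.frame of strictly positive
#'   measurements, rows named by species; at least `n_axes` columns.
#' @param n_axes number of retained axes (2 by default: convex-hull overlap
#'   is computed in the plane).
#' @return object of class `trait_space`: `scores` (species x n_axes),
#'   `loadings`, `var_explained` (fraction of total variance per retained
#'   axis), `sdev` (all singular values / sqrt(n-1)).
#' @examples
#' tr <- matrix(rlnorm(20, 3), 10, 2,
#'              dimnames = list(paste0("sp", 1:10), c("mass", "length")))
#' ts <- build_trait_space(tr)
#' sum(ts$var_explained)  # two traits: first two axes carry all variance
#' @export
build_trait_space <- function(traits, n_axes = 2) {
  X <- as.matrix(traits)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) stop("trait rows must be named by species", call. = FALSE)
  if (ncol(X) < n_axes)
    stop(sprintf("need at least %d trait columns for %d axes", n_axes, n_axes),
         call. = FALSE)
  if (any(X <= 0)) stop("trait values must be strictly positive", call. = FALSE)
  L <- log(X)
  sds <- apply(L, 2L, stats::sd)
  if (any(sds < .Machine$double.eps^0.5)) {
    bad <- colnames(X)[sds < .Machine$double.eps^0.5]
    stop(sprintf("constant trait column(s) after log transform: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Z <- scale(L)
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pr$rotation
  sc <- pr$x
  for (j in seq_len(ncol(rot))) { # deterministic axis orientation
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = sc[, seq_len(n_axes), drop = FALSE],
                 loadings = rot[, seq_len(n_axes), drop = FALSE],
                 var_explained = var_frac[seq_len(n_axes)],
                 sdev = pr$sdev),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species on %d axes (%.1f%% of variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$var_explained)))
  invisible(x)
}

# Hull vertices in counter-clockwise order (grDevices::chull is clockwise).
hull_vertices <- function(pts) {
  pts <- unique(as.matrix(pts))
  h <- grDevices::chull(pts)
  pts[rev(h), , drop = FALSE]
}

#' Convex-hull area of a 2-D point set
#'
#' Hull via [grDevices::chull()], area via the shoelace formula. A collinear
#' point set has area 0 and carries a `degenerate` attribute.
#'
#' @param points two-column numeric matrix, at least 3 points.
#' @return scalar area with attribute `degenerate` (logical).
#' @examples
#' hull_area(rbind(c(0, 0), c(2, 0), c(0, 2)))  # 2
#' @export
hull_area <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) stop("need at least 3 points for a hull", call. = FALSE)
  v <- hull_vertices(pts)
  area <- if (nrow(v) < 3L) 0 else shoelace_area(v)
  structure(area, degenerate = area <= 0)
}

# Clip a polygon by the half-plane left of directed edge (p1 -> p2)
# (Sutherland-Hodgman step; clip polygon must be counter-clockwise).
clip_halfplane <- function(poly, p1, p2, eps = 1e-12) {
  if (nrow(poly) == 0L) return(poly)
  ex <- p2[1L] - p1[1L]
  ey <- p2[2L] - p1[2L]
  side <- ex * (poly[, 2L] - p1[2L]) - ey * (poly[, 1L] - p1[1L])
  n <- nrow(poly)
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ci <- side[i] >= -eps
    cj <- side[j] >= -eps
    if (ci) out <- rbind(out, poly[i, ])
    if (xor(ci, cj)) { # edge crosses the clip line: add the intersection
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Intersection area of two convex hulls
#'
#' Builds the convex hull of each point set and clips the first by every
#' edge of the second (Sutherland-Hodgman on convex polygons), returning the
#' shoelace area of the clipped polygon; 0 when the hulls do not overlap.
#'
#' @param ptsA,ptsB two-column numeric matrices (>= 3 non-collinear points
#'   each; degenerate hulls are an error).
#' @return scalar intersection area.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' hull_intersection_area(sq, sq + 0.5)  # 0.25
#' @export
hull_intersection_area <- function(ptsA, ptsB) {
  ha <- hull_vertices(ptsA)
  hb <- hull_vertices(ptsB)
  if (nrow(ha) < 3L || nrow(hb) < 3L)
    stop("degenerate (collinear) hull: intersection undefined", call. = FALSE)
  if (shoelace_area(ha) <= 0 || shoelace_area(hb) <= 0)
    stop("degenerate (zero-area) hull: intersection undefined", call. = FALSE)
  poly <- ha
  nb <- nrow(hb)
  for (i in seq_len(nb)) {
    j <- if (i == nb) 1L else i + 1L
    poly <- clip_halfplane(poly, hb[i, ], hb[j, ])
    if (nrow(poly) < 3L) return(0)
  }
  shoelace_area(poly)
}

# Per-site hulls: vertex list, area and exclusion reason. Shared with the
# label-shuffle null (where only the species -> coordinate map changes).
site_hulls <- function(m, scores, min_richness) {
  lapply(seq_len(nrow(m)), function(i) {
    sp <- colnames(m)[m[i, ] > 0]
    if (length(sp) < min_richness)
      return(list(excluded = TRUE, reason = "below min_richness"))
    v <- hull_vertices(scores[sp, , drop = FALSE])
    if (nrow(v) < 3L || shoelace_area(v) <= 0)
      return(list(excluded = TRUE, reason = "degenerate hull"))
    list(excluded = FALSE, reason = "", v = v, area = shoelace_area(v))
  })
}

# Triplets for all pairs given per-site hulls; exclusion bookkeeping done by
# the caller. b and c are clamped at 0 when within `tol` below it
# (floating-point seepage from clipping); intersection likewise clamped at
# min(V1, V2).
func_triplets <- function(hulls, tol = 1e-9) {
  n <- length(hulls)
  idx <- pair_index(n)
  np <- nrow(idx)
  a <- b <- c <- rep(NA_real_, np)
  for (k in seq_len(np)) {
    h1 <- hulls[[idx[k, 1L]]]
    h2 <- hulls[[idx[k, 2L]]]
    if (h1$excluded || h2$excluded) next
    ia <- hull_intersection_area(h1$v, h2$v)
    ia <- min(ia, h1$area, h2$area)
    bb <- h1$area - ia
    cc <- h2$area - ia
    if (bb < 0 && bb > -tol) bb <- 0
    if (cc < 0 && cc > -tol) cc <- 0
    a[k] <- ia; b[k] <- bb; c[k] <- cc
  }
  list(idx = idx, a = a, b = b, c = c)
}

#' Pairwise functional (convex-hull) beta-diversity table
#'
#' The trait-based analogue of [beta_matrix_taxonomic()]: each community is
#' the convex hull of its species' coordinates in the 2-D trait space, and
#' the matching components are the intersection area (`a_area`) and the
#' areas unique to each hull (`b_area`, `c_area`), fed through the same
#' turnover/nestedness decomposition. Communities with fewer than
#' `min_richness` species (default 3, the minimum for a planar hull) or with
#' a degenerate zero-area hull are excluded and flagged; such pairs carry no
#' dissimilarity.
#'
#' @param cm a [community_matrix].
#' @param ts a [build_trait_space()] result covering every species present
#'   in included communities.
#' @param min_richness minimum species count for a community to enter.
#' @param drop_unmatched prune species without coordinates instead of erroring.
#' @return `pairwise_beta` data.frame with components `a_area, b_area, c_area`.
#' @export
beta_matrix_functional <- function(cm, ts, min_richness = 3,
                                   drop_unmatched = FALSE) {
  stopifnot(inherits(cm, "community_matrix"), inherits(ts, "trait_space"))
  if (min_richness < 3L)
    stop("min_richness must be >= 3 for planar convex hulls", call. = FALSE)
  cm <- match_species_pool(cm, rownames(ts$scores), "trait-space coordinate",
                           drop_unmatched)
  m <- unclass(cm)
  hulls <- site_hulls(m, ts$scores, min_richness)
  ft <- func_triplets(hulls)
  idx <- ft$idx
  trip <- sorensen_triplet(ft$a, ft$b, ft$c)
  excl_i <- vapply(hulls, `[[`, TRUE, "excluded")
  reason_i <- vapply(hulls, `[[`, "", "reason")
  pair_excl <- excl_i[idx[, 1L]] | excl_i[idx[, 2L]]
  pair_reason <- ifelse(excl_i[idx[, 1L]], reason_i[idx[, 1L]],
                        reason_i[idx[, 2L]])
  r <- rowSums(m)
  assemble_beta_table(rownames(m)[idx[, 1L]], rownames(m)[idx[, 2L]],
                      list(ft$a, ft$b, ft$c),
                      c("a_area", "b_area", "c_area"), trip,
                      empty_i = r[idx[, 1L]] == 0, empty_j = r[idx[, 2L]] == 0,
                      extra_excluded = list(which = pair_excl,
                                            reason = pair_reason),
                      dimension = "functional")
}
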