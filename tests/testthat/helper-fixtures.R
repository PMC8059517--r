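# Fixture builders shared across the suite. Everything is generated in code.

make_cm <- function(m, sites = NULL, sp = NULL) {
  if (is.null(sites)) sites <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(sp)) sp <- sprintf("sp%d", seq_len(ncol(m)))
  dimnames(m) <- list(sites, sp)
  community_matrix(m)
}

# Random binary matrix with no empty sites (guaranteed by one forced presence).
random_cm <- function(n_sites, n_sp, p = 0.4) {
  m <- matrix(rbinom(n_sites * n_sp, 1, p), n_sites, n_sp)
  for (i in seq_len(n_sites)) if (sum(m[i, ]) == 0) m[i, sample(n_sp, 2)] <- 1
  make_cm(m)
}

unit_star_tree <- function(n) {
  tr <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", seq_len(n)), collapse = ","), ");"))
  tr
}

# Direct formula application on species sets: the brute-force oracle the
# matrix path is checked against.
oracle_triplet <- function(set1, set2) {
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  c <- length(setdiff(set2, set1))
  sor <- (b + c) / (2 * a + b + c)
  sim <- min(b, c) / (a + min(b, c))
  c(sim = sim, sne = sor - sim, sor = sor)
}

# Per-branch enumeration oracle for phylogenetic components: walks every
# edge, lists its descendant tips by brute-force path tracing.
oracle_branch_components <- function(tree, comm1, comm2) {
  n_tip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  a <- b <- cc <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- desc_tips(tree$edge[k, 2])
    in1 <- any(tips %in% comm1)
    in2 <- any(tips %in% comm2)
    len <- tree$edge.length[k]
    if (in1 && in2) a <- a + len
    else if (in1) b <- b + len
    else if (in2) cc <- cc + len
  }
  c(a = a, b = b, c = cc)
}

# Random convex polygon: hull of points on a noisy circle.
random_convex_poly <- function(n = 8, centre = c(0, 0), scale = 1) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- scale * runif(n, 0.5, 1)
  pts <- cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Monte-Carlo estimate of the intersection area of two convex polygons,
# with its standard error. Samples the intersection of the two bounding
# boxes (the smallest axis-aligned region containing the estimand); the se
# uses the add-one adjusted proportion so it is never degenerately zero when
# a sliver intersection receives no hits.
mc_intersection <- function(pa, pb, n = 1e5) {
  inside <- function(pts, poly) {
    v <- poly[rev(grDevices::chull(poly)), , drop = FALSE] # CCW
    nv <- nrow(v)
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1 else i + 1
      ok <- ok & ((v[j, 1] - v[i, 1]) * (pts[, 2] - v[i, 2]) -
                    (v[j, 2] - v[i, 2]) * (pts[, 1] - v[i, 1]) >= -1e-12)
    }
    ok
  }
  la <- apply(pa, 2, range)
  lb <- apply(pb, 2, range)
  lo <- pmax(la[1, ], lb[1, ])
  hi <- pmin(la[2, ], lb[2, ])
  if (any(hi <= lo)) return(list(area = 0, se = 0)) # boxes disjoint: area 0
  area_box <- prod(hi - lo)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]))
  hit <- inside(pts, pa) & inside(pts, pb)
  p <- mean(hit)
  p_adj <- (sum(hit) + 1) / (n + 2)
  list(area = p * area_box, se = sqrt(p_adj * (1 - p_adj) / n) * area_box)
}

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

shift_poly <- function(poly, dx = 0, dy = 0) cbind(poly[, 1] + dx, poly[, 2] + dy)
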