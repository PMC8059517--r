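test_that("branch components match hand computations", {
  star <- unit_star_tree(4)
  expect_equal(branch_components(star, c("t1", "t2", "t3"), c("t2", "t3", "t4")),
               c(a = 2, b = 1, c = 1))
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(branch_components(tr, c("A", "B"), c("C", "D")),
               c(a = 0, b = 3, c = 3))
  # identical communities: all branch length shared
  bc <- branch_components(tr, c("A", "B"), c("A", "B"))
  expect_equal(bc, c(a = 3, b = 0, c = 0))
})

test_that("branch classification agrees with per-branch enumeration on random trees", {
  withr::local_seed(20)
  for (rep in 1:8) {
    tr <- ape::rtree(5)
    tips <- tr$tip.label
    subsets <- lapply(1:31, function(k) tips[bitwAnd(k, 2^(0:4)) > 0])
    pick <- sample(length(subsets), 6)
    for (i in pick) for (j in pick) {
      got <- branch_components(tr, subsets[[i]], subsets[[j]])
      want <- oracle_branch_components(tr, subsets[[i]], subsets[[j]])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("phylogenetic decomposition keeps the taxonomic invariants and reduces on star trees", {
  withr::local_seed(8)
  star <- unit_star_tree(12)
  for (rep in 1:10) {
    cm <- random_cm(6, 12)
    colnames(cm) <- star$tip.label
    cmx <- community_matrix(unclass(cm))
    bp <- beta_matrix_phylo(cmx, star)
    bt <- beta_matrix_taxonomic(cmx)
    ok <- !bp$excluded
    # star-tree equivalence with unit branches
    expect_equal(bp$beta_sim[ok], bt$beta_sim[ok], tolerance = 1e-12)
    expect_equal(bp$beta_sne[ok], bt$beta_sne[ok], tolerance = 1e-12)
    expect_equal(bp$beta_sor[ok], bt$beta_sor[ok], tolerance = 1e-12)
    # additivity and bounds
    expect_lt(max(abs(bp$beta_sor[ok] - bp$beta_sim[ok] - bp$beta_sne[ok])), 1e-12)
    expect_true(all(bp$beta_sor[ok] >= 0 & bp$beta_sor[ok] <= 1))
  }

  # nested lineages: a subset community contributes no exclusive branches
  tr <- ape::rtree(8)
  m <- rbind(rep(1, 8), c(rep(1, 4), rep(0, 4)))
  cm2 <- make_cm(m, sp = tr$tip.label)
  bp2 <- beta_matrix_phylo(cm2, tr)
  expect_equal(bp2$c_bl, 0)
  expect_equal(bp2$beta_sim, 0)
})

test_that("phylogenetic total dissimilarity matches picante's PhyloSor complement", {
  withr::local_seed(77)
  tr <- ape::rtree(15)
  cm <- random_cm(6, 15)
  colnames(cm) <- tr$tip.label
  cmx <- community_matrix(unclass(cm))
  bp <- beta_matrix_phylo(cmx, tr)
  ps <- as.matrix(picante::phylosor(unclass(cmx), tr))
  for (k in seq_len(nrow(bp))) {
    if (bp$excluded[k]) next
    expect_equal(bp$beta_sor[k], 1 - ps[bp$site_i[k], bp$site_j[k]],
                 tolerance = 1e-10)
  }
})

test_that("multi-tree summaries average indices and report spread", {
  withr::local_seed(5)
  cm <- random_cm(5, 10)
  tr1 <- ape::rcoal(10, tip.label = colnames(cm))
  tr2 <- ape::rcoal(10, tip.label = colnames(cm))

  one <- multi_tree_summary(cm, list(tr1))
  direct <- beta_matrix_phylo(cm, tr1)
  expect_equal(one$beta_sor, direct$beta_sor)
  expect_equal(one$beta_sor_sd[!one$excluded], rep(0, sum(!one$excluded)))

  twin <- multi_tree_summary(cm, list(tr1, tr1))
  expect_equal(twin$beta_sor_sd[!twin$excluded], rep(0, sum(!twin$excluded)))

  both <- multi_tree_summary(cm, list(tr1, tr2))
  d1 <- beta_matrix_phylo(cm, tr1)
  d2 <- beta_matrix_phylo(cm, tr2)
  expect_equal(both$beta_sor, (d1$beta_sor + d2$beta_sor) / 2)
  # mean triplet stays additive
  ok <- !both$excluded
  expect_lt(max(abs(both$beta_sor[ok] - both$beta_sim[ok] - both$beta_sne[ok])),
            1e-12)

  tr3 <- ape::rcoal(10) # different tip set
  expect_error(multi_tree_summary(cm, list(tr1, tr3)), "identical tip set")
})

test_that("Blomberg's K: star-tree closed form, BM self-consistency, cross-check", {
  # star tree: V proportional to identity forces K = 1 for any trait
  star <- unit_star_tree(10)
  withr::local_seed(1)
  for (rep in 1:5) {
    trait <- setNames(rnorm(10), star$tip.label)
    expect_equal(blomberg_k(star, trait, n_perm = 0)$K, 1, tolerance = 1e-10)
  }

  # agrees with phytools' implementation on random trees
  withr::local_seed(2)
  for (rep in 1:5) {
    tr <- ape::rcoal(20)
    trait <- setNames(rnorm(20), tr$tip.label)
    k1 <- blomberg_k(tr, trait, n_perm = 0)$K
    k2 <- unname(phytools::phylosig(tr, trait, method = "K"))
    expect_equal(k1, as.numeric(k2), tolerance = 1e-6)
  }

  # white-noise traits on imbalanced trees lose signal: K < 1
  withr::local_seed(3)
  cat_tree <- ape::compute.brlen(ape::stree(16, type = "left"), method = "Grafen")
  ks <- replicate(40, blomberg_k(
    cat_tree, setNames(rnorm(16), cat_tree$tip.label), n_perm = 0)$K)
  expect_gt(mean(ks < 1), 0.9)

  # permutation p is seed-reproducible and in (0, 1]
  tr <- ape::rcoal(12)
  trait <- setNames(rnorm(12), tr$tip.label)
  k1 <- blomberg_k(tr, trait, n_perm = 99, seed = 11)
  k2 <- blomberg_k(tr, trait, n_perm = 99, seed = 11)
  expect_identical(k1$p, k2$p)
  expect_gt(k1$p, 0)
  expect_lte(k1$p, 1)
})
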