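test_that("mode guarantees hold exactly on every generated dataset", {
  for (seed in c(1, 7, 99)) {
    # nested: every pair is an elevational subset, so turnover is zero
    ds <- simulate_metacommunity(simulation_config(mode = "nested", seed = seed))
    bt <- beta_matrix_taxonomic(ds$community)
    expect_true(all(bt$beta_sim[!bt$excluded] == 0))
    # ordered by elevation, the higher site of each pair adds no species
    expect_true(all(bt$c[!bt$excluded] >= 0))

    # turnover: pairs farther apart than the range breadth are disjoint
    cfg <- simulation_config(mode = "turnover", seed = seed)
    ds2 <- simulate_metacommunity(cfg)
    exp_t <- expected_behaviour(cfg)
    bt2 <- beta_matrix_taxonomic(ds2$community)
    elev <- setNames(ds2$sites$elevation, ds2$sites$site)
    d <- abs(elev[bt2$site_i] - elev[bt2$site_j])
    far <- d > exp_t$disjoint_beyond_m & !bt2$excluded
    expect_true(any(far))
    expect_true(all(bt2$beta_sim[far] == exp_t$beta_sim_on_disjoint))
    expect_true(all(bt2$beta_sne[far] == exp_t$beta_sne_on_disjoint))
  }
})

test_that("turnover breadth below site spacing forces adjacent disjointness", {
  cfg <- simulation_config(n_sites = 6, n_species = 60, mode = "turnover",
                           turnover_breadth = 100, seed = 13)
  ds <- simulate_metacommunity(cfg)
  bt <- beta_matrix_taxonomic(ds$community)
  adj <- abs(match(bt$site_i, sites(ds$community)) -
               match(bt$site_j, sites(ds$community))) == 1
  expect_true(all(bt$beta_sim[adj & !bt$excluded] == 1))
})

test_that("generation is bitwise reproducible from the seed", {
  cfg <- simulation_config(mode = "mixed", seed = 555)
  d1 <- simulate_metacommunity(cfg)
  d2 <- simulate_metacommunity(cfg)
  expect_identical(unclass(d1$community), unclass(d2$community))
  expect_identical(d1$tree, d2$tree)
  expect_identical(d1$traits, d2$traits)
  expect_identical(d1$sites, d2$sites)
  d3 <- simulate_metacommunity(simulation_config(mode = "mixed", seed = 556))
  expect_false(identical(unclass(d1$community), unclass(d3$community)))
})

test_that("expected_behaviour exposes closed forms only for the pure modes", {
  e1 <- expected_behaviour(simulation_config(mode = "turnover", seed = 1))
  expect_true(e1$closed_form)
  expect_equal(e1$beta_sne_on_disjoint, 0)
  e2 <- expected_behaviour(simulation_config(mode = "nested", seed = 1))
  expect_equal(e2$beta_sim_all_pairs, 0)
  e3 <- expected_behaviour(simulation_config(mode = "mixed", seed = 1))
  expect_false(e3$closed_form)
})

test_that("phylogeny-range coupling controls the signal in range position", {
  # kappa = 1: midpoint is a linear map of a Brownian trait, K near 1;
  # kappa = 0: position is independent noise, K well below 1
  k_of <- function(kappa, seed) {
    cfg <- simulation_config(n_species = 64, mode = "mixed", kappa = kappa,
                             seed = seed, allow_empty_sites = TRUE)
    ds <- simulate_metacommunity(cfg)
    mids <- (ds$ground_truth$lower + ds$ground_truth$upper) / 2
    blomberg_k(ds$tree, setNames(mids, names(ds$ground_truth$position_score)),
               n_perm = 0)$K
  }
  k1 <- vapply(1:40, function(s) k_of(1, s), numeric(1))
  k0 <- vapply(41:80, function(s) k_of(0, s), numeric(1))
  expect_gt(mean(k1), 0.8)
  expect_lt(mean(k1), 1.2)
  expect_lt(mean(k0), 0.7)
  expect_gt(mean(k1), mean(k0))
})

test_that("environment tracks elevation as designed", {
  ds <- simulate_metacommunity(simulation_config(seed = 2, env_noise_sd = 0))
  s <- ds$sites
  expect_true(all(diff(s$AMT) < 0)) # monotone cooling, noise off
  expect_true(all(diff(s$AP) < 0))
  expect_true(all(diff(s$PET) < 0))
  # NPP humps at mid-elevation
  expect_gt(s$NPP[9], s$NPP[1])
  expect_gt(s$NPP[9], s$NPP[17])
  # lapse rate: 5.5 degC per km over the 2500 m span
  expect_equal(s$AMT[1] - s$AMT[17], 5.5 * 2.5, tolerance = 1e-9)
})

test_that("synthetic datasets round-trip through the pipeline file formats", {
  ds <- simulate_metacommunity(simulation_config(n_sites = 6, n_species = 12,
                                                 seed = 8))
  d <- withr::local_tempdir()
  p <- write_synthetic_dataset(ds, d)
  cm <- read_community_matrix(p[["community"]])
  expect_identical(unclass(cm), unclass(ds$community))
  st <- read_site_table(p[["sites"]], cm)
  expect_equal(st$elevation, ds$sites$elevation)
  tr <- read_newick(p[["tree"]])
  expect_setequal(tr$tip.label, species(cm))
  tt <- read_trait_table(p[["traits"]])
  expect_equal(unname(tt), unname(ds$traits), tolerance = 1e-9)
})
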