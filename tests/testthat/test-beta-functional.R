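test_that("trait space: variance accounting, sign convention, degenerate input", {
  withr::local_seed(4)
  tr2 <- matrix(rlnorm(20, 3), 10, 2,
                dimnames = list(paste0("sp", 1:10), c("len_max", "len_min")))
  ts <- build_trait_space(tr2)
  # two traits: the two axes carry all the variance
  expect_equal(sum(ts$var_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(ts$var_explained) <= 1e-12))
  # axes orthogonal
  expect_equal(crossprod(ts$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # sign rule: each axis's largest-magnitude loading is positive
  for (j in 1:2) expect_gt(ts$loadings[which.max(abs(ts$loadings[, j])), j], 0)

  # duplicate species rows land on identical coordinates
  tr3 <- rbind(tr2, dup = tr2[1, ])
  rownames(tr3)[11] <- "sp1dup"
  ts3 <- build_trait_space(tr3)
  expect_equal(unname(ts3$scores["sp1dup", ]), unname(ts3$scores["sp1", ]))

  # constant column is named in the error
  tr4 <- tr2; tr4[, 2] <- 5
  expect_error(build_trait_space(tr4), "len_min")
})

test_that("hull area and intersection match hand geometry", {
  expect_equal(as.numeric(hull_area(unit_square)), 1)
  expect_equal(as.numeric(hull_area(rbind(c(0, 0), c(2, 0), c(0, 2)))), 2)
  col3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  a <- hull_area(col3)
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
  expect_error(hull_area(unit_square[1:2, ]), "at least 3")

  expect_equal(hull_intersection_area(unit_square, shift_poly(unit_square, 0.5)),
               0.5, tolerance = 1e-12)
  expect_equal(hull_intersection_area(unit_square, shift_poly(unit_square, 2)),
               0)
  inner <- unit_square * 0.5 + 0.25
  expect_equal(hull_intersection_area(unit_square, inner), 0.25,
               tolerance = 1e-12)
  expect_error(hull_intersection_area(unit_square, col3), "degenerate")
})

test_that("clipping agrees with a Monte-Carlo oracle on random polygon pairs", {
  withr::local_seed(9)
  for (rep in 1:10) {
    pa <- random_convex_poly(8, centre = runif(2, -0.3, 0.3))
    pb <- random_convex_poly(8, centre = runif(2, -0.3, 0.3))
    got <- hull_intersection_area(pa, pb)
    mc <- mc_intersection(pa, pb, n = 2e4)
    expect_lt(abs(got - mc$area), 3 * mc$se + 1e-9)
  }
})

test_that("functional decomposition: hand cases, containment, exclusions", {
  # two communities whose hulls are the shifted squares: a = b = c = 0.5
  sq_sp <- paste0("q", 1:4)
  sh_sp <- paste0("h", 1:4)
  scores <- rbind(unit_square, shift_poly(unit_square, 0.5))
  rownames(scores) <- c(sq_sp, sh_sp)
  ts <- structure(list(scores = scores,
                       loadings = diag(2), var_explained = c(0.6, 0.4),
                       sdev = c(1, 1)), class = "trait_space")
  m <- rbind(c(rep(1, 4), rep(0, 4)), c(rep(0, 4), rep(1, 4)))
  cm <- make_cm(m, sp = rownames(scores))
  bf <- beta_matrix_functional(cm, ts)
  expect_equal(bf$a_area, 0.5, tolerance = 1e-12)
  expect_equal(bf$beta_sor, 0.5, tolerance = 1e-12)
  expect_equal(bf$beta_sim, 0.5, tolerance = 1e-12)
  expect_equal(bf$beta_sne, 0, tolerance = 1e-12)

  # nested hulls: pure functional nestedness (V1=1, V2=0.25, a=0.25)
  scores2 <- rbind(unit_square, unit_square * 0.5 + 0.25)
  rownames(scores2) <- c(sq_sp, sh_sp)
  ts2 <- ts; ts2$scores <- scores2
  bf2 <- beta_matrix_functional(cm, ts2)
  expect_equal(bf2$beta_sim, 0, tolerance = 1e-12)
  expect_equal(bf2$beta_sne, 0.6, tolerance = 1e-12)
  expect_equal(bf2$beta_sor, 0.6, tolerance = 1e-12)

  # identical communities
  m3 <- rbind(c(rep(1, 4), rep(0, 4)), c(rep(1, 4), rep(0, 4)))
  bf3 <- beta_matrix_functional(make_cm(m3, sp = rownames(scores)), ts)
  expect_equal(bf3$beta_sor, 0)

  # a 2-species community is excluded with the stated reason
  m4 <- rbind(c(1, 1, 0, 0, rep(0, 4)), c(rep(0, 4), rep(1, 4)),
              c(rep(1, 4), rep(0, 4)))
  bf4 <- beta_matrix_functional(make_cm(m4, sp = rownames(scores)), ts)
  s1rows <- bf4$site_i == "s1" | bf4$site_j == "s1"
  expect_true(all(bf4$excluded[s1rows]))
  expect_true(all(bf4$reason[s1rows] == "below min_richness"))
  expect_false(any(bf4$excluded[!s1rows]))
})

test_that("functional indices are invariant under rigid motions of trait space", {
  withr::local_seed(12)
  n_sp <- 12
  scores <- cbind(rnorm(n_sp), rnorm(n_sp))
  rownames(scores) <- paste0("sp", 1:n_sp)
  ts <- structure(list(scores = scores, loadings = diag(2),
                       var_explained = c(0.6, 0.4), sdev = c(1, 1)),
                  class = "trait_space")
  cm <- random_cm(5, n_sp)
  colnames(cm) <- rownames(scores)
  cmx <- community_matrix(unclass(cm))
  bf <- beta_matrix_functional(cmx, ts)

  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ts_rot <- ts
  ts_rot$scores <- scores %*% R + matrix(c(3, -7), n_sp, 2, byrow = TRUE)
  bf_rot <- beta_matrix_functional(cmx, ts_rot)
  ok <- !bf$excluded
  expect_equal(bf$beta_sor[ok], bf_rot$beta_sor[ok], tolerance = 1e-9)
  expect_equal(bf$beta_sim[ok], bf_rot$beta_sim[ok], tolerance = 1e-9)

  # intersection never exceeds the smaller hull; additivity preserved
  expect_true(all(bf$a_area[ok] <= pmin(bf$a_area[ok] + bf$b_area[ok],
                                        bf$a_area[ok] + bf$c_area[ok]) + 1e-9))
  expect_lt(max(abs(bf$beta_sor[ok] - bf$beta_sim[ok] - bf$beta_sne[ok])), 1e-12)
})
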