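test_that("exact contributions reproduce the additive closed forms", {
  # 2 tiles, additive predictor with per-tile values 2 and 1, non-empty
  # subsets only: contribution of tile 1 = (f({1}) + f({1,2}))/2 - f({2})
  w <- c(2, 1)
  add <- function(idx) sum(w[idx])
  ar <- exact_contributions(add, 2)
  # tile 2: (f({2}) + f({1,2}))/2 - f({1}) = (1 + 3)/2 - 2 = 0
  expect_equal(ar$contributions$contribution, c(1.5, 0))
  expect_equal(ar$contributions$se, c(0, 0))
  expect_equal(ar$n_subsets, 3L)

  # general additive closed forms at larger N: with the empty set included
  # the contribution is exactly w_i; under the non-empty convention it is
  # w_i - sum(w[-i]) / (2 * (2^(N-1) - 1))
  set.seed(61)
  N <- 6; wN <- rnorm(N)
  addN <- function(idx) sum(wN[idx])
  with_empty <- exact_contrib_with_empty(addN, N, f_empty = 0)
  expect_equal(with_empty, wN, tolerance = 1e-12)
  nonempty <- exact_contributions(addN, N)$contributions$contribution
  want <- vapply(1:N, function(i) wN[i] - sum(wN[-i]) / (2 * (2^(N - 1) - 1)),
                 numeric(1))
  expect_equal(nonempty, want, tolerance = 1e-12)

  # constant predictor: zero everywhere
  expect_equal(exact_contributions(function(idx) 7, 5)$contributions$contribution,
               rep(0, 5))
  expect_error(exact_contributions(add, 25), "capped")
})

test_that("sampled contributions estimate the exact values with honest errors", {
  cfg <- mil_config(3, scoring_hidden = 4L, n_extreme = 2L, head_hidden = 3L,
                    seed = 62)
  m <- mil_init(cfg)
  bag <- random_bag(8, 3, seed = 63)
  pf <- mil_subset_predictor(m, bag)

  ex <- exact_contributions(pf, 8)$contributions$contribution
  sa <- sampled_contributions(pf, 8, n_subsets = 4000, seed = 64)
  expect_true(all(abs(sa$contributions$contribution - ex) <=
                    3 * sa$contributions$se))
  expect_equal(sa$method, "sampled")
  expect_length(sa$undetermined, 0)

  # determinism under the seed
  sa2 <- sampled_contributions(pf, 8, n_subsets = 4000, seed = 64)
  expect_identical(sa$contributions, sa2$contributions)

  # constant predictor: estimates and standard errors are exactly zero
  s0 <- sampled_contributions(function(idx) 1, 4, n_subsets = 500, seed = 65)
  expect_equal(s0$contributions$contribution, rep(0, 4))
  expect_equal(s0$contributions$se, rep(0, 4))

  # duplicate tiles under the (symmetric) cached-score predictor get equal
  # contributions from exact enumeration
  feats <- matrix(rnorm(12), 4, 3)
  feats[2, ] <- feats[1, ]
  bagd <- tile_bag("s", "p", tile_grid(224 * 4, 224)[1:4, ], feats)
  exd <- exact_contributions(mil_subset_predictor(m, bagd), 4)
  expect_equal(exd$contributions$contribution[1],
               exd$contributions$contribution[2], tolerance = 1e-12)
})

test_that("more subsets shrink the Monte-Carlo error", {
  cfg <- mil_config(3, scoring_hidden = 4L, n_extreme = 2L, head_hidden = 3L,
                    seed = 66)
  m <- mil_init(cfg)
  bag <- random_bag(8, 3, seed = 67)
  pf <- mil_subset_predictor(m, bag)
  ex <- exact_contributions(pf, 8)$contributions$contribution
  mae <- function(n_sub, seed)
    mean(abs(sampled_contributions(pf, 8, n_sub, seed)$contributions$contribution - ex))
  err_small <- mean(vapply(1:10, function(s) mae(400, 70 + s), numeric(1)))
  err_big <- mean(vapply(1:10, function(s) mae(1600, 70 + s), numeric(1)))
  expect_lt(err_big, err_small)
})

test_that("attribution is invariant to tile order within the bag", {
  cfg <- mil_config(3, scoring_hidden = 4L, n_extreme = 2L, head_hidden = 3L,
                    seed = 68)
  m <- mil_init(cfg)
  bag <- random_bag(7, 3, seed = 69)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  bag_p <- tile_bag(bag$slide_id, bag$patient_id, bag$coords[perm, ],
                    bag$features[perm, ])
  ex <- exact_contributions(mil_subset_predictor(m, bag), 7)
  exp_ <- exact_contributions(mil_subset_predictor(m, bag_p), 7)
  expect_equal(exp_$contributions$contribution,
               ex$contributions$contribution[perm], tolerance = 1e-12)
})

test_that("extreme-tile selection is deterministic with tie-breaks", {
  at <- data.frame(slide_id = rep(c("s1", "s2"), each = 3),
                   patient_id = "p", tile = rep(1:3, 2),
                   x = 0, y = 0, contribution = c(-2, 0, 5, 1, -1, 0), se = 0)
  ext <- select_extreme_tiles(at, k = 1)
  expect_equal(ext$high$contribution, 5)
  expect_equal(ext$low$contribution, -2)

  tied <- at; tied$contribution <- 0
  e1 <- select_extreme_tiles(tied, k = 2)
  e2 <- select_extreme_tiles(tied[sample(6), ], k = 2)
  expect_equal(e1$high[c("slide_id", "tile")], e2$high[c("slide_id", "tile")],
               ignore_attr = TRUE)
  expect_error(select_extreme_tiles(at, k = 4), "2k")
})

test_that("the pooled two-proportion Z-test matches the textbook formula", {
  # reviewed-tile counts: 8/167 high-risk vs 52/110 low-risk
  zt <- proportion_ztest(8, 167, 52, 110)
  p1 <- 8 / 167; p2 <- 52 / 110; pp <- 60 / 277
  z_hand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 167 + 1 / 110))
  expect_lt(abs(zt$z - z_hand), 1e-12)
  expect_lt(abs(abs(zt$z) - 8.40), 0.01)

  expect_equal(proportion_ztest(5, 10, 10, 20), list(z = 0, p = 1))

  # artifact-style check: 12/200 vs 9/200 is nowhere near significant
  za <- proportion_ztest(12, 200, 9, 200)
  expect_lt(abs(za$z), 1)
  expect_gt(za$p, 0.4)
  expect_error(proportion_ztest(3, 2, 1, 5))
})

test_that("Holm-Sidak step-down adjustment has its closed form and monotonicity", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  expect_equal(holm_sidak(0.2), 0.2)
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.5, 1.2)), "0, 1")

  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
  }
})

test_that("enrichment tables rank a planted exclusive feature first and stay null otherwise", {
  grp <- rep(c("high", "low"), each = 100)
  set.seed(72)
  ann <- cbind(planted = c(rbinom(100, 1, 0.5), rep(0, 100)),
               noise1 = rbinom(200, 1, 0.3),
               noise2 = rbinom(200, 1, 0.1))
  et <- enrichment_table(ann, grp)
  expect_equal(et$feature[1], "planted")
  expect_lt(et$p_adj[1], 0.001)
  expect_true(all(et$p_adj >= et$p_raw - 1e-15))

  # identical distributions: adjusted significance is rare
  set.seed(73)
  hits <- 0L
  for (s in 1:100) {
    ann0 <- matrix(rbinom(200 * 3, 1, 0.3), 200, 3)
    et0 <- enrichment_table(ann0, grp)
    if (any(et0$p_adj < 0.05)) hits <- hits + 1L
  }
  # family-wise error control at 5%: the hit count over 100 null families
  # stays within binomial noise of 5
  expect_lte(hits, 10L)

  empty <- enrichment_table(matrix(0, 4, 0), rep(c("high", "low"), 2))
  expect_equal(nrow(empty), 0)
})
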