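test_that("tile scoring is a per-tile map: equivariant, duplication-faithful", {
  cfg <- small_mil_config(4, seed = 1)
  m <- mil_init(cfg)
  bag <- random_bag(12, 4, seed = 2)
  s <- score_tiles(m, bag)
  expect_length(s, 12)
  expect_true(all(is.finite(s)))

  perm <- sample(12)
  bag_p <- tile_bag(bag$slide_id, bag$patient_id,
                    bag$coords[perm, ], bag$features[perm, ])
  expect_equal(score_tiles(m, bag_p), s[perm])

  dup <- rbind(bag$features, bag$features[1, , drop = FALSE])
  expect_equal(score_tiles(m, dup)[13], s[1])

  expect_error(score_tiles(m, matrix(0, 3, 7)), "dimension")

  zero <- milsurv:::mil_set_theta(m, rep(0, length(milsurv:::mil_theta(m))))
  expect_equal(score_tiles(zero, bag), rep(0, 12))
})

test_that("slide risk is permutation invariant and reduces to extreme sums under an identity head", {
  cfg <- small_mil_config(4, seed = 3)
  m <- mil_init(cfg)
  bag <- random_bag(15, 4, seed = 4)
  r <- predict_slide(m, bag)
  perm <- sample(15)
  bag_p <- tile_bag(bag$slide_id, bag$patient_id,
                    bag$coords[perm, ], bag$features[perm, ])
  expect_equal(predict_slide(m, bag_p), r)

  # k = 1 with a linear summing head: risk = max score + min score
  cfg1 <- mil_config(4, scoring_hidden = 4L, n_extreme = 1L,
                     head_hidden = integer(0), seed = 5)
  m1 <- mil_init(cfg1)
  m1$head <- list(list(W = matrix(c(1, 1), 2, 1), b = 0))
  s <- score_tiles(m1, bag)
  expect_equal(predict_slide(m1, bag), max(s) + min(s))

  # constant bag: head sees a constant vector
  const <- tile_bag("s", "p", tile_grid(224 * 5, 224)[1:5, ],
                    matrix(1, 5, 4) * rep(1, 5))
  expect_equal(predict_slide(m1, const), 2 * score_tiles(m1, const)[1])
})

test_that("patient risk is the mean of slide risks", {
  cfg <- small_mil_config(4, seed = 6)
  m <- mil_init(cfg)
  b1 <- random_bag(8, 4, seed = 7, slide = "s1")
  b2 <- random_bag(11, 4, seed = 8, slide = "s2")
  expect_equal(predict_patient(m, list(b1)), predict_slide(m, b1))
  expect_equal(predict_patient(m, list(b1, b1)), predict_slide(m, b1))
  expect_equal(predict_patient(m, list(b1, b2)),
               mean(c(predict_slide(m, b1), predict_slide(m, b2))))
})

test_that("smooth concordance loss has the right fixed points, limit and gradient", {
  set.seed(10)
  n <- 20
  t <- rexp(n); e <- rbinom(n, 1, 0.7); r <- rnorm(n)

  expect_equal(smooth_cindex_loss(rep(1, n), t, e, tau = 1), 0.5)

  # perfectly anti-ranked times: risk = -time, loss -> 0 as tau -> 0
  expect_lt(smooth_cindex_loss(-t, t, rep(1, n), tau = 1e-4), 1e-6)

  hard <- concordance_index(t, e, r)$value
  expect_lt(abs((1 - smooth_cindex_loss(r, t, e, tau = 1e-4)) - hard), 1e-6)

  lg <- milsurv:::smooth_cindex_loss_grad(r, t, e, tau = 0.7)
  fd <- vapply(seq_len(n), function(i) {
    h <- 1e-6; rp <- r; rm <- r
    rp[i] <- rp[i] + h; rm[i] <- rm[i] - h
    (smooth_cindex_loss(rp, t, e, 0.7) - smooth_cindex_loss(rm, t, e, 0.7)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(lg$grad - fd)), 1e-5)

  # raising the risk of the shortest-surviving event patient lowers the loss
  i0 <- which(e == 1)[which.min(t[e == 1])]
  r2 <- r; r2[i0] <- r2[i0] + 0.5
  expect_lt(smooth_cindex_loss(r2, t, e, 1), smooth_cindex_loss(r, t, e, 1))

  expect_error(smooth_cindex_loss(1:3, c(1, 1, 1), c(1, 1, 1), 1), "admissible")
  expect_error(smooth_cindex_loss(1:3, 1:3, c(0, 0, 0), 1), "admissible")
})

test_that("analytic model gradient matches finite differences through sort-and-select", {
  cfg <- mil_config(5, scoring_hidden = 4L, n_extreme = 3L, head_hidden = 4L,
                    seed = 11)
  m <- mil_init(cfg)
  set.seed(12)
  slides <- lapply(1:6, function(i)
    lapply(seq_len(sample(1:2, 1)), function(s) matrix(rnorm(8 * 5), 8, 5)))
  t <- rexp(6); e <- c(1, 1, 0, 1, 1, 0)
  lg <- milsurv:::mil_loss_grad(m, slides, t, e, tau = 1)
  th <- milsurv:::mil_theta(m)
  fd <- vapply(seq_along(th), function(i) {
    h <- 1e-6
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (milsurv:::mil_loss_grad(milsurv:::mil_set_theta(m, tp), slides, t, e, 1)$loss -
     milsurv:::mil_loss_grad(milsurv:::mil_set_theta(m, tm), slides, t, e, 1)$loss) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(lg$grad - fd)), 1e-5)
})

test_that("training descends on a signal cohort and stays at chance on a null cohort", {
  co <- small_cohort(n = 120, d = 8, beta_hist = 1.5, beta_clin = 0, seed = 13)
  cfg <- small_mil_config(8, seed = 13)
  fit <- mil_train(co, cfg)
  expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1])

  # determinism of the whole training run
  fit2 <- mil_train(co, cfg)
  expect_identical(milsurv:::mil_theta(fit$model), milsurv:::mil_theta(fit2$model))

  # null cohort: out-of-fold concordance near 1/2
  co0 <- small_cohort(n = 150, d = 8, beta_hist = 0, beta_clin = 0, seed = 14)
  o <- co0$outcomes
  fp <- make_folds(o, n_folds = 2, n_repeats = 1, seed = 14)
  views <- split_modalities(co0)
  cis <- vapply(1:2, function(f) {
    tr <- milsurv:::fold_train_ids(fp, 1, f)
    te <- milsurv:::fold_test_ids(fp, 1, f)
    hv <- list(patient_id = tr, bags = views$histologic$bags[tr],
               outcomes = o[match(tr, o$patient_id), ])
    mdl <- mil_train(hv, small_mil_config(8, seed = 14 + f))$model
    ote <- o[match(te, o$patient_id), ]
    concordance_index(ote$time_months, ote$event,
                      predict_cohort(mdl, views$histologic, te)$score)$value
  }, numeric(1))
  expect_lt(abs(mean(cis) - 0.5), 0.08)
})

test_that("fine-tuning continues from the given parameters", {
  co <- small_cohort(n = 60, d = 8, seed = 15)
  cfg <- small_mil_config(8, seed = 15, epochs_pretrain = 5L)
  pre <- mil_train(co, cfg)$model

  cfg0 <- cfg; cfg0$epochs_finetune <- 0L
  same <- fine_tune(pre, co, cfg0)$model
  expect_identical(milsurv:::mil_theta(same), milsurv:::mil_theta(pre))

  cfg_lr0 <- cfg; cfg_lr0$learning_rate <- 0
  frozen <- fine_tune(pre, co, cfg_lr0)$model
  expect_identical(milsurv:::mil_theta(frozen), milsurv:::mil_theta(pre))

  cfg_bad <- small_mil_config(9, seed = 1)
  expect_error(fine_tune(pre, co, cfg_bad), "dimension")

  # continuing on the same cohort keeps the loss from rising appreciably
  ft <- fine_tune(pre, co, cfg)
  pre_log <- mil_train(co, cfg)$log
  expect_lt(ft$log$loss[nrow(ft$log)], pre_log$loss[nrow(pre_log)] + 0.05)
})

test_that("pretraining on a cohort sharing the signature direction transfers", {
  wins <- 0L
  for (s in 1:5) {
    specA <- cohort_spec(n_patients = 150, feature_dim = 8, beta_hist = 1.5,
                         beta_clin = 0, tiles_per_slide = c(5L, 15L),
                         slides_per_patient = c(1L, 1L), seed = 100 + s)
    coA <- generate_cohort(specA)
    specB <- specA; specB$n_patients <- 50L; specB$seed <- 200L + s
    coB <- generate_cohort(specB, signature_direction = coA$truth$signature_direction)

    cfg <- small_mil_config(8, seed = 300 + s, epochs_pretrain = 10L,
                            epochs_finetune = 10L)
    pre <- mil_train(coA, cfg)$model

    oB <- coB$outcomes
    fp <- make_folds(oB, 2, 1, seed = s)
    views <- split_modalities(coB)
    ci_of <- function(model_fn) {
      mean(vapply(1:2, function(f) {
        tr <- milsurv:::fold_train_ids(fp, 1, f)
        te <- milsurv:::fold_test_ids(fp, 1, f)
        hv <- list(patient_id = tr, bags = views$histologic$bags[tr],
                   outcomes = oB[match(tr, oB$patient_id), ])
        mdl <- model_fn(hv)
        ote <- oB[match(te, oB$patient_id), ]
        concordance_index(ote$time_months, ote$event,
                          predict_cohort(mdl, views$histologic, te)$score)$value
      }, numeric(1)))
    }
    ci_ft <- ci_of(function(hv) fine_tune(pre, hv, cfg)$model)
    ci_scratch <- ci_of(function(hv)
      mil_train(hv, cfg, epochs = cfg$epochs_finetune)$model)
    if (ci_ft >= ci_scratch) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
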