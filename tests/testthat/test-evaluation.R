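test_that("concordance follows the admissible/concordant pair rules", {
  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1))$value, 1)

  ci <- concordance_index(c(2, 4, 5, 7), c(1, 0, 1, 0), c(0.9, 0.3, 0.1, 0.7))
  expect_equal(ci$value, 0.75)
  expect_equal(ci$n_admissible, 4L)
  expect_equal(ci$n_concordant, 3L)

  expect_equal(concordance_index(c(1, 2, 3), c(1, 1, 0), c(5, 5, 5))$value, 0.5)
  expect_error(concordance_index(c(3, 3), c(1, 1), c(1, 2)), "admissible")
})

test_that("concordance matches a brute-force enumerator and its symmetries", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    t <- sample(1:10, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    e <- rbinom(n, 1, 0.7)
    r <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    got <- tryCatch(concordance_index(t, e, r)$value, error = function(x) NA)
    want <- tryCatch(cindex_brute(t, e, r), error = function(x) NA)
    expect_equal(got, want)
  }
  # monotone-transform invariance and complement symmetry (distinct risks)
  set.seed(32)
  t <- rexp(30); e <- rbinom(30, 1, 0.6); r <- rnorm(30)
  v <- concordance_index(t, e, r)$value
  expect_equal(concordance_index(t, e, exp(3 * r))$value, v)
  expect_equal(concordance_index(t, e, -r)$value, 1 - v)
})

test_that("fold plans are stratified on the event indicator, balanced and reproducible", {
  o <- data.frame(patient_id = sprintf("P%03d", 1:100),
                  time_months = rexp(100) + 0.1,
                  event = rep(c(0, 1), 50), endpoint = "RFS")
  fp <- make_folds(o, 5, 5, seed = 41)
  for (r in 1:5) {
    sizes <- lengths(fp$folds[[r]])
    expect_true(all(sizes == 20))
    ev <- vapply(fp$folds[[r]], function(ids)
      sum(o$event[match(ids, o$patient_id)]), numeric(1))
    expect_true(all(ev == 10))
    expect_setequal(unlist(fp$folds[[r]]), o$patient_id)
  }
  expect_identical(make_folds(o, 5, 5, seed = 41)$folds, fp$folds)

  o2 <- o[1:101 - 0, ]
  o2 <- rbind(o, data.frame(patient_id = "P101", time_months = 1,
                            event = 1, endpoint = "RFS"))
  fp2 <- make_folds(o2, 5, 1, seed = 42)
  expect_equal(sort(lengths(fp2$folds[[1]]), decreasing = TRUE),
               c(21, 20, 20, 20, 20))
  expect_error(make_folds(o[1:3, ], 5, 1, 1), "fewer")
})

test_that("cross-validated concordance averages the per-fold values", {
  o <- data.frame(patient_id = sprintf("P%03d", 1:60),
                  time_months = rexp(60) + 0.1,
                  event = rbinom(60, 1, 0.7), endpoint = "RFS")
  fp <- make_folds(o, 3, 2, seed = 43)
  set.seed(44)
  preds <- do.call(rbind, lapply(1:2, function(r) do.call(rbind, lapply(1:3, function(f)
    data.frame(patient_id = fp$folds[[r]][[f]], rep = r, fold = f,
               score = rnorm(length(fp$folds[[r]][[f]])))))))
  cv <- cv_cindex(preds, o, fp)
  expect_equal(cv$mean, mean(cv$per_fold$cindex))
  expect_equal(nrow(cv$per_fold), 6)
  hand <- vapply(seq_len(6), function(i) {
    pf <- cv$per_fold[i, ]
    sel <- preds$rep == pf$rep & preds$fold == pf$fold
    oo <- o[match(preds$patient_id[sel], o$patient_id), ]
    cindex_brute(oo$time_months, oo$event, preds$score[sel])
  }, numeric(1))
  expect_equal(cv$per_fold$cindex, hand)
  expect_error(cv_cindex(preds[-1, ], o, fp), "cover")
})

test_that("bootstrap comparison is null at identity, powered at a planted effect, antisymmetric", {
  co <- small_cohort(n = 150, d = 4, beta_hist = 1.5, beta_clin = 0, seed = 45,
                     tiles = c(3L, 6L), slides = c(1L, 1L))
  o <- co$outcomes
  fp <- make_folds(o, 3, 1, seed = 45)
  mk <- function(scores) do.call(rbind, lapply(1:3, function(f)
    data.frame(patient_id = fp$folds[[1]][[f]], rep = 1, fold = f,
               score = scores[match(fp$folds[[1]][[f]], o$patient_id)])))
  predsT <- mk(co$truth$eta)
  set.seed(46)
  predsN <- mk(rnorm(150))

  same <- bootstrap_compare(predsT, predsT, o, fp, B = 200, seed = 1)
  expect_true(all(same$deltas == 0))
  expect_equal(same$p, 1)

  bc <- bootstrap_compare(predsT, predsN, o, fp, B = 500, seed = 2)
  expect_lt(bc$p, 0.01)
  expect_gt(bc$delta_mean, 0)

  rev <- bootstrap_compare(predsN, predsT, o, fp, B = 500, seed = 2)
  expect_equal(rev$deltas, -bc$deltas)
  expect_equal(rev$p, bc$p)
})

test_that("median stratification sends ties to low risk", {
  expect_equal(unname(stratify_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(unname(stratify_by_median(c(1, 2, 3))), c("low", "low", "high"))
  set.seed(47)
  g <- stratify_by_median(rnorm(300))
  expect_equal(unname(table(g)["high"]), 150, ignore_attr = TRUE)
  expect_error(stratify_by_median(rep(2, 5)), "identical")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km$surv, c(0.5, 0))

  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))

  # no censoring: equals the empirical survival function
  set.seed(48)
  t <- sample(1:20, 15, replace = TRUE)
  km4 <- kaplan_meier(t, rep(1, 15))
  expect_equal(km4$surv, vapply(km4$time, function(u) mean(t > u), numeric(1)))
})

test_that("log-rank and hazard-ratio behave under known group structure", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two")

  set.seed(49)
  n <- 1000
  g <- rep(c("high", "low"), each = n / 2)
  t <- c(rexp(n / 2, 0.1), rexp(n / 2, 0.05))
  e <- rbinom(n, 1, 0.85)
  hr <- hazard_ratio(g, t, e)
  expect_gt(hr$hr, 1.7); expect_lt(hr$hr, 2.3)
  hr_flip <- hazard_ratio(ifelse(g == "high", "low", "high"), t, e)
  expect_equal(hr_flip$hr, 1 / hr$hr, tolerance = 1e-8)

  lr <- logrank_test(t, e, g)
  expect_lt(lr$p, 1e-6)

  # identical survival: HR near 1
  t0 <- rexp(n, 0.08); e0 <- rbinom(n, 1, 0.8)
  hr0 <- hazard_ratio(g, t0, e0)
  expect_lt(abs(log(hr0$hr)), 0.3)
})
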