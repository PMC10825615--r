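#!/usr/bin/env Rscript
# Stage 3 — evaluation: cross-validated concordance, bootstrap model
# comparison, and median-threshold stratification.
#
# For each model: the mean C-index over the 25 folds; pairwise bootstrap
# comparisons (patients resampled with replacement, per-fold C-indexes
# recomputed on the resampled membership, Z-test on the bootstrapped
# difference); and a median split of the pooled out-of-fold scores with
# Kaplan-Meier curves, a log-rank test and a Cox hazard ratio. Writes
# results/evaluation.json and results/km_curves.csv.

suppressMessages(library(milsurv))

seed <- 2026L
B <- 2000L
cohort <- read_cohort("results/cohort")
o <- cohort$outcomes
preds <- as.data.frame(data.table::fread("results/risks.csv"))
foldplan <- make_folds(o, n_folds = 5L, n_repeats = 5L, seed = seed)

models <- c("histologic", "clinical", "combined")
report <- list(seed = seed, models = list())
km_rows <- list()
for (m in models) {
  pm <- preds[preds$model == m, ]
  cv <- cv_cindex(pm, o, foldplan)
  pooled <- aggregate(score ~ patient_id, pm, mean)
  oo <- o[match(pooled$patient_id, o$patient_id), ]
  grp <- stratify_by_median(pooled$score)
  hr <- hazard_ratio(grp, oo$time_months, oo$event)
  lr <- logrank_test(oo$time_months, oo$event, grp)
  cat(sprintf("%-11s C=%.3f  HR=%.2f [%.2f, %.2f]  logrank p=%.2g\n",
              m, cv$mean, hr$hr, hr$ci_low, hr$ci_high, lr$p))
  for (g in c("high", "low")) {
    km <- kaplan_meier(oo$time_months[grp == g], oo$event[grp == g])
    km$model <- m; km$group <- g
    km_rows[[paste(m, g)]] <- km
  }
  report$models[[m]] <- list(cindex_mean = cv$mean,
                             cindex_per_fold = cv$per_fold$cindex,
                             hazard_ratio = hr, logrank = lr)
}
report$comparisons <- lapply(
  list(c("combined", "histologic"), c("combined", "clinical"),
       c("histologic", "clinical")),
  function(cmp) {
    bc <- bootstrap_compare(preds[preds$model == cmp[1], ],
                            preds[preds$model == cmp[2], ],
                            o, foldplan, B = B, seed = seed + 17L)
    cat(sprintf("%s vs %s: dC=%.4f, p=%.3g\n", cmp[1], cmp[2],
                bc$delta_mean, bc$p))
    list(a = cmp[1], b = cmp[2], delta_mean = bc$delta_mean, z = bc$z, p = bc$p)
  })

jsonlite::write_json(report, "results/evaluation.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = 10)
data.table::fwrite(do.call(rbind, km_rows), "results/km_curves.csv")
cat("evaluation written to results/evaluation.json and results/km_curves.csv\n")
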