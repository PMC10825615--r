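#' Experiment configuration
#'
#' Single source of truth for a full run: cohort source, endpoint, model
#' configurations, fold-plan and bootstrap parameters, attribution
#' parameters and the global seed every stage derives its randomness from.
#'
#' @param cohort_spec a [cohort_spec()] (synthetic source), or `NULL` with
#'   `cohort_dir` pointing at a [write_cohort()] directory.
#' @param cohort_dir directory of an on-disk cohort (ignored when
#'   `cohort_spec` given).
#' @param endpoint endpoint label under study.
#' @param mil_cfg a [mil_config()]; when `NULL` one is built from the
#'   cohort's feature dimension and `seed`.
#' @param covariates clinical covariates of the Cox arm.
#' @param n_folds,n_repeats fold-plan dimensions.
#' @param bootstrap_B bootstrap replicates for model comparison.
#' @param attribution_subsets subsets per bag for tile attribution.
#' @param attribution_top_k extreme tiles per direction.
#' @param fusion_mode see [combine_risks()].
#' @param seed global seed.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(cohort_spec = NULL, cohort_dir = NULL,
                              endpoint = "RFS", mil_cfg = NULL,
                              covariates = c("afp", "invasion", "tumor_count"),
                              n_folds = 5L, n_repeats = 5L,
                              bootstrap_B = 10000L,
                              attribution_subsets = 1000L,
                              attribution_top_k = 100L,
                              fusion_mode = "standardized_mean",
                              seed = 1L) {
  if (is.null(cohort_spec) && is.null(cohort_dir))
    stop("either a cohort spec or a cohort directory is required")
  if (!is.null(cohort_dir) && is.null(cohort_spec) && !dir.exists(cohort_dir))
    stop("cohort directory does not exist: ", cohort_dir)
  structure(list(cohort_spec = cohort_spec, cohort_dir = cohort_dir,
                 endpoint = endpoint, mil_cfg = mil_cfg,
                 covariates = covariates,
                 n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 bootstrap_B = as.integer(bootstrap_B),
                 attribution_subsets = as.integer(attribution_subsets),
                 attribution_top_k = as.integer(attribution_top_k),
                 fusion_mode = fusion_mode, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full experiment
#'
#' Executes every stage in order: cohort synthesis (or load), fold-plan
#' construction, per-fold training of both arms with fusion, evaluation
#' (cross-validated C-index per model, bootstrap pairwise comparisons,
#' median stratification with Kaplan-Meier, log-rank and hazard ratio), and
#' tile attribution with enrichment against planted tile labels when those
#' exist. All artifacts (`risks.csv`, `evaluation.json`, `km_curves.csv`,
#' `attributions.csv`, `enrichment.csv`, `manifest.json`) are written under
#' `out_dir`; reruns with the same config reproduce them.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @return The run manifest, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function(name, prev) {
    now <- proc.time()[["elapsed"]]
    stage_times[[name]] <<- round(now - prev, 3)
    now
  }
  manifest <- list(seed = config$seed, endpoint = config$endpoint,
                   status = "failed", stage_times = NULL, files = character(0))
  write_manifest <- function() {
    manifest$stage_times <- as.list(stage_times)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(write_manifest())

  t <- t_start
  cohort <- if (!is.null(config$cohort_spec)) generate_cohort(config$cohort_spec)
            else read_cohort(config$cohort_dir)
  t <- tick("cohort", t)

  o <- cohort$outcomes[cohort$outcomes$endpoint == config$endpoint, ]
  if (nrow(o) == 0L) stop("no outcomes for endpoint ", config$endpoint)
  foldplan <- make_folds(o, config$n_folds, config$n_repeats,
                         seed = config$seed)
  t <- tick("folds", t)

  mil_cfg <- config$mil_cfg
  if (is.null(mil_cfg))
    mil_cfg <- mil_config(feature_dim = ncol(cohort$bags[[1]]$features),
                          seed = config$seed)
  preds <- predict_all_models(cohort, foldplan, mil_cfg,
                              covariates = config$covariates,
                              endpoint = config$endpoint,
                              mode = config$fusion_mode)
  risks_path <- file.path(out_dir, "risks.csv")
  data.table::fwrite(preds, risks_path)
  t <- tick("models", t)

  models <- c("histologic", "clinical", "combined")
  evaluation <- list(endpoint = config$endpoint, seed = config$seed,
                     models = list())
  km_rows <- list()
  for (m in models) {
    pm <- model_predictions(preds, m)
    cv <- cv_cindex(pm, o, foldplan)
    pooled <- stats::aggregate(score ~ patient_id, pm, mean)
    oo <- o[match(pooled$patient_id, o$patient_id), ]
    grp <- stratify_by_median(pooled$score)
    lr <- logrank_test(oo$time_months, oo$event, grp)
    hr <- hazard_ratio(grp, oo$time_months, oo$event)
    for (g in c("high", "low")) {
      km <- kaplan_meier(oo$time_months[grp == g], oo$event[grp == g])
      km$model <- m; km$group <- g
      km_rows[[paste(m, g)]] <- km
    }
    evaluation$models[[m]] <- list(
      cindex_mean = cv$mean,
      cindex_per_fold = cv$per_fold$cindex,
      dropped_folds = cv$n_dropped,
      hazard_ratio = hr, logrank = lr)
  }
  comparisons <- list(c("combined", "histologic"), c("combined", "clinical"),
                      c("histologic", "clinical"))
  evaluation$comparisons <- lapply(comparisons, function(cmp) {
    bc <- bootstrap_compare(model_predictions(preds, cmp[1]),
                            model_predictions(preds, cmp[2]),
                            o, foldplan, B = config$bootstrap_B,
                            seed = config$seed + 17L)
    list(a = cmp[1], b = cmp[2], delta_mean = bc$delta_mean, z = bc$z, p = bc$p)
  })
  eval_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(evaluation, eval_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  km_path <- file.path(out_dir, "km_curves.csv")
  data.table::fwrite(do.call(rbind, km_rows), km_path)
  t <- tick("evaluation", t)

  # attribution uses a model trained on the full cohort
  full_cfg <- mil_cfg; full_cfg$seed <- mil_cfg$seed + 99991L
  full_view <- split_modalities(cohort)$histologic
  full_view$outcomes <- o
  mil_full <- mil_train(full_view, full_cfg)$model
  attr_df <- attribute_cohort(mil_full, cohort$bags,
                              n_subsets = config$attribution_subsets,
                              seed = config$seed + 7L)
  attr_path <- file.path(out_dir, "attributions.csv")
  data.table::fwrite(attr_df, attr_path)
  enr_path <- NULL
  if (!is.null(attr_df$tile_label)) {
    ext <- select_extreme_tiles(attr_df, k = config$attribution_top_k)
    ann <- rbind(ext$high, ext$low)
    enr <- enrichment_table(
      matrix(ann$tile_label, ncol = 1L,
             dimnames = list(NULL, "signature")),
      c(rep("high", nrow(ext$high)), rep("low", nrow(ext$low))))
    enr_path <- file.path(out_dir, "enrichment.csv")
    data.table::fwrite(enr, enr_path)
  }
  t <- tick("attribution", t)

  manifest$status <- "ok"
  manifest$files <- basename(c(risks_path, eval_path, km_path, attr_path,
                               enr_path, file.path(out_dir, "manifest.json")))
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_start, 3)
  invisible(manifest)
}

#' Pretrain-then-fine-tune transfer protocol
#'
#' Trains the tile-bag model once on a pretraining cohort (default 20
#' epochs), then fine-tunes a copy per target cohort/endpoint (default 10
#' epochs) and evaluates each fine-tuned model by cross-validated C-index
#' on its target cohort.
#'
#' @param pretrain_cohort cohort for the initial fit.
#' @param finetune_cohorts named list of target cohorts.
#' @param mil_cfg shared [mil_config()]; feature dimensions must match.
#' @param n_folds,n_repeats,seed evaluation fold plan per target.
#' @return List with `pretrained` model and, per target, `model` and
#'   `cv` (out-of-fold C-index of the fine-tuned model's scores).
#' @export
transfer_protocol <- function(pretrain_cohort, finetune_cohorts, mil_cfg,
                              n_folds = 5L, n_repeats = 1L, seed = 1L) {
  d0 <- ncol(pretrain_cohort$bags[[1]]$features)
  for (co in finetune_cohorts)
    if (ncol(co$bags[[1]]$features) != d0)
      stop("feature dimension mismatch between pretraining and fine-tuning cohorts")
  pre <- mil_train(pretrain_cohort, mil_cfg)$model
  out <- list(pretrained = pre, targets = list())
  for (nm in names(finetune_cohorts)) {
    co <- finetune_cohorts[[nm]]
    views <- split_modalities(co)
    o <- co$outcomes
    fp <- make_folds(o, n_folds, n_repeats, seed = seed)
    rows <- list()
    for (r in seq_len(n_repeats)) for (f in seq_len(n_folds)) {
      tr <- fold_train_ids(fp, r, f); te <- fold_test_ids(fp, r, f)
      cfg <- mil_cfg; cfg$seed <- mil_cfg$seed + 1000L * r + f
      hv <- list(patient_id = tr, bags = views$histologic$bags[tr],
                 outcomes = o[match(tr, o$patient_id), ])
      ft <- fine_tune(pre, hv, cfg)$model
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = te, rep = r, fold = f, model = "histologic",
                   score = predict_cohort(ft, views$histologic, te)$score)
    }
    preds <- do.call(rbind, rows)
    model_full <- fine_tune(pre, co, mil_cfg)$model
    out$targets[[nm]] <- list(model = model_full,
                              cv = cv_cindex(preds, o, fp))
  }
  out
}
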