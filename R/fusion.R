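#' Fuse histologic and clinical risk predictions
#'
#' The combined model averages the two arms' predictions patient by
#' patient. A Cox linear predictor and a tile-bag risk live on incomparable
#' scales, so the default first z-standardizes each arm within a fold using
#' statistics estimated on the *training* patients of that fold (passed in
#' as `center`/`scale_` per arm) and then takes the plain mean; `raw_mean`
#' averages the scores as-is. Weights are fixed at 1/2 each.
#'
#' @param hist,clin data.frames with `patient_id`, `score` (and optionally
#'   `rep`, `fold`), covering identical patient sets.
#' @param mode `"standardized_mean"` (default) or `"raw_mean"`.
#' @param center,scale_ length-2 numeric vectors (hist, clin) of the
#'   standardization statistics; required for `standardized_mean`. Scale 0
#'   (a constant training score set) is an error.
#' @return data.frame like `hist` with the combined `score`.
#' @export
combine_risks <- function(hist, clin, mode = c("standardized_mean", "raw_mean"),
                          center = NULL, scale_ = NULL) {
  mode <- match.arg(mode)
  if (!setequal(hist$patient_id, clin$patient_id))
    stop("histologic and clinical predictions cover different patients")
  clin <- clin[match(hist$patient_id, clin$patient_id), ]
  if (mode == "standardized_mean") {
    if (is.null(center) || is.null(scale_))
      stop("standardized_mean needs training-fold center and scale")
    if (any(scale_ == 0)) stop("zero-variance training scores cannot be standardized")
    h <- (hist$score - center[1L]) / scale_[1L]
    c_ <- (clin$score - center[2L]) / scale_[2L]
  } else {
    h <- hist$score; c_ <- clin$score
  }
  out <- hist
  out$score <- (h + c_) / 2
  out
}

#' Out-of-fold predictions for the three models
#'
#' For every (repeat, fold) of the plan: trains the tile-bag survival model
#' and fits the clinical Cox model on the training patients only, scores
#' the held-out patients with both, and fuses the two scores using
#' standardization statistics taken from the training-fold predictions —
#' so no held-out information leaks into any score.
#'
#' @param cohort cohort list with `bags`, `clinical`, `outcomes`.
#' @param foldplan a [make_folds()] plan over the cohort's patients.
#' @param mil_cfg a [mil_config()] (a fresh model is trained per fold, seed
#'   offset by fold).
#' @param covariates clinical covariate columns for the Cox arm.
#' @param endpoint endpoint label selecting outcome rows.
#' @param mode fusion mode, see [combine_risks()].
#' @return data.frame with `patient_id`, `rep`, `fold`, `model` in
#'   {histologic, clinical, combined}, `score`.
#' @export
predict_all_models <- function(cohort, foldplan, mil_cfg,
                               covariates = c("afp", "invasion", "tumor_count"),
                               endpoint = cohort$outcomes$endpoint[1],
                               mode = "standardized_mean") {
  views <- split_modalities(cohort)
  o <- cohort$outcomes[cohort$outcomes$endpoint == endpoint, ]
  X <- clinical_design(cohort$clinical, covariates)
  rows <- list()
  for (r in seq_len(foldplan$n_repeats)) {
    for (f in seq_len(foldplan$n_folds)) {
      tr <- fold_train_ids(foldplan, r, f)
      te <- fold_test_ids(foldplan, r, f)
      otr <- o[match(tr, o$patient_id), ]

      cfg <- mil_cfg
      cfg$seed <- mil_cfg$seed + 1000L * r + f
      hist_view <- list(patient_id = tr, bags = views$histologic$bags[tr],
                        outcomes = otr)
      mil <- mil_train(hist_view, cfg)$model
      h_tr <- predict_cohort(mil, views$histologic, tr)$score
      h_te <- predict_cohort(mil, views$histologic, te)$score

      cox <- fit_cox(X[tr, , drop = FALSE], otr$time_months, otr$event)
      c_tr <- linear_predictor(cox, X[tr, , drop = FALSE])
      c_te <- linear_predictor(cox, X[te, , drop = FALSE])

      hist_df <- data.frame(patient_id = te, rep = r, fold = f,
                            model = "histologic", score = h_te,
                            stringsAsFactors = FALSE)
      clin_df <- data.frame(patient_id = te, rep = r, fold = f,
                            model = "clinical", score = c_te,
                            stringsAsFactors = FALSE)
      comb <- combine_risks(hist_df, clin_df, mode = mode,
                            center = c(mean(h_tr), mean(c_tr)),
                            scale_ = c(stats::sd(h_tr), stats::sd(c_tr)))
      comb$model <- "combined"
      rows[[length(rows) + 1L]] <- rbind(hist_df, clin_df, comb)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

model_predictions <- function(preds, which) {
  out <- preds[preds$model == which, , drop = FALSE]
  rownames(out) <- NULL
  out
}
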