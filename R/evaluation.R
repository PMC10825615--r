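#' Harrell's concordance index
#'
#' Fraction of admissible patient pairs whose risk ordering matches their
#' survival ordering. A pair (i, j) is admissible when the shorter observed
#' time belongs to a patient who had the event (`t_i < t_j` and
#' `event_i = 1`, or symmetrically); pairs with tied times are not
#' admissible. An admissible pair is concordant when the shorter-lived
#' patient carries the strictly higher risk; tied risks count 1/2.
#'
#' @param times,events,risks aligned numeric vectors.
#' @return An object of class `cindex_result`: `value`, `n_admissible`,
#'   `n_concordant`, `n_tied_risk`.
#' @export
concordance_index <- function(times, events, risks) {
  stopifnot(length(times) == length(events), length(times) == length(risks))
  # unordered pairs, counted once: i is the strictly shorter-time member
  adm <- outer(times, times, `<`) & (events == 1)
  conc <- sum(adm & outer(risks, risks, `>`))
  tied <- sum(adm & outer(risks, risks, `==`))
  n_adm <- sum(adm)
  if (n_adm == 0L)
    stop("no admissible pairs (all censored or all times tied)")
  structure(list(value = (conc + 0.5 * tied) / n_adm,
                 n_admissible = n_adm, n_concordant = conc,
                 n_tied_risk = tied),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%d concordant + %d/2 tied of %d admissible pairs)\n",
              x$value, x$n_concordant, x$n_tied_risk, x$n_admissible))
  invisible(x)
}

cindex_value <- function(times, events, risks)
  concordance_index(times, events, risks)$value

#' Repeated stratified cross-validation plan
#'
#' Builds `n_repeats` independent random partitions of the patients into
#' `n_folds` folds, each partition stratified on the event indicator so the
#' censoring mix is balanced across folds (event counts per fold differ by
#' at most one).
#'
#' @param outcomes outcome table (one endpoint) with `patient_id` and
#'   `event`.
#' @param n_folds,n_repeats plan dimensions (default 5 x 5).
#' @param seed integer seed; the plan is deterministic given it.
#' @return Object of class `fold_plan`: list `folds[[repeat]][[fold]]` of
#'   held-out patient-id vectors, plus the plan parameters.
#' @export
make_folds <- function(outcomes, n_folds = 5L, n_repeats = 5L, seed = 1L) {
  pid <- outcomes$patient_id
  ev <- outcomes$event
  if (length(pid) < n_folds) stop("fewer patients than folds")
  if (sum(ev) < n_folds)
    warning("fewer events than folds; stratification is best-effort")
  plan <- local_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      assign_fold <- integer(length(pid))
      for (g in unique(ev)) {
        idx <- which(ev == g)
        idx <- idx[sample.int(length(idx))]
        assign_fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      lapply(seq_len(n_folds), function(f) pid[assign_fold == f])
    })
  })
  structure(list(folds = plan, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 patient_id = pid),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds x %d repeats over %d patients (seed %d)\n",
              x$n_folds, x$n_repeats, length(x$patient_id), x$seed))
  invisible(x)
}

fold_test_ids <- function(foldplan, r, f) foldplan$folds[[r]][[f]]
fold_train_ids <- function(foldplan, r, f)
  setdiff(foldplan$patient_id, foldplan$folds[[r]][[f]])

#' Cross-validated concordance
#'
#' C-index computed within each held-out fold of the plan, then averaged
#' (unweighted) over all `n_folds * n_repeats` folds. Folds without an
#' admissible pair are dropped with a warning.
#'
#' @param predictions data.frame of out-of-fold scores with columns
#'   `patient_id`, `rep`, `fold`, `score` (a single model).
#' @param outcomes outcome table for the endpoint under study.
#' @param foldplan the [make_folds()] plan the predictions were made under.
#' @return List with `mean`, `per_fold` (data.frame rep, fold, cindex) and
#'   `n_dropped`.
#' @export
cv_cindex <- function(predictions, outcomes, foldplan) {
  o <- outcomes[match(predictions$patient_id, outcomes$patient_id), ]
  rows <- list(); dropped <- 0L
  for (r in seq_len(foldplan$n_repeats)) {
    for (f in seq_len(foldplan$n_folds)) {
      sel <- predictions$rep == r & predictions$fold == f
      ids <- fold_test_ids(foldplan, r, f)
      if (!setequal(predictions$patient_id[sel], ids))
        stop(sprintf("predictions do not cover fold %d of repeat %d", f, r))
      ci <- tryCatch(
        cindex_value(o$time_months[sel], o$event[sel], predictions$score[sel]),
        error = function(e) NA_real_)
      if (is.na(ci)) { dropped <- dropped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(rep = r, fold = f, cindex = ci)
    }
  }
  if (dropped > 0L) warning(dropped, " fold(s) without admissible pairs dropped")
  per_fold <- do.call(rbind, rows)
  list(mean = mean(per_fold$cindex), per_fold = per_fold, n_dropped = dropped)
}

#' Bootstrap comparison of two models' cross-validated concordance
#'
#' Patients are resampled with replacement `B` times; for every replicate
#' the per-fold C-indexes of both models are recomputed on the resampled
#' fold membership (out-of-fold predictions are fixed; no refitting) and
#' averaged over folds, giving a bootstrapped difference
#' `delta = C_A - C_B`. The p-value is the two-sided normal tail of
#' `mean(delta) / sd(delta)`. Replicates in which no fold has an admissible
#' pair are redrawn. Identical prediction sets give `delta = 0` everywhere
#' and p = 1 by convention.
#'
#' @param predsA,predsB out-of-fold prediction data.frames (as in
#'   [cv_cindex()]) on the same fold plan.
#' @param outcomes outcome table.
#' @param foldplan shared [make_folds()] plan.
#' @param B bootstrap replicates (the reference protocol uses 10000).
#' @param seed integer seed for the resampling.
#' @return List with `delta_mean`, `z`, `p`, and the replicate `deltas`.
#' @export
bootstrap_compare <- function(predsA, predsB, outcomes, foldplan,
                              B = 10000L, seed = 1L) {
  pid <- foldplan$patient_id
  n <- length(pid)
  o <- outcomes[match(pid, outcomes$patient_id), ]
  # per fold: positions (into pid) of its test patients plus both score sets
  fold_data <- list()
  for (r in seq_len(foldplan$n_repeats)) for (f in seq_len(foldplan$n_folds)) {
    ids <- fold_test_ids(foldplan, r, f)
    pos <- match(ids, pid)
    selA <- predsA$rep == r & predsA$fold == f
    selB <- predsB$rep == r & predsB$fold == f
    sA <- predsA$score[selA][match(ids, predsA$patient_id[selA])]
    sB <- predsB$score[selB][match(ids, predsB$patient_id[selB])]
    if (anyNA(sA) || anyNA(sB)) stop("predictions do not cover the fold plan")
    fold_data[[length(fold_data) + 1L]] <-
      list(pos = pos, time = o$time_months[pos], event = o$event[pos],
           sA = sA, sB = sB)
  }
  deltas <- numeric(B)
  local_seed(seed, {
    b <- 1L
    while (b <= B) {
      counts <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      cA <- cB <- c()
      for (fd in fold_data) {
        reps <- rep(seq_along(fd$pos), counts[fd$pos])
        if (length(reps) < 2L) next
        ciA <- tryCatch(cindex_value(fd$time[reps], fd$event[reps], fd$sA[reps]),
                        error = function(e) NA_real_)
        if (is.na(ciA)) next
        ciB <- cindex_value(fd$time[reps], fd$event[reps], fd$sB[reps])
        cA <- c(cA, ciA); cB <- c(cB, ciB)
      }
      if (!length(cA)) next   # degenerate replicate: redraw
      deltas[b] <- mean(cA) - mean(cB)
      b <- b + 1L
    }
  })
  sd_d <- stats::sd(deltas)
  if (sd_d == 0) {
    z <- 0; p <- 1
  } else {
    z <- mean(deltas) / sd_d
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(delta_mean = mean(deltas), z = z, p = p, deltas = deltas)
}

#' Median-threshold risk stratification
#'
#' Splits patients into high- and low-risk groups at the median of their
#' scores: strictly above the median is high risk, at or below is low risk
#' (ties to low).
#'
#' @param scores named or plain numeric vector of risk scores (>= 2).
#' @return Character vector in {"high", "low"} aligned with `scores`.
#' @export
stratify_by_median <- function(scores) {
  stopifnot(length(scores) >= 2L)
  if (length(unique(scores)) == 1L)
    stop("all scores identical: median stratification is undefined")
  m <- stats::median(scores)
  out <- ifelse(scores > m, "high", "low")
  names(out) <- names(scores)
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function (via
#' [survival::survfit()]), returned as a step-function table.
#'
#' @param times,events aligned outcome vectors.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv`, rows at the
#'   distinct observed times.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) >= 1L)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk,
             n_event = sf$n.event, surv = sf$surv)
}

#' Two-group log-rank test
#'
#' @param times,events outcome vectors.
#' @param groups two-level factor/character of group labels.
#' @return List with `chisq` (1 df) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("logrank_test needs exactly two non-empty groups")
  if (sum(events) < 1) stop("no events in either group")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = sd_$chisq, p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE))
}

#' Hazard ratio between two risk groups
#'
#' Univariate Cox fit on the binary group indicator (high vs low).
#'
#' @param groups labels in {"high", "low"}.
#' @param times,events outcome vectors.
#' @return List with `hr`, `ci_low`, `ci_high`, `p` (high relative to low).
#' @export
hazard_ratio <- function(groups, times, events) {
  x <- matrix(as.numeric(groups == "high"), ncol = 1L,
              dimnames = list(NULL, "high_risk"))
  f <- fit_cox(x, times, events)
  list(hr = f$hr[1L], ci_low = f$ci_low[1L], ci_high = f$ci_high[1L],
       p = f$p[1L])
}
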