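#' Exact subset-sampling tile contributions
#'
#' A slide is a set of N tiles; the prediction can be evaluated on any
#' non-empty subset. The contribution of tile i is the mean prediction over
#' all non-empty subsets containing i minus the mean over all non-empty
#' subsets not containing i. (Uniform weighting over subsets makes this a
#' Banzhaf-type value rather than the Shapley weighting; the difference-of-
#' conditional-means definition is implemented as stated.) Exact enumeration
#' costs 2^N - 1 predictions and is capped at N = 20.
#'
#' @param predict_fn function taking an integer vector of tile indices and
#'   returning the scalar prediction for that sub-bag; see
#'   [mil_subset_predictor()].
#' @param n_tiles_bag number of tiles N in the bag (<= 20).
#' @return Object of class `attribution_result`: data.frame `contributions`
#'   (tile, contribution, se) with `se = 0`, `n_subsets`, `method = "exact"`.
#' @export
exact_contributions <- function(predict_fn, n_tiles_bag) {
  N <- as.integer(n_tiles_bag)
  if (N > 20L)
    stop("exact enumeration capped at N = 20 tiles; use sampled_contributions()")
  stopifnot(N >= 1L)
  n_sub <- 2L^N - 1L
  preds <- numeric(n_sub)
  member <- matrix(FALSE, n_sub, N)
  for (m in seq_len(n_sub)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(N - 1L))) != 0L)
    member[m, idx] <- TRUE
    preds[m] <- predict_fn(idx)
  }
  contrib <- vapply(seq_len(N), function(i) {
    inside <- member[, i]
    mean(preds[inside]) - if (any(!inside)) mean(preds[!inside]) else NA_real_
  }, numeric(1))
  structure(list(contributions = data.frame(tile = seq_len(N),
                                            contribution = contrib, se = 0),
                 n_subsets = n_sub, method = "exact"),
            class = "attribution_result")
}

#' Monte-Carlo subset-sampling tile contributions
#'
#' Estimates the same estimand as [exact_contributions()] by sampling
#' subsets: each tile enters a subset independently with probability 1/2
#' (uniform over all subsets) and empty draws are rejected, matching the
#' subset sizes running from 1 to N. Per tile, the estimate is the mean
#' prediction over sampled subsets containing it minus the mean over those
#' not containing it; the standard error combines the two group means. A
#' tile that never landed in both groups is returned as `NA` and flagged.
#'
#' @param predict_fn as in [exact_contributions()].
#' @param n_tiles_bag number of tiles N.
#' @param n_subsets subsets to sample (default 10000, >= 100).
#' @param seed integer seed; the draw is deterministic given it.
#' @return `attribution_result` with `method = "sampled"`, per-tile
#'   Monte-Carlo standard errors and an `undetermined` tile-index vector.
#' @export
sampled_contributions <- function(predict_fn, n_tiles_bag,
                                  n_subsets = 10000L, seed = 1L) {
  N <- as.integer(n_tiles_bag)
  stopifnot(N >= 1L, n_subsets >= 100L)
  local_seed(seed, {
    member <- matrix(stats::runif(n_subsets * N) < 0.5, n_subsets, N)
    empty <- rowSums(member) == 0L
    while (any(empty)) {
      member[empty, ] <- matrix(stats::runif(sum(empty) * N) < 0.5,
                                sum(empty), N)
      empty <- rowSums(member) == 0L
    }
    preds <- vapply(seq_len(n_subsets),
                    function(m) predict_fn(which(member[m, ])), numeric(1))
    est <- se <- rep(NA_real_, N)
    for (i in seq_len(N)) {
      inside <- member[, i]
      n1 <- sum(inside); n0 <- n_subsets - n1
      if (n1 == 0L || n0 == 0L) next
      est[i] <- mean(preds[inside]) - mean(preds[!inside])
      v1 <- if (n1 > 1L) stats::var(preds[inside]) else 0
      v0 <- if (n0 > 1L) stats::var(preds[!inside]) else 0
      se[i] <- sqrt(v1 / n1 + v0 / n0)
    }
    structure(list(contributions = data.frame(tile = seq_len(N),
                                              contribution = est, se = se),
                   n_subsets = n_subsets, method = "sampled",
                   undetermined = which(is.na(est))),
              class = "attribution_result")
  })
}

#' Subset predictor for a tile-bag survival model
#'
#' Returns a closure `f(idx)` giving the model's slide risk for the
#' sub-bag made of tiles `idx`. Tile scores do not depend on the subset, so
#' they are computed once and cached; each subset evaluation only re-selects
#' the extreme scores and reruns the prediction head.
#'
#' @param model a trained `mil_model`.
#' @param bag a [tile_bag()].
#' @return Function from integer tile-index vectors to a scalar risk.
#' @export
mil_subset_predictor <- function(model, bag) {
  scores <- score_tiles(model, bag)
  k <- model$config$n_extreme
  head_layers <- model$head
  function(idx) {
    s <- scores[idx]
    v <- s[extreme_indices(s, k)]
    drop(mlp_forward(head_layers, matrix(v, nrow = 1L))$out)
  }
}

#' Per-tile contributions across a cohort
#'
#' Runs [sampled_contributions()] on every bag with the model's cached-score
#' subset predictor and assembles the cohort-wide attribution table.
#'
#' @param model trained `mil_model`.
#' @param bags list of [tile_bag()].
#' @param n_subsets,seed passed to [sampled_contributions()] (the per-bag
#'   seed is offset by the bag's position).
#' @return data.frame: `slide_id`, `patient_id`, `tile`, `x`, `y`,
#'   `contribution`, `se`, and `tile_label` when the bags carry labels.
#' @export
attribute_cohort <- function(model, bags, n_subsets = 1000L, seed = 1L) {
  rows <- lapply(seq_along(bags), function(b) {
    bag <- bags[[b]]
    ar <- sampled_contributions(mil_subset_predictor(model, bag),
                                n_tiles(bag), n_subsets, seed + b)
    out <- data.frame(slide_id = bag$slide_id, patient_id = bag$patient_id,
                      tile = ar$contributions$tile,
                      x = bag$coords[, 1L], y = bag$coords[, 2L],
                      contribution = ar$contributions$contribution,
                      se = ar$contributions$se,
                      stringsAsFactors = FALSE)
    if (!is.null(bag$tile_labels)) out$tile_label <- bag$tile_labels
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extreme-contribution tile selection
#'
#' The k tiles with the highest contributions (high-risk set) and the k
#' with the lowest (low-risk set), cohort-wide. Ties are broken by
#' (slide_id, tile index) so the selection is deterministic.
#'
#' @param attributions cohort attribution table from [attribute_cohort()].
#' @param k tiles per extreme set (default 100).
#' @return List with data.frames `high` and `low`.
#' @export
select_extreme_tiles <- function(attributions, k = 100L) {
  if (nrow(attributions) < 2L * k)
    stop("need at least 2k tiles to select k high and k low")
  ord_high <- order(-attributions$contribution,
                    attributions$slide_id, attributions$tile)
  ord_low <- order(attributions$contribution,
                   attributions$slide_id, attributions$tile)
  list(high = attributions[ord_high[seq_len(k)], , drop = FALSE],
       low = attributions[ord_low[seq_len(k)], , drop = FALSE])
}

#' Two-proportion Z-test
#'
#' Pooled two-sample Z statistic for H0: p1 = p2, with a two-sided normal
#' p-value and no continuity correction.
#'
#' @param x1,n1 successes and size of group 1.
#' @param x2,n2 successes and size of group 2.
#' @return List with `z` and `p`.
#' @export
proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) return(list(z = 0, p = 1))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down multiple-testing correction using Sidak's inequality: with the
#' raw p-values sorted ascending, the i-th adjusted value is
#' `max_{j <= i} 1 - (1 - p_(j))^(m - j + 1)`, capped at 1, and results are
#' returned in the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
holm_sidak <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  ord <- order(pvals)
  ps <- pvals[ord]
  # -expm1(k * log1p(-p)) is 1 - (1 - p)^k without cancellation near p = 0
  adj <- pmin(1, cummax(-expm1((m - seq_len(m) + 1) * log1p(-ps))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "+", "-"))
}

#' Feature-enrichment table for extreme tiles
#'
#' Compares, feature by feature, the proportion of annotated high-risk vs
#' low-risk tiles carrying each binary feature: pooled two-proportion
#' Z-tests with Holm-Sidak adjustment across features, plus the
#' significance tiers used in the accompanying reports (***, **, *, +, -).
#' Features absent from both groups are skipped and listed in the
#' `skipped` attribute.
#'
#' @param annotations logical/0-1 matrix or data.frame, one row per tile,
#'   one column per feature.
#' @param groups per-tile labels in {"high", "low"}.
#' @return data.frame with `feature`, `total`, `high_risk`, `low_risk`,
#'   `z`, `p_raw`, `p_adj`, `tier`.
#' @export
enrichment_table <- function(annotations, groups) {
  A <- as.matrix(annotations)
  if (is.null(colnames(A)) && ncol(A) > 0L)
    colnames(A) <- paste0("feature", seq_len(ncol(A)))
  stopifnot(nrow(A) == length(groups), all(groups %in% c("high", "low")))
  n_hi <- sum(groups == "high"); n_lo <- sum(groups == "low")
  rows <- list(); skipped <- character(0)
  for (v in colnames(A)) {
    x_hi <- sum(A[groups == "high", v]); x_lo <- sum(A[groups == "low", v])
    if (x_hi + x_lo == 0) { skipped <- c(skipped, v); next }
    zt <- proportion_ztest(x_hi, n_hi, x_lo, n_lo)
    rows[[v]] <- data.frame(feature = v, total = x_hi + x_lo,
                            high_risk = x_hi, low_risk = x_lo,
                            z = zt$z, p_raw = zt$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature = character(0), total = integer(0),
                      high_risk = integer(0), low_risk = integer(0),
                      z = numeric(0), p_raw = numeric(0))
  out$p_adj <- holm_sidak(out$p_raw)
  out$tier <- as.character(significance_tier(out$p_adj))
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
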