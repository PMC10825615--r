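#' Configuration of the tile-scoring survival model
#'
#' The model maps each tile's feature vector to a scalar tile score with a
#' small multilayer perceptron, summarizes a slide by the sorted top-k and
#' bottom-k tile scores (the extremes are where a minority prognostic tile
#' population shows up), and maps that 2k-vector to a scalar slide risk with
#' a second perceptron. Patient risk is the mean over the patient's slides.
#' Training minimizes a smooth concordance-index loss by minibatch Adam.
#'
#' @param feature_dim tile feature dimension d.
#' @param scoring_hidden integer vector of hidden-layer widths of the
#'   tile-scoring map (empty for a linear scorer).
#' @param n_extreme k, number of top and of bottom tile scores kept.
#' @param head_hidden hidden widths of the prediction head.
#' @param tau temperature of the logistic relaxation of the concordance
#'   index; the loss approaches the hard C-index complement as `tau -> 0`.
#' @param learning_rate Adam step size.
#' @param batch_size patients per minibatch (ranking pairs are formed within
#'   a batch).
#' @param epochs_pretrain training epochs for a from-scratch fit.
#' @param epochs_finetune epochs used when continuing from a pretrained
#'   model.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return An object of class `mil_config`.
#' @export
mil_config <- function(feature_dim,
                       scoring_hidden = c(16L),
                       n_extreme = 25L,
                       head_hidden = c(8L),
                       tau = 1,
                       learning_rate = 1e-2,
                       batch_size = 32L,
                       epochs_pretrain = 20L,
                       epochs_finetune = 10L,
                       seed = 1L) {
  stopifnot(feature_dim >= 1, n_extreme >= 1, tau > 0,
            epochs_pretrain >= 1, epochs_finetune >= 0, batch_size >= 2)
  structure(list(feature_dim = as.integer(feature_dim),
                 scoring_hidden = as.integer(scoring_hidden),
                 n_extreme = as.integer(n_extreme),
                 head_hidden = as.integer(head_hidden),
                 tau = tau, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 seed = as.integer(seed)),
            class = "mil_config")
}

#' Initialize an untrained model
#'
#' @param config a [mil_config()].
#' @return An object of class `mil_model` holding the tile-scoring and
#'   prediction-head parameters plus its config.
#' @export
mil_init <- function(config) {
  stopifnot(inherits(config, "mil_config"))
  local_seed(config$seed, {
    scoring <- mlp_init(c(config$feature_dim, config$scoring_hidden, 1L))
    head <- mlp_init(c(2L * config$n_extreme, config$head_hidden, 1L))
    structure(list(scoring = scoring, head = head, config = config),
              class = "mil_model")
  })
}

mil_theta <- function(model) c(mlp_flatten(model$scoring), mlp_flatten(model$head))

mil_set_theta <- function(model, theta) {
  ns <- length(mlp_flatten(model$scoring))
  model$scoring <- mlp_unflatten(model$scoring, theta[seq_len(ns)])
  model$head <- mlp_unflatten(model$head, theta[-seq_len(ns)])
  model
}

#' Per-tile scores
#'
#' Applies the tile-scoring map to every tile of a bag. The map acts on each
#' feature row independently, so scores are equivariant under tile
#' permutation and duplicated tiles receive duplicated scores.
#'
#' @param model a [mil_init()]-style `mil_model`.
#' @param bag a [tile_bag()] or a bare feature matrix.
#' @return Numeric vector, one score per tile.
#' @export
score_tiles <- function(model, bag) {
  X <- if (inherits(bag, "tile_bag")) bag$features else as.matrix(bag)
  if (ncol(X) != model$config$feature_dim)
    stop("feature dimension ", ncol(X), " does not match model (",
         model$config$feature_dim, ")")
  drop(mlp_forward(model$scoring, X)$out)
}

# Indices of the 2k extreme scores: k largest (descending) then k smallest
# (ascending). Bags with fewer than k tiles recycle their observed extremes
# so the head input size stays fixed.
extreme_indices <- function(scores, k) {
  n <- length(scores)
  ord <- order(scores)
  top <- rep_len(rev(ord)[seq_len(min(k, n))], k)
  bot <- rep_len(ord[seq_len(min(k, n))], k)
  c(top, bot)
}

#' Slide-level risk
#'
#' Risk of one slide: the prediction head applied to the sorted top-k and
#' bottom-k tile scores. Invariant to tile order by construction.
#'
#' @inheritParams score_tiles
#' @return A single finite risk score.
#' @export
predict_slide <- function(model, bag) {
  s <- score_tiles(model, bag)
  if (length(s) == 0L) stop("empty bag")
  v <- s[extreme_indices(s, model$config$n_extreme)]
  drop(mlp_forward(model$head, matrix(v, nrow = 1L))$out)
}

#' Patient-level risk
#'
#' The model is applied independently to each of the patient's slides and
#' the slide risks are averaged.
#'
#' @param model a `mil_model`.
#' @param bags list of [tile_bag()] for one patient (at least one).
#' @return A single risk score.
#' @export
predict_patient <- function(model, bags) {
  stopifnot(length(bags) >= 1L)
  mean(vapply(bags, function(b) predict_slide(model, b), numeric(1)))
}

#' Cohort-wide patient risks
#'
#' @param model a `mil_model`.
#' @param hist histologic view from [split_modalities()], or a cohort list
#'   with `bags` and `clinical`.
#' @param patient_ids optional subset of patients to score.
#' @return data.frame with `patient_id` and `score`.
#' @export
predict_cohort <- function(model, hist, patient_ids = NULL) {
  if (!is.null(hist$bags) && is.null(names(hist$bags)) && !is.null(hist$clinical))
    hist <- split_modalities(hist)$histologic
  pid <- if (is.null(patient_ids)) hist$patient_id else patient_ids
  data.frame(patient_id = pid,
             score = vapply(pid, function(p) predict_patient(model, hist$bags[[p]]),
                            numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Smooth concordance-index loss
#'
#' Logistic relaxation of the complement of Harrell's C-index:
#' `loss = 1 - (1/|A|) * sum over admissible pairs (i, j) of
#' sigmoid((r_i - r_j) / tau)`, where a pair is admissible when
#' `t_i < t_j` and patient i had the event (the strict-inequality
#' admissibility rule; tied times are never admissible). Perfectly ordered
#' risks drive the loss to 0 as `tau -> 0`; all-equal risks give exactly
#' 0.5. Differentiable in the risks everywhere.
#'
#' @param risks,times,events aligned numeric vectors; `events` in {0, 1}.
#' @param tau positive temperature.
#' @return Scalar loss in (0, 1).
#' @export
smooth_cindex_loss <- function(risks, times, events, tau = 1) {
  smooth_cindex_loss_grad(risks, times, events, tau)$loss
}

# Loss plus analytic gradient with respect to the risks.
smooth_cindex_loss_grad <- function(risks, times, events, tau) {
  stopifnot(tau > 0, length(risks) == length(times),
            length(times) == length(events))
  n <- length(risks)
  adm <- outer(times, times, `<`) & (events == 1)
  diag(adm) <- FALSE
  pairs <- which(adm, arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    stop("no admissible pairs: every comparison is blocked by censoring or ties")
  i <- pairs[, 1L]; j <- pairs[, 2L]
  z <- (risks[i] - risks[j]) / tau
  sig <- stats::plogis(z)
  loss <- 1 - mean(sig)
  w <- sig * (1 - sig) / (tau * length(i))
  g <- numeric(n)
  # d loss / d r_i = -w, d loss / d r_j = +w, accumulated over pairs
  g <- g - tabulate_sum(i, w, n) + tabulate_sum(j, w, n)
  list(loss = loss, grad = g, n_pairs = length(i))
}

tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

# ---- training ---------------------------------------------------------------

# patient_data: list(per patient: list of feature matrices), times, events.
mil_prepare <- function(hist, outcomes_df = NULL) {
  if (!is.null(hist$clinical)) {
    outcomes_df <- hist$outcomes
    hist <- split_modalities(hist)$histologic
  }
  if (is.null(outcomes_df)) outcomes_df <- hist$outcomes
  pid <- hist$patient_id
  o <- outcomes_df[match(pid, outcomes_df$patient_id), ]
  list(pid = pid,
       slides = lapply(hist$bags, function(bb) lapply(bb, `[[`, "features")),
       times = o$time_months, events = o$event)
}

# Loss and flat-parameter gradient for one minibatch of patients.
mil_loss_grad <- function(model, slides, times, events, tau) {
  k <- model$config$n_extreme
  n_slides <- vapply(slides, length, integer(1))
  feats <- do.call(rbind, unlist(slides, recursive = FALSE))
  tiles_per_slide <- vapply(unlist(slides, recursive = FALSE), nrow, integer(1))
  offsets <- cumsum(c(0L, tiles_per_slide))

  fwd_s <- mlp_forward(model$scoring, feats)
  scores <- drop(fwd_s$out)

  total_slides <- length(tiles_per_slide)
  sel <- matrix(0L, total_slides, 2L * k)   # global tile index per head input
  V <- matrix(0, total_slides, 2L * k)
  for (s in seq_len(total_slides)) {
    idx <- seq.int(offsets[s] + 1L, offsets[s + 1L])
    loc <- extreme_indices(scores[idx], k)
    sel[s, ] <- idx[loc]
    V[s, ] <- scores[idx[loc]]
  }
  fwd_h <- mlp_forward(model$head, V)
  slide_risk <- drop(fwd_h$out)

  pat_of_slide <- rep(seq_along(slides), n_slides)
  risks <- as.numeric(rowsum(slide_risk, pat_of_slide) / n_slides)

  lg <- smooth_cindex_loss_grad(risks, times, events, tau)

  d_slide <- (lg$grad / n_slides)[pat_of_slide]
  back_h <- mlp_backward(model$head, fwd_h, matrix(d_slide, ncol = 1L))
  d_score <- numeric(length(scores))
  flat_sel <- as.integer(sel)
  flat_dV <- as.numeric(back_h$dX)
  agg <- rowsum(flat_dV, flat_sel)
  d_score[as.integer(rownames(agg))] <- agg[, 1L]
  back_s <- mlp_backward(model$scoring, fwd_s, matrix(d_score, ncol = 1L))

  grad <- c(unlist(lapply(back_s$grads, function(g) c(as.numeric(g$W), g$b))),
            unlist(lapply(back_h$grads, function(g) c(as.numeric(g$W), g$b))))
  list(loss = lg$loss, grad = grad, risks = risks)
}

#' Train the tile-scoring survival model
#'
#' Minibatch Adam on the smooth concordance-index loss, for
#' `epochs_pretrain` epochs (or `epochs` if given). Deterministic given the
#' config seed, which drives initialization and batch shuffling. Batches
#' with no admissible pair (possible in heavily censored small batches) are
#' skipped for that pass.
#'
#' @param cohort a cohort list (or histologic view) with outcomes.
#' @param config a [mil_config()].
#' @param init_model optional starting `mil_model` (used by [fine_tune()]).
#' @param epochs optional override of the epoch count.
#' @return List with `model` (trained `mil_model`) and `log` (data.frame of
#'   per-epoch mean training loss).
#' @export
mil_train <- function(cohort, config, init_model = NULL, epochs = NULL) {
  stopifnot(inherits(config, "mil_config"))
  dat <- mil_prepare(cohort)
  model <- if (is.null(init_model)) mil_init(config) else init_model
  if (is.null(epochs)) epochs <- config$epochs_pretrain
  theta <- mil_theta(model)
  opt <- adam_init(length(theta), lr = config$learning_rate)
  n <- length(dat$pid)
  log_loss <- numeric(epochs)
  if (epochs == 0L)
    return(list(model = model, log = data.frame(epoch = integer(0), loss = numeric(0))))
  local_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      losses <- c()
      for (b in batches) {
        if (length(b) < 2L) next
        model <- mil_set_theta(model, theta)
        lg <- tryCatch(
          mil_loss_grad(model, dat$slides[b], dat$times[b], dat$events[b],
                        config$tau),
          error = function(e) NULL)
        if (is.null(lg)) next   # no admissible pairs in this batch
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        st <- adam_step(opt, theta, lg$grad)
        theta <- st$theta; opt <- st$state
        losses <- c(losses, lg$loss)
      }
      log_loss[ep] <- mean(losses)
    }
  })
  model <- mil_set_theta(model, theta)
  list(model = model, log = data.frame(epoch = seq_len(epochs), loss = log_loss))
}

#' Fine-tune a pretrained model
#'
#' Continues training from the given parameters for `epochs_finetune`
#' epochs, transferring a model pretrained on one cohort/endpoint to
#' another. With `epochs_finetune = 0` the model is returned unchanged.
#'
#' @param pretrained a trained `mil_model` whose dimensions match `config`.
#' @param cohort target cohort.
#' @param config a [mil_config()].
#' @return As [mil_train()].
#' @export
fine_tune <- function(pretrained, cohort, config) {
  stopifnot(inherits(pretrained, "mil_model"))
  if (pretrained$config$feature_dim != config$feature_dim)
    stop("feature dimension mismatch between pretrained model and config")
  mil_train(cohort, config, init_model = pretrained,
            epochs = config$epochs_finetune)
}
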