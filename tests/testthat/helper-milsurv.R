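# Independent brute-force concordance enumerator: explicit double loop over
# unordered pairs, applying both admissibility rules directly. Kept separate
# from the package's vectorized implementation on purpose.
cindex_brute <- function(times, events, risks) {
  num <- 0; den <- 0
  n <- length(times)
  for (a in seq_len(n - 1)) for (b in seq.int(a + 1, n)) {
    if (times[a] == times[b]) next
    s <- if (times[a] < times[b]) a else b
    l <- if (times[a] < times[b]) b else a
    if (events[s] != 1) next
    den <- den + 1
    if (risks[s] > risks[l]) num <- num + 1
    else if (risks[s] == risks[l]) num <- num + 0.5
  }
  if (den == 0) stop("no admissible pairs")
  num / den
}

# Small fast cohort for model tests: few tiles, low dimension.
small_cohort <- function(n = 80, d = 8, beta_hist = 1.5, beta_clin = 0,
                         seed = 1, tiles = c(5L, 15L), slides = c(1L, 2L),
                         censoring = 0.3, ...) {
  generate_cohort(cohort_spec(
    n_patients = n, feature_dim = d, beta_hist = beta_hist,
    beta_clin = beta_clin, tiles_per_slide = tiles,
    slides_per_patient = slides, target_censoring = censoring,
    seed = seed, ...))
}

# Random bag with continuous features (no ties anywhere).
random_bag <- function(n_tiles = 10, d = 4, seed = 1, patient = "P1",
                       slide = "P1_S1") {
  set.seed(seed)
  tile_bag(slide, patient,
           tile_grid(224L * n_tiles, 224L)[seq_len(n_tiles), , drop = FALSE],
           matrix(rnorm(n_tiles * d), n_tiles, d))
}

small_mil_config <- function(d, ...) {
  mil_config(feature_dim = d, scoring_hidden = 4L, n_extreme = 3L,
             head_hidden = 4L, batch_size = 16L, ...)
}

# Exact subset enumerator including the empty set (test-only variant used to
# pin down the additive closed form).
exact_contrib_with_empty <- function(predict_fn, N, f_empty) {
  n_sub <- 2L^N
  preds <- numeric(n_sub)
  member <- matrix(FALSE, n_sub, N)
  for (m in seq_len(n_sub) - 1L) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(N - 1L))) != 0L)
    member[m + 1L, idx] <- TRUE
    preds[m + 1L] <- if (length(idx)) predict_fn(idx) else f_empty
  }
  vapply(seq_len(N), function(i)
    mean(preds[member[, i]]) - mean(preds[!member[, i]]), numeric(1))
}
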