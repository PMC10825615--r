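#' Specification of a synthetic cohort
#'
#' Defines the generative model used to emulate a post-surgical HCC study
#' cohort at desk scale: per-patient bags of tile features in which a
#' minority sub-population of "signature" tiles carries the histologic risk
#' signal, clinical covariates (a heavy-tailed AFP-like serum marker, a
#' binary vascular-invasion-like flag, a tumor count), and right-censored
#' survival times from a proportional-hazards model whose log-hazard sums a
#' bag-level histologic signal and a clinical linear predictor.
#'
#' Half of the patients are drawn as signature carriers; each of a carrier's
#' tiles is a signature tile independently with probability
#' `signature_fraction`, while non-carriers have none. Signature tiles are
#' standard Gaussian features shifted by `signature_shift` along one fixed
#' random unit direction; background tiles are unshifted. The patient's
#' latent histologic risk is the realized fraction of signature tiles across
#' all their bags.
#'
#' @param n_patients number of patients.
#' @param slides_per_patient integer range `c(lo, hi)`; slides drawn
#'   uniformly, emulating 1-3 representative slides per case.
#' @param tiles_per_slide integer range `c(lo, hi)` of tiles kept per slide.
#' @param feature_dim tile feature dimension d (64 default; 2048 mirrors a
#'   full self-supervised extractor).
#' @param signature_fraction probability that a carrier's tile is a
#'   signature tile.
#' @param signature_shift mean shift magnitude of signature tiles along the
#'   signature direction (feature-space effect size).
#' @param beta_hist log-hazard coefficient on the standardized histologic
#'   signal.
#' @param beta_clin log-hazard coefficients on the standardized clinical
#'   covariates (log AFP, invasion flag, tumor count); shorter vectors are
#'   zero-padded.
#' @param rho_clin_hist correlation knob in `[0, 1]`: tilts the invasion
#'   flag towards signature carriers; 0 (default) keeps the histologic and
#'   clinical signals independent.
#' @param baseline_scale baseline exponential event rate per month; 0.02
#'   puts the median uncensored event time near 35 months.
#' @param target_censoring desired censoring proportion in `[0, 1)`;
#'   achieved in expectation by calibrating an independent exponential
#'   censoring rate.
#' @param endpoint_label endpoint tag for the outcome table (RFS/DSS/OS).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 300L,
                        slides_per_patient = c(1L, 3L),
                        tiles_per_slide = c(50L, 150L),
                        feature_dim = 64L,
                        signature_fraction = 0.1,
                        signature_shift = 2,
                        beta_hist = 1,
                        beta_clin = c(1, 0.5, 0.25),
                        rho_clin_hist = 0,
                        baseline_scale = 0.02,
                        target_censoring = 0.3,
                        endpoint_label = "RFS",
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               slides_per_patient = as.integer(slides_per_patient),
               tiles_per_slide = as.integer(tiles_per_slide),
               feature_dim = as.integer(feature_dim),
               signature_fraction = signature_fraction,
               signature_shift = signature_shift,
               beta_hist = beta_hist,
               beta_clin = beta_clin,
               rho_clin_hist = rho_clin_hist,
               baseline_scale = baseline_scale,
               target_censoring = target_censoring,
               endpoint_label = endpoint_label,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_patients < 1L) stop("n_patients must be positive")
    if (feature_dim < 2L) stop("feature_dim must be at least 2")
    if (length(slides_per_patient) != 2L || slides_per_patient[1] > slides_per_patient[2] ||
        slides_per_patient[1] < 1L) stop("slides_per_patient must be a nonempty positive range")
    if (length(tiles_per_slide) != 2L || tiles_per_slide[1] > tiles_per_slide[2] ||
        tiles_per_slide[1] < 1L) stop("tiles_per_slide must be a nonempty positive range")
    if (signature_fraction < 0 || signature_fraction > 1)
      stop("signature_fraction must be in [0, 1]")
    if (target_censoring < 0 || target_censoring >= 1)
      stop("target_censoring must be in [0, 1)")
    if (baseline_scale <= 0) stop("baseline_scale must be positive")
  })
  invisible(spec)
}

# Exponential censoring rate c solving mean_i c / (c + lambda_i) = target.
# The left side is increasing in c from 0 to 1, so a sign-changing bracket
# always exists for target in (0, 1).
calibrate_censoring_rate <- function(lambda, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) - target
  lo <- log(min(lambda)) - 20
  hi <- log(max(lambda)) + 20
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort from a [cohort_spec()]: tile bags with planted
#' signature labels, a clinical table, an outcome table, and a `truth`
#' element carrying the generative quantities downstream tests compare
#' against (true log-hazard, histologic signal, carrier status).
#'
#' @param spec a [cohort_spec()].
#' @param signature_direction optional unit vector of length `feature_dim`
#'   fixing the signature direction; used to share the histologic signal
#'   between a pretraining and a fine-tuning cohort. Drawn at random when
#'   `NULL`.
#' @return List of class `synthetic_cohort` with elements `bags` (list of
#'   [tile_bag()]), `clinical`, `outcomes`, `truth` and the originating
#'   `spec`.
#' @export
generate_cohort <- function(spec, signature_direction = NULL) {
  validate_cohort_spec(spec)
  local_seed(spec$seed, {
    n <- spec$n_patients
    d <- spec$feature_dim
    pid <- sprintf("P%04d", seq_len(n))

    if (is.null(signature_direction)) {
      u <- stats::rnorm(d)
      u <- u / sqrt(sum(u^2))
    } else {
      stopifnot(length(signature_direction) == d)
      u <- signature_direction / sqrt(sum(signature_direction^2))
    }

    carrier <- stats::rbinom(n, 1L, 0.5)
    n_slides <- sample(seq(spec$slides_per_patient[1], spec$slides_per_patient[2]),
                       n, replace = TRUE)

    bags <- vector("list", sum(n_slides))
    h <- numeric(n)
    b <- 0L
    for (i in seq_len(n)) {
      n_sig_tot <- 0L
      n_tile_tot <- 0L
      for (s in seq_len(n_slides[i])) {
        nt <- sample(seq(spec$tiles_per_slide[1], spec$tiles_per_slide[2]), 1L)
        lab <- if (carrier[i]) stats::rbinom(nt, 1L, spec$signature_fraction)
               else integer(nt)
        X <- matrix(stats::rnorm(nt * d), nt, d)
        if (any(lab == 1L))
          X[lab == 1L, ] <- X[lab == 1L, , drop = FALSE] +
            matrix(spec$signature_shift * u, sum(lab), d, byrow = TRUE)
        grid <- tile_grid(224L * ceiling(sqrt(nt)) , 224L * ceiling(sqrt(nt)), 224L)
        b <- b + 1L
        bags[[b]] <- tile_bag(sprintf("%s_S%d", pid[i], s), pid[i],
                              grid[seq_len(nt), , drop = FALSE], X, lab)
        n_sig_tot <- n_sig_tot + sum(lab)
        n_tile_tot <- n_tile_tot + nt
      }
      h[i] <- n_sig_tot / n_tile_tot
    }

    afp <- stats::rlnorm(n, meanlog = 2.3, sdlog = 1.6)
    p_inv <- stats::plogis(stats::qlogis(0.3) +
                             spec$rho_clin_hist * 2 * (carrier - 0.5))
    invasion <- stats::rbinom(n, 1L, p_inv)
    tumor_count <- 1L + stats::rpois(n, 1)
    clinical <- data.frame(patient_id = pid, afp = afp,
                           invasion = invasion, tumor_count = tumor_count,
                           stringsAsFactors = FALSE)

    zh <- if (stats::sd(h) > 0) (h - mean(h)) / stats::sd(h) else h * 0
    Xc <- scale(cbind(log(afp), invasion, tumor_count))
    bc <- rep(0, 3)
    bc[seq_along(spec$beta_clin)] <- spec$beta_clin
    eta <- drop(spec$beta_hist * zh + Xc %*% bc)

    lambda <- spec$baseline_scale * exp(eta)
    t_event <- stats::rexp(n, rate = 1) / lambda
    crate <- calibrate_censoring_rate(lambda, spec$target_censoring)
    if (crate > 0) {
      t_cens <- stats::rexp(n, rate = 1) / crate
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }

    outcomes <- data.frame(patient_id = pid, time_months = time,
                           event = event, endpoint = spec$endpoint_label,
                           stringsAsFactors = FALSE)
    structure(
      list(bags = bags, clinical = clinical, outcomes = outcomes,
           truth = list(eta = eta, h = h, z_hist = zh, carrier = carrier,
                        signature_direction = u, censoring_rate = crate),
           spec = spec),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d slides, d=%d, %.0f%% events (%s)\n",
              nrow(x$clinical), length(x$bags), ncol(x$bags[[1]]$features),
              100 * mean(x$outcomes$event), x$outcomes$endpoint[1]))
  invisible(x)
}

#' Split a cohort into its histologic and clinical views
#'
#' Both views list the same patients in the same order and share the outcome
#' table, so arm-specific code cannot diverge on cohort membership.
#'
#' @param cohort a cohort list with `bags`, `clinical`, `outcomes`.
#' @return List with elements `histologic` (patient ids, bags, outcomes) and
#'   `clinical` (patient ids, covariate table, outcomes).
#' @export
split_modalities <- function(cohort) {
  pid <- cohort$clinical$patient_id
  bag_pid <- vapply(cohort$bags, `[[`, character(1), "patient_id")
  bags_by_patient <- lapply(pid, function(p) cohort$bags[bag_pid == p])
  names(bags_by_patient) <- pid
  list(
    histologic = list(patient_id = pid, bags = bags_by_patient,
                      outcomes = cohort$outcomes),
    clinical = list(patient_id = pid, table = cohort$clinical,
                    outcomes = cohort$outcomes))
}

#' Rejoin modality views into a cohort
#'
#' Inverse of [split_modalities()]; used to assert the split is lossless.
#'
#' @param views list returned by [split_modalities()].
#' @return List with `bags`, `clinical`, `outcomes`.
#' @export
join_modalities <- function(views) {
  list(bags = unname(do.call(c, views$histologic$bags)),
       clinical = views$clinical$table,
       outcomes = views$clinical$outcomes)
}
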