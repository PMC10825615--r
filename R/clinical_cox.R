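#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial-likelihood maximization (via
#' [survival::coxph()]) and returns a compact summary: coefficients with
#' standard errors, hazard ratios with 95% Wald confidence intervals and
#' p-values, and the partial log-likelihood at the optimum. Complete cases
#' only; rows with missing covariates are dropped and the effective n is
#' recorded.
#'
#' @param X numeric covariate matrix (columns named) or data.frame.
#' @param times positive event/censoring times.
#' @param events event indicators in {0, 1}; at least one event required.
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit` with elements `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `loglik`, `terms`, `ties`, `n`, `n_events`
#'   and the training covariate means `x_center` used by
#'   [linear_predictor()].
#' @export
fit_cox <- function(X, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(times) == nrow(X), length(events) == nrow(X))
  cc <- stats::complete.cases(X) & is.finite(times) & !is.na(events)
  X <- X[cc, , drop = FALSE]; times <- times[cc]; events <- events[cc]
  if (sum(events) < 1) stop("no events: the partial likelihood is flat")
  const <- apply(X, 2L, function(col) stats::sd(col) == 0)
  if (any(const))
    stop("constant covariate column(s): ", paste(colnames(X)[const], collapse = ", "))
  fit <- survival::coxph(survival::Surv(times, events) ~ X, ties = ties,
                         control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  if (any(!is.finite(coef(fit))))
    stop("Cox fit did not converge (possible separation); inspect covariates")
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  z <- beta / se
  structure(list(beta = beta, se = se,
                 hr = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 loglik = fit$loglik[2L],
                 loglik_null = fit$loglik[1L],
                 terms = colnames(X), ties = ties,
                 n = nrow(X), n_events = sum(events),
                 x_center = colMeans(X)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  df <- data.frame(term = x$terms, beta = x$beta, HR = x$hr,
                   CI_low = x$ci_low, CI_high = x$ci_high, p = x$p)
  cat(sprintf("<cox_fit> n=%d, events=%d, ties=%s, loglik=%.3f\n",
              x$n, x$n_events, x$ties, x$loglik))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Clinical risk score from a Cox fit
#'
#' The linear predictor `(X - center) %*% beta`, centered on the *training*
#' covariate means stored in the fit, so held-out patients are scored
#' without touching their own distribution. Higher score = higher hazard.
#'
#' @param fit a [fit_cox()] result.
#' @param X covariate matrix with the same columns as the fit.
#' @return Numeric vector of per-patient clinical risk scores.
#' @export
linear_predictor <- function(fit, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!identical(colnames(X), fit$terms))
    stop("covariate columns do not match the fit: expected ",
         paste(fit$terms, collapse = ", "))
  drop(sweep(X, 2L, fit$x_center) %*% fit$beta)
}

#' Design matrix from a clinical table
#'
#' Extracts the requested covariates; AFP-like columns (named in
#' `log_transform`) are log-transformed first, reflecting their heavy right
#' tail.
#'
#' @param clinical clinical table with `patient_id`.
#' @param covariates character vector of column names to use.
#' @param log_transform columns to log-transform (default `"afp"` when
#'   present).
#' @return Numeric matrix with rownames set to patient ids.
#' @export
clinical_design <- function(clinical, covariates,
                            log_transform = intersect("afp", covariates)) {
  miss <- setdiff(covariates, names(clinical))
  if (length(miss)) stop("covariates absent from clinical table: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(clinical[covariates])
  for (v in log_transform) X[, v] <- log(X[, v])
  rownames(X) <- clinical$patient_id
  X
}

#' Univariate Cox screen of clinical covariates
#'
#' One univariate Cox fit per covariate against the chosen endpoint,
#' reported sorted by p-value. No multiplicity correction is applied (the
#' screen is descriptive); unfittable columns (constant, non-converging)
#' are skipped and flagged.
#'
#' @param clinical clinical table.
#' @param outcomes outcome table ([validate_outcomes()] schema).
#' @param endpoint endpoint label to select from `outcomes`.
#' @param covariates covariate columns to screen (default: all non-id
#'   columns).
#' @param log_transform see [clinical_design()].
#' @return data.frame with one row per covariate: `term`, `beta`, `HR`,
#'   `CI_low`, `CI_high`, `p`, `n`, plus a `skipped` attribute naming any
#'   unfittable columns.
#' @export
univariate_screen <- function(clinical, outcomes, endpoint,
                              covariates = setdiff(names(clinical), "patient_id"),
                              log_transform = intersect("afp", covariates)) {
  o <- outcomes[outcomes$endpoint == endpoint, ]
  o <- o[match(clinical$patient_id, o$patient_id), ]
  if (anyNA(o$time_months)) stop("outcomes missing for some clinical patients")
  rows <- list(); skipped <- character(0)
  for (v in covariates) {
    Xv <- clinical_design(clinical, v, intersect(log_transform, v))
    f <- tryCatch(fit_cox(Xv, o$time_months, o$event), error = function(e) e)
    if (inherits(f, "error")) { skipped <- c(skipped, v); next }
    rows[[v]] <- data.frame(term = v, beta = f$beta, HR = f$hr,
                            CI_low = f$ci_low, CI_high = f$ci_high,
                            p = f$p, n = f$n)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(term = character(0), beta = numeric(0),
                                      HR = numeric(0), CI_low = numeric(0),
                                      CI_high = numeric(0), p = numeric(0),
                                      n = integer(0))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
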