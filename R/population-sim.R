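#' Draw individual parameter sets under the population model
#'
#' Random effects are multivariate normal on the log scale (exponential IIV):
#' `CL_i = TVCL(CrCl_i) * exp(eta1)`, `V1_i = TVV1 * exp(eta2)`; Q and V2
#' carry no interindividual variability.
#'
#' @param model a `pk_model` (see [final_model()]).
#' @param covs data.frame of subject covariates (needs every covariate the
#'   model's covariate effects reference, e.g. `crcl_ml_min`).
#' @param seed integer seed for the eta stream (`NULL` uses the current RNG
#'   state).
#' @param eta optional pre-drawn n x 2 matrix of random effects (columns cl,
#'   v1); overrides the draw, used for common-random-number designs.
#' @return data.frame with columns `subject_id`, `eta_cl`, `eta_v1`, `cl`,
#'   `v1`, `q`, `v2` and the covariates.
#' @export
sample_individuals <- function(model, covs, seed = NULL, eta = NULL) {
  n <- nrow(covs)
  if (is.null(eta)) {
    if (!is.null(seed)) set.seed(seed)
    z <- matrix(stats::rnorm(2L * n), n, 2L)
    eta <- z %*% .omega_sqrt(model$omega)
  }
  colnames(eta) <- c("cl", "v1")
  tv <- .typical_params(model, covs)
  out <- data.frame(subject_id = covs$subject_id %||% seq_len(n),
                    eta_cl = eta[, 1L], eta_v1 = eta[, 2L],
                    cl = tv$cl * exp(eta[, 1L]),
                    v1 = tv$v1 * exp(eta[, 2L]),
                    q = tv$q, v2 = tv$v2)
  cbind(out, covs[setdiff(names(covs), "subject_id")])
}

# typical (covariate-adjusted, eta = 0) parameters for a covariate table;
# vectorised over subjects
.typical_params <- function(model, covs) {
  n <- nrow(covs)
  p <- model$params
  base <- list(cl = rep(p$theta_nr, n), v1 = rep(p$v1, n),
               q = rep(p$q, n), v2 = rep(p$v2, n))
  for (e in model$covariates$effects) {
    nm <- if (e$cov == "crcl") "crcl_ml_min" else e$cov
    x <- covs[[nm]] %||% covs[[e$cov]]
    if (is.null(x)) stop(sprintf("covariate '%s' missing from covariate table", e$cov))
    th <- if (is.na(e$theta %||% NA_real_)) p$theta_r else e$theta
    base[[e$param]] <- switch(
      e$form,
      power       = base[[e$param]] + (x / e$centre)^th,
      linear      = base[[e$param]] * (1 + th * (x - e$centre)),
      exponential = base[[e$param]] * exp(th * (x - e$centre)),
      shift       = base[[e$param]] * (1 + th * as.numeric(x == e$level)))
  }
  base
}

#' Simulate observed concentrations for one individual
#'
#' Structural predictions from the closed-form two-compartment model, with
#' optional residual error. Proportional error multiplies each prediction by
#' `(1 + eps)`, `eps ~ N(0, sigma_prop^2)`; an additive term is added when the
#' residual model includes one. Negative simulated values are floored at 0
#' (count logged).
#'
#' @param ind individual parameters (list/row with `cl`, `v1`, `q`, `v2`).
#' @param regimen a [dosing_regimen()].
#' @param times sampling times (h since first dose).
#' @param residual a [residual_spec()].
#' @param include_residual add residual noise (default `TRUE`).
#' @param seed optional seed for the residual stream.
#' @return data.frame with `time_h`, `pred` (noise-free) and `dv` (with
#'   residual error if requested).
#' @export
simulate_observations <- function(ind, regimen, times, residual = residual_spec(),
                                  include_residual = TRUE, seed = NULL) {
  f <- conc_profile(ind, regimen, times)
  dv <- f
  if (include_residual) {
    if (!is.null(seed)) set.seed(seed)
    dv <- f * (1 + stats::rnorm(length(f), 0, residual$sigma_prop)) +
      stats::rnorm(length(f), 0, residual$sigma_add)
    n_neg <- sum(dv < 0)
    if (n_neg) lp_log("floored %d negative simulated concentrations at 0", n_neg)
    dv <- pmax(dv, 0)
  }
  data.frame(time_h = times, pred = f, dv = dv)
}

#' Replicate a study: re-simulate concentrations for an observed design
#'
#' Keeps the dataset's subjects, covariates, dose events and sampling times
#' and draws new interindividual and residual variability from the model —
#' the simulation step of the visual predictive check ("replicating studies
#' with the same design").
#'
#' @param dataset template [pk_dataset()].
#' @param model a `pk_model`.
#' @param seed integer seed (split internally into eta and residual streams).
#' @param include_residual add residual error to simulated observations.
#' @return a [pk_dataset()] with the same rows and new `dv_mg_L` values.
#' @export
simulate_study <- function(dataset, model, seed = NULL,
                           include_residual = TRUE) {
  seeds <- if (is.null(seed)) c(NA, NA) else split_seed(seed, 2L)
  if (!is.na(seeds[1L])) set.seed(seeds[1L])
  inds <- sample_individuals(model, dataset$subjects)
  f <- .predict_dataset(dataset, inds)
  r <- dataset$records
  obs <- r$evid == 0L
  dv <- f
  if (include_residual) {
    if (!is.na(seeds[2L])) set.seed(seeds[2L])
    dv <- f * (1 + stats::rnorm(length(f), 0, model$residual$sigma_prop)) +
      stats::rnorm(length(f), 0, model$residual$sigma_add)
    dv <- pmax(dv, 0)
  }
  r$dv_mg_L[obs] <- dv
  r$bloq[obs] <- FALSE
  pk_dataset(r, dataset$subjects, validate = FALSE)
}

# Predict noise-free concentrations at every observation row of a dataset,
# given per-subject individual parameters (data.frame with subject_id, cl,
# v1, q, v2). Returns a vector over observation rows (dataset order).
.predict_dataset <- function(dataset, inds) {
  sched <- .build_sched(dataset)
  idx <- match(dataset$subjects$subject_id, inds$subject_id)
  .predict_sched(sched, inds$cl[idx], inds$v1[idx], inds$q[idx], inds$v2[idx])
}
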