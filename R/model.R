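#' Structural fixed-effect parameters
#'
#' Parameters of the two-compartment disposition model with the renal-function
#' covariate on clearance. Typical clearance for a subject with creatinine
#' clearance `crcl` (mL/min) is `theta_nr + (crcl / 120)^theta_r` L/h:
#' `theta_nr` is the clearance intercept (non-renal plus the renal component at
#' the centring value minus one, strictly the additive intercept of the printed
#' equation) and `theta_r` the exponent of the renal term centred on the cohort
#' median CrCl of 120 mL/min.
#'
#' @param theta_nr clearance intercept (L/h).
#' @param theta_r exponent of the CrCl power term (dimensionless).
#' @param v1 central volume of distribution (L).
#' @param q intercompartmental clearance (L/h).
#' @param v2 peripheral volume of distribution (L).
#' @return object of class `pk_params`.
#' @export
pk_params <- function(theta_nr = 3.5, theta_r = 2.5, v1 = 20.7, q = 31.9,
                      v2 = 33.5) {
  p <- list(theta_nr = theta_nr, theta_r = theta_r, v1 = v1, q = q, v2 = v2)
  for (nm in c("theta_nr", "v1", "q", "v2")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm))
    }
  }
  if (!is.numeric(theta_r) || !is.finite(theta_r)) stop("'theta_r' must be finite")
  structure(p, class = "pk_params")
}

#' Interindividual-variability specification
#'
#' Standard deviations of the log-scale (exponential) random effects. A value
#' of 0.327 corresponds to the conventional "IIV 32.7%" report
#' (100 * omega, SD of the log-scale effect).
#'
#' @param cl omega for clearance.
#' @param v1 omega for central volume.
#' @param correlation correlation between the two random effects (none was
#'   detected in the cohort; default 0).
#' @return object of class `omega_spec`.
#' @export
omega_spec <- function(cl = 0.327, v1 = 0.561, correlation = 0) {
  if (cl < 0 || v1 < 0) stop("omega values must be >= 0")
  if (abs(correlation) > 1) stop("correlation must be in [-1, 1]")
  structure(list(cl = cl, v1 = v1, correlation = correlation),
            class = "omega_spec")
}

#' Covariance matrix implied by an omega_spec
#' @param omega an [omega_spec()].
#' @return 2x2 matrix (rows/cols cl, v1).
#' @export
omega_matrix <- function(omega) {
  m <- matrix(c(omega$cl^2, rep(omega$correlation * omega$cl * omega$v1, 2),
                omega$v1^2), 2L, 2L,
              dimnames = list(c("cl", "v1"), c("cl", "v1")))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("implied omega covariance matrix is not positive semidefinite")
  m
}

# matrix square root of the (possibly singular) omega covariance: A with
# A' A = Omega, so eta = z %*% A has the right covariance even when an
# omega is exactly zero
.omega_sqrt <- function(omega) {
  om <- omega_matrix(omega)
  e <- eigen(om, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(om)))
}

#' Residual-error specification
#'
#' @param kind "proportional", "additive" or "combined".
#' @param sigma_prop proportional error SD as a fraction (0.223 = 22.3%).
#' @param sigma_add additive error SD (mg/L).
#' @return object of class `residual_spec`.
#' @export
residual_spec <- function(kind = c("proportional", "additive", "combined"),
                          sigma_prop = 0.223, sigma_add = 0) {
  kind <- match.arg(kind)
  if (kind == "proportional") sigma_add <- 0
  if (kind == "additive") sigma_prop <- 0
  if (sigma_prop < 0 || sigma_add < 0) stop("sigma values must be >= 0")
  structure(list(kind = kind, sigma_prop = sigma_prop, sigma_add = sigma_add),
            class = "residual_spec")
}

#' Covariate model
#'
#' A set of covariate effects, one per (parameter, covariate) pair. Functional
#' forms, with `x` the covariate value, `c` the centring value and `t` the
#' effect coefficient:
#' \describe{
#'   \item{power}{additive power term: parameter becomes `base + (x/c)^t`
#'     (the form of the final clearance--CrCl relation).}
#'   \item{linear}{multiplicative: `base * (1 + t * (x - c))`.}
#'   \item{exponential}{multiplicative: `base * exp(t * (x - c))`.}
#'   \item{shift}{dichotomous shift for the flagged category:
#'     `base * (1 + t * I(x == level))`.}
#' }
#'
#' @param effects list of effects created by [cov_effect()].
#' @return object of class `covariate_model`.
#' @export
covariate_model <- function(effects = list()) {
  keys <- vapply(effects, function(e) paste(e$param, e$cov), "")
  if (anyDuplicated(keys)) stop("one effect per (parameter, covariate) pair")
  structure(list(effects = effects), class = "covariate_model")
}

#' @rdname covariate_model
#' @param param parameter name ("cl" or "v1").
#' @param cov covariate name (a column of the subject covariate table).
#' @param form functional form.
#' @param centre centring value (median of the cohort) for continuous forms.
#' @param theta effect coefficient (exponent for "power").
#' @param level category treated as the shifted group for "shift".
#' @export
cov_effect <- function(param, cov, form = c("power", "linear", "exponential", "shift"),
                       centre = NA_real_, theta = NA_real_, level = NULL) {
  form <- match.arg(form)
  if (form %in% c("power", "exponential", "linear") &&
      (!is.finite(centre) || (form != "linear" && centre <= 0))) {
    stop("continuous covariate effects need a positive centring value")
  }
  list(param = param, cov = cov, form = form, centre = centre,
       theta = theta, level = level)
}

#' Published final population model
#'
#' The final model for intravenous levetiracetam in critically ill patients:
#' `CL = (3.5 + (CrCl/120)^2.5) * exp(eta1)` L/h, `V1 = 20.7 * exp(eta2)` L,
#' Q = 31.9 L/h, V2 = 33.5 L, log-scale IIV SDs 0.327 (CL) and 0.561 (V1),
#' proportional residual error 22.3%.
#'
#' @param params,omega,residual,covariates optional overrides.
#' @return object of class `pk_model`: a list with elements `params`,
#'   `covariates`, `omega`, `residual`.
#' @export
final_model <- function(params = pk_params(), omega = omega_spec(),
                        residual = residual_spec(),
                        covariates = NULL) {
  if (is.null(covariates)) {
    # theta = NA ties the exponent to params$theta_r (kept in sync when fitted)
    covariates <- covariate_model(list(
      cov_effect("cl", "crcl", "power", centre = 120, theta = NA_real_)))
  }
  structure(list(params = params, covariates = covariates, omega = omega,
                 residual = residual), class = "pk_model")
}

#' Typical (population) clearance as a function of creatinine clearance
#'
#' @param crcl urinary creatinine clearance (mL/min), vectorised.
#' @param params a [pk_params()].
#' @return typical clearance (L/h).
#' @examples
#' typical_clearance(120) # 4.5
#' typical_clearance(240) # 9.16 (9.2 to one decimal)
#' @export
typical_clearance <- function(crcl, params = pk_params()) {
  if (any(!is.finite(crcl)) || any(crcl <= 0)) stop("crcl must be positive")
  params$theta_nr + (crcl / 120)^params$theta_r
}

#' Apply a covariate model to the structural parameters of one subject
#'
#' @param params a [pk_params()].
#' @param model a [covariate_model()]; the final-model CrCl power effect on CL
#'   may carry `theta = NA`, in which case `params$theta_r` is used.
#' @param covs named list or one-row data.frame of subject covariates.
#' @return list with individual typical `cl`, `v1`, `q`, `v2`.
#' @export
apply_covariates <- function(params, model, covs) {
  base <- list(cl = params$theta_nr, v1 = params$v1, q = params$q, v2 = params$v2)
  for (e in model$effects) {
    x <- covs[[e$cov]]
    if (is.null(x) || (is.atomic(x) && length(x) == 1L && is.na(x))) {
      stop(sprintf("covariate '%s' missing for subject%s", e$cov,
                   if (!is.null(covs$subject_id)) paste0(" ", covs$subject_id) else ""))
    }
    th <- if (is.na(e$theta %||% NA_real_)) params$theta_r else e$theta
    base[[e$param]] <- switch(
      e$form,
      power       = base[[e$param]] + (x / e$centre)^th,
      linear      = base[[e$param]] * (1 + th * (x - e$centre)),
      exponential = base[[e$param]] * exp(th * (x - e$centre)),
      shift       = base[[e$param]] * (1 + th * as.numeric(x == e$level)),
      stop(sprintf("unknown covariate function '%s'", e$form)))
  }
  base
}
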