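#' Area under the curve by the linear-log trapezoidal rule
#'
#' Segment-wise: the linear trapezoid when the concentration is rising,
#' constant, or either endpoint is zero; the logarithmic trapezoid
#' `(C1 - C2) dt / log(C1 / C2)` on declining segments with both endpoints
#' positive.
#'
#' @param times strictly increasing times (h), length >= 2.
#' @param concs non-negative concentrations (mg/L).
#' @return AUC (mg h/L).
#' @export
auc_linlog <- function(times, concs) {
  if (length(times) < 2L) stop("need at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concs < 0)) stop("concentrations must be non-negative")
  c1 <- concs[-length(concs)]
  c2 <- concs[-1L]
  dt <- diff(times)
  uselog <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(uselog, (c1 - c2) * dt / log(c1 / c2), (c1 + c2) * dt / 2)
  sum(seg)
}

#' Terminal slope (lambda_z) by best-adjusted-R2 log-linear regression
#'
#' Candidate windows are the last 3, 4, ... observations with positive
#' concentration, excluding the observation at Cmax; the window with the
#' highest adjusted R2 wins (the convention of standard NCA software, which
#' the source analysis used). The slope must be negative (lambda_z > 0).
#'
#' @param times observation times (h).
#' @param concs concentrations (mg/L).
#' @return list with `lambda_z` (1/h), `n_points`, `r2adj`, `t_half`.
#' @export
fit_lambda_z <- function(times, concs) {
  keep <- concs > 0
  times <- times[keep]; concs <- concs[keep]
  if (length(times) < 3L) stop("terminal phase not estimable: need >= 3 positive concentrations")
  imax <- which.max(concs)
  cand_start <- which(seq_along(times) > imax)
  best <- NULL
  n <- length(times)
  for (k in 3:(n - imax)) {
    idx <- (n - k + 1L):n
    if (any(idx <= imax)) next
    lt <- log(concs[idx])
    fitk <- stats::lm.fit(cbind(1, times[idx]), lt)
    slope <- fitk$coefficients[2L]
    ssr <- sum(fitk$residuals^2)
    sst <- sum((lt - mean(lt))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
    r2adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (k - 1) / (k - 2)
    if (!is.na(r2adj) && slope < 0 &&
        (is.null(best) || r2adj > best$r2adj + 1e-12)) {
      best <- list(lambda_z = -unname(slope), n_points = k,
                   r2adj = unname(r2adj))
    }
  }
  if (is.null(best)) stop("terminal phase not estimable: no window with a positive lambda_z")
  best$t_half <- log(2) / best$lambda_z
  best
}

#' Noncompartmental analysis of a steady-state profile
#'
#' Exposure metrics over one dosing interval: observed Cmax/Tmax, AUC within
#' the interval by [auc_linlog()], terminal slope by [fit_lambda_z()],
#' `t_half = log(2)/lambda_z`, `CL = dose / AUC_tau` (steady-state identity,
#' no extrapolation) and `Vz = CL / lambda_z`.
#'
#' @param times observation times within the interval (h).
#' @param concs concentrations (mg/L).
#' @param dose administered dose (mg).
#' @param tau dosing interval (h).
#' @return data.frame of class `nca_result` with `cmax`, `tmax`, `auc_tau`,
#'   `lambda_z`, `t_half`, `cl`, `vz`, `n_lambda_points`, `lambda_fit_r2adj`.
#' @export
nca_steady_state <- function(times, concs, dose, tau) {
  ord <- order(times)
  times <- times[ord]; concs <- concs[ord]
  auc <- auc_linlog(times, concs)
  lz <- fit_lambda_z(times, concs)
  cl <- dose / auc
  out <- data.frame(cmax = max(concs), tmax = times[which.max(concs)],
                    auc_tau = auc, lambda_z = lz$lambda_z,
                    t_half = lz$t_half, cl = cl, vz = cl / lz$lambda_z,
                    n_lambda_points = lz$n_points,
                    lambda_fit_r2adj = lz$r2adj)
  class(out) <- c("nca_result", class(out))
  out
}

#' Per-subject NCA over a dataset
#'
#' Runs [nca_steady_state()] on every subject's observations; the dose and
#' interval are taken from the subject's (first) dose row.
#'
#' @param dataset a [pk_dataset()].
#' @return data.frame with one row per subject (`subject_id`, `crcl_ml_min`,
#'   `arc`, then the NCA metrics); subjects whose terminal phase is not
#'   estimable are reported with `NA` metrics.
#' @export
nca_dataset <- function(dataset) {
  r <- dataset$records
  out <- lapply(dataset$subjects$subject_id, function(id) {
    ri <- r[r$subject_id == id, , drop = FALSE]
    dose_row <- ri[ri$evid == 1L, ][1L, ]
    obs <- ri[ri$evid == 0L & is.finite(ri$dv_mg_L), , drop = FALSE]
    tau <- if (is.finite(dose_row$tau_h)) dose_row$tau_h else 12
    res <- tryCatch(nca_steady_state(obs$time_h, obs$dv_mg_L,
                                     dose_row$amt_mg, tau),
                    error = function(e) NULL)
    if (is.null(res)) {
      res <- data.frame(cmax = NA_real_, tmax = NA_real_, auc_tau = NA_real_,
                        lambda_z = NA_real_, t_half = NA_real_, cl = NA_real_,
                        vz = NA_real_, n_lambda_points = NA_integer_,
                        lambda_fit_r2adj = NA_real_)
    }
    cbind(data.frame(subject_id = id,
                     crcl_ml_min = dataset$subjects$crcl_ml_min[
                       dataset$subjects$subject_id == id],
                     dose_mg = dose_row$amt_mg), res)
  })
  out <- do.call(rbind, out)
  out$arc <- out$crcl_ml_min > 130
  out
}
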