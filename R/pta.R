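#' Configuration of the Monte Carlo target-attainment simulations
#'
#' Defaults reproduce the published simulation grid: 1000 virtual subjects at
#' each creatinine clearance of 80, 120, 160, 200 and 240 mL/min; doses of
#' 500--2000 mg every 12 or 8 h as 30-min infusions; steady-state trough
#' targets of 6, 12 and 46 mg/L. All subjects of a group are simulated at the
#' stated CrCl value. Residual error is excluded from the trough by default
#' (the target concerns the true trough).
#'
#' @param crcl_groups CrCl grid (mL/min).
#' @param regimens list of [dosing_regimen()]s.
#' @param thresholds trough targets (mg/L), ascending.
#' @param n_subjects virtual subjects per (group, regimen) cell.
#' @param include_residual add residual error to the simulated troughs.
#' @return object of class `pta_config`.
#' @export
pta_config <- function(crcl_groups = c(80, 120, 160, 200, 240),
                       regimens = default_regimen_grid(),
                       thresholds = c(6, 12, 46),
                       n_subjects = 1000L,
                       include_residual = FALSE) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(crcl_groups = crcl_groups, regimens = regimens,
                 thresholds = thresholds, n_subjects = as.integer(n_subjects),
                 include_residual = include_residual), class = "pta_config")
}

#' @rdname pta_config
#' @param doses dose grid (mg).
#' @param taus dosing intervals (h).
#' @param tinf infusion duration (h).
#' @export
default_regimen_grid <- function(doses = c(500, 1000, 1500, 2000),
                                 taus = c(12, 8), tinf = 0.5) {
  g <- expand.grid(dose = doses, tau = taus)
  lapply(seq_len(nrow(g)), function(i)
    dosing_regimen(g$dose[i], tau = g$tau[i], tinf = tinf, steady_state = TRUE))
}

#' Monte Carlo probability of target attainment
#'
#' For every (CrCl group, regimen) cell, draws `n_subjects` individual
#' parameter sets from the population model at that CrCl, computes each
#' subject's steady-state trough (concentration at the end of the interval by
#' the closed-form steady-state solution) and reports the percentage above
#' each target. One set of random effects is drawn per call and reused across
#' all groups and regimens (common random numbers), so monotonicity in dose
#' and CrCl holds exactly per draw.
#'
#' @param config a [pta_config()].
#' @param model a `pk_model`.
#' @param seed integer seed.
#' @return data.frame of class `pta_result`: one row per cell with `crcl`,
#'   `dose_mg`, `tau_h`, `tinf_h`, `daily_dose_mg` and one `pta_gt_<x>`
#'   percentage column per threshold.
#' @export
simulate_pta <- function(config = pta_config(), model = final_model(),
                         seed = 1L) {
  seeds <- split_seed(seed, 2L)
  n <- config$n_subjects
  set.seed(seeds[1L])
  eta <- matrix(stats::rnorm(2L * n), n, 2L) %*% .omega_sqrt(model$omega)
  eps_seed <- seeds[2L]

  rows <- list()
  for (crcl in config$crcl_groups) {
    covs <- data.frame(subject_id = seq_len(n), crcl_ml_min = crcl)
    inds <- sample_individuals(model, covs, eta = eta)
    for (reg in config$regimens) {
      trough <- .conc_ss(rep(reg$tau, n), reg$dose, reg$tau, reg$tinf,
                         inds$cl, inds$v1, inds$q, inds$v2)
      if (reg$dose == 0) trough <- numeric(n)
      if (config$include_residual) {
        set.seed(eps_seed)
        trough <- pmax(trough * (1 + stats::rnorm(n, 0, model$residual$sigma_prop)) +
                         stats::rnorm(n, 0, model$residual$sigma_add), 0)
      }
      p <- vapply(config$thresholds,
                  function(th) 100 * mean(trough > th), 0)
      row <- data.frame(crcl = crcl, dose_mg = reg$dose, tau_h = reg$tau,
                        tinf_h = reg$tinf,
                        daily_dose_mg = reg$dose * 24 / reg$tau)
      row[sprintf("pta_gt_%g", config$thresholds)] <- as.list(p)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    cols <- c("crcl", "dose_mg", "tau_h", "tinf_h", "daily_dose_mg",
              sprintf("pta_gt_%g", config$thresholds))
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("pta_result", class(out))
  out
}

#' Render a target-attainment table
#'
#' Lays the PTA results out as in the published tables (CrCl group, dose,
#' perfusion duration, daily dose, probability per target), marking cells at
#' or above the highlight cutoff with bold markers in the text rendering.
#'
#' @param result a `pta_result` from [simulate_pta()].
#' @param highlight percentage cutoff for highlighting (default 80).
#' @return list with `data` (the machine-readable table) and `text`
#'   (character vector, markdown-style rendering); printed invisibly.
#' @export
pta_table <- function(result, highlight = 80) {
  pcols <- grep("^pta_gt_", names(result), value = TRUE)
  data <- result[c("crcl", "dose_mg", "tinf_h", "tau_h", "daily_dose_mg", pcols)]
  fmt <- data
  for (pc in pcols) {
    v <- round(result[[pc]])
    fmt[[pc]] <- ifelse(v >= highlight, sprintf("**%d**", v), sprintf("%d", v))
  }
  hdr <- c("CrCl (mL/min)", "Dose (mg)", "Perfusion (h)", "Tau (h)",
           "Daily dose (mg)", sub("pta_gt_", ">", pcols))
  lines <- c(paste(hdr, collapse = " | "),
             paste(rep("---", length(hdr)), collapse = " | "),
             apply(fmt, 1L, function(z) paste(trimws(z), collapse = " | ")))
  list(data = data, text = lines)
}
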