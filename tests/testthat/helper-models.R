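# shared fixtures, all built in code

published_params <- function() pk_params() # Table-like final fixed effects

# a small deterministic event dataset: one subject, steady-state 1000 mg q12h
tiny_dataset <- function(times = c(0, 0.5, 2, 6, 12), dv = NULL,
                         crcl = 120, dose = 1000, tau = 12, tinf = 0.5) {
  n <- length(times)
  recs <- rbind(
    data.frame(subject_id = 1L, time_h = 0, evid = 1L, amt_mg = dose,
               dur_h = tinf, dv_mg_L = NA_real_, bloq = FALSE, ss = 1L,
               tau_h = tau),
    data.frame(subject_id = 1L, time_h = times, evid = 0L, amt_mg = NA_real_,
               dur_h = NA_real_, dv_mg_L = dv %||% rep(10, n), bloq = FALSE,
               ss = 0L, tau_h = NA_real_))
  pk_dataset(recs, data.frame(subject_id = 1L, crcl_ml_min = crcl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerical ODE oracle for the two-compartment infusion model (independent
# of the closed-form implementation)
ode_profile <- function(ind, regimen, times) {
  # integrate piecewise between infusion on/off boundaries so the RHS is
  # smooth within every segment (the integrator cannot step across a short
  # infusion window unnoticed)
  starts <- (seq_len(regimen$n_doses) - 1) * regimen$tau
  bounds <- sort(unique(c(0, starts, starts + regimen$tinf,
                          max(times) + 1e-9)))
  bounds <- bounds[bounds <= max(times) + 1e-9]
  rhs <- function(t, y, p) {
    k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
    list(c(p$rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  y <- c(0, 0)
  sol_t <- 0; sol_a <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    mid <- (lo + hi) / 2
    p <- ind
    p$rate <- if (any(mid >= starts & mid < starts + regimen$tinf)) {
      regimen$dose / regimen$tinf
    } else 0
    tt <- sort(unique(c(lo, times[times > lo & times <= hi], hi)))
    out <- deSolve::lsoda(y, tt, rhs, p, rtol = 1e-10, atol = 1e-10)
    y <- out[nrow(out), 2:3]
    sol_t <- c(sol_t, out[-1, 1]); sol_a <- c(sol_a, out[-1, 2])
  }
  approx(sol_t, sol_a / ind$v1, xout = times)$y
}

# fast 200-subject design used by recovery checks
big_design <- function(n = 200L) {
  study_design(n_subjects = n,
               dose_allocation = c("500" = ceiling(n * 18 / 27),
                                   "1000" = ceiling(n * 6 / 27),
                                   "1500" = n - ceiling(n * 18 / 27) -
                                     ceiling(n * 6 / 27)),
               n_five_sample = round(n * 4 / 27))
}
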