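#' Dosing regimen
#'
#' @param dose dose per administration (mg); 0 allowed (placebo profile).
#' @param tau dosing interval (h).
#' @param tinf infusion duration (h); must satisfy `0 < tinf <= tau`.
#' @param n_doses number of administered doses for finite superposition.
#' @param steady_state if `TRUE`, profiles are evaluated with the closed-form
#'   steady-state multiple-infusion solution instead of enumerating doses.
#' @return object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(dose, tau = 12, tinf = 0.5, n_doses = 1L,
                           steady_state = FALSE) {
  if (dose < 0) stop("dose must be >= 0")
  if (tinf <= 0 || tinf > tau) stop("infusion duration must be in (0, tau]")
  if (!steady_state && n_doses < 1) stop("n_doses must be >= 1")
  structure(list(dose = dose, tau = tau, tinf = tinf,
                 n_doses = as.integer(n_doses), steady_state = steady_state),
            class = "dosing_regimen")
}

# macro-constant pieces, vectorised over parameter vectors
.macro <- function(cl, v1, q, v2) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

#' Micro/macro rate constants of the two-compartment model
#'
#' Converts (CL, V1, Q, V2) to first-order micro constants and the macro
#' constants of the bi-exponential disposition function
#' `C(t) = (D/V1) (coefA e^(-alpha t) + coefB e^(-beta t))` after a bolus.
#'
#' @param cl clearance (L/h).
#' @param v1 central volume (L).
#' @param q intercompartmental clearance (L/h).
#' @param v2 peripheral volume (L).
#' @return list of class `micro_constants` with `k10`, `k12`, `k21`, `alpha`,
#'   `beta`, `coefA`, `coefB`. `alpha >= beta > 0`, `coefA + coefB = 1`.
#' @export
micro_constants <- function(cl, v1, q, v2) {
  if (any(c(cl, v1, q, v2) <= 0)) stop("all parameters must be > 0")
  m <- .macro(cl, v1, q, v2)
  if (m$alpha - m$beta < 1e-12 * m$alpha) {
    stop("repeated disposition root (alpha == beta); profile functions use an explicit limit branch")
  }
  structure(list(k10 = m$k10, k12 = m$k12, k21 = m$k21,
                 alpha = m$alpha, beta = m$beta,
                 coefA = (m$alpha - m$k21) / (m$alpha - m$beta),
                 coefB = (m$k21 - m$beta) / (m$alpha - m$beta)),
            class = "micro_constants")
}

# Central-compartment concentration for a single zero-order infusion, at time
# `t` since infusion start (vector, any length; t < 0 gives 0). All parameter
# arguments are vectors recycled to length(t).
.conc_single <- function(t, amt, tinf, cl, v1, q, v2) {
  m <- .macro(cl, v1, q, v2)
  rate <- amt / tinf
  degen <- is.finite(m$alpha) & (m$alpha - m$beta) < 1e-10 * m$alpha
  t1 <- pmin(pmax(t, 0), tinf)
  t2 <- pmax(t - tinf, 0)
  if (any(!degen)) {
    A <- (m$alpha - m$k21) / (m$alpha - m$beta)
    B <- (m$k21 - m$beta) / (m$alpha - m$beta)
    out <- rate / v1 * (A / m$alpha * (1 - exp(-m$alpha * t1)) * exp(-m$alpha * t2) +
                        B / m$beta * (1 - exp(-m$beta * t1)) * exp(-m$beta * t2))
  } else {
    out <- numeric(length(t1))
  }
  if (any(degen)) {
    # limit alpha -> beta = lambda of the bolus response
    # D/V1 e^(-lambda t)(1 - (lambda - k21) t); infusion by analytic integral
    lam <- (m$alpha + m$beta) / 2
    # infusion response = (step up at 0) - (step down at tinf) of the integral
    # of the bolus limit kernel e^(-lam s) (1 - (lam - k21) s)
    gfull <- function(x) {
      xx <- pmax(x, 0)
      (1 - exp(-lam * xx)) / lam -
        (lam - m$k21) * (1 - exp(-lam * xx) * (1 + lam * xx)) / lam^2
    }
    val <- rate / v1 * (gfull(t1 + t2) - gfull(t2))
    out[degen] <- val[degen]
  }
  out[t < 0] <- 0
  pmax(out, 0)
}

# Steady-state multiple-infusion solution at time `t` within the interval
# (0 <= t <= tau; values outside are wrapped modulo tau). Vectorised.
.conc_ss <- function(t, amt, tau, tinf, cl, v1, q, v2) {
  m <- .macro(cl, v1, q, v2)
  if (isTRUE(any((m$alpha - m$beta) < 1e-10 * m$alpha))) {
    # degenerate repeated root: fall back to long superposition (>=10 t1/2)
    lam <- (m$alpha + m$beta) / 2
    n <- ceiling(pmax(10 * log(2) / lam / tau, 20))
    n <- max(n)
    tt <- t %% tau
    tot <- numeric(length(tt))
    for (i in seq_len(n)) tot <- tot + .conc_single(tt + (i - 1) * tau, amt, tinf, cl, v1, q, v2)
    return(tot)
  }
  rate <- amt / tinf
  A <- (m$alpha - m$k21) / (m$alpha - m$beta)
  B <- (m$k21 - m$beta) / (m$alpha - m$beta)
  tt <- t %% tau  # Css(0) == Css(tau) by periodicity, so wrapping is exact
  ton <- pmin(tt, tinf)   # elapsed part of the current infusion
  toff <- pmax(tt - tinf, 0)
  term <- function(coef, lam) {
    acc <- 1 - exp(-lam * tau)
    # current (possibly partial) infusion + accumulated residue of all
    # previous doses; both branches collapse to this single expression
    v <- (1 - exp(-lam * ton)) * exp(-lam * toff) +
      (1 - exp(-lam * tinf)) * exp(-lam * (tau + tt - tinf)) / acc
    coef / lam * v
  }
  pmax(rate / v1 * (term(A, m$alpha) + term(B, m$beta)), 0)
}

#' Concentration-time profile under a dosing regimen
#'
#' Plasma (central-compartment) concentrations from the closed-form
#' two-compartment zero-order-infusion solution, by superposition over the
#' administered doses (doses at 0, tau, 2*tau, ...), or by the steady-state
#' closed form when `regimen$steady_state` is set.
#'
#' @param ind individual parameters: list with `cl`, `v1`, `q`, `v2`.
#' @param regimen a [dosing_regimen()].
#' @param times times since first dose (h).
#' @return concentrations (mg/L), same length as `times`.
#' @export
conc_profile <- function(ind, regimen, times) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (regimen$dose == 0) return(numeric(length(times)) )
  if (regimen$steady_state) {
    return(.conc_ss(times, regimen$dose, regimen$tau, regimen$tinf,
                    ind$cl, ind$v1, ind$q, ind$v2))
  }
  out <- numeric(length(times))
  for (i in seq_len(regimen$n_doses)) {
    out <- out + .conc_single(times - (i - 1) * regimen$tau, regimen$dose,
                              regimen$tinf, ind$cl, ind$v1, ind$q, ind$v2)
  }
  out
}

#' Steady-state concentration within one dosing interval
#'
#' Closed-form steady-state multiple-infusion solution; every exponential term
#' carries its accumulation factor `1/(1 - exp(-lambda * tau))`. The value at
#' `t = 0` (pre-dose) equals the value at `t = tau` (trough).
#'
#' @param ind individual parameters: list with `cl`, `v1`, `q`, `v2`.
#' @param regimen a [dosing_regimen()].
#' @param t time within the interval, `0 <= t <= tau` (h).
#' @return concentration (mg/L).
#' @export
conc_steady_state <- function(ind, regimen, t) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (any(t < 0 | t > regimen$tau)) stop("t must be within [0, tau]")
  if (regimen$dose == 0) return(numeric(length(t)))
  .conc_ss(t, regimen$dose, regimen$tau, regimen$tinf,
           ind$cl, ind$v1, ind$q, ind$v2)
}
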