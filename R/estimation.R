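# Nonlinear mixed-effects estimation by first-order conditional estimation
# with interaction (FOCE-I).
#
# For each subject the conditional mode eta_hat minimises
#   g_i(eta) = sum_j [ log v_ij(eta) + (y_ij - f_ij(eta))^2 / v_ij(eta) ]
#              + eta' Omega^-1 eta
# with v_ij = sigma_prop^2 f_ij^2 + sigma_add^2 (the eta-dependence of v is
# the "interaction"). The marginal -2 log-likelihood contribution is then the
# Laplacian/FOCE approximation obtained by linearising f around eta_hat
# (G = df/deta at eta_hat):
#   OFV_i = log det V_i + r_i' V_i^-1 r_i,
#   V_i = G_i Omega G_i' + diag(v_i(eta_hat)),  r_i = y_i - f_i + G_i eta_hat.
# The 2*pi constant is omitted throughout (NONMEM convention); OFV
# differences between nested models are unaffected.

# per-subject sums of a per-observation vector; `ends` = cumulative row count
.grpsum <- function(x, ends) {
  cs <- cumsum(x)
  tot <- cs[ends]
  tot - c(0, tot[-length(tot)])
}

# Generic FOCE-I engine.
#   y          observations (sorted by subject)
#   ends       index of the last observation of each subject (cumulative)
#   f_fun      function(eta_matrix) -> predictions for all observations
#   omega      K x K covariance matrix of the random effects (K in 1:2);
#              zero-variance dimensions are held at 0
#   resid      residual_spec
#   eta        warm-start matrix (n_subj x K) or NULL
#   f_stencil  optional function(eta, h) evaluating the whole finite-
#              difference stencil [eta, eta +/- h e_k for active k] in one
#              vectorised call (list of prediction vectors); the default
#              falls back to repeated f_fun calls
.foce_engine <- function(y, ends, f_fun, omega, resid, eta = NULL,
                         interaction = TRUE, max_iter = 30L,
                         grad_tol = 1e-7, compute_cwres = FALSE,
                         objective = c("foce", "laplace"),
                         f_stencil = NULL) {
  objective <- match.arg(objective)
  n_subj <- length(ends)
  K <- ncol(omega)
  act <- which(diag(omega) > 1e-12)
  if (is.null(eta)) eta <- matrix(0, n_subj, K)

  sp2 <- resid$sigma_prop^2
  sa2 <- resid$sigma_add^2
  vfloor <- 1e-12

  f0_pop <- NULL
  if (!interaction) f0_pop <- f_fun(matrix(0, n_subj, K))
  vfun <- function(f) {
    fv <- if (interaction) f else f0_pop
    pmax(sp2 * fv^2 + sa2, vfloor)
  }
  gvec <- function(eta) { # per-subject conditional objective (data + penalty)
    f <- f_fun(eta)
    v <- vfun(f)
    gi <- .grpsum(log(v) + (y - f)^2 / v, ends)
    if (length(act)) {
      oinv <- solve(omega[act, act, drop = FALSE])
      ea <- eta[, act, drop = FALSE]
      gi <- gi + rowSums((ea %*% oinv) * ea)
    }
    gi
  }

  if (!length(act)) {
    f0 <- f_fun(eta)
    v0 <- vfun(f0)
    r0 <- y - f0
    ofv_i <- .grpsum(log(v0) + r0^2 / v0, ends)
    out <- list(ofv = sum(ofv_i), ofv_i = ofv_i, eta = eta, f = f0, v = v0)
    if (compute_cwres) out$cwres <- r0 / sqrt(v0)
    return(out)
  }

  nA <- length(act)
  oinv <- solve(omega[act, act, drop = FALSE])
  h <- 5e-4
  if (is.null(f_stencil)) {
    f_stencil <- function(eta, h) {
      out <- vector("list", 1L + 2L * nA)
      out[[1L]] <- f_fun(eta)
      for (k in seq_len(nA)) {
        ep <- eta; ep[, act[k]] <- ep[, act[k]] + h
        em <- eta; em[, act[k]] <- em[, act[k]] - h
        out[[2L * k]] <- f_fun(ep)
        out[[2L * k + 1L]] <- f_fun(em)
      }
      out
    }
  }

  # one stencil evaluation: predictions, analytic gradient of the
  # conditional objective, the objective itself and (optionally) the
  # positive-definite Fisher/Gauss-Newton Hessian terms
  eval_at <- function(eta, with_gn = FALSE) {
    fs <- f_stencil(eta, h)
    f0 <- fs[[1L]]
    v0 <- vfun(f0)
    r0 <- y - f0
    Fk <- vector("list", nA)
    vk <- vector("list", nA)
    grad <- matrix(0, n_subj, nA)
    for (k in seq_len(nA)) {
      Fk[[k]] <- (fs[[2L * k]] - fs[[2L * k + 1L]]) / (2 * h)
      vk[[k]] <- if (interaction) 2 * sp2 * f0 * Fk[[k]] else 0 * Fk[[k]]
      grad[, k] <- .grpsum(vk[[k]] / v0 - 2 * r0 * Fk[[k]] / v0 -
                             r0^2 * vk[[k]] / v0^2, ends)
    }
    grad <- grad + 2 * eta[, act, drop = FALSE] %*% oinv
    grad[!is.finite(grad)] <- 0  # pathological regions: the marginal OFV
                                 # (non-finite) rejects them later
    ea <- eta[, act, drop = FALSE]
    gi <- .grpsum(log(v0) + r0^2 / v0, ends) + rowSums((ea %*% oinv) * ea)
    out <- list(f0 = f0, v0 = v0, r0 = r0, Fk = Fk, grad = grad, gi = gi)
    if (with_gn) {
      out$h11 <- .grpsum(2 * Fk[[1L]]^2 / v0 + vk[[1L]]^2 / v0^2, ends) +
        2 * oinv[1L, 1L] + 1e-8
      if (nA == 2L) {
        out$h22 <- .grpsum(2 * Fk[[2L]]^2 / v0 + vk[[2L]]^2 / v0^2, ends) +
          2 * oinv[2L, 2L] + 1e-8
        out$h12 <- .grpsum(2 * Fk[[1L]] * Fk[[2L]] / v0 +
                             vk[[1L]] * vk[[2L]] / v0^2, ends) +
          2 * oinv[1L, 2L]
      }
    }
    out
  }

  # per-subject 2x2 (or 1x1) solve of H step = -grad with an eigenvalue
  # floor so every step is a descent direction
  solve_step <- function(grad, h11, h22 = NULL, h12 = NULL) {
    if (nA == 1L) {
      hh <- pmax(h11, 1e-4)
      step <- cbind(-grad[, 1L] / hh)
    } else {
      tr <- h11 + h22
      dd <- h11 * h22 - h12^2
      lam_min <- tr / 2 - sqrt(pmax(tr^2 / 4 - dd, 0))
      ridge <- pmax(1e-4 - lam_min, 0)
      h11 <- h11 + ridge; h22 <- h22 + ridge
      dd <- pmax(h11 * h22 - h12^2, 1e-12)
      step <- cbind(-( h22 * grad[, 1L] - h12 * grad[, 2L]) / dd,
                    -(-h12 * grad[, 1L] + h11 * grad[, 2L]) / dd)
    }
    step[!is.finite(step)] <- 0
    pmin(pmax(step, -2), 2)
  }

  # damped update: halve the step per subject until the conditional
  # objective does not get worse; subjects whose remaining step is below
  # measurable size are frozen (lam = 0 makes their trial a no-op)
  g0 <- NULL
  take_step <- function(eta, step) {
    lam <- rep(1, n_subj)
    worse <- rep(FALSE, n_subj)
    step_size <- do.call(pmax, c(lapply(seq_len(nA), function(k) abs(step[, k])),
                                 list(0)))
    for (ls in 1:30) {
      trial <- eta
      trial[, act] <- pmin(pmax(eta[, act, drop = FALSE] + step * lam, -8), 8)
      gt <- gvec(trial)
      worse <- !is.finite(gt) | gt > g0 + 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
      lam[worse & step_size * lam < 1e-10] <- 0
    }
    lam[worse] <- 0
    eta[, act] <- pmin(pmax(eta[, act, drop = FALSE] + step * lam, -8), 8)
    g0 <<- ifelse(worse, g0, gt)
    list(eta = eta, moved = max(abs(step * lam)))
  }

  # Gauss-Newton sweeps bring every subject near its mode; Newton
  # iterations (true Hessian by differencing the analytic gradient) then
  # converge the modes tightly, which the linearised marginal OFV needs
  # because it is first-order sensitive to where the inner search stops
  dN <- 1e-4
  cur <- eval_at(eta, with_gn = TRUE)
  g0 <- cur$gi
  g0[!is.finite(g0)] <- 1e300
  newton <- FALSE
  prev_gn <- Inf
  for (iter in seq_len(max_iter + 12L)) {
    gn <- max(abs(cur$grad))
    if (gn < grad_tol) break
    if (!newton && (gn < 1e-2 || iter > max_iter)) newton <- TRUE
    if (newton) {
      # no quadratic contraction means the finite-difference noise floor
      # has been reached for some subject; further sweeps cannot help
      if (gn > 0.5 * prev_gn) break
      prev_gn <- gn
      Hc <- vector("list", nA)
      for (k in seq_len(nA)) {
        ep <- eta; ep[, act[k]] <- ep[, act[k]] + dN
        Hc[[k]] <- (eval_at(ep)$grad - cur$grad) / dN
      }
      step <- if (nA == 1L) {
        solve_step(cur$grad, Hc[[1L]][, 1L])
      } else {
        solve_step(cur$grad, Hc[[1L]][, 1L], Hc[[2L]][, 2L],
                   (Hc[[1L]][, 2L] + Hc[[2L]][, 1L]) / 2)
      }
    } else {
      step <- solve_step(cur$grad, cur$h11, cur$h22, cur$h12)
    }
    upd <- take_step(eta, step)
    eta <- upd$eta
    if (upd$moved < 1e-11) break
    cur <- eval_at(eta, with_gn = !newton)
  }

  if (objective == "laplace") {
    # second-order (Laplace) marginal: g_i at the mode plus the log
    # determinants of Omega and of half the conditional Hessian
    Hd <- vector("list", nA)
    for (k in seq_len(nA)) {
      ep <- eta; ep[, act[k]] <- ep[, act[k]] + dN
      Hd[[k]] <- (eval_at(ep)$grad - cur$grad) / dN
    }
    detH <- if (nA == 1L) {
      pmax(Hd[[1L]][, 1L], 1e-10)
    } else {
      pmax(Hd[[1L]][, 1L] * Hd[[2L]][, 2L] -
             ((Hd[[1L]][, 2L] + Hd[[2L]][, 1L]) / 2)^2, 1e-10)
    }
    ofv_i <- cur$gi + log(det(omega[act, act, drop = FALSE])) +
      log(detH / 2^nA)
    return(list(ofv = sum(ofv_i), ofv_i = ofv_i, eta = eta,
                f = cur$f0, v = cur$v0))
  }

  # assemble the linearised marginal OFV, reusing the last stencil
  # (df/deta at the mode doubles as the linearisation matrix G)
  f0 <- cur$f0
  v0 <- cur$v0
  r0 <- cur$r0
  G <- do.call(cbind, cur$Fk)
  omA <- omega[act, act, drop = FALSE]
  starts <- c(1L, head(ends, -1L) + 1L)
  ofv_i <- numeric(n_subj)
  cw <- if (compute_cwres) numeric(length(y)) else NULL
  for (i in seq_len(n_subj)) {
    jj <- starts[i]:ends[i]
    Gi <- G[jj, , drop = FALSE]
    Vi <- Gi %*% omA %*% t(Gi)
    diag(Vi) <- diag(Vi) + v0[jj]
    ri <- r0[jj] + Gi %*% eta[i, act]
    ch <- tryCatch(chol(Vi), error = function(e) NULL)
    if (is.null(ch)) {
      ofv_i[i] <- NA_real_
      next
    }
    z <- backsolve(ch, ri, transpose = TRUE)
    ofv_i[i] <- 2 * sum(log(diag(ch))) + sum(z^2)
    if (compute_cwres) cw[jj] <- z
  }
  out <- list(ofv = sum(ofv_i), ofv_i = ofv_i, eta = eta, f = f0, v = v0, G = G)
  if (compute_cwres) out$cwres <- cw
  out
}

# Compile a dataset + model into the structures the engine needs.
.build_fit_data <- function(dataset) {
  r <- dataset$records
  obs_all <- r$evid == 0L
  usable <- is.finite(r$dv_mg_L[obs_all])
  sched <- .build_sched(dataset, keep = usable)
  if (any(diff(sched$obs_subj) < 0)) stop("dataset must be sorted by subject")
  ends <- cumsum(as.integer(table(factor(sched$obs_subj,
                                         levels = seq_len(nrow(dataset$subjects))))))
  if (any(diff(c(0, ends)) == 0)) {
    keep_subj <- which(diff(c(0, ends)) > 0)
    stop(sprintf("subject(s) without usable observations: %s",
                 paste(dataset$subjects$subject_id[-keep_subj], collapse = ", ")))
  }
  list(sched = sched, y = sched$y, ends = ends, subjects = dataset$subjects)
}

# parameter packing: fixed effects and variance components on log scale,
# extra covariate-effect coefficients on the natural scale
.pack <- function(model) {
  effs <- model$covariates$effects
  # theta_r is estimated only when a covariate effect is tied to it
  # (theta = NA); otherwise it is a flat, unused dimension
  tied <- any(vapply(effs, function(e) is.na(e$theta %||% NA_real_), TRUE))
  x <- c(theta_nr = log(model$params$theta_nr),
         if (tied) c(theta_r = log(model$params$theta_r)),
         v1 = log(model$params$v1),
         q = log(model$params$q),
         v2 = log(model$params$v2))
  logpar <- rep(TRUE, length(x))
  for (i in seq_along(effs)) {
    if (!is.na(effs[[i]]$theta)) {
      nm <- sprintf("beta_%s_%s", effs[[i]]$param, effs[[i]]$cov)
      x <- c(x, stats::setNames(effs[[i]]$theta, nm))
      logpar <- c(logpar, FALSE)
    }
  }
  if (model$omega$cl > 0) { x <- c(x, omega_cl = log(model$omega$cl)); logpar <- c(logpar, TRUE) }
  if (model$omega$v1 > 0) { x <- c(x, omega_v1 = log(model$omega$v1)); logpar <- c(logpar, TRUE) }
  if (model$residual$kind %in% c("proportional", "combined")) {
    x <- c(x, sigma_prop = log(model$residual$sigma_prop)); logpar <- c(logpar, TRUE)
  }
  if (model$residual$kind %in% c("additive", "combined")) {
    x <- c(x, sigma_add = log(model$residual$sigma_add)); logpar <- c(logpar, TRUE)
  }
  list(x = x, logpar = logpar)
}

.unpack <- function(x, model) {
  m <- model
  m$params$theta_nr <- exp(x[["theta_nr"]])
  if ("theta_r" %in% names(x)) m$params$theta_r <- exp(x[["theta_r"]])
  m$params$v1 <- exp(x[["v1"]])
  m$params$q <- exp(x[["q"]])
  m$params$v2 <- exp(x[["v2"]])
  effs <- m$covariates$effects
  for (i in seq_along(effs)) {
    nm <- sprintf("beta_%s_%s", effs[[i]]$param, effs[[i]]$cov)
    if (nm %in% names(x)) m$covariates$effects[[i]]$theta <- x[[nm]]
  }
  if ("omega_cl" %in% names(x)) m$omega$cl <- exp(x[["omega_cl"]])
  if ("omega_v1" %in% names(x)) m$omega$v1 <- exp(x[["omega_v1"]])
  if ("sigma_prop" %in% names(x)) m$residual$sigma_prop <- exp(x[["sigma_prop"]])
  if ("sigma_add" %in% names(x)) m$residual$sigma_add <- exp(x[["sigma_add"]])
  m
}

# natural-scale named estimates from a model
.estimates_vec <- function(model) {
  p <- .pack(model)
  ifelse(p$logpar, exp(p$x), p$x) |> stats::setNames(names(p$x))
}

# Objective closure. The linearised marginal OFV is first-order sensitive to
# where the inner eta search stops, so the engine polishes every mode to
# |grad| ~ 1e-8 (Newton tail); at that precision the OFV is independent of
# the inner starting point to ~1e-10, and warm-starting the modes across
# outer iterations (warm = TRUE, used inside fit_foce) is purely a speed-up.
# The default cold start from 0 keeps ofv_foce strictly deterministic.
.model_ofv_fun <- function(fd, model, warm = FALSE, grad_tol = 1e-7,
                           objective = "foce") {
  env <- if (warm) new.env(parent = emptyenv()) else NULL
  n_subj <- nrow(fd$subjects)
  # the engine evaluates f on a fixed finite-difference stencil over the
  # active random effects; stacking the schedule lets the whole stencil be
  # computed in one vectorised closed-form call
  act <- which(c(model$omega$cl, model$omega$v1) > 0)
  m_stencil <- 1L + 2L * length(act)
  sstack <- .stack_sched(fd$sched, m_stencil, n_subj)
  function(x, compute_cwres = FALSE) {
    m <- .unpack(x, model)
    tv <- .typical_params(m, fd$subjects)
    if (any(!is.finite(unlist(tv))) || any(tv$cl <= 0) || any(tv$v1 <= 0)) {
      return(list(ofv = 1e10))
    }
    f_fun <- function(eta) .predict_sched(fd$sched, tv$cl * exp(eta[, 1L]),
                                          tv$v1 * exp(eta[, 2L]), tv$q, tv$v2)
    cl_rep <- rep(tv$cl, m_stencil)
    v1_rep <- rep(tv$v1, m_stencil)
    q_rep <- rep(tv$q, m_stencil)
    v2_rep <- rep(tv$v2, m_stencil)
    f_stencil <- function(eta, h) {
      e1 <- rep(eta[, 1L], m_stencil)
      e2 <- rep(eta[, 2L], m_stencil)
      pos <- n_subj
      for (k in act) {
        idx <- pos + seq_len(n_subj)
        if (k == 1L) e1[idx] <- e1[idx] + h else e2[idx] <- e2[idx] + h
        idx <- idx + n_subj
        if (k == 1L) e1[idx] <- e1[idx] - h else e2[idx] <- e2[idx] - h
        pos <- pos + 2L * n_subj
      }
      fb <- .predict_sched(sstack, cl_rep * exp(e1), v1_rep * exp(e2),
                           q_rep, v2_rep)
      n_obs <- fd$sched$n_obs
      lapply(seq_len(m_stencil), function(i)
        fb[((i - 1L) * n_obs + 1L):(i * n_obs)])
    }
    res <- .foce_engine(fd$y, fd$ends, f_fun, omega_matrix(m$omega),
                        m$residual,
                        eta = if (!is.null(env)) env$eta else NULL,
                        grad_tol = grad_tol, compute_cwres = compute_cwres,
                        objective = objective, f_stencil = f_stencil)
    if (!is.null(env) && !is.null(res$eta)) env$eta <- res$eta
    res
  }
}

# replicate a prediction schedule m times (block-diagonal stacking over
# subjects and observations) so a whole eta stencil evaluates in one call
.stack_sched <- function(sched, m, n_subj) {
  if (m == 1L) return(sched)
  npair <- length(sched$pair_obs)
  counts <- diff(c(0L, sched$pair_ends))
  list(n_obs = m * sched$n_obs,
       pair_obs = rep(sched$pair_obs, m) +
         rep((0:(m - 1L)) * sched$n_obs, each = npair),
       pair_subj = rep(sched$pair_subj, m) +
         rep((0:(m - 1L)) * n_subj, each = npair),
       pair_dt = rep(sched$pair_dt, m),
       pair_amt = rep(sched$pair_amt, m),
       pair_tinf = rep(sched$pair_tinf, m),
       pair_ss = rep(sched$pair_ss, m),
       pair_tau = rep(sched$pair_tau, m),
       pair_ends = cumsum(rep(counts, m)),
       one_to_one = sched$one_to_one,
       all_ss = sched$all_ss,
       none_ss = sched$none_ss)
}

#' FOCE-I objective function value of a model on a dataset
#'
#' @param dataset a [pk_dataset()].
#' @param model a `pk_model`.
#' @return the OFV (-2 log-likelihood up to the additive `n log 2pi`
#'   constant), deterministic for fixed inputs.
#' @export
ofv_foce <- function(dataset, model) {
  fd <- .build_fit_data(dataset)
  f <- .model_ofv_fun(fd, model)
  res <- f(.pack(model)$x)
  if (!is.finite(res$ofv)) stop("OFV not finite at the supplied parameters")
  res$ofv
}

#' Fit the population model by FOCE-I
#'
#' Minimises the FOCE-I objective over the fixed effects, IIV standard
#' deviations and residual-error parameters (all on log scale; covariate
#' effect coefficients added by SCM on the natural scale). Standard errors
#' come from the inverse central-difference Hessian of the OFV
#' (`cov = 2 H^-1`); empirical Bayes estimates (EBE) and eta/epsilon
#' shrinkage are reported.
#'
#' @param dataset a [pk_dataset()].
#' @param model starting `pk_model` (structure + initial values).
#' @param compute_se compute the Hessian-based standard errors.
#' @param method likelihood approximation: "foce" (default, FOCE with
#'   interaction) or "laplace" (second-order Laplace; cross-check option).
#' @param control list: `factr` (L-BFGS-B relative-reduction stop, default
#'   1e7, i.e. ~2e-9 relative), `iter_max` (default 300) and `inner_tol`
#'   (gradient tolerance of the conditional-mode search, default 1e-7).
#' @return object of class `pk_fit`: estimates, `se`, `rse_pct`, `ofv`,
#'   `ebe`, `shrinkage_pct`, `eps_shrinkage_pct`, `converged`, and the fitted
#'   `model`.
#' @export
fit_foce <- function(dataset, model = final_model(), compute_se = TRUE,
                     method = c("foce", "laplace"), control = list()) {
  method <- match.arg(method)
  ctl <- utils::modifyList(list(factr = 1e7, iter_max = 300L,
                                inner_tol = 1e-7), control)
  fd <- .build_fit_data(dataset)
  ofun <- .model_ofv_fun(fd, model, warm = TRUE, grad_tol = ctl$inner_tol,
                         objective = method)
  x0 <- .pack(model)$x
  o0 <- ofun(x0)$ofv
  if (!is.finite(o0)) stop("OFV not finite at the initial estimates")
  obj <- function(x) {
    v <- ofun(x)$ofv
    if (!is.finite(v)) 1e10 else v
  }
  # L-BFGS-B with finite-difference steps well above the ~1e-9 truncation
  # noise of the inner eta search; log-scale parameters are boxed generously
  logpar <- .pack(model)$logpar
  lower <- ifelse(logpar, -7, -50)
  upper <- ifelse(logpar, 7, 50)
  opt <- stats::optim(x0, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper,
                      control = list(ndeps = rep(1e-5, length(x0)),
                                     factr = ctl$factr,
                                     maxit = ctl$iter_max))
  xhat <- opt$par
  final <- .model_ofv_fun(fd, model, grad_tol = ctl$inner_tol,
                          objective = method)(xhat, compute_cwres = method == "foce")
  m_hat <- .unpack(xhat, model)
  # keep theta_r and the tied CrCl-effect exponent consistent by construction
  est <- .estimates_vec(m_hat)

  se <- rse <- rep(NA_real_, length(xhat))
  names(se) <- names(rse) <- names(xhat)
  converged <- opt$convergence == 0
  if (compute_se) {
    H <- .num_hessian(obj, xhat, rel_h = 1e-4)
    cov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (is.null(cov_t) || any(diag(cov_t) <= 0)) {
      warning("OFV Hessian not positive definite; standard errors not reported")
      converged <- FALSE
    } else {
      se_t <- sqrt(diag(cov_t))
      logpar <- .pack(m_hat)$logpar
      se <- ifelse(logpar, se_t * est, se_t)   # delta method for log-scale pars
      rse <- 100 * se / abs(est)
    }
  }

  omv <- c(cl = m_hat$omega$cl, v1 = m_hat$omega$v1)
  shr <- 100 * (1 - apply(final$eta, 2L, stats::sd) / pmax(omv, 1e-12))
  names(shr) <- c("cl", "v1")
  iwres <- (fd$y - final$f) / sqrt(final$v)
  eps_shr <- 100 * (1 - stats::sd(iwres))

  structure(list(model = m_hat, estimates = est, se = se, rse_pct = rse,
                 ofv = final$ofv, ebe = final$eta, shrinkage_pct = shr,
                 eps_shrinkage_pct = eps_shr, converged = converged,
                 n_subjects = nrow(fd$subjects), n_obs = length(fd$y),
                 n_eval = opt$counts[[1L]],
                 message = opt$message), class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-I fit: %d subjects, %d observations, OFV = %.3f (%s)\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse_pct, 1))
  print(tab)
  cat(sprintf("eta shrinkage (%%): cl %.1f, v1 %.1f; eps shrinkage %.1f\n",
              x$shrinkage_pct[["cl"]], x$shrinkage_pct[["v1"]],
              x$eps_shrinkage_pct))
  invisible(x)
}

# central-difference Hessian with relative steps
.num_hessian <- function(fn, x, rel_h = 1e-4) {
  p <- length(x)
  hh <- rel_h * pmax(abs(x), 1)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hh[i]
        xm <- x; xm[i] <- x[i] - hh[i]
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hh[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + hh[i]; xpp[j] <- x[j] + hh[j]
        xpm <- x; xpm[i] <- x[i] + hh[i]; xpm[j] <- x[j] - hh[j]
        xmp <- x; xmp[i] <- x[i] - hh[i]; xmp[j] <- x[j] + hh[j]
        xmm <- x; xmm[i] <- x[i] - hh[i]; xmm[j] <- x[j] - hh[j]
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) /
          (4 * hh[i] * hh[j])
      }
    }
  }
  H
}

#' Stepwise covariate model building
#'
#' Forward inclusion: at each step every remaining candidate is added to the
#' current model and refitted; the candidate with the largest OFV drop is
#' retained if the drop is at least `forward_delta` (3.84, p < 0.05 for 1
#' d.f.). Ties are broken by fewer added parameters, then lexically. Backward
#' elimination then removes, one at a time, any retained covariate whose
#' removal raises the OFV by at most `backward_delta` (6.63, p > 0.01).
#'
#' @param dataset a [pk_dataset()].
#' @param base_model starting `pk_model` (typically without covariates).
#' @param candidates list of [cov_effect()] entries (with starting `theta`).
#' @param forward_delta,backward_delta OFV gates.
#' @param refit_base fit the base model first (TRUE) or trust its values.
#' @return list with `model` (final fitted model), `fit` (its `pk_fit`) and
#'   `log` (data.frame auditing every tested step with its delta-OFV).
#' @export
scm <- function(dataset, base_model, candidates,
                forward_delta = 3.84, backward_delta = 6.63,
                refit_base = TRUE) {
  stopifnot(forward_delta < backward_delta)
  cand_name <- function(e) sprintf("%s~%s(%s)", e$param, e$cov, e$form)
  fit0 <- fit_foce(dataset, base_model, compute_se = FALSE)
  cur_model <- fit0$model
  cur_fit <- fit0
  log <- data.frame(phase = character(), candidate = character(),
                    ofv_ref = numeric(), ofv_test = numeric(),
                    delta_ofv = numeric(), action = character())
  included <- list()
  remaining <- candidates

  repeat {
    if (!length(remaining)) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      m_try <- cur_model
      m_try$covariates <- covariate_model(c(cur_model$covariates$effects,
                                            list(remaining[[i]])))
      fits[[i]] <- tryCatch(fit_foce(dataset, m_try, compute_se = FALSE),
                            error = function(e) NULL)
      deltas[i] <- if (is.null(fits[[i]])) NA_real_ else cur_fit$ofv - fits[[i]]$ofv
      log <- rbind(log, data.frame(phase = "forward",
                                   candidate = cand_name(remaining[[i]]),
                                   ofv_ref = cur_fit$ofv,
                                   ofv_test = if (is.null(fits[[i]])) NA_real_ else fits[[i]]$ofv,
                                   delta_ofv = deltas[i], action = "tested"))
    }
    ok <- which(!is.na(deltas) & deltas >= forward_delta)
    if (!length(ok)) break
    nms <- vapply(remaining, cand_name, "")
    best <- ok[order(-deltas[ok], nms[ok])][1L]
    log$action[nrow(log) - length(remaining) + best] <- "added"
    included <- c(included, remaining[best])
    cur_fit <- fits[[best]]
    cur_model <- cur_fit$model
    remaining <- remaining[-best]
  }

  # backward elimination over covariates added during forward selection
  repeat {
    if (!length(included)) break
    ups <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    inc_names <- vapply(included, cand_name, "")
    for (i in seq_along(included)) {
      m_try <- cur_model
      keys <- vapply(m_try$covariates$effects,
                     function(e) sprintf("%s~%s(%s)", e$param, e$cov, e$form), "")
      m_try$covariates <- covariate_model(
        m_try$covariates$effects[keys != inc_names[i]])
      fits[[i]] <- tryCatch(fit_foce(dataset, m_try, compute_se = FALSE),
                            error = function(e) NULL)
      ups[i] <- if (is.null(fits[[i]])) NA_real_ else fits[[i]]$ofv - cur_fit$ofv
      log <- rbind(log, data.frame(phase = "backward", candidate = inc_names[i],
                                   ofv_ref = cur_fit$ofv,
                                   ofv_test = if (is.null(fits[[i]])) NA_real_ else fits[[i]]$ofv,
                                   delta_ofv = ups[i], action = "tested"))
    }
    drop_ok <- which(!is.na(ups) & ups <= backward_delta)
    if (!length(drop_ok)) break
    worst <- drop_ok[order(ups[drop_ok], inc_names[drop_ok])][1L]
    log$action[nrow(log) - length(included) + worst] <- "removed"
    cur_fit <- fits[[worst]]
    cur_model <- cur_fit$model
    included <- included[-worst]
  }

  list(model = cur_model, fit = cur_fit, log = log)
}

#' Nonparametric bootstrap of the population-model fit
#'
#' Resamples subjects with replacement to the original subject count, refits
#' each replicate starting from the supplied model's values, and summarises
#' replicate estimates by their median and 2.5/97.5 percentiles. Failed or
#' non-converged replicates are counted and excluded.
#'
#' @param dataset a [pk_dataset()].
#' @param model `pk_model` used both as the fitted structure and the starting
#'   values (typically the original fit's model).
#' @param n_replicates number of bootstrap samples.
#' @param seed integer seed for the resampling stream.
#' @param control optimiser control for the replicate refits; since every
#'   refit starts at the original estimates, a tighter iteration budget and
#'   slightly relaxed stopping rule are the default.
#' @return object of class `pk_bootstrap`: `summary` (data.frame of median
#'   and percentile columns per parameter), `replicates` (matrix), `n_failed`.
#' @export
bootstrap_fit <- function(dataset, model, n_replicates = 200L, seed = 1L,
                          control = list(factr = 1e9, iter_max = 100L,
                                         inner_tol = 1e-6)) {
  stopifnot(n_replicates >= 1L)
  ids <- dataset$subjects$subject_id
  n <- length(ids)
  draws <- matrix(split_seed(seed, n_replicates), ncol = 1L)
  reps <- list()
  n_failed <- 0L
  for (b in seq_len(n_replicates)) {
    set.seed(draws[b, 1L])
    take <- sample(ids, n, replace = TRUE)
    recs <- list(); subs <- list()
    for (k in seq_along(take)) {
      rr <- dataset$records[dataset$records$subject_id == take[k], , drop = FALSE]
      ss <- dataset$subjects[dataset$subjects$subject_id == take[k], , drop = FALSE]
      rr$subject_id <- k
      ss$subject_id <- k
      recs[[k]] <- rr; subs[[k]] <- ss
    }
    dat_b <- pk_dataset(do.call(rbind, recs), do.call(rbind, subs),
                        validate = FALSE)
    fit_b <- tryCatch(fit_foce(dat_b, model, compute_se = FALSE,
                               control = control),
                      error = function(e) NULL)
    if (is.null(fit_b) || !is.finite(fit_b$ofv)) {
      n_failed <- n_failed + 1L
    } else {
      reps[[length(reps) + 1L]] <- fit_b$estimates
    }
  }
  if (n_failed > n_replicates / 2) {
    stop(sprintf("bootstrap unstable: %d of %d replicates failed", n_failed,
                 n_replicates))
  }
  mat <- do.call(rbind, reps)
  qs <- apply(mat, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975))
  summary <- data.frame(parameter = colnames(mat), median = qs[1L, ],
                        ci_lo = qs[2L, ], ci_hi = qs[3L, ], row.names = NULL)
  structure(list(summary = summary, replicates = mat,
                 n_replicates = n_replicates, n_failed = n_failed),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("bootstrap: %d replicates (%d failed)\n", x$n_replicates,
              x$n_failed))
  print(transform(x$summary, median = signif(median, 4),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4)))
  invisible(x)
}
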