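# Internal prediction machinery shared by simulation, estimation and
# diagnostics: a dataset is compiled once into a "schedule" of
# (observation, dose) pairs so that concentrations for the whole population
# can be evaluated with a handful of vectorised closed-form calls.

# Compile a dataset into a prediction schedule.
# Observations are the evid == 0 rows (optionally restricted by `keep`,
# a logical over those rows). Every observation is paired with each dose row
# of its subject: steady-state dose rows (ss == 1, interval tau_h) use the
# steady-state closed form at (t - dose time) mod tau; ordinary dose rows
# contribute the single-infusion solution (zero before the dose).
.build_sched <- function(dataset, keep = NULL) {
  r <- dataset$records
  sid <- dataset$subjects$subject_id
  obs <- which(r$evid == 0L)
  if (!is.null(keep)) obs <- obs[keep]
  dos <- which(r$evid == 1L)
  obs_subj <- match(r$subject_id[obs], sid)
  dose_subj <- match(r$subject_id[dos], sid)

  # pair expansion: for each subject, (its obs) x (its doses)
  od <- split(seq_along(obs), obs_subj)
  dd <- split(seq_along(dos), dose_subj)
  po <- integer(0); pd <- integer(0)
  for (s in names(od)) {
    if (!is.null(dd[[s]])) {
      g <- expand.grid(o = od[[s]], d = dd[[s]])
      po <- c(po, g$o); pd <- c(pd, g$d)
    }
  }
  # order pairs by observation so per-observation sums are contiguous
  ord <- order(po)
  po <- po[ord]; pd <- pd[ord]
  dt <- r$time_h[obs][po] - r$time_h[dos][pd]
  is_ss <- r$ss[dos][pd] %in% 1L
  counts <- tabulate(po, nbins = length(obs))
  list(n_obs = length(obs),
       obs_rows = obs,
       obs_subj = obs_subj,
       y = r$dv_mg_L[obs],
       pair_obs = po,
       pair_subj = obs_subj[po],
       pair_dt = dt,
       pair_amt = r$amt_mg[dos][pd],
       pair_tinf = r$dur_h[dos][pd],
       pair_ss = is_ss,
       pair_tau = r$tau_h[dos][pd],
       pair_ends = cumsum(counts),
       one_to_one = all(counts == 1L),
       all_ss = all(is_ss),
       none_ss = !any(is_ss))
}

# Evaluate predictions for a schedule given per-subject parameters
# (vectors over the subject table). Returns a vector over observations.
.predict_sched <- function(sched, cl, v1, q, v2) {
  ps <- sched$pair_subj
  if (sched$all_ss) {
    contrib <- .conc_ss(sched$pair_dt, sched$pair_amt, sched$pair_tau,
                        sched$pair_tinf, cl[ps], v1[ps], q[ps], v2[ps])
  } else if (sched$none_ss) {
    contrib <- .conc_single(sched$pair_dt, sched$pair_amt, sched$pair_tinf,
                            cl[ps], v1[ps], q[ps], v2[ps])
  } else {
    ss <- sched$pair_ss
    contrib <- numeric(length(ps))
    contrib[ss] <- .conc_ss(sched$pair_dt[ss], sched$pair_amt[ss],
                            sched$pair_tau[ss], sched$pair_tinf[ss],
                            cl[ps[ss]], v1[ps[ss]], q[ps[ss]], v2[ps[ss]])
    contrib[!ss] <- .conc_single(sched$pair_dt[!ss], sched$pair_amt[!ss],
                                 sched$pair_tinf[!ss],
                                 cl[ps[!ss]], v1[ps[!ss]], q[ps[!ss]], v2[ps[!ss]])
  }
  if (sched$one_to_one) return(contrib)
  if (!length(contrib)) return(numeric(sched$n_obs))
  .grpsum(contrib, sched$pair_ends)
}

#' Population and individual predictions for every observation row
#'
#' @param dataset a [pk_dataset()].
#' @param model a `pk_model`.
#' @param eta optional n_subjects x 2 matrix of random effects (0 = population
#'   prediction).
#' @return numeric vector of predicted concentrations, one per observation
#'   row (dataset order).
#' @export
predict_conc <- function(dataset, model, eta = NULL) {
  sched <- .build_sched(dataset)
  tv <- .typical_params(model, dataset$subjects)
  if (is.null(eta)) eta <- matrix(0, nrow(dataset$subjects), 2L)
  .predict_sched(sched, tv$cl * exp(eta[, 1L]), tv$v1 * exp(eta[, 2L]),
                 tv$q, tv$v2)
}
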