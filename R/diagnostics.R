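#' Conditional weighted residuals (CWRES)
#'
#' FOCE-linearised residuals: for each subject, with `eta_hat` the conditional
#' mode and `G = df/deta` at `eta_hat`, the residual
#' `r = y - f(eta_hat) + G eta_hat` is decorrelated by the inverse Cholesky
#' square root of the linearised covariance `V = G Omega G' + diag(v)`. Under
#' a correct model CWRES are approximately standard normal.
#'
#' @param dataset a [pk_dataset()].
#' @param model a `pk_model` (e.g. a fitted `pk_fit$model`).
#' @return data.frame with `subject_id`, `time_h`, `dv`, `pred` (population
#'   prediction), `ipred` (individual prediction at `eta_hat`) and `cwres`,
#'   one row per usable observation.
#' @export
cwres <- function(dataset, model) {
  fd <- .build_fit_data(dataset)
  ofun <- .model_ofv_fun(fd, model)
  res <- ofun(.pack(model)$x, compute_cwres = TRUE)
  tv <- .typical_params(model, fd$subjects)
  pred <- .predict_sched(fd$sched, tv$cl, tv$v1, tv$q, tv$v2)
  data.frame(subject_id = fd$subjects$subject_id[fd$sched$obs_subj],
             time_h = dataset$records$time_h[fd$sched$obs_rows],
             dv = fd$y, pred = pred, ipred = res$f, cwres = res$cwres)
}

#' Goodness-of-fit table
#'
#' Observed concentrations with population (PRED) and individual (IPRED)
#' predictions and CWRES, ready for the standard DV-vs-PRED / CWRES-vs-time
#' panels.
#'
#' @inheritParams cwres
#' @return data.frame (same layout as [cwres()]).
#' @export
gof_table <- function(dataset, model) cwres(dataset, model)

.default_bins <- function() c(0, 0.25, 0.75, 2.5, 5.5, 9, 12.001)

#' Prediction-corrected visual predictive check
#'
#' Replicates the study design `n_replicates` times under the model, corrects
#' each observed and simulated concentration by
#' `bin-median population prediction / own population prediction`, and
#' compares the observed 10th/50th/90th percentiles per time-after-dose bin
#' with the simulation-based 95% confidence band of each percentile.
#' Bins with fewer than 5 observations are merged with their left neighbour
#' (logged).
#'
#' @param dataset a [pk_dataset()].
#' @param model a `pk_model`.
#' @param n_replicates number of simulated replicate studies.
#' @param bins bin edges on time after dose (h); default follows the nominal
#'   design times 0, 0.5, 1-2, 3-5, 6-8, 12.
#' @param seed integer seed.
#' @param probs percentiles to check.
#' @return object of class `pk_vpc`: `table` (per bin and percentile:
#'   observed value, band low/high), `n_replicates`, `bins`.
#' @export
pcvpc <- function(dataset, model, n_replicates = 1000L,
                  bins = .default_bins(), seed = 1L,
                  probs = c(0.1, 0.5, 0.9)) {
  r <- dataset$records
  obs <- r$evid == 0L & is.finite(r$dv_mg_L)
  tad <- r$time_h[obs]  # single-interval steady-state designs: time == TAD
  y <- r$dv_mg_L[obs]
  pred <- predict_conc(dataset, model)[is.finite(r$dv_mg_L[r$evid == 0L])]

  bin_id <- cut(tad, bins, include.lowest = TRUE, right = FALSE)
  # merge sparse bins leftward
  repeat {
    cnt <- table(bin_id)
    small <- which(cnt > 0 & cnt < 5)
    if (!length(small) || length(levels(bin_id)) == 1L) break
    k <- small[1L]
    to <- if (k == 1L) 2L else k - 1L
    lp_log("merging sparse VPC bin %s into %s", levels(bin_id)[k], levels(bin_id)[to])
    levels(bin_id)[k] <- levels(bin_id)[to]
  }
  bin_id <- droplevels(bin_id)

  pcorr <- function(v, pred, bin_id) {
    med <- tapply(pred, bin_id, stats::median)
    v * as.numeric(med[bin_id]) / pred
  }
  obs_pc <- pcorr(y, pred, bin_id)
  obs_q <- do.call(rbind, tapply(obs_pc, bin_id, stats::quantile, probs = probs))

  seeds <- split_seed(seed, n_replicates)
  nb <- nlevels(bin_id)
  sim_q <- array(NA_real_, c(n_replicates, nb, length(probs)))
  for (b in seq_len(n_replicates)) {
    simd <- simulate_study(dataset, model, seed = seeds[b])
    ys <- simd$records$dv_mg_L[obs]
    ys_pc <- pcorr(ys, pred, bin_id)
    sim_q[b, , ] <- do.call(rbind, tapply(ys_pc, bin_id, stats::quantile, probs = probs))
  }
  lo <- apply(sim_q, c(2L, 3L), stats::quantile, probs = 0.025)
  hi <- apply(sim_q, c(2L, 3L), stats::quantile, probs = 0.975)
  md <- apply(sim_q, c(2L, 3L), stats::median)

  tab <- expand.grid(bin = levels(bin_id), percentile = 100 * probs)
  tab$observed <- as.vector(obs_q)
  tab$sim_median <- as.vector(md)
  tab$band_lo <- as.vector(lo)
  tab$band_hi <- as.vector(hi)
  tab$n_obs <- as.vector(table(bin_id))[match(tab$bin, levels(bin_id))]
  structure(list(table = tab, n_replicates = n_replicates, bins = bins),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("prediction-corrected VPC, %d replicates\n", x$n_replicates))
  print(transform(x$table, observed = signif(observed, 4),
                  sim_median = signif(sim_median, 4),
                  band_lo = signif(band_lo, 4), band_hi = signif(band_hi, 4)))
  invisible(x)
}

#' Plot a prediction-corrected VPC
#'
#' @param vpc a `pk_vpc` from [pcvpc()].
#' @return a ggplot object.
#' @export
plot_pcvpc <- function(vpc) {
  tab <- vpc$table
  tab$mid <- as.numeric(tab$bin)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mid, group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "time-after-dose bin", y = "prediction-corrected concentration (mg/L)",
                  title = "Prediction-corrected visual predictive check") +
    ggplot2::theme_bw()
}

#' Plot goodness-of-fit panels
#'
#' DV vs PRED, DV vs IPRED, CWRES vs PRED and CWRES vs time after dose.
#'
#' @param gof data.frame from [gof_table()].
#' @return a ggplot object (faceted).
#' @export
plot_gof <- function(gof) {
  long <- rbind(
    data.frame(panel = "DV vs PRED", x = gof$pred, y = gof$dv, ref = "identity"),
    data.frame(panel = "DV vs IPRED", x = gof$ipred, y = gof$dv, ref = "identity"),
    data.frame(panel = "CWRES vs PRED", x = gof$pred, y = gof$cwres, ref = "zero"),
    data.frame(panel = "CWRES vs TAD", x = gof$time_h, y = gof$cwres, ref = "zero"))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(data = data.frame(panel = c("DV vs PRED", "DV vs IPRED")),
                         ggplot2::aes(intercept = 0, slope = 1), linetype = 2) +
    ggplot2::geom_hline(data = data.frame(panel = c("CWRES vs PRED", "CWRES vs TAD")),
                        ggplot2::aes(yintercept = 0), linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
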