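# closed-form marginal -2 log-likelihood (omitting the n log 2pi constant)
# for y_i ~ N(mu_i, V_i): the independent oracle for the FOCE objective
gauss_m2ll <- function(r_list, V_list) {
  sum(vapply(seq_along(r_list), function(i) {
    V <- V_list[[i]]; r <- r_list[[i]]
    ch <- chol(V)
    2 * sum(log(diag(ch))) + sum(backsolve(ch, r, transpose = TRUE)^2)
  }, 0))
}

test_that("without IIV and with additive error the OFV is weighted least squares", {
  sigma <- 1.5
  d <- tiny_dataset(times = c(0.5, 2, 6, 12), dv = c(38, 25, 16, 9))
  m <- final_model(omega = omega_spec(0, 0),
                   residual = residual_spec("additive", sigma_add = sigma))
  f <- predict_conc(d, m)
  r <- d$records$dv_mg_L[d$records$evid == 0L] - f
  oracle <- sum(log(sigma^2) + r^2 / sigma^2)
  expect_equal(ofv_foce(d, m), oracle, tolerance = 1e-10)
})

test_that("the FOCE engine reproduces the exact likelihood of a linear mixed model", {
  # one-parameter model f = theta + eta with additive IIV and additive error
  # is linear in eta, so FOCE-I is exact; oracle = closed-form marginal -2LL
  set.seed(7)
  theta <- 5; omega <- 1.2; sigma <- 0.8
  n_per <- c(4L, 3L, 5L)
  y <- unlist(lapply(n_per, function(k) theta + rnorm(1, 0, omega) +
                       rnorm(k, 0, sigma)))
  ends <- cumsum(n_per)
  f_fun <- function(eta) (theta + eta[, 1L])[rep(seq_along(n_per), n_per)]
  res <- levipop:::.foce_engine(y, ends, f_fun,
                                omega = matrix(omega^2, 1L, 1L),
                                resid = residual_spec("additive",
                                                      sigma_add = sigma))
  starts <- c(1L, head(ends, -1L) + 1L)
  r_list <- lapply(seq_along(n_per), function(i) y[starts[i]:ends[i]] - theta)
  V_list <- lapply(n_per, function(k)
    diag(sigma^2, k) + matrix(omega^2, k, k))
  expect_equal(res$ofv, gauss_m2ll(r_list, V_list), tolerance = 1e-6)
})

test_that("the OFV prefers the data-generating parameters over a distorted model", {
  des <- study_design(n_subjects = 100L, dose_allocation = c("500" = 70L,
                                                             "1000" = 20L,
                                                             "1500" = 10L),
                      n_five_sample = 15L)
  d <- generate_study(des, final_model(), seed = 21)
  ofv_true <- ofv_foce(d, final_model())
  bad <- final_model(params = pk_params(theta_nr = 7.0))  # CL intercept doubled
  expect_lt(ofv_true, ofv_foce(d, bad))
  # deterministic for fixed inputs
  expect_identical(ofv_true, ofv_foce(d, final_model()))
})

test_that("the OFV is invariant to subject relabelling and record order", {
  d <- generate_study(study_design(n_subjects = 8L,
                                   dose_allocation = c("500" = 8L),
                                   n_five_sample = 0L),
                      final_model(), seed = 5)
  ofv0 <- ofv_foce(d, final_model())
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  r <- d$records; s <- d$subjects
  r$subject_id <- perm[r$subject_id]
  s$subject_id <- perm[s$subject_id]
  d2 <- pk_dataset(r[sample(nrow(r)), ], s[order(s$subject_id), ])
  expect_equal(ofv_foce(d2, final_model()), ofv0, tolerance = 1e-8)
})

test_that("a refit from converged estimates is a fixed point", {
  d <- generate_study(seed = 5)
  f1 <- fit_foce(d, final_model(), compute_se = FALSE)
  f2 <- fit_foce(d, f1$model, compute_se = FALSE)
  expect_lt(abs(f2$ofv - f1$ofv), 0.1)
})

test_that("restricting a model at its optimum cannot lower the OFV", {
  d <- generate_study(study_design(n_subjects = 12L,
                                   dose_allocation = c("500" = 12L),
                                   n_five_sample = 0L),
                      final_model(), seed = 17)
  base <- final_model(covariates = covariate_model())  # no covariate
  fit_base <- fit_foce(d, base, compute_se = FALSE)
  fit_full <- fit_foce(d, final_model(params = fit_base$model$params,
                                      omega = fit_base$model$omega,
                                      residual = fit_base$model$residual),
                       compute_se = FALSE)
  expect_gte(fit_base$ofv - fit_full$ofv, -1e-3)
})

test_that("IIV estimates shrink toward zero when the data carry none", {
  m0 <- final_model(omega = omega_spec(0.02, 0.02),
                    residual = residual_spec(sigma_prop = 0.05))
  des <- study_design(n_subjects = 30L, dose_allocation = c("500" = 30L),
                      n_five_sample = 0L)
  d <- generate_study(des, m0, seed = 99)
  fit <- fit_foce(d, final_model(omega = omega_spec(0.2, 0.2),
                                 residual = residual_spec(sigma_prop = 0.05)),
                  compute_se = FALSE)
  expect_lt(fit$model$omega$cl, 0.08)
  expect_lt(fit$model$omega$v1, 0.12)
})

test_that("scm returns the base model untouched when there are no candidates", {
  d <- generate_study(study_design(n_subjects = 10L,
                                   dose_allocation = c("500" = 10L),
                                   n_five_sample = 0L),
                      final_model(), seed = 2)
  base <- final_model()
  out <- scm(d, base, candidates = list())
  expect_equal(length(out$model$covariates$effects),
               length(base$covariates$effects))
  expect_equal(nrow(out$log), 0L)
})

test_that("bootstrap percentiles behave at the degenerate and seeded limits", {
  d <- generate_study(study_design(n_subjects = 10L,
                                   dose_allocation = c("500" = 10L),
                                   n_five_sample = 0L),
                      final_model(), seed = 11)
  f <- fit_foce(d, final_model(), compute_se = FALSE)
  b1 <- bootstrap_fit(d, f$model, n_replicates = 1L, seed = 4)
  expect_equal(unname(b1$summary$median), unname(b1$summary$ci_lo))
  expect_equal(unname(b1$summary$median), unname(b1$summary$ci_hi))
  b2 <- bootstrap_fit(d, f$model, n_replicates = 2L, seed = 8)
  b3 <- bootstrap_fit(d, f$model, n_replicates = 2L, seed = 8)
  expect_identical(b2$replicates, b3$replicates)
})
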