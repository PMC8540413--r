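test_that("log-normal IIV has the stated median and log-scale spread", {
  covs <- data.frame(subject_id = 1:100000, crcl_ml_min = 120)
  inds <- sample_individuals(final_model(), covs, seed = 33)
  # log-normal median equals the typical value
  expect_equal(median(inds$cl), 4.5, tolerance = 0.01)
  expect_equal(sd(log(inds$cl)), 0.327, tolerance = 0.02)
  expect_equal(sd(log(inds$v1)), 0.561, tolerance = 0.02)
  expect_equal(mean(inds$eta_cl), 0, tolerance = 0.005)
  expect_equal(mean(inds$eta_v1), 0, tolerance = 0.01)
  expect_lt(abs(cor(inds$eta_cl, inds$eta_v1)), 0.02)
})

test_that("zero IIV collapses to the typical individual", {
  m <- final_model(omega = omega_spec(cl = 0, v1 = 0))
  covs <- data.frame(subject_id = 1:5, crcl_ml_min = c(60, 80, 120, 180, 240))
  inds <- sample_individuals(m, covs, seed = 1)
  expect_equal(inds$cl, typical_clearance(covs$crcl_ml_min))
  expect_equal(inds$v1, rep(20.7, 5))
})

test_that("proportional residual error has the stated spread and respects zero predictions", {
  ind <- list(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5)
  reg <- dosing_regimen(1000, steady_state = TRUE)
  noise_free <- simulate_observations(ind, reg, c(0.5, 6), include_residual = FALSE)
  expect_equal(noise_free$dv, noise_free$pred)

  sim <- simulate_observations(ind, reg, rep(6, 1e5),
                               residual = residual_spec(sigma_prop = 0.223),
                               seed = 9)
  expect_equal(sd(sim$dv / sim$pred - 1), 0.223, tolerance = 0.02 * 0.223)

  # a zero structural prediction stays zero under multiplicative error
  pre <- simulate_observations(ind, dosing_regimen(1000, n_doses = 1L),
                               times = 0, seed = 4)
  expect_equal(pre$dv, 0)
})

test_that("study replication is seed-reproducible and collapses without variability", {
  d <- generate_study(seed = 3)
  s1 <- simulate_study(d, final_model(), seed = 42)
  s2 <- simulate_study(d, final_model(), seed = 42)
  expect_identical(s1$records$dv_mg_L, s2$records$dv_mg_L)
  s3 <- simulate_study(d, final_model(), seed = 43)
  expect_false(identical(s1$records$dv_mg_L, s3$records$dv_mg_L))

  # no IIV, no residual error: subjects with equal CrCl and dose coincide
  m0 <- final_model(omega = omega_spec(0, 0),
                    residual = residual_spec(sigma_prop = 0))
  des <- study_design(n_subjects = 4L, dose_allocation = c("500" = 4L),
                      n_five_sample = 0L, windows = list())
  d4 <- generate_study(des, m0, seed = 7)
  d4$subjects$crcl_ml_min <- 120
  s4 <- simulate_study(d4, m0, seed = 1)
  obs <- s4$records[s4$records$evid == 0L, ]
  by_time <- split(obs$dv_mg_L, obs$time_h)
  for (v in by_time) expect_lt(diff(range(v)), 1e-12)
})

test_that("simulated steady-state troughs have the deterministic typical median", {
  covs <- data.frame(subject_id = 1:20000, crcl_ml_min = 120)
  inds <- sample_individuals(final_model(), covs, seed = 88)
  reg <- dosing_regimen(1000, tau = 12, tinf = 0.5, steady_state = TRUE)
  troughs <- levipop:::.conc_ss(rep(12, nrow(inds)), 1000, 12, 0.5,
                                inds$cl, inds$v1, inds$q, inds$v2)
  typical <- conc_steady_state(list(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5),
                               reg, 12)
  # median of the log-normal-driven trough ~ typical trough (MC tolerance)
  expect_equal(median(troughs), typical, tolerance = 0.03 * typical)
})
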