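test_that("typical clearance reproduces the covariate-equation anchors", {
  p <- published_params()
  expect_identical(typical_clearance(120, p), p$theta_nr + 1)
  expect_equal(typical_clearance(120, p), 4.5)
  expect_equal(round(typical_clearance(240, p), 1), 9.2)
  expect_equal(typical_clearance(80, p), 3.5 + (80 / 120)^2.5)
  expect_error(typical_clearance(0, p), "positive")
  expect_error(typical_clearance(-5, p), "positive")
})

test_that("micro constants match an independent eigen-decomposition", {
  mc <- micro_constants(4.5, 20.7, 31.9, 33.5)
  A <- matrix(c(-(mc$k10 + mc$k12), mc$k12, mc$k21, -mc$k21), 2L, 2L)
  ev <- sort(-eigen(A, only.values = TRUE)$values)
  expect_equal(sort(c(mc$alpha, mc$beta)), ev, tolerance = 1e-12)

  set.seed(101)
  for (i in 1:25) {
    cl <- runif(1, 1, 20); v1 <- runif(1, 5, 60)
    q <- runif(1, 1, 60); v2 <- runif(1, 5, 80)
    mc <- micro_constants(cl, v1, q, v2)
    # root identities of the characteristic polynomial
    expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21, tolerance = 1e-12)
    expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-10)
    expect_equal(mc$coefA + mc$coefB, 1, tolerance = 1e-12)
    expect_true(mc$alpha >= mc$beta && mc$beta > 0)
  }
})

test_that("closed-form profile agrees with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(202)
  times <- c(0.1, 0.25, 0.5, 0.75, 1, 2, 4, 8, 12, 18, 24)
  for (i in 1:20) {
    ind <- list(cl = runif(1, 1, 15), v1 = runif(1, 8, 50),
                q = runif(1, 2, 60), v2 = runif(1, 8, 80))
    reg <- dosing_regimen(1000, tau = 12, tinf = runif(1, 0.25, 2),
                          n_doses = 2L)
    cf <- conc_profile(ind, reg, times)
    od <- ode_profile(ind, reg, times)
    expect_lt(max(abs(cf - od) / pmax(od, 1e-6)), 1e-4)
  }
})

test_that("profiles are dose-proportional and vanish at zero dose", {
  ind <- list(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5)
  times <- seq(0, 24, by = 0.5)
  expect_identical(conc_profile(ind, dosing_regimen(0, n_doses = 2L), times),
                   numeric(length(times)))
  c1 <- conc_profile(ind, dosing_regimen(500, n_doses = 3L), times)
  c3 <- conc_profile(ind, dosing_regimen(1500, n_doses = 3L), times)
  expect_equal(c3, 3 * c1, tolerance = 1e-12)
})

test_that("steady-state closed form matches long superposition and is periodic", {
  ind <- list(cl = typical_clearance(120), v1 = 20.7, q = 31.9, v2 = 33.5)
  reg_ss <- dosing_regimen(1000, tau = 12, tinf = 0.5, steady_state = TRUE)
  reg_50 <- dosing_regimen(1000, tau = 12, tinf = 0.5, n_doses = 50L)
  tt <- c(0, 0.25, 0.5, 1, 3, 6, 12)
  ss <- conc_steady_state(ind, reg_ss, tt)
  sup <- conc_profile(ind, reg_50, 49 * 12 + tt)
  expect_lt(max(abs(ss - sup) / sup), 0.001)
  # periodicity: pre-dose equals end-of-interval trough
  expect_equal(conc_steady_state(ind, reg_ss, 0),
               conc_steady_state(ind, reg_ss, 12), tolerance = 1e-12)
  # washout: very long interval drives the trough to zero
  long <- dosing_regimen(1000, tau = 2000, tinf = 0.5, steady_state = TRUE)
  expect_lt(conc_steady_state(ind, long, 2000), 1e-6)
  expect_error(conc_steady_state(ind, reg_ss, 13), "within")
})

test_that("steady-state trough is monotone in clearance and dose", {
  reg <- dosing_regimen(1000, tau = 12, tinf = 0.5, steady_state = TRUE)
  cls <- seq(2, 12, by = 0.5)
  troughs <- vapply(cls, function(cl)
    conc_steady_state(list(cl = cl, v1 = 20.7, q = 31.9, v2 = 33.5), reg, 12), 0)
  expect_true(all(diff(troughs) < 0))
  ind <- list(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5)
  doses <- c(250, 500, 1000, 1500, 2000)
  td <- vapply(doses, function(dd)
    conc_steady_state(ind, dosing_regimen(dd, steady_state = TRUE), 12), 0)
  expect_true(all(diff(td) > 0))
})

test_that("terminal slope of a single-dose profile equals -beta on log scale", {
  ind <- list(cl = 4.5, v1 = 20.7, q = 31.9, v2 = 33.5)
  mc <- micro_constants(ind$cl, ind$v1, ind$q, ind$v2)
  tt <- seq(30, 60, by = 2)  # well past distribution
  cc <- conc_profile(ind, dosing_regimen(1000), tt)
  slope <- stats::coef(stats::lm(log(cc) ~ tt))[2]
  expect_equal(unname(slope), -mc$beta, tolerance = 1e-3)
})

test_that("covariate application honours functional forms and identities", {
  p <- pk_params()
  # empty model: identity
  ind <- apply_covariates(p, covariate_model(), list(crcl = 90))
  expect_equal(ind$cl, p$theta_nr)
  expect_equal(ind$v1, p$v1)
  # power on CL at the centring value contributes exactly 1
  cm <- covariate_model(list(cov_effect("cl", "crcl", "power", 120, theta = 2.5)))
  expect_equal(apply_covariates(p, cm, list(crcl = 120))$cl, p$theta_nr + 1)
  expect_equal(apply_covariates(p, cm, list(crcl = 80))$cl,
               typical_clearance(80, p))
  # dichotomous shift leaves the reference category unchanged
  sm <- covariate_model(list(cov_effect("v1", "diagnosis", "shift",
                                        theta = 0.4, level = "trauma")))
  expect_equal(apply_covariates(p, sm, list(diagnosis = "other"))$v1, p$v1)
  expect_equal(apply_covariates(p, sm, list(diagnosis = "trauma"))$v1, 1.4 * p$v1)
  expect_error(apply_covariates(p, cm, list(age = 50)), "crcl")
})
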