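make_random_dataset <- function(n_subj = 4L, seed = 1L) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    tt <- sort(runif(4, 0.6, 11.9))
    rbind(
      data.frame(subject_id = i, time_h = 0, evid = 1L,
                 amt_mg = sample(c(500, 1000, 1500), 1L), dur_h = 0.5,
                 dv_mg_L = NA_real_, bloq = FALSE, ss = 1L, tau_h = 12),
      data.frame(subject_id = i, time_h = tt, evid = 0L, amt_mg = NA_real_,
                 dur_h = NA_real_, dv_mg_L = round(runif(4, 2.5, 60), 4),
                 bloq = FALSE, ss = 0L, tau_h = NA_real_))
  }))
  subs <- data.frame(subject_id = seq_len(n_subj),
                     crcl_ml_min = round(runif(n_subj, 60, 230), 1),
                     age_y = sample(25:80, n_subj), sex = "male")
  pk_dataset(recs, subs)
}

test_that("datasets round-trip through write/read field-for-field", {
  for (seed in 1:5) {
    d <- make_random_dataset(seed = seed)
    path <- withr::local_tempfile(fileext = if (seed %% 2) ".csv" else ".tsv")
    write_dataset(d, path)
    d2 <- read_dataset(path)
    expect_equal(nrow(d2$records), nrow(d$records))
    for (col in c("subject_id", "time_h", "evid", "amt_mg", "dur_h",
                  "dv_mg_L", "bloq", "ss", "tau_h")) {
      expect_equal(d2$records[[col]], d$records[[col]], tolerance = 0,
                   label = col)
    }
    expect_equal(d2$subjects$crcl_ml_min, d$subjects$crcl_ml_min)
    expect_equal(d2$subjects$age_y, d$subjects$age_y)
  }
})

test_that("BLOQ policies are applied as stated and flags survive round-trip", {
  d <- tiny_dataset(times = c(2, 6), dv = c(1.5, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  half <- read_dataset(path, assay_config(lloq = 2, bloq_policy = "lloq_half"))
  obs <- half$records[half$records$evid == 0L, ]
  expect_equal(obs$dv_mg_L[obs$time_h == 2], 1.0)
  expect_true(obs$bloq[obs$time_h == 2])
  expect_false(obs$bloq[obs$time_h == 6])

  dropd <- read_dataset(path, assay_config(lloq = 2, bloq_policy = "drop"))
  expect_equal(n_observations(dropd), 1L)
  zero <- read_dataset(path, assay_config(lloq = 2, bloq_policy = "zero"))
  expect_equal(zero$records$dv_mg_L[zero$records$evid == 0L &
                                      zero$records$time_h == 2], 0)
  # flags persist on a second round-trip under a non-censoring policy
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(half, path2)
  again <- read_dataset(path2, assay_config(lloq = 2, bloq_policy = "lloq_half"))
  expect_equal(sum(again$records$bloq), 1L)
})

test_that("an empty file with a valid header loads as an empty dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("subject_id", "time_h", "evid", "amt_mg", "dur_h",
                     "dv_mg_L", "bloq", "crcl_ml_min"), collapse = ","), path)
  d <- read_dataset(path)
  expect_equal(nrow(d$subjects), 0L)
  expect_equal(n_observations(d), 0L)
})

test_that("schema and validation errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,time_h,evid,amt_mg", "1,0,1,500"), path)
  expect_error(read_dataset(path), "dur_h")

  recs <- data.frame(subject_id = 1L, time_h = -1, evid = 0L,
                     amt_mg = NA_real_, dur_h = NA_real_, dv_mg_L = 5,
                     bloq = FALSE)
  subs <- data.frame(subject_id = 1L, crcl_ml_min = 100)
  expect_error(pk_dataset(recs, subs), "row")
  # observation without any dose
  recs$time_h <- 1
  expect_error(pk_dataset(recs, subs), "no dose")
  # dose with non-positive amount
  recs2 <- data.frame(subject_id = 1L, time_h = 0, evid = 1L, amt_mg = 0,
                      dur_h = 0.5, dv_mg_L = NA_real_, bloq = FALSE)
  expect_error(pk_dataset(recs2, subs), "amount")
  # non-positive creatinine clearance
  expect_error(pk_dataset(recs2[0, ], data.frame(subject_id = 1L,
                                                 crcl_ml_min = 0)), "crcl")
})

test_that("model config defaults to the published final model", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  m <- load_model_config(path)
  expect_equal(m$params$theta_nr, 3.5)
  expect_equal(m$params$theta_r, 2.5)
  expect_equal(m$params$v1, 20.7)
  expect_equal(m$params$q, 31.9)
  expect_equal(m$params$v2, 33.5)
  expect_equal(m$omega$cl, 0.327)
  expect_equal(m$omega$v1, 0.561)
  expect_equal(m$residual$sigma_prop, 0.223)

  # overriding the exponent to 0 makes the covariate term constant (adds 1)
  writeLines("theta_r: 0", path)
  m0 <- load_model_config(path)
  tv <- sapply(c(60, 120, 240), typical_clearance, params = m0$params)
  expect_true(all(tv == m0$params$theta_nr + 1))

  # zero IIV makes simulation deterministic
  writeLines(c("iiv_cl_pct: 0", "iiv_v1_pct: 0", "residual:",
               "  sigma_prop_pct: 0"), path)
  mz <- load_model_config(path)
  d <- tiny_dataset()
  s1 <- simulate_study(d, mz, seed = 1)
  s2 <- simulate_study(d, mz, seed = 2)
  expect_equal(s1$records$dv_mg_L, s2$records$dv_mg_L)

  writeLines(c("covariates:", "  - param: cl", "    cov: crcl",
               "    form: sigmoid"), path)
  expect_error(load_model_config(path), "unknown covariate function")
  writeLines("v1: -3", path)
  expect_error(load_model_config(path), "positive")
})
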