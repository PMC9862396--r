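test_that("noise-free single-subject study equals the model prediction", {
  des <- study_design(50, 1, 24, FALSE, n_subjects = 1, residual_cv = 0,
                      lloq = 0.5, seed = 3, variability = c())
  st <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), oral_regimen(50),
                       t_end = 25,
                       options = solver_options(rtol = 1e-6, atol = 1e-9,
                                                dt = 0.25,
                                                extra_times = des$sampling_times))
  rec <- st$datasets$tegoprazan$records
  pred <- stats::approx(sim$conc$time_h, sim$conc$tegoprazan,
                        xout = rec$time_h)$y
  expect_equal(rec$conc_ng_mL, pred, tolerance = 1e-10)
  expect_identical(names(st$datasets), c("tegoprazan", "M1"))
})

test_that("generation is a pure function of the seed", {
  des <- study_design(100, 1, 24, FALSE, n_subjects = 4, residual_cv = 0.2,
                      seed = 77)
  a <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  b <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  expect_identical(a$datasets$tegoprazan$records,
                   b$datasets$tegoprazan$records)
  des2 <- des; des2$seed <- 78L
  c2 <- generate_study(tp_drug(), tp_m1(), des2, tp_ind())
  expect_false(identical(a$datasets$tegoprazan$records,
                         c2$datasets$tegoprazan$records))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_study(tp_drug(), tp_m1(), des, tp_ind()))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("residual error reproduces the design CV on the log scale", {
  # the residual model itself: log-normal multipliers with unit geometric
  # mean and the requested CV
  set.seed(13)
  mult <- tegopbpk:::lognormal_multiplier(20000, 0.2)
  expect_equal(stats::sd(mult) / mean(mult), 0.2, tolerance = 0.02)
  expect_equal(mean(log(mult)), 0, tolerance = 0.005)
  # and as applied per subject: a noisy single-subject study scatters
  # around the noise-free profile with that spread
  des <- study_design(50, 1, 24, FALSE, n_subjects = 1, residual_cv = 0.2,
                      sampling_times = c(0.5, 1, 2, 3, 4, 6, 8, 12),
                      lloq = 0.1, seed = 13, variability = c())
  des0 <- des; des0$residual_cv <- 0
  noisy <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  clean <- generate_study(tp_drug(), tp_m1(), des0, tp_ind())
  ratio <- noisy$datasets$tegoprazan$records$conc_ng_mL /
    clean$datasets$tegoprazan$records$conc_ng_mL
  expect_gt(stats::sd(log(ratio)), 0.05)
  expect_lt(stats::sd(log(ratio)), 0.5)
})

test_that("LLOQ censoring removes and counts low records", {
  des <- study_design(50, 1, 24, FALSE, n_subjects = 1, residual_cv = 0,
                      lloq = 50, seed = 5, variability = c())
  st <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  expect_true(all(st$datasets$tegoprazan$records$conc_ng_mL >= 50))
  expect_gt(st$censored[["tegoprazan"]], 0)
  # M1 concentrations are low: heavily censored at this LLOQ
  expect_gt(st$censored[["M1"]], 5)
  expect_identical(st$censored[["tegoprazan"]] +
                     nrow(st$datasets$tegoprazan$records),
                   length(des$sampling_times))
})

test_that("the emulated corpus has the documented layout", {
  suite <- emulate_training_suite(tp_drug(), tp_m1(), seed = 20230104,
                                  n_subjects = 2)
  expect_length(suite, 19)
  roles <- vapply(suite, attr, character(1), "role")
  expect_identical(sum(roles == "training"), 10L)
  expect_identical(sum(roles == "test"), 9L)
  doses <- vapply(suite, function(s) s$truth$design$dose_mg, numeric(1))
  expect_setequal(unique(doses), c(50, 100, 200, 400))
  fed <- vapply(suite, function(s) s$truth$design$fed, logical(1))
  expect_true(any(fed) && any(!fed))
  multi <- vapply(suite, function(s) s$truth$design$n_doses > 1, logical(1))
  expect_true(any(multi) && any(!multi))
  # every study carries both analytes
  expect_true(all(vapply(suite, function(s)
    length(s$datasets) == 2, logical(1))))
  # exactly one DDI-layout arm, with its metabolite excluded from fitting
  ddi <- vapply(suite, function(s) isTRUE(s$ddi_layout), logical(1))
  expect_identical(sum(ddi), 1L)
  expect_true(attr(suite[[which(ddi)]]$datasets$M1, "excluded_from_fit"))
  expect_identical(attr(suite[[which(ddi)]], "role"), "training")
})

test_that("observed datasets round-trip losslessly through delimited text", {
  des <- study_design(100, 3, 12, TRUE, n_subjects = 3, residual_cv = 0.15,
                      seed = 21)
  st <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  ds <- st$datasets$tegoprazan
  path <- withr::local_tempfile(fileext = ".tsv")
  write_observed_dataset(ds, path)
  back <- read_observed_dataset(path)
  expect_identical(back$records$time_h, ds$records$time_h)
  expect_identical(back$records$conc_ng_mL, ds$records$conc_ng_mL)
  expect_identical(back$study_id, ds$study_id)
  expect_identical(back$analyte, ds$analyte)
  expect_identical(attr(back, "design")$dose_mg,
                   attr(ds, "design")$dose_mg)
  expect_identical(attr(back, "design")$fed, attr(ds, "design")$fed)
  expect_identical(attr(back, "excluded_from_fit"), FALSE)
})
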