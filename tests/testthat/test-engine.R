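test_that("rate helpers convert units correctly and are linear", {
  r <- metabolic_clearance_rate(100, 0.236, 1)
  expect_equal(attr(r, "clearance_L_per_h"), 1.416e-3)
  expect_equal(as.numeric(metabolic_clearance_rate(5, 0.3, 0)), 0)
  expect_equal(as.numeric(metabolic_clearance_rate(200, 0.236, 1)),
               2 * as.numeric(r))
  expect_error(metabolic_clearance_rate(-1, 0.2, 1), ">= 0")

  rr <- renal_elimination_rate(0.297, 73.5, 1)
  expect_equal(attr(rr, "clearance_L_per_h"), 1.31, tolerance = 1e-3)
  expect_equal(attr(renal_elimination_rate(0.297, 50, 1),
                    "clearance_L_per_h"), 0.891)
  expect_equal(as.numeric(renal_elimination_rate(0.297, 50, 0)), 0)

  hh <- m1_hepatic_elimination_rate(0.140, 50, 2)
  expect_equal(attr(hh, "clearance_L_per_h"), 0.42)
  expect_equal(as.numeric(m1_hepatic_elimination_rate(0.140, 50, 1)),
               as.numeric(hh) / 2)
})

test_that("zero dose gives identically zero concentrations", {
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(),
                       regimen(dose_event(0, 0)), t_end = 12,
                       options = fast_opts())
  expect_true(all(sim$conc$tegoprazan == 0))
  expect_true(all(sim$conc$M1 == 0))
})

test_that("degenerate one-compartment IV bolus matches the closed form", {
  cfg <- one_compartment_setup(V = 40, cl_mL_min_kg = 2, weight = 70)
  dose_mg <- 10
  sim <- simulate_pbpk(cfg$drug, NULL, cfg$individual,
                       regimen(dose_event(0, dose_mg, route = "iv")),
                       t_end = 24, options = cfg$options)
  t <- sim$conc$time_h
  pred <- sim$conc$probe
  expected <- dose_mg * 1e6 / (cfg$V * 1000) * exp(-cfg$CL * t / cfg$V)
  sel <- t > 0.05   # clear of the bolus event itself
  expect_lt(max(abs(pred[sel] - expected[sel]) / expected[sel]), 0.001)
})

test_that("parent mass is conserved to within 0.1% of dose at all times", {
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), oral_regimen(50),
                       t_end = 96, options = fast_opts())
  total <- parent_mass_total(sim$states)
  sel <- sim$time > 0        # t = 0 is reported before the dose event
  expect_lt(max(abs(total[sel] - sim$dose_umol)) / sim$dose_umol, 0.001)
  # metabolite subtree balances against its formation
  formed <- sim$states[, "cum_liv_cyp3a4_m1"] +
    sim$states[, "cum_liv_cyp2c19_m1"] + sim$states[, "cum_gut_cyp3a4_m1"]
  m_total <- rowSums(sim$states[, grep("^M_", colnames(sim$states))]) +
    sim$states[, "cum_m1_hepatic"]
  expect_lt(max(abs(m_total[sel] - formed[sel])) / sim$dose_umol, 0.001)
})

test_that("AUC and Cmax are dose-linear from 50 to 400 mg", {
  ind <- tp_ind()
  ref <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(50),
                       t_end = 96, options = fast_opts())
  for (dose in c(100, 400)) {
    sim <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(dose),
                         t_end = 96, options = fast_opts())
    scale <- dose / 50
    for (an in c("tegoprazan", "M1")) {
      expect_equal(auc_of(sim, an), scale * auc_of(ref, an),
                   tolerance = 0.005)
      expect_equal(max(sim$conc[[an]]), scale * max(ref$conc[[an]]),
                   tolerance = 0.005)
    }
  }
})

test_that("multiple-dose profile superposes shifted single doses", {
  ind <- tp_ind()
  single <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(50),
                          t_end = 96, options = fast_opts())
  multi <- simulate_pbpk(tp_drug(), tp_m1(), ind,
                         oral_regimen(50, n_doses = 3, interval_h = 24),
                         t_end = 96, options = fast_opts())
  t <- multi$conc$time_h
  f <- stats::approxfun(single$conc$time_h, single$conc$tegoprazan,
                        yleft = 0, rule = 2)
  super <- f(t) + f(t - 24) + f(t - 48)
  cmax <- max(multi$conc$tegoprazan)
  expect_lt(max(abs(multi$conc$tegoprazan - super)) / cmax, 0.005)
})

test_that("steady-state interval AUC equals single-dose AUC to infinity", {
  ind <- tp_ind()
  single <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(50),
                          t_end = 168, options = fast_opts())
  auc_inf <- auc_of(single, "tegoprazan")
  multi <- simulate_pbpk(tp_drug(), tp_m1(), ind,
                         oral_regimen(50, n_doses = 7, interval_h = 24),
                         t_end = 7 * 24, options = fast_opts())
  prof <- data.frame(time_h = multi$conc$time_h,
                     conc = multi$conc$tegoprazan)
  auc_ss <- tegopbpk:::interval_auc(prof, 144, 168)
  expect_equal(auc_ss, auc_inf, tolerance = 0.01)
})

test_that("within-enzyme product splits equal the intrinsic clearance ratios", {
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), oral_regimen(50),
                       t_end = 168, options = fast_opts())
  mb <- mass_balance(sim, warn_incomplete = FALSE)
  drug <- tp_drug()
  r3 <- get_drug_parameter(drug, "clint/CYP3A4/M1") /
    get_drug_parameter(drug, "clint/CYP3A4/other")
  r2 <- get_drug_parameter(drug, "clint/CYP2C19/M1") /
    get_drug_parameter(drug, "clint/CYP2C19/other")
  expect_equal(mb$cyp3a4_m1 / mb$cyp3a4_other, r3, tolerance = 1e-6)
  expect_equal(mb$cyp2c19_m1 / mb$cyp2c19_other, r2, tolerance = 1e-6)
  # the split holds at the gut site too
  expect_equal(sim$states[nrow(sim$states), "cum_gut_cyp3a4_m1"] /
                 sim$states[nrow(sim$states), "cum_gut_cyp3a4_other"],
               r3, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("compiled and reference right-hand sides agree", {
  ind <- tp_ind()
  reg <- oral_regimen(50, n_doses = 2, interval_h = 12, fed = TRUE)
  simc <- simulate_pbpk(tp_drug(), tp_m1(), ind, reg, t_end = 36,
                        options = fast_opts(use_compiled = TRUE))
  simr <- simulate_pbpk(tp_drug(), tp_m1(), ind, reg, t_end = 36,
                        options = fast_opts(use_compiled = FALSE))
  expect_true(simc$meta$compiled)
  expect_false(simr$meta$compiled)
  for (an in c("tegoprazan", "M1"))
    expect_lt(max(abs(simc$conc[[an]] - simr$conc[[an]])) /
                max(simc$conc[[an]]), 1e-6)
  # and with a perpetrator on board
  clari <- load_perpetrator_config(system.file("extdata",
                                               "clarithromycin.yaml",
                                               package = "tegopbpk"))
  pr <- oral_regimen(500, 4, 8)
  sc <- simulate_pbpk(tp_drug(), tp_m1(), ind, reg, t_end = 36,
                      perpetrator = clari, perpetrator_regimen = pr,
                      options = fast_opts(use_compiled = TRUE))
  sr <- simulate_pbpk(tp_drug(), tp_m1(), ind, reg, t_end = 36,
                      perpetrator = clari, perpetrator_regimen = pr,
                      options = fast_opts(use_compiled = FALSE))
  expect_lt(max(abs(sc$conc$tegoprazan - sr$conc$tegoprazan)) /
              max(sc$conc$tegoprazan), 1e-6)
})

test_that("simulation rejects inconsistent horizons and reports provenance", {
  expect_error(simulate_pbpk(tp_drug(), tp_m1(), tp_ind(),
                             oral_regimen(50, 3, 24), t_end = 24),
               "t_end")
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), oral_regimen(50),
                       t_end = 12, options = fast_opts())
  expect_identical(sim$meta$kp_method, "poulin-theil")
  expect_true(all(diff(sim$conc$time_h) > 0))
  expect_true(all(sim$conc$tegoprazan >= 0))
})
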