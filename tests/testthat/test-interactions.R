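clari <- function() load_perpetrator_config(
  system.file("extdata", "clarithromycin.yaml", package = "tegopbpk"))
rifam <- function() load_perpetrator_config(
  system.file("extdata", "rifampicin.yaml", package = "tegopbpk"))

test_that("turnover right-hand side reproduces the limiting identities", {
  rsyn <- enzyme_baseline(4, 0.02)
  # baseline is a steady state with or without a silent perpetrator
  expect_equal(turnover_rhs(4, rsyn, 0.02, 0, NULL), 0)
  expect_equal(turnover_rhs(4, rsyn, 0.02, 0, clari()), 0)
  expect_equal(turnover_rhs(4, rsyn, 0.02, 0, rifam()), 0)
  # induction at I = EC50: synthesis scaled by 1 + Emax/2
  rf <- rifam()
  d <- turnover_rhs(4, rsyn, 0.02, rf$EC50, rf)
  expect_equal(d, rsyn * (1 + rf$Emax / 2) - 0.02 * 4)
  # MBI at I = KI: added loss (kinact/2) * E
  cl <- clari()
  d2 <- turnover_rhs(4, rsyn, 0.02, cl$KI, cl)
  expect_equal(d2, rsyn - (0.02 + cl$kinact / 2) * 4)
  expect_error(turnover_rhs(-1, rsyn, 0.02), ">= 0")
  expect_error(perpetrator_spec("x", "mbi", KI = -1, kinact = 1,
                                own_kinetics = list()), "KI")
})

test_that("induction asymptote and inactivation floor bound enzyme levels", {
  rsyn <- enzyme_baseline(4, 0.02)
  rf <- rifam()
  run <- function(I, spec) {
    deSolve::ode(c(E = 4), seq(0, 600, 5),
                 function(t, y, p) list(turnover_rhs(y, rsyn, 0.02, I, spec)),
                 parms = NULL)[, "E"]
  }
  e_ind <- run(1e6, rf)
  expect_equal(e_ind[length(e_ind)], 4 * (1 + rf$Emax), tolerance = 1e-3)
  cl <- clari()
  e_mbi <- run(1e6, cl)
  expect_true(all(e_mbi >= 0))
  expect_lt(e_mbi[length(e_mbi)], 4 * 0.01 + 1e-6)
})

test_that("fold change uses the arm-ratio conventions of a DDI table", {
  expect_equal(fold_change(2994.4, 11312.0, "increase"), 3.78,
               tolerance = 1e-3)
  expect_equal(fold_change(2994.4, 568.8, "decrease"), 5.26,
               tolerance = 1e-3)
  expect_equal(fold_change(7, 7, "increase"), 1)
  expect_error(fold_change(0, 1, "increase"), "positive")
})

test_that("a null perpetrator leaves every fold change at 1", {
  null_mbi <- perpetrator_spec("null-inhibitor", "mbi", KI = 5, kinact = 0,
                               own_kinetics = clari()$own_kinetics)
  sc <- ddi_scenario(oral_regimen(50, 3, 24), null_mbi,
                     oral_regimen(500, 9, 8), pretreatment_h = 24)
  res <- simulate_ddi(sc, tp_drug(), tp_m1(), tp_ind(),
                      options = fast_opts())
  expect_true(all(abs(res$table$fold - 1) < 0.005))
  null_ind <- perpetrator_spec("null-inducer", "induction", Emax = 0,
                               EC50 = 0.3, own_kinetics = rifam()$own_kinetics)
  sc2 <- ddi_scenario(oral_regimen(50, 3, 24), null_ind,
                      oral_regimen(600, 2, 24), pretreatment_h = 24)
  res2 <- simulate_ddi(sc2, tp_drug(), tp_m1(), tp_ind(),
                       options = fast_opts())
  expect_true(all(abs(res2$table$fold - 1) < 0.005))
})

test_that("hepatic CYP3A4 knockout matches the closed-form fm identity", {
  ind <- tp_ind_nogut()
  base <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(50),
                        t_end = 200, options = fast_opts())
  mb <- mass_balance(base, warn_incomplete = FALSE)
  # fm as fraction of total eliminated drug
  eliminated <- mb$hepatic_total + mb$renal
  fm_hep3a4 <- mb$hepatic_cyp3a4 / eliminated
  ko <- ind
  ko$enzymes$reference_concentration[ko$enzymes$enzyme == "CYP3A4"] <- 0
  kos <- simulate_pbpk(tp_drug(), tp_m1(), ko, oral_regimen(50),
                       t_end = 400, options = fast_opts())
  aucr_engine <- auc_of(kos, "tegoprazan") / auc_of(base, "tegoprazan")
  aucr_formula <- 1 / (1 - fm_hep3a4)
  expect_equal(aucr_engine, aucr_formula, tolerance = 0.02)
  expect_gt(aucr_engine, 2.5)   # a strong, CYP3A4-dominated interaction
})

test_that("DDI magnitude is monotone in kinact and in Emax", {
  victim <- oral_regimen(50, 3, 24)
  auc_ratio <- function(perp, preg) {
    sc <- ddi_scenario(victim, perp, preg, pretreatment_h = 48,
                       washout_h = 0)
    res <- simulate_ddi(sc, tp_drug(), tp_m1(), tp_ind(),
                        options = fast_opts())
    res$table$combined[res$table$parameter == "AUC_SS"] /
      res$table$alone[res$table$parameter == "AUC_SS"]
  }
  base_cl <- clari()
  ratios_mbi <- vapply(c(0.2, 1, 2.52), function(k) {
    p <- base_cl; p$kinact <- k
    auc_ratio(p, oral_regimen(500, 15, 8))
  }, numeric(1))
  expect_true(all(diff(ratios_mbi) > 0))
  expect_true(all(ratios_mbi > 1))
  base_rf <- rifam()
  ratios_ind <- vapply(c(1, 4, 9), function(em) {
    p <- base_rf; p$Emax <- em
    auc_ratio(p, oral_regimen(600, 5, 24))
  }, numeric(1))
  expect_true(all(diff(ratios_ind) < 0))
  expect_true(all(ratios_ind < 1))
})

test_that("enzymes return to baseline after perpetrator washout", {
  ind <- tp_ind()
  # short clarithromycin course, then a washout >= 10 / kdeg (kdeg 0.019/h)
  sim <- simulate_pbpk(tp_drug(), tp_m1(), ind, oral_regimen(50), t_end = 700,
                       perpetrator = clari(),
                       perpetrator_regimen = oral_regimen(500, 6, 8),
                       options = fast_opts(dt = 0.5))
  e <- sim$states[, "E_liv_cyp3a4"]
  eref <- e[1]
  expect_lt(min(e) / eref, 0.6)                   # inactivation did bite
  expect_equal(e[length(e)], eref, tolerance = 0.01)  # and washed out
  eg <- sim$states[, "E_gut_cyp3a4"]
  expect_equal(eg[length(eg)], eg[1], tolerance = 0.01)
})

test_that("the alone arm is identical inside and outside the DDI driver", {
  sc <- ddi_scenario(oral_regimen(50, 2, 24), clari(),
                     oral_regimen(500, 9, 8), pretreatment_h = 24,
                     washout_h = 0)
  res <- simulate_ddi(sc, tp_drug(), tp_m1(), tp_ind(),
                      options = fast_opts())
  res2 <- simulate_ddi(sc, tp_drug(), tp_m1(), tp_ind(),
                       options = fast_opts())
  expect_identical(res$alone, res2$alone)
  # standalone simulation of the shifted victim regimen reproduces it
  vshift <- tegopbpk:::shift_events(oral_regimen(50, 2, 24), 24)
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), regimen(vshift),
                       t_end = 24 + 24 + 24, options = fast_opts())
  prof <- data.frame(time_h = sim$conc$time_h, conc = sim$conc$tegoprazan)
  expect_identical(unname(res$alone[1, "AUC_first"]),
                   tegopbpk:::interval_auc(prof, 24, 48))
})

test_that("perpetrator forcing tables drive the interaction", {
  # constant unbound exposure at KI: enzyme settles at kdeg/(kdeg+kinact/2)
  cl <- clari()
  forcing <- data.frame(time_h = c(0, 1000), conc_umol_L = cl$KI)
  pf <- perpetrator_spec("forced", "mbi", KI = cl$KI, kinact = cl$kinact,
                         own_kinetics = forcing)
  sim <- simulate_pbpk(tp_drug(), tp_m1(), tp_ind(), oral_regimen(50),
                       t_end = 500, perpetrator = pf,
                       options = fast_opts(dt = 0.5))
  expect_false(sim$meta$compiled)   # forcing runs on the reference RHS
  e <- sim$states[, "E_liv_cyp3a4"]
  kdeg <- 0.019
  expect_equal(e[length(e)] / e[1], kdeg / (kdeg + cl$kinact / 2),
               tolerance = 0.01)
})
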