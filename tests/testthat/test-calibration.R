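test_that("parameter paths address every tunable entry both ways", {
  drug <- tp_drug()
  expect_equal(get_drug_parameter(drug, "clint/CYP2C19/other"), 0.242)
  d2 <- set_drug_parameter(drug, "clint/CYP2C19/other", 0.3)
  expect_equal(get_drug_parameter(d2, "clint/CYP2C19/other"), 0.3)
  expect_equal(get_drug_parameter(drug, "dissolution/fed/t50"), 4.23)
  d3 <- set_drug_parameter(drug, "dissolution/fasted/shape", 1.2)
  expect_equal(d3$dissolution$fasted$shape, 1.2)
  expect_equal(get_drug_parameter(drug, "fu_plasma"), 0.087)
  expect_error(get_drug_parameter(drug, "clint/CYP1A2/M1"), "no reaction")
  expect_error(get_drug_parameter(drug, "frobnicate"), "unknown parameter")
})

test_that("pathway apportionment by clint ratios matches the fm split", {
  ap <- apportion_pathways(tp_drug(), c(CYP3A4 = 71.6, CYP2C19 = 20.2))
  pick <- function(e, p)
    ap$fraction_percent[ap$enzyme == e & ap$product == p]
  expect_equal(pick("CYP3A4", "M1"), 2.71, tolerance = 0.005)
  expect_equal(pick("CYP3A4", "other"), 68.9, tolerance = 0.0005)
  expect_equal(pick("CYP2C19", "M1"), 5.57, tolerance = 0.0005)
  expect_equal(pick("CYP2C19", "other"), 14.6, tolerance = 0.005)
  expect_equal(attr(ap, "to_m1"), 8.3, tolerance = 0.005)
  expect_equal(attr(ap, "to_other"), 83.5, tolerance = 0.001)
  expect_equal(attr(ap, "hepatic_total"), 91.8, tolerance = 1e-12)
})

test_that("analytic abundance ratio matches its defining identity", {
  expect_equal(enzyme_abundance_ratio(71.6, 20.2, 0.2453, 0.3341), 4.828,
               tolerance = 1e-3)
  expect_equal(enzyme_abundance_ratio(30, 30, 0.5, 0.5), 1)
  expect_error(enzyme_abundance_ratio(10, 0, 1, 1), "positive")
})

test_that("abundance calibration reproduces its own fm targets", {
  ind <- tp_ind_nogut()   # liver-only: the analytic ratio applies exactly
  # start well away from the solution
  ind$enzymes$reference_concentration[ind$enzymes$organ == "liver"] <- 1
  cal <- calibrate_enzyme_abundance(tp_drug(), tp_m1(), ind,
                                    fm_targets = c(CYP3A4 = 71.6,
                                                   CYP2C19 = 20.2),
                                    renal_share = 7.82,
                                    options = fast_opts())
  ach <- attr(cal, "fm_achieved")    # shares of total elimination
  tgt <- 100 * c(71.6, 20.2, 7.82) / (71.6 + 20.2 + 7.82)
  expect_lt(max(abs(ach - tgt)), 0.2)
  e <- cal$enzymes
  ratio <- e$reference_concentration[e$enzyme == "CYP3A4" & e$organ == "liver"] /
    e$reference_concentration[e$enzyme == "CYP2C19"]
  expect_equal(ratio, enzyme_abundance_ratio(71.6, 20.2,
                                             9.29e-3 + 0.236,
                                             0.0921 + 0.242),
               tolerance = 0.01)
  expect_error(calibrate_enzyme_abundance(tp_drug(), tp_m1(), tp_ind(),
                                          fm_targets = c(CYP3A4 = 60,
                                                         CYP2C19 = 45)),
               "sum")
})

test_that("sensitivity coefficients isolate the causal pathways", {
  params <- c("fu_plasma", "clint/CYP3A4/other", "clint/CYP2C19/other",
              "renal_plasma_clearance", "clint/CYP3A4/M1",
              "metabolite:hepatic_plasma_clearance")
  sens <- local_sensitivity(tp_drug(), tp_m1(), params,
                            perturbation = 0.1, output = "parent",
                            t_end = 96, options = fast_opts())
  co <- stats::setNames(sens$coefficient, sens$parameter)
  # no pathway from M1 elimination back to the parent
  expect_lt(abs(co[["metabolite:hepatic_plasma_clearance"]]), 1e-6)
  # elimination parameters reduce exposure, ranked by their fm share
  expect_lt(co[["clint/CYP3A4/other"]], co[["clint/CYP2C19/other"]])
  expect_lt(co[["clint/CYP2C19/other"]], co[["renal_plasma_clearance"]])
  expect_true(all(co[c("clint/CYP3A4/other", "clint/CYP2C19/other",
                       "renal_plasma_clearance", "fu_plasma")] < 0))
  # the dominant drivers of parent exposure, in rank order
  expect_identical(sens$parameter[1:2],
                   c("fu_plasma", "clint/CYP3A4/other"))
  # M1 exposure is driven by its own hepatic clearance
  # M1 is cleared slowly, so its AUC needs a long horizon to be AUC_inf
  sens_m1 <- local_sensitivity(tp_drug(), tp_m1(),
                               c("metabolite:hepatic_plasma_clearance",
                                 "clint/CYP3A4/other"),
                               output = "metabolite", t_end = 480,
                               options = fast_opts(dt = 0.5))
  com <- stats::setNames(sens_m1$coefficient, sens_m1$parameter)
  expect_lt(com[["metabolite:hepatic_plasma_clearance"]], -0.5)
})

test_that("one-compartment AUC sensitivity to clearance is -1", {
  cfg <- one_compartment_setup(V = 30, cl_mL_min_kg = 2, weight = 70)
  auc_at <- function(cl) {
    d <- set_drug_parameter(cfg$drug, "renal_plasma_clearance", cl)
    sim <- simulate_pbpk(d, NULL, cfg$individual,
                         regimen(dose_event(0, 10, route = "iv")),
                         t_end = 300, options = cfg$options)
    conc <- sim$conc$probe
    conc[1] <- 10e6 / (cfg$V * 1000)   # back-extrapolated bolus C0
    tegopbpk:::auc_linlog(sim$conc$time_h, conc)
  }
  # small central difference: the curvature of AUC ~ 1/CL biases larger steps
  base <- auc_at(2); up <- auc_at(2 * 1.02); dn <- auc_at(2 * 0.98)
  coef <- (up - dn) / base / (2 * 0.02)
  expect_equal(coef, -1, tolerance = 0.005)
})

test_that("sensitivity converges as the perturbation shrinks", {
  p <- c("clint/CYP3A4/other", "fu_plasma")
  s10 <- local_sensitivity(tp_drug(), tp_m1(), p, perturbation = 0.10,
                           t_end = 96, options = fast_opts())
  s05 <- local_sensitivity(tp_drug(), tp_m1(), p, perturbation = 0.05,
                           t_end = 96, options = fast_opts())
  m10 <- stats::setNames(s10$coefficient, s10$parameter)
  m05 <- stats::setNames(s05$coefficient, s05$parameter)
  for (q in p)
    expect_lt(abs(m10[[q]] - m05[[q]]) / abs(m05[[q]]), 0.10)
  expect_error(local_sensitivity(tp_drug(), tp_m1(), p, perturbation = 0.8),
               "perturbation")
})

test_that("fitting is deterministic and self-consistent on noise-free data", {
  des <- study_design(50, 1, 24, FALSE, n_subjects = 1, residual_cv = 0,
                      lloq = 0.5, seed = 11, variability = c())
  st <- generate_study(tp_drug(), tp_m1(), des, tp_ind())
  paths <- c(clint_paths, "dissolution/fasted/t50")
  truth <- vapply(paths, function(p) get_drug_parameter(tp_drug(), p),
                  numeric(1))
  sp <- fit_spec(paths, lower = 1e-5, upper = 10, max_iter = 40)
  fr1 <- fit(tp_drug(), tp_m1(), st$datasets, sp, tp_ind())
  fr2 <- fit(tp_drug(), tp_m1(), st$datasets, sp, tp_ind())
  expect_identical(fr1$estimates, fr2$estimates)
  expect_true(fr1$converged)
  expect_true(all(abs(fr1$estimates / truth - 1) < 0.01))
  # datasets flagged excluded_from_fit are dropped
  flagged <- st$datasets
  attr(flagged[[1]], "excluded_from_fit") <- TRUE
  attr(flagged[[2]], "excluded_from_fit") <- TRUE
  expect_error(fit(tp_drug(), tp_m1(), flagged, sp, tp_ind()),
               "no datasets")
})
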