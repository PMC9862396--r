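# Shared fixtures: bundled compounds, reference physiology, and a
# degenerate one-compartment configuration used for closed-form checks.

tp_drug <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- load_drug_config(system.file("extdata", "tegoprazan.yaml",
                                           package = "tegopbpk"))
    val
  }
})

tp_m1 <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- load_drug_config(system.file("extdata", "m1.yaml",
                                           package = "tegopbpk"))
    val
  }
})

tp_ind <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_reference_individual()
    val
  }
})

# Reference individual with the gut-wall enzyme site switched off
# (matches the assumptions of the hepatic-knockout closed form).
tp_ind_nogut <- function() {
  ind <- tp_ind()
  ind$enzymes$reference_concentration[ind$enzymes$organ == "gut"] <- 0
  ind
}

fast_opts <- function(...) solver_options(rtol = 1e-8, atol = 1e-10, ...)

# Degenerate one-compartment configuration: all organ volumes collapsed
# onto the venous pool, Kp forced to 1, renal clearance only.  Flows are
# inflated so arterial and venous plasma are effectively one mixed pool
# and the closed form C(t) = (D/V) exp(-CL t / V) applies.
one_compartment_setup <- function(V = 40, cl_mL_min_kg = 2, weight = 70) {
  tab <- tegopbpk:::read_physiology_table()
  shrink <- !tab$organ %in% c("venous")
  tab$volume_L[shrink] <- 1e-4
  tab$volume_L[tab$organ == "venous"] <- V * 73.5 / weight  # undo scaling
  tab$flow_L_per_h <- tab$flow_L_per_h * 1000
  ind <- build_reference_individual(weight = weight, physiology = tab)
  ind$enzymes$reference_concentration[] <- 0
  drug <- drug_parameters("probe", molecular_weight = 100, logP = 0,
                          fu_plasma = 1,
                          renal_plasma_clearance_mL_min_kg = cl_mL_min_kg)
  kp1 <- stats::setNames(rep(1, 14), tegopbpk:::ORGAN_ORDER)
  list(drug = drug, individual = ind,
       options = fast_opts(kp_overrides = kp1),
       V = V, CL = cl_mL_min_kg * weight * 60 / 1000)
}

# Parent-side mass total: dose = lumen + fecal + parent organs +
# parent-leaving cumulatives (the ->M1 cumulatives track material that
# lives on in the metabolite states).
parent_mass_total <- function(states) {
  lum <- rowSums(states[, grep("^(und|dis)_", colnames(states)), drop = FALSE])
  porg <- rowSums(states[, grep("^P_", colnames(states)), drop = FALSE])
  lum + porg + states[, "fecal"] + states[, "cum_renal"] +
    states[, "cum_liv_cyp3a4_m1"] + states[, "cum_liv_cyp3a4_other"] +
    states[, "cum_liv_cyp2c19_m1"] + states[, "cum_liv_cyp2c19_other"] +
    states[, "cum_gut_cyp3a4_m1"] + states[, "cum_gut_cyp3a4_other"]
}

auc_of <- function(sim, analyte) {
  tegopbpk:::auc_linlog(sim$conc$time_h, sim$conc[[analyte]])
}

clint_paths <- c("clint/CYP3A4/M1", "clint/CYP3A4/other",
                 "clint/CYP2C19/M1", "clint/CYP2C19/other")
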