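# Parameter-vector and state-vector layout shared by the compiled and the
# reference R right-hand sides.  Positions are 1-based here and mirrored
# 0-based in src/pbpk_rhs.c -- any change must be made in both places.

# scalar slots
P_MW_P <- 1L;  P_MW_M <- 2L;  P_FU_P <- 3L;  P_FU_M <- 4L
P_CL_REN <- 5L; P_CL_M1HEP <- 6L
P_K3A4_M1 <- 7L; P_K3A4_OTH <- 8L; P_K2C19_M1 <- 9L; P_K2C19_OTH <- 10L
P_EREF_L3A4 <- 11L; P_EREF_L2C19 <- 12L; P_EREF_G3A4 <- 13L
P_KDEG_L3A4 <- 14L; P_KDEG_L2C19 <- 15L; P_KDEG_G3A4 <- 16L
P_T50_FAST <- 17L; P_B_FAST <- 18L; P_T50_FED <- 19L; P_B_FED <- 20L
P_HAZ_CAP <- 21L; P_EMPTY_MULT <- 22L; P_EMPTY_DECAY <- 23L
P_PERP_MODE <- 24L; P_PERP_KA <- 25L; P_PERP_V <- 26L; P_PERP_CL <- 27L
P_PERP_FU <- 28L; P_PERP_MECH <- 29L; P_PERP_KI <- 30L; P_PERP_KINACT <- 31L
P_PERP_EMAX <- 32L; P_PERP_EC50 <- 33L
P_N_DOSE <- 34L; P_N_MEAL <- 35L
# array slots
P_V <- 36L      # 14 organ volumes (L)
P_Q <- 50L      # 14 organ flows (L/h); lung slot = cardiac output
P_KPP <- 64L    # 14 parent Kp
P_KPM <- 78L    # 14 metabolite Kp
P_VLUM <- 92L   # 6 lumen volumes (stomach, 4 x SI, colon)
P_KTRANS <- 98L # 6 transit rates (stomach first)
P_KABS <- 104L  # 6 absorption rate constants (1/h)
P_DOSE_T <- 110L   # up to 64 oral dose times
P_DOSE_FED <- 174L # fed flag per dose
P_MEAL_T <- 238L   # up to 64 meal times
N_PARMS <- 301L
MAX_EVENTS <- 64L
N_SEG <- 6L

# organ positions within the 14-slot blocks (ORGAN_ORDER)
O_ADIPOSE <- 1L; O_BONE <- 2L; O_BRAIN <- 3L; O_HEART <- 4L; O_KIDNEY <- 5L
O_MUSCLE <- 6L; O_SKIN <- 7L; O_REST <- 8L; O_GUT <- 9L; O_SPLEEN <- 10L
O_LIVER <- 11L; O_LUNG <- 12L; O_ART <- 13L; O_VEN <- 14L

# state positions
S_UND <- 1L     # 6 undissolved lumen pools
S_DIS <- 7L     # 6 dissolved lumen pools
S_FECAL <- 13L
S_P <- 14L      # 14 parent organ amounts (umol)
S_M <- 28L      # 14 metabolite organ amounts (umol)
S_EL3A4 <- 42L; S_EL2C19 <- 43L; S_EG3A4 <- 44L
S_CREN <- 45L; S_CM1HEP <- 46L
S_CL3A4M1 <- 47L; S_CL3A4OTH <- 48L; S_CL2C19M1 <- 49L; S_CL2C19OTH <- 50L
S_CG3A4M1 <- 51L; S_CG3A4OTH <- 52L
S_PDEPOT <- 53L; S_PCENT <- 54L
N_STATES <- 54L

state_names <- function() {
  segs <- c("stomach", "si1", "si2", "si3", "si4", "colon")
  c(paste0("und_", segs), paste0("dis_", segs), "fecal",
    paste0("P_", ORGAN_ORDER), paste0("M_", ORGAN_ORDER),
    "E_liv_cyp3a4", "E_liv_cyp2c19", "E_gut_cyp3a4",
    "cum_renal", "cum_m1_hepatic",
    "cum_liv_cyp3a4_m1", "cum_liv_cyp3a4_other",
    "cum_liv_cyp2c19_m1", "cum_liv_cyp2c19_other",
    "cum_gut_cyp3a4_m1", "cum_gut_cyp3a4_other",
    "perp_depot", "perp_central")
}

mg_to_umol <- function(mg, mw) mg * 1000 / mw
umol_L_to_ng_mL <- function(conc, mw) conc * mw

# Assemble the numeric parameter vector, initial state, solver event table
# and output times for one simulation.
build_engine_inputs <- function(drug, metabolite, individual, events,
                                t_end, perpetrator = NULL,
                                perpetrator_events = NULL,
                                options = solver_options()) {
  validate_drug_parameters(drug)
  validate_individual(individual)
  if (!is.null(metabolite)) validate_drug_parameters(metabolite)
  ev <- as.data.frame(events)
  doses <- ev[ev$type == "dose" & ev$amount_mg > 0, , drop = FALSE]
  meals <- ev[ev$type == "meal", , drop = FALSE]
  oral <- doses[doses$route == "oral", , drop = FALSE]
  iv <- doses[doses$route == "iv", , drop = FALSE]
  if (nrow(oral) > MAX_EVENTS || nrow(meals) > MAX_EVENTS)
    stop("regimen exceeds the supported number of events (", MAX_EVENTS, ")")

  pp <- numeric(N_PARMS)
  mults <- individual$multipliers
  w <- individual$weight
  pp[P_MW_P] <- drug$molecular_weight
  pp[P_FU_P] <- min(1, drug$fu_plasma * mults[["fu_plasma"]])
  pp[P_CL_REN] <- drug$renal_plasma_clearance_mL_min_kg * w * 60 / 1000
  pp[P_K3A4_M1]   <- reaction_clint(drug, "CYP3A4", "M1")
  pp[P_K3A4_OTH]  <- reaction_clint(drug, "CYP3A4", "other")
  pp[P_K2C19_M1]  <- reaction_clint(drug, "CYP2C19", "M1")
  pp[P_K2C19_OTH] <- reaction_clint(drug, "CYP2C19", "other")
  if (!is.null(metabolite)) {
    pp[P_MW_M] <- metabolite$molecular_weight
    pp[P_FU_M] <- metabolite$fu_plasma
    pp[P_CL_M1HEP] <-
      metabolite$total_hepatic_plasma_clearance_mL_min_kg * w * 60 / 1000
  } else {
    pp[P_MW_M] <- drug$molecular_weight   # placeholder; M1 states stay zero
    pp[P_FU_M] <- 1
  }

  enz <- individual$enzymes
  pick <- function(enzyme, organ) {
    hit <- enz$enzyme == enzyme & enz$organ == organ
    if (!any(hit)) list(ref = 0, kdeg = 1) else
      list(ref = enz$reference_concentration[hit][1], kdeg = enz$kdeg[hit][1])
  }
  l3 <- pick("CYP3A4", "liver"); g3 <- pick("CYP3A4", "gut")
  l2 <- pick("CYP2C19", "liver")
  pp[P_EREF_L3A4] <- l3$ref * mults[["cyp3a4_abundance"]]
  pp[P_EREF_G3A4] <- g3$ref * mults[["cyp3a4_abundance"]]
  pp[P_EREF_L2C19] <- l2$ref * mults[["cyp2c19_abundance"]]
  pp[P_KDEG_L3A4] <- l3$kdeg; pp[P_KDEG_G3A4] <- g3$kdeg
  pp[P_KDEG_L2C19] <- l2$kdeg

  dis <- drug$dissolution
  fasted <- dis$fasted %||% list(t50_h = 1, shape = 1)
  fed <- dis$fed %||% fasted
  pp[P_T50_FAST] <- fasted$t50_h; pp[P_B_FAST] <- fasted$shape
  pp[P_T50_FED] <- fed$t50_h;     pp[P_B_FED] <- fed$shape
  pp[P_HAZ_CAP] <- options$hazard_cap

  if (nrow(meals)) {
    pp[P_EMPTY_MULT] <- meals$emptying_multiplier[1]
    pp[P_EMPTY_DECAY] <- log(2) / meals$pH_decay_halflife[1]
    pp[P_MEAL_T + seq_len(nrow(meals)) - 1] <- meals$time
  } else {
    pp[P_EMPTY_MULT] <- 1; pp[P_EMPTY_DECAY] <- 1
  }
  pp[P_N_MEAL] <- nrow(meals)

  kp_p <- partition_coefficients(drug, individual, method = options$kp_method,
                                 overrides = options$kp_overrides)
  kp_m <- if (is.null(metabolite)) rep(1, 14) else
    partition_coefficients(metabolite, individual, method = options$kp_method)
  org <- individual$organs
  pp[P_V + 0:13] <- org$volume_L
  pp[P_Q + 0:13] <- org$flow_L_per_h
  pp[P_KPP + 0:13] <- as.numeric(kp_p)
  pp[P_KPM + 0:13] <- as.numeric(kp_m)

  tract <- options$gi_tract %||% default_gi_tract()
  if (nrow(tract) != N_SEG)
    stop("GI tract must have ", N_SEG, " segments (stomach, 4 x SI, colon)")
  peff <- drug$specific_intestinal_permeability_cm_s
  if (is.na(peff)) peff <- 0
  pp[P_VLUM + 0:5] <- tract$volume_L
  pp[P_KTRANS + 0:5] <- tract$transit_rate_per_h
  pp[P_KABS + 0:5] <- peff * tract$surface_area_cm2 *
    tract$effective_area_multiplier * 3.6 / tract$volume_L
  if (!isTRUE(options$colon_absorption)) pp[P_KABS + 5] <- 0

  pp[P_N_DOSE] <- nrow(oral)
  if (nrow(oral)) {
    pp[P_DOSE_T + seq_len(nrow(oral)) - 1] <- oral$time
    pp[P_DOSE_FED + seq_len(nrow(oral)) - 1] <- as.numeric(oral$fed)
  }

  # perpetrator block
  forcing <- NULL
  pp[P_PERP_MODE] <- 0
  if (!is.null(perpetrator)) {
    validate_perpetrator(perpetrator)
    pp[P_PERP_MECH] <- switch(perpetrator$mechanism, mbi = 1, induction = 2)
    pp[P_PERP_KI] <- perpetrator$KI %||% 1
    pp[P_PERP_KINACT] <- perpetrator$kinact %||% 0
    pp[P_PERP_EMAX] <- perpetrator$Emax %||% 0
    pp[P_PERP_EC50] <- perpetrator$EC50 %||% 1
    own <- perpetrator$own_kinetics
    if (is.data.frame(own)) {
      pp[P_PERP_MODE] <- 2
      pp[P_PERP_FU] <- 1  # forcing tables are unbound concentrations
      forcing <- stats::approxfun(own$time_h, own$conc_umol_L, rule = 2,
                                  yleft = 0)
    } else {
      pp[P_PERP_MODE] <- 1
      pp[P_PERP_KA] <- own$ka_per_h
      pp[P_PERP_V] <- own$volume_L
      pp[P_PERP_CL] <- own$clearance_L_per_h
      pp[P_PERP_FU] <- own$fu_plasma
      if (is.null(perpetrator_events) || !nrow(perpetrator_events))
        stop("perpetrator regimen required when simulating perpetrator kinetics")
    }
  }

  # deSolve event table: oral doses -> stomach undissolved; iv -> venous;
  # perpetrator doses -> perpetrator depot.
  evrows <- list()
  if (nrow(oral))
    evrows$oral <- data.frame(var = S_UND, time = oral$time,
                              value = mg_to_umol(oral$amount_mg, pp[P_MW_P]),
                              method = "add")
  if (nrow(iv))
    evrows$iv <- data.frame(var = S_P + O_VEN - 1L, time = iv$time,
                            value = mg_to_umol(iv$amount_mg, pp[P_MW_P]),
                            method = "add")
  if (!is.null(perpetrator) && pp[P_PERP_MODE] == 1) {
    pev <- as.data.frame(perpetrator_events)
    pev <- pev[pev$type == "dose", , drop = FALSE]
    evrows$perp <- data.frame(
      var = S_PDEPOT, time = pev$time,
      value = mg_to_umol(pev$amount_mg, perpetrator$own_kinetics$molecular_weight),
      method = "add")
  }
  evdat <- if (length(evrows)) do.call(rbind, evrows) else NULL
  if (!is.null(evdat)) {
    evdat <- evdat[order(evdat$time, evdat$var), , drop = FALSE]
    rownames(evdat) <- NULL
  }

  y0 <- numeric(N_STATES)
  y0[S_EL3A4] <- pp[P_EREF_L3A4]
  y0[S_EL2C19] <- pp[P_EREF_L2C19]
  y0[S_EG3A4] <- pp[P_EREF_G3A4]
  names(y0) <- state_names()

  times <- seq(0, t_end, by = options$dt)
  extra <- c(if (!is.null(evdat)) evdat$time, options$extra_times)
  extra <- extra[extra >= 0 & extra <= t_end]
  times <- sort(unique(c(times, extra, t_end)))

  list(parms = pp, y0 = y0, events = evdat, times = times, forcing = forcing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_perpetrator <- function(p) {
  if (!p$mechanism %in% c("mbi", "induction"))
    stop("perpetrator mechanism must be 'mbi' or 'induction'")
  if (p$mechanism == "mbi") {
    if (is.null(p$KI) || is.null(p$kinact) || p$KI <= 0 || p$kinact < 0)
      stop("mbi perpetrator requires KI > 0 and kinact >= 0")
  } else {
    if (is.null(p$Emax) || is.null(p$EC50) || p$Emax < 0 || p$EC50 <= 0)
      stop("induction perpetrator requires Emax >= 0 and EC50 > 0")
  }
  if (is.null(p$own_kinetics))
    stop("perpetrator requires own_kinetics (model parameters or forcing table)")
  if (is.data.frame(p$own_kinetics)) {
    need <- c("time_h", "conc_umol_L")
    if (!all(need %in% names(p$own_kinetics)))
      stop("forcing table needs columns time_h, conc_umol_L")
  }
  invisible(p)
}
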