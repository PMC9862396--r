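# Reference (pure R) right-hand side of the coupled parent + metabolite
# whole-body system.  The compiled version in src/pbpk_rhs.c implements
# the same equations; the two are cross-checked in the test suite and the
# R version additionally supports perpetrator forcing tables.
#
# Model structure:
#   - GI lumen: stomach + 4 small-intestinal segments + colon; Weibull
#     dissolution hazard (time since most recent oral dose, fasted/fed
#     parameter set per dose), first-order transit, permeability-limited
#     uptake of the dissolved pool into gut tissue; material leaving the
#     colon is unabsorbed ('fecal').
#   - Distribution: perfusion-limited organ model, venous outflow
#     concentration C_organ / Kp; gut + spleen drain through the liver
#     (portal vein); lung in series between venous and arterial pools.
#   - Parent elimination: four first-order CYP reactions in liver (CYP3A4
#     and CYP2C19, each to M1 / other) driven by the unbound liver-plasma
#     concentration, a gut-wall CYP3A4 copy of the two CYP3A4 reactions,
#     and renal plasma clearance applied to arterial plasma.
#   - Metabolite: formed molar 1:1 in liver/gut tissue, distributed with
#     its own Kp set, eliminated by total hepatic plasma clearance.
#   - Enzymes: synthesis/degradation turnover; mechanism-based
#     inactivation adds kinact*I/(KI+I) to the loss rate, induction scales
#     synthesis by 1 + Emax*I/(EC50+I), with I the unbound perpetrator
#     plasma concentration.

pbpk_rhs_r <- function(t, y, parms) {
  pp <- parms$vec
  nd <- as.integer(pp[P_N_DOSE])

  # dissolution hazard from the most recent oral dose
  haz <- 0
  if (nd > 0) {
    dt_ <- pp[P_DOSE_T + 0:(nd - 1)]
    past <- which(dt_ <= t + 1e-12)
    if (length(past)) {
      i <- past[which.max(dt_[past])]
      age <- max(t - dt_[i], 1e-9)
      fed <- pp[P_DOSE_FED + i - 1] > 0.5
      t50 <- if (fed) pp[P_T50_FED] else pp[P_T50_FAST]
      b <- if (fed) pp[P_B_FED] else pp[P_B_FAST]
      haz <- min(log(2) * b / t50 * (age / t50)^(b - 1), pp[P_HAZ_CAP])
    }
  }

  # gastric emptying under meals
  empty_mult <- 1
  nm <- as.integer(pp[P_N_MEAL])
  if (nm > 0) {
    mt <- pp[P_MEAL_T + 0:(nm - 1)]
    past <- which(mt <= t + 1e-12)
    if (length(past)) {
      tm <- max(mt[past])
      empty_mult <- 1 + (pp[P_EMPTY_MULT] - 1) *
        exp(-pp[P_EMPTY_DECAY] * (t - tm))
    }
  }

  und <- y[S_UND + 0:5]; dis <- y[S_DIS + 0:5]
  ktr <- pp[P_KTRANS + 0:5]
  ktr[1] <- ktr[1] * empty_mult
  kabs <- pp[P_KABS + 0:5]

  dund <- numeric(6); ddis <- numeric(6)
  dund[1] <- -haz * und[1] - ktr[1] * und[1]
  ddis[1] <-  haz * und[1] - ktr[1] * dis[1]
  for (s in 2:6) {
    dund[s] <- ktr[s - 1] * und[s - 1] - haz * und[s] - ktr[s] * und[s]
    ddis[s] <- ktr[s - 1] * dis[s - 1] + haz * und[s] -
      (ktr[s] + kabs[s]) * dis[s]
  }
  absorbed <- sum(kabs * dis)
  dfecal <- ktr[6] * (und[6] + dis[6])

  V <- pp[P_V + 0:13]; Q <- pp[P_Q + 0:13]
  kpp <- pp[P_KPP + 0:13]; kpm <- pp[P_KPM + 0:13]
  AP <- y[S_P + 0:13]; AM <- y[S_M + 0:13]
  CP <- AP / V; CM <- AM / V                 # tissue concentrations
  CPv <- CP / kpp; CMv <- CM / kpm           # venous-equilibrium (plasma)

  # enzymes and perpetrator
  E_l3 <- y[S_EL3A4]; E_l2 <- y[S_EL2C19]; E_g3 <- y[S_EG3A4]
  perp_mode <- pp[P_PERP_MODE]
  Iu <- 0
  dperp <- c(0, 0)
  if (perp_mode == 1) {
    dep <- y[S_PDEPOT]; cen <- y[S_PCENT]
    dperp[1] <- -pp[P_PERP_KA] * dep
    dperp[2] <- pp[P_PERP_KA] * dep - pp[P_PERP_CL] / pp[P_PERP_V] * cen
    Iu <- pp[P_PERP_FU] * cen / pp[P_PERP_V]
  } else if (perp_mode == 2) {
    Iu <- parms$forcing(t)
  }

  turnover <- function(E, Eref, kdeg) {
    rsyn <- Eref * kdeg
    mech <- pp[P_PERP_MECH]
    if (perp_mode > 0 && mech == 1) {        # mechanism-based inactivation
      rsyn - (kdeg + pp[P_PERP_KINACT] * Iu / (pp[P_PERP_KI] + Iu)) * E
    } else if (perp_mode > 0 && mech == 2) { # Emax induction of synthesis
      rsyn * (1 + pp[P_PERP_EMAX] * Iu / (pp[P_PERP_EC50] + Iu)) - kdeg * E
    } else rsyn - kdeg * E
  }
  dE_l3 <- turnover(E_l3, pp[P_EREF_L3A4], pp[P_KDEG_L3A4])
  dE_g3 <- turnover(E_g3, pp[P_EREF_G3A4], pp[P_KDEG_G3A4])
  # perpetrators here target CYP3A4 only
  dE_l2 <- pp[P_EREF_L2C19] * pp[P_KDEG_L2C19] - pp[P_KDEG_L2C19] * E_l2

  # metabolism: clint (uL/min/pmol) * E (umol/L) * V (L) * 60 -> L/h,
  # applied to the unbound plasma-water concentration in the tissue.
  fuP <- pp[P_FU_P]
  cl_scale_liv <- 60 * V[O_LIVER]
  cl_scale_gut <- 60 * V[O_GUT]
  cu_liv <- fuP * CPv[O_LIVER]
  cu_gut <- fuP * CPv[O_GUT]
  v_l3_m1  <- pp[P_K3A4_M1]   * E_l3 * cl_scale_liv * cu_liv
  v_l3_oth <- pp[P_K3A4_OTH]  * E_l3 * cl_scale_liv * cu_liv
  v_l2_m1  <- pp[P_K2C19_M1]  * E_l2 * cl_scale_liv * cu_liv
  v_l2_oth <- pp[P_K2C19_OTH] * E_l2 * cl_scale_liv * cu_liv
  v_g3_m1  <- pp[P_K3A4_M1]   * E_g3 * cl_scale_gut * cu_gut
  v_g3_oth <- pp[P_K3A4_OTH]  * E_g3 * cl_scale_gut * cu_gut
  v_ren <- pp[P_CL_REN] * CPv[O_ART]           # renal: arterial plasma
  v_m1hep <- pp[P_CL_M1HEP] * CMv[O_ART]       # M1: arterial plasma

  simple <- c(O_ADIPOSE, O_BONE, O_BRAIN, O_HEART, O_KIDNEY, O_MUSCLE,
              O_SKIN, O_REST)
  dAP <- numeric(14); dAM <- numeric(14)
  # blood pools carry Kp 1, so these are plasma concentrations
  CPart <- CP[O_ART]; CMart <- CM[O_ART]

  dAP[simple] <- Q[simple] * (CPart - CPv[simple])
  dAM[simple] <- Q[simple] * (CMart - CMv[simple])
  dAP[O_GUT] <- Q[O_GUT] * (CPart - CPv[O_GUT]) + absorbed -
    (v_g3_m1 + v_g3_oth)
  dAM[O_GUT] <- Q[O_GUT] * (CMart - CMv[O_GUT]) + v_g3_m1
  dAP[O_SPLEEN] <- Q[O_SPLEEN] * (CPart - CPv[O_SPLEEN])
  dAM[O_SPLEEN] <- Q[O_SPLEEN] * (CMart - CMv[O_SPLEEN])
  Q_liv_out <- Q[O_LIVER] + Q[O_GUT] + Q[O_SPLEEN]
  dAP[O_LIVER] <- Q[O_LIVER] * CPart + Q[O_GUT] * CPv[O_GUT] +
    Q[O_SPLEEN] * CPv[O_SPLEEN] - Q_liv_out * CPv[O_LIVER] -
    (v_l3_m1 + v_l3_oth + v_l2_m1 + v_l2_oth)
  dAM[O_LIVER] <- Q[O_LIVER] * CMart + Q[O_GUT] * CMv[O_GUT] +
    Q[O_SPLEEN] * CMv[O_SPLEEN] - Q_liv_out * CMv[O_LIVER] +
    (v_l3_m1 + v_l2_m1)
  CO <- Q[O_LUNG]
  dAP[O_LUNG] <- CO * (CP[O_VEN] - CPv[O_LUNG])
  dAM[O_LUNG] <- CO * (CM[O_VEN] - CMv[O_LUNG])
  dAP[O_ART] <- CO * (CPv[O_LUNG] - CPart) - v_ren
  dAM[O_ART] <- CO * (CMv[O_LUNG] - CMart) - v_m1hep
  dAP[O_VEN] <- sum(Q[simple] * CPv[simple]) + Q_liv_out * CPv[O_LIVER] -
    CO * CP[O_VEN]
  dAM[O_VEN] <- sum(Q[simple] * CMv[simple]) + Q_liv_out * CMv[O_LIVER] -
    CO * CM[O_VEN]

  dy <- numeric(N_STATES)
  dy[S_UND + 0:5] <- dund
  dy[S_DIS + 0:5] <- ddis
  dy[S_FECAL] <- dfecal
  dy[S_P + 0:13] <- dAP
  dy[S_M + 0:13] <- dAM
  dy[S_EL3A4] <- dE_l3; dy[S_EL2C19] <- dE_l2; dy[S_EG3A4] <- dE_g3
  dy[S_CREN] <- v_ren; dy[S_CM1HEP] <- v_m1hep
  dy[S_CL3A4M1] <- v_l3_m1; dy[S_CL3A4OTH] <- v_l3_oth
  dy[S_CL2C19M1] <- v_l2_m1; dy[S_CL2C19OTH] <- v_l2_oth
  dy[S_CG3A4M1] <- v_g3_m1; dy[S_CG3A4OTH] <- v_g3_oth
  dy[S_PDEPOT] <- dperp[1]; dy[S_PCENT] <- dperp[2]
  list(dy)
}
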