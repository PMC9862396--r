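#' @title Enzyme-turnover drug-drug interaction engine
#' @name interactions
NULL

#' Construct a perpetrator specification
#'
#' Two mechanisms are supported, both acting on CYP3A4 at every
#' expression site (liver and gut wall):
#' * `"mbi"` -- mechanism-based inactivation: the enzyme loss rate becomes
#'   `kdeg + kinact * I / (KI + I)`;
#' * `"induction"` -- Emax stimulation of de-novo synthesis:
#'   `Rsyn * (1 + Emax * I / (EC50 + I))`;
#' with `I` the unbound perpetrator plasma concentration.  The
#' perpetrator's own kinetics are either a one-compartment oral model
#' (list with `ka_per_h`, `volume_L`, `clearance_L_per_h`, `fu_plasma`,
#' `molecular_weight`) or a forcing table
#' (`data.frame(time_h, conc_umol_L)` of unbound concentrations).
#'
#' @param name Label.
#' @param mechanism `"mbi"` or `"induction"`.
#' @param KI,kinact MBI parameters (umol/L, 1/h).
#' @param Emax,EC50 Induction parameters (unitless, umol/L).
#' @param own_kinetics One-compartment parameter list or forcing table.
#' @return Object of class `perpetrator_spec`.
#' @export
perpetrator_spec <- function(name, mechanism = c("mbi", "induction"),
                             KI = NULL, kinact = NULL,
                             Emax = NULL, EC50 = NULL,
                             own_kinetics = NULL) {
  mechanism <- match.arg(mechanism)
  p <- structure(list(name = name, mechanism = mechanism, KI = KI,
                      kinact = kinact, Emax = Emax, EC50 = EC50,
                      own_kinetics = own_kinetics),
                 class = "perpetrator_spec")
  validate_perpetrator(p)
  p
}

#' Enzyme-turnover rate under a perpetrator
#'
#' The turnover right-hand side used by the engine, exposed for direct
#' inspection: without a perpetrator `dE/dt = Rsyn - kdeg * E`; under
#' induction the synthesis term is scaled by `1 + Emax * I / (EC50 + I)`;
#' under mechanism-based inactivation the loss rate gains
#' `kinact * I / (KI + I)`.
#'
#' @param E Current enzyme concentration (umol/L), >= 0.
#' @param Rsyn Synthesis rate (umol/L/h).
#' @param kdeg Degradation rate constant (1/h).
#' @param perpetrator_conc Unbound perpetrator concentration I (umol/L).
#' @param spec `perpetrator_spec`, or `NULL` for plain turnover.
#' @return dE/dt (umol/L/h).
#' @examples
#' turnover_rhs(4, Rsyn = 0.08, kdeg = 0.02, 0, NULL)  # 0 at baseline
#' @export
turnover_rhs <- function(E, Rsyn, kdeg, perpetrator_conc = 0, spec = NULL) {
  if (any(E < 0)) stop("E must be >= 0")
  I <- perpetrator_conc
  if (is.null(spec)) return(Rsyn - kdeg * E)
  validate_perpetrator(spec)
  if (spec$mechanism == "induction")
    Rsyn * (1 + spec$Emax * I / (spec$EC50 + I)) - kdeg * E
  else
    Rsyn - (kdeg + spec$kinact * I / (spec$KI + I)) * E
}

#' Define a DDI simulation scenario
#'
#' @param victim_regimen Victim dosing events (times relative to the start
#'   of victim dosing).
#' @param perpetrator `perpetrator_spec`.
#' @param perpetrator_regimen Perpetrator dosing events (same convention);
#'   ignored for forcing-table perpetrators.
#' @param pretreatment_h Perpetrator run-in before the first victim dose,
#'   so that the perpetrator (and the enzyme pool) is at its own steady
#'   state when victim dosing starts.
#' @param washout_h Horizon after the last victim dose.
#' @return Object of class `ddi_scenario`.
#' @export
ddi_scenario <- function(victim_regimen, perpetrator, perpetrator_regimen,
                         pretreatment_h = 72, washout_h = 24) {
  if (!nrow(as.data.frame(victim_regimen))) stop("victim regimen is empty")
  structure(list(victim_regimen = victim_regimen,
                 perpetrator = perpetrator,
                 perpetrator_regimen = perpetrator_regimen,
                 pretreatment_h = pretreatment_h,
                 washout_h = washout_h), class = "ddi_scenario")
}

shift_events <- function(ev, dt) {
  ev <- as.data.frame(ev)
  if (nrow(ev)) ev$time <- ev$time + dt
  ev
}

# Repeat a one-interval perpetrator pattern over [0, t_end].
extend_regimen <- function(ev, interval, t_end) {
  ev <- as.data.frame(ev)
  base <- ev[ev$time < interval, , drop = FALSE]
  reps <- ceiling(t_end / interval)
  out <- do.call(rbind, lapply(seq_len(reps) - 1, function(k)
    shift_events(base, k * interval)))
  out[out$time < t_end, , drop = FALSE]
}

#' Simulate a drug-drug interaction scenario
#'
#' Runs the victim alone and co-administered with the perpetrator on
#' identical individuals (same physiology objects in both arms), computes
#' victim PK parameters for the first dose and at steady state, and
#' reports fold changes.  Victim dosing starts after the perpetrator
#' pretreatment in both arms so the two are time-aligned.
#'
#' @param scenario `ddi_scenario`.
#' @param victim,metabolite `drug_parameters` of the victim and its
#'   metabolite.
#' @param population List of individuals (e.g. [sample_population()]); a
#'   single `individual` is accepted.
#' @param options [solver_options()].
#' @return Object of class `ddi_result`: `table` with one row per PK
#'   parameter (value plus min--max per arm and fold change), `direction`,
#'   and per-arm per-individual values.
#' @export
simulate_ddi <- function(scenario, victim, metabolite = NULL,
                         population = build_reference_individual(),
                         options = solver_options()) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  if (inherits(population, "individual")) population <- list(population)
  perp <- scenario$perpetrator
  vr <- as.data.frame(scenario$victim_regimen)
  vdoses <- vr[vr$type == "dose", , drop = FALSE]
  if (!nrow(vdoses)) stop("victim regimen holds no doses")
  tau <- if (nrow(vdoses) > 1) min(diff(sort(vdoses$time))) else 24
  pre <- scenario$pretreatment_h
  vshift <- shift_events(vr, pre)
  t_end <- pre + max(vdoses$time) + tau + scenario$washout_h
  forcing <- is.data.frame(perp$own_kinetics)
  pregimen <- NULL
  if (!forcing) {
    pr <- as.data.frame(scenario$perpetrator_regimen)
    prd <- pr[pr$type == "dose", , drop = FALSE]
    if (!nrow(prd)) stop("perpetrator regimen holds no doses")
    ptau <- if (nrow(prd) > 1) min(diff(sort(prd$time))) else 24
    covering <- if (max(prd$time) + ptau >= t_end) prd
                else extend_regimen(prd, max(prd$time) + ptau, t_end)
    pregimen <- covering
  }
  first_t <- pre + min(vdoses$time)
  last_t <- pre + max(vdoses$time)
  run <- function(ind, with_perp) {
    sim <- simulate_pbpk(
      victim, metabolite, ind, regimen = regimen(vshift), t_end = t_end,
      perpetrator = if (with_perp) perp else NULL,
      perpetrator_regimen = if (with_perp) pregimen else NULL,
      options = options)
    prof <- sim$conc[, c("time_h", victim$name)]
    names(prof) <- c("time_h", "conc")
    c(AUC_first = interval_auc(prof, first_t, first_t + tau),
      AUC_SS = interval_auc(prof, last_t, last_t + tau),
      Cmax_first = interval_cmax(prof, first_t, first_t + tau),
      Cmax_SS = interval_cmax(prof, last_t, last_t + tau))
  }
  alone <- t(vapply(population, run, numeric(4), with_perp = FALSE))
  comb <- t(vapply(population, run, numeric(4), with_perp = TRUE))
  direction <- if (perp$mechanism == "mbi") "increase" else "decrease"
  summ <- function(m) data.frame(value = colMeans(m),
                                 min = apply(m, 2, min),
                                 max = apply(m, 2, max))
  sa <- summ(alone); sc <- summ(comb)
  folds <- fold_change(stats::setNames(sa$value, rownames(sa)),
                       stats::setNames(sc$value, rownames(sc)), direction)
  tab <- data.frame(parameter = colnames(alone),
                    alone = sa$value, alone_min = sa$min, alone_max = sa$max,
                    combined = sc$value, combined_min = sc$min,
                    combined_max = sc$max, fold = as.numeric(folds),
                    row.names = NULL)
  structure(list(table = tab, direction = direction,
                 alone = alone, combined = comb,
                 perpetrator = perp$name, n = length(population)),
            class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> perpetrator %s (fold %s), n = %d\n",
              x$perpetrator, x$direction, x$n))
  print(x$table, digits = 4)
  invisible(x)
}

#' Fold change between study arms
#'
#' `"increase"` reports combined/alone, `"decrease"` reports
#' alone/combined (both conventions yield values > 1 for an effect in the
#' named direction).
#'
#' @param alone,combined Positive PK parameter values (vectors are matched
#'   by position).
#' @param direction `"increase"` or `"decrease"`.
#' @return Fold changes, same length as the inputs.
#' @examples
#' fold_change(2994.4, 11312.0, "increase")  # 3.78
#' @export
fold_change <- function(alone, combined, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (any(alone <= 0) || any(combined <= 0))
    stop("fold change needs positive values in both arms")
  if (direction == "increase") combined / alone else alone / combined
}

# Linear trapezoid on the dense model grid, restricted to [t0, t1].
interval_auc <- function(prof, t0, t1) {
  sel <- prof$time_h >= t0 - 1e-9 & prof$time_h <= t1 + 1e-9
  t <- prof$time_h[sel]; c <- prof$conc[sel]
  sum(diff(t) * (head(c, -1) + c[-1]) / 2)
}

interval_cmax <- function(prof, t0, t1) {
  sel <- prof$time_h >= t0 - 1e-9 & prof$time_h <= t1 + 1e-9
  max(prof$conc[sel])
}
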