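#' @title Gastrointestinal absorption: dissolution, transit, meals
#' @name absorption
NULL

#' Default gastrointestinal tract
#'
#' Stomach plus four small-intestinal segments with first-order transit,
#' read from the bundled segment table.  The stomach must be (and is) the
#' first segment; its effective absorptive area is zero.
#'
#' @param path Optional replacement segment table.
#' @return Object of class `gi_tract` (a validated data.frame).
#' @export
default_gi_tract <- function(path = tp_extdata("gi_tract.tsv")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_gi_tract(structure(tab, class = c("gi_tract", "data.frame")))
}

validate_gi_tract <- function(tract) {
  if (tract$segment[1] != "stomach") stop("stomach must be the first GI segment")
  if (any(tract$transit_rate_per_h <= 0)) stop("transit rates must be > 0")
  if (any(tract$pH < 1 | tract$pH > 8.5)) stop("segment pH must lie in [1, 8.5]")
  if (any(tract$volume_L <= 0)) stop("segment volumes must be > 0")
  tract
}

#' Weibull cumulative fraction dissolved
#'
#' `m(t) = 1 - exp(-ln 2 * (t / t50)^shape)`, parameterised so that
#' `m(t50) = 0.5` exactly: `t50` is the time at which half of the dose is
#' in solution, `shape` controls the curve steepness.
#'
#' @param t Time since dose (h), >= 0 (vectorised).
#' @param spec `list(t50_h=, shape=)` as stored under
#'   `drug$dissolution$fasted` / `$fed`.
#' @return Fraction dissolved in `[0, 1)`, nondecreasing in `t`.
#' @examples
#' weibull_fraction(0.942, list(t50_h = 0.942, shape = 0.990))  # 0.5
#' @export
weibull_fraction <- function(t, spec) {
  if (any(t < 0)) stop("t must be >= 0")
  if (spec$t50_h <= 0 || spec$shape <= 0) stop("t50 and shape must be > 0")
  1 - exp(-log(2) * (t / spec$t50_h)^spec$shape)
}

# Instantaneous dissolution hazard d(-log(1-m))/dt, capped to keep the
# integrand finite for shape < 1 (the cap distorts only the first
# ~1e-5 h after a dose at the default value).
weibull_hazard <- function(t, t50, shape, cap = 200) {
  t <- pmax(t, 1e-9)
  h <- log(2) * shape / t50 * (t / t50)^(shape - 1)
  pmin(h, cap)
}

#' Permeability-driven absorptive flux from a luminal segment
#'
#' `flux = Peff * effective area * concentration`, converted to umol/h
#' (`cm/s * cm^2 * umol/L * 3.6e-3 L s / (cm^3 h)`).
#'
#' @param lumen_concentration umol/L, >= 0.
#' @param segment One row of a `gi_tract` table (uses `surface_area_cm2`
#'   and `effective_area_multiplier`).
#' @param peff Specific intestinal permeability, cm/s.
#' @return Flux in umol/h, linear in both `peff` and concentration.
#' @examples
#' seg <- data.frame(surface_area_cm2 = 100, effective_area_multiplier = 1)
#' absorption_flux(1, seg, 1.16e-6)  # 4.176e-4 umol/h
#' @export
absorption_flux <- function(lumen_concentration, segment, peff) {
  if (any(lumen_concentration < 0)) stop("lumen concentration must be >= 0")
  area <- segment$surface_area_cm2 * segment$effective_area_multiplier
  peff * area * 3.6e-3 * 1000 * lumen_concentration
}

#' Dose and meal events
#'
#' `dose_event()` describes administration of `amount` mg at `time` h
#' (oral doses deposit undissolved drug in the stomach; `route = "iv"`
#' places the dose in venous blood, used for degenerate closed-form
#' checks).  `meal_event()` raises gastric pH to `gastric_pH_peak` and
#' scales the gastric emptying rate by `emptying_multiplier`, both
#' relaxing back to the fasted baseline exponentially with
#' `pH_decay_halflife`; doses flagged `fed = TRUE` use the fed Weibull
#' dissolution parameters.
#'
#' @param time Event time (h).
#' @param amount Dose in mg, >= 0.
#' @param route `"oral"` or `"iv"`.
#' @param fed Logical; use the fed dissolution specification.
#' @param gastric_pH_peak Post-prandial gastric pH peak.
#' @param pH_decay_halflife Half-life (h) of the return to fasted state.
#' @param emptying_multiplier Multiplier (< 1 slows) on the gastric
#'   emptying rate immediately after the meal.
#' @return One-row event data.frame.
#' @export
dose_event <- function(time, amount, route = c("oral", "iv"), fed = FALSE) {
  route <- match.arg(route)
  if (amount < 0) stop("dose amount must be >= 0")
  data.frame(time = time, type = "dose", amount_mg = amount, route = route,
             fed = fed, gastric_pH_peak = NA_real_,
             pH_decay_halflife = NA_real_, emptying_multiplier = NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname dose_event
#' @export
meal_event <- function(time, gastric_pH_peak = 5.5, pH_decay_halflife = 0.75,
                       emptying_multiplier = 0.25) {
  if (gastric_pH_peak < 1 || gastric_pH_peak > 8.5)
    stop("gastric_pH_peak must lie in [1, 8.5]")
  if (emptying_multiplier <= 0) stop("emptying_multiplier must be > 0")
  data.frame(time = time, type = "meal", amount_mg = NA_real_,
             route = NA_character_, fed = NA,
             gastric_pH_peak = gastric_pH_peak,
             pH_decay_halflife = pH_decay_halflife,
             emptying_multiplier = emptying_multiplier,
             stringsAsFactors = FALSE)
}

#' Build a dosing regimen
#'
#' Convenience constructor for repeated oral dosing; `fed = TRUE` attaches
#' a meal event at every dose time.
#'
#' @param dose_mg Dose per administration (mg).
#' @param n_doses Number of doses.
#' @param interval_h Dosing interval (h).
#' @param fed Logical fed state.
#' @param start_h Time of the first dose.
#' @return Event data.frame sorted by time (class `regimen`).
#' @examples
#' oral_regimen(50, n_doses = 7, interval_h = 24)
#' @export
oral_regimen <- function(dose_mg, n_doses = 1, interval_h = 24, fed = FALSE,
                         start_h = 0) {
  times <- start_h + (seq_len(n_doses) - 1) * interval_h
  ev <- do.call(rbind, lapply(times, dose_event, amount = dose_mg, fed = fed))
  if (fed) ev <- rbind(ev, do.call(rbind, lapply(times, meal_event)))
  regimen(ev)
}

#' @rdname oral_regimen
#' @param ... Event data.frames (from [dose_event()] / [meal_event()]) or
#'   a single data.frame of events.
#' @export
regimen <- function(...) {
  ev <- do.call(rbind, list(...))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("regimen", "data.frame"))
}

#' Gastric state under meal events
#'
#' Returns the gastric pH and emptying-rate multiplier at time `t` given
#' the meal events of a regimen: pH jumps to the meal peak and decays
#' exponentially back to the fasted baseline; the emptying rate is scaled
#' by the meal multiplier, relaxing on the same half-life.
#'
#' @param tract `gi_tract` (supplies the fasted gastric pH baseline).
#' @param events Regimen (only meal rows are used), or `NULL` for the
#'   fasted state.
#' @param t Query time (h).
#' @return `list(gastric_pH=, emptying_multiplier=, dissolution_state=)`.
#' @export
apply_meal <- function(tract, events, t) {
  base_pH <- tract$pH[tract$segment == "stomach"]
  out <- list(gastric_pH = base_pH, emptying_multiplier = 1,
              dissolution_state = "fasted")
  meals <- if (is.null(events)) NULL else events[events$type == "meal", ]
  if (is.null(meals) || !nrow(meals)) return(out)
  past <- meals[meals$time <= t, ]
  if (!nrow(past)) return(out)
  last <- past[which.max(past$time), ]
  lam <- log(2) / last$pH_decay_halflife
  decay <- exp(-lam * (t - last$time))
  out$gastric_pH <- base_pH + (last$gastric_pH_peak - base_pH) * decay
  out$emptying_multiplier <- 1 + (last$emptying_multiplier - 1) * decay
  out$dissolution_state <- "fed"
  out
}
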