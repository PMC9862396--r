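#' @title Parameter identification, enzyme-abundance calibration and
#'   local sensitivity analysis
#' @name calibration
NULL

#' Get or set a compound parameter by path
#'
#' Paths address the tunable entries of a `drug_parameters` object:
#' `"clint/CYP3A4/M1"` (and the other enzyme/product pairs),
#' `"dissolution/fasted/t50"`, `"dissolution/fed/shape"`, `"fu_plasma"`,
#' `"logP"`, `"renal_plasma_clearance"`, `"hepatic_plasma_clearance"`,
#' `"peff_intestinal"`, `"solubility"`.
#'
#' @param drug `drug_parameters`.
#' @param path Parameter path string.
#' @param value Replacement value (set form).
#' @return The value (get form) or the updated object (set form).
#' @export
get_drug_parameter <- function(drug, path) {
  pp <- strsplit(path, "/", fixed = TRUE)[[1]]
  switch(pp[1],
    clint = {
      rx <- drug$reactions
      hit <- rx$enzyme == pp[2] & rx$product == pp[3]
      if (!any(hit)) stop("no reaction ", pp[2], " -> ", pp[3])
      rx$clint[hit][1]
    },
    dissolution = drug$dissolution[[pp[2]]][[
      if (pp[3] == "t50") "t50_h" else pp[3]]],
    fu_plasma = drug$fu_plasma,
    logP = drug$logP,
    renal_plasma_clearance = drug$renal_plasma_clearance_mL_min_kg,
    hepatic_plasma_clearance = drug$total_hepatic_plasma_clearance_mL_min_kg,
    peff_intestinal = drug$specific_intestinal_permeability_cm_s,
    solubility = drug$solubility_mg_per_L,
    stop("unknown parameter path: ", path))
}

#' @rdname get_drug_parameter
#' @export
set_drug_parameter <- function(drug, path, value) {
  pp <- strsplit(path, "/", fixed = TRUE)[[1]]
  switch(pp[1],
    clint = {
      hit <- drug$reactions$enzyme == pp[2] & drug$reactions$product == pp[3]
      if (!any(hit)) stop("no reaction ", pp[2], " -> ", pp[3])
      drug$reactions$clint[hit] <- value
    },
    dissolution = {
      field <- if (pp[3] == "t50") "t50_h" else pp[3]
      drug$dissolution[[pp[2]]][[field]] <- value
    },
    fu_plasma = drug$fu_plasma <- value,
    logP = drug$logP <- value,
    renal_plasma_clearance = drug$renal_plasma_clearance_mL_min_kg <- value,
    hepatic_plasma_clearance =
      drug$total_hepatic_plasma_clearance_mL_min_kg <- value,
    peff_intestinal = drug$specific_intestinal_permeability_cm_s <- value,
    solubility = drug$solubility_mg_per_L <- value,
    stop("unknown parameter path: ", path))
  validate_drug_parameters(drug)
  drug
}

#' Specify a fitting problem
#'
#' @param parameters Character vector of parameter paths (see
#'   [get_drug_parameter()]); prefix a path with `"metabolite:"` to
#'   address the metabolite object.
#' @param lower,upper Bounds on the natural scale (recycled).
#' @param scale `"log"` (default; positive parameters are fitted as
#'   log10) or `"linear"`.
#' @param max_iter Iteration cap of the least-squares search.
#' @param seed RNG seed recorded with the fit (the objective itself is
#'   deterministic).
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(parameters, lower = NULL, upper = NULL,
                     scale = c("log", "linear"), max_iter = 100,
                     seed = 20230104) {
  scale <- match.arg(scale)
  np <- length(parameters)
  lower <- rep(if (is.null(lower)) -Inf else lower, length.out = np)
  upper <- rep(if (is.null(upper)) Inf else upper, length.out = np)
  if (any(lower >= upper)) stop("bounds must satisfy lower < upper")
  structure(list(parameters = parameters, lower = lower, upper = upper,
                 scale = scale, max_iter = max_iter, seed = seed),
            class = "fit_spec")
}

apply_paths <- function(drug, metabolite, paths, values) {
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (startsWith(p, "metabolite:")) {
      metabolite <- set_drug_parameter(metabolite,
                                       sub("^metabolite:", "", p), values[i])
    } else drug <- set_drug_parameter(drug, p, values[i])
  }
  list(drug = drug, metabolite = metabolite)
}

#' Fit model parameters to observed concentration data
#'
#' Minimises the summed squared log10 residuals between model predictions
#' and all observations, jointly across datasets, with a
#' Levenberg--Marquardt search on log10-transformed parameters (matching
#' the geometry of the MRD evaluation metric).  Datasets flagged
#' `excluded_from_fit` are skipped.  The result is deterministic given
#' `(datasets, spec, seed)`.
#'
#' @param drug,metabolite Starting `drug_parameters`.
#' @param datasets List of `observed_dataset` objects carrying their
#'   design attributes.
#' @param spec `fit_spec`.
#' @param individual Physiology used for the predictions.
#' @param options [solver_options()] (a looser tolerance than the
#'   simulation default is adequate inside the search).
#' @return Object of class `fit_result`: `estimates` (named), `objective`
#'   (sum of squared log10 residuals), `converged`, `iterations`,
#'   `message`, and the updated `drug` / `metabolite` objects.
#' @export
fit <- function(drug, metabolite, datasets, spec,
                individual = build_reference_individual(),
                options = solver_options(rtol = 1e-6, atol = 1e-9)) {
  stopifnot(inherits(spec, "fit_spec"))
  datasets <- Filter(function(d) !isTRUE(attr(d, "excluded_from_fit")),
                     datasets)
  if (!length(datasets)) stop("no datasets available for fitting")
  start <- vapply(seq_along(spec$parameters), function(i) {
    p <- spec$parameters[i]
    if (startsWith(p, "metabolite:"))
      get_drug_parameter(metabolite, sub("^metabolite:", "", p))
    else get_drug_parameter(drug, p)
  }, numeric(1))
  uselog <- spec$scale == "log"
  if (uselog && any(start <= 0))
    stop("log-scale fitting requires positive starting values")
  tx <- if (uselog) log10 else identity
  itx <- if (uselog) function(x) 10^x else identity

  # group datasets by design so one simulation serves both analytes
  keys <- vapply(datasets, function(d) {
    des <- attr(d, "design")
    paste(des$dose_mg, des$n_doses, des$interval_h, des$fed, sep = "|")
  }, character(1))
  groups <- split(seq_along(datasets), keys)

  residuals_for <- function(theta) {
    th <- pmin(pmax(itx(theta), spec$lower), spec$upper)
    upd <- apply_paths(drug, metabolite, spec$parameters, th)
    unlist(lapply(groups, function(ix) {
      des <- attr(datasets[[ix[1]]], "design")
      obs_times <- sort(unique(unlist(
        lapply(datasets[ix], function(d) d$records$time_h))))
      reg <- oral_regimen(des$dose_mg, des$n_doses, des$interval_h, des$fed)
      t_end <- (des$n_doses - 1) * des$interval_h + max(obs_times) + 1
      sim <- simulate_pbpk(upd$drug, upd$metabolite, individual, reg,
                           t_end = t_end,
                           options = modifyList(options, list(
                             dt = 0.25, extra_times = obs_times)))
      unlist(lapply(datasets[ix], function(d) {
        pred <- stats::approx(sim$conc$time_h, sim$conc[[d$analyte]],
                              xout = d$records$time_h)$y
        keep <- d$records$conc_ng_mL > 0 & pred > 0
        log10(pred[keep]) - log10(d$records$conc_ng_mL[keep])
      }))
    }), use.names = FALSE)
  }

  with_preserved_seed({
    set.seed(as.integer(spec$seed))
    res <- minpack.lm::nls.lm(
      par = tx(start), fn = residuals_for,
      lower = if (uselog) log10(pmax(spec$lower, 1e-300)) else spec$lower,
      upper = if (uselog) log10(spec$upper) else spec$upper,
      control = minpack.lm::nls.lm.control(maxiter = spec$max_iter,
                                           ftol = 1e-12, ptol = 1e-10))
  })
  est <- itx(res$par)
  names(est) <- spec$parameters
  upd <- apply_paths(drug, metabolite, spec$parameters, est)
  structure(list(estimates = est,
                 objective = res$deviance,
                 converged = res$info %in% 1:4,
                 iterations = res$niter,
                 message = res$message,
                 drug = upd$drug, metabolite = upd$metabolite,
                 start = stats::setNames(start, spec$parameters)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s after %d iteration(s), objective %.4g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$objective))
  print(data.frame(start = x$start, estimate = x$estimates), digits = 5)
  invisible(x)
}

#' Apportion enzyme-level fm values onto metabolic products
#'
#' For first-order parallel reactions on one enzyme the product split is
#' proportional to the intrinsic clearances, so an enzyme-level eliminated
#' fraction apportions onto its products as `fm * clint_i / sum(clint)`.
#'
#' @param drug `drug_parameters` with a reaction table.
#' @param fm_by_enzyme Named percentages per enzyme, e.g.
#'   `c(CYP3A4 = 71.6, CYP2C19 = 20.2)`.
#' @return `data.frame(enzyme, product, fraction_percent)` plus totals as
#'   attributes `to_m1`, `to_other`, `hepatic_total`.
#' @examples
#' drug <- load_drug_config(system.file("extdata", "tegoprazan.yaml",
#'                                      package = "tegopbpk"))
#' apportion_pathways(drug, c(CYP3A4 = 71.6, CYP2C19 = 20.2))
#' @export
apportion_pathways <- function(drug, fm_by_enzyme) {
  rx <- drug$reactions
  rows <- do.call(rbind, lapply(names(fm_by_enzyme), function(enz) {
    sub <- rx[rx$enzyme == enz, , drop = FALSE]
    if (!nrow(sub)) stop("no reactions for enzyme ", enz)
    data.frame(enzyme = enz, product = sub$product,
               fraction_percent = fm_by_enzyme[[enz]] * sub$clint /
                 sum(sub$clint))
  }))
  attr(rows, "to_m1") <- sum(rows$fraction_percent[rows$product == "M1"])
  attr(rows, "to_other") <- sum(rows$fraction_percent[rows$product == "other"])
  attr(rows, "hepatic_total") <- sum(rows$fraction_percent)
  rows
}

#' Analytic enzyme-abundance ratio implied by an fm split
#'
#' Within one organ the eliminated-fraction ratio between two enzymes
#' equals the ratio of their (abundance x total intrinsic clearance)
#' products, so the abundance ratio required to apportion `fm1 : fm2` is
#' `(fm1/fm2) * (clint_sum2/clint_sum1)`.
#'
#' @param fm1,fm2 Target eliminated fractions (% of dose) of the two
#'   enzymes.
#' @param clint_sum1,clint_sum2 Summed intrinsic clearances
#'   (uL/min/pmol) of the two enzymes.
#' @return Abundance ratio enzyme1 : enzyme2.
#' @examples
#' enzyme_abundance_ratio(71.6, 20.2, 0.2453, 0.3341)  # ~4.83
#' @export
enzyme_abundance_ratio <- function(fm1, fm2, clint_sum1, clint_sum2) {
  if (fm1 < 0 || fm2 <= 0 || clint_sum1 <= 0 || clint_sum2 <= 0)
    stop("fm and clint sums must be positive")
  (fm1 / fm2) * (clint_sum2 / clint_sum1)
}

#' Calibrate enzyme abundances to a target fm split
#'
#' Finds hepatic CYP3A4 and CYP2C19 reference concentrations (the gut
#' CYP3A4 concentration keeps its fixed expression ratio to the liver)
#' such that the simulated terminal mass balance of a single oral dose
#' apportions the stated percentages of the dose to each enzyme, with the
#' renal pathway taking up the eliminated remainder.  Fixed-point
#' iteration on the pathway odds against renal excretion; each iteration
#' is one mass-balance simulation.
#'
#' @param drug,metabolite `drug_parameters`.
#' @param individual Physiology whose enzyme table is calibrated.
#' @param fm_targets Named percentages, e.g. `c(CYP3A4 = 71.6, CYP2C19 =
#'   20.2)`; must sum to < 100 with a positive renal remainder.
#' @param renal_share Renal percentage completing the split (default: the
#'   remainder to 100).  Because a printed split need not sum exactly to
#'   100, the three entries are interpreted as relative shares of total
#'   elimination and normalised internally.
#' @param dose_mg Calibration dose.
#' @param t_end Mass-balance horizon (h), >= 7 half-lives.
#' @param tol Convergence tolerance on the fm percentages (points).
#' @param max_iter Iteration cap.
#' @param options [solver_options()].
#' @return The input `individual` with a calibrated enzyme table;
#'   attributes `fm_achieved` and `iterations`.
#' @export
calibrate_enzyme_abundance <- function(drug, metabolite,
                                       individual = build_reference_individual(),
                                       fm_targets = c(CYP3A4 = 71.6,
                                                      CYP2C19 = 20.2),
                                       renal_share = NULL,
                                       dose_mg = 50, t_end = 168,
                                       tol = 0.02, max_iter = 25,
                                       options = solver_options()) {
  if (any(fm_targets < 0) || any(fm_targets >= 100) ||
      sum(fm_targets) >= 100)
    stop("fm targets must lie in [0, 100) and sum to < 100")
  if (is.null(renal_share)) renal_share <- 100 - sum(fm_targets)
  if (renal_share <= 0) stop("renal share must be positive")
  # relative shares of total elimination
  tshare <- 100 * c(fm_targets, renal = renal_share) /
    (sum(fm_targets) + renal_share)
  s3 <- reaction_clint(drug, "CYP3A4", "M1") +
    reaction_clint(drug, "CYP3A4", "other")
  s2 <- reaction_clint(drug, "CYP2C19", "M1") +
    reaction_clint(drug, "CYP2C19", "other")
  if ((fm_targets[["CYP3A4"]] > 0 && s3 <= 0) ||
      (fm_targets[["CYP2C19"]] > 0 && s2 <= 0))
    stop("infeasible fm target: no intrinsic clearance for that enzyme")
  enz <- individual$enzymes
  reg <- oral_regimen(dose_mg, 1, 24, fed = FALSE)
  it <- 0
  repeat {
    it <- it + 1
    ind <- individual; ind$enzymes <- enz
    sim <- simulate_pbpk(drug, metabolite, ind, reg, t_end = t_end,
                         options = options)
    mb <- mass_balance(sim, warn_incomplete = FALSE)
    eliminated <- mb$cyp3a4 + mb$cyp2c19 + mb$renal
    achieved <- 100 * c(CYP3A4 = mb$cyp3a4, CYP2C19 = mb$cyp2c19,
                        renal = mb$renal) / eliminated
    if (max(abs(achieved - tshare)) < tol || it >= max_iter) break
    # odds against the renal pathway drive the multiplicative update
    share_ren <- max(achieved[["renal"]], 1e-9)
    for (enzyme in names(fm_targets)) {
      tgt <- tshare[[enzyme]]
      cur <- max(achieved[[enzyme]], 1e-9)
      fac <- if (tgt == 0) 0 else (tgt / tshare[["renal"]]) / (cur / share_ren)
      rows <- enz$enzyme == enzyme
      enz$reference_concentration[rows] <-
        enz$reference_concentration[rows] * fac
    }
  }
  if (max(abs(achieved - tshare)) >= tol)
    warning("enzyme-abundance calibration did not reach tolerance")
  out <- individual; out$enzymes <- enz
  attr(out, "fm_achieved") <- achieved
  attr(out, "fm_renal") <- mb$renal
  attr(out, "iterations") <- it
  out
}

#' Local sensitivity of exposure to model parameters
#'
#' Normalised sensitivity coefficients
#' `(dAUC/AUC) / (dp/p)` by central differences around the current
#' parameter values, for the AUC (to `t_end`, effectively AUC_inf for an
#' adequate horizon) of the parent or the metabolite after a single oral
#' dose.
#'
#' @param drug,metabolite `drug_parameters`.
#' @param parameters Parameter paths (see [get_drug_parameter()];
#'   `"metabolite:"` prefix addresses the metabolite).
#' @param perturbation Relative perturbation in (0, 0.5].
#' @param output `"parent"` or `"metabolite"` AUC.
#' @param dose_mg,fed Single-dose regimen for the analysis.
#' @param t_end Simulation horizon (h).
#' @param individual Physiology.
#' @param options [solver_options()].
#' @return `data.frame(parameter, coefficient, perturbation)` sorted by
#'   decreasing `|coefficient|` (class `sensitivity_result`); entries
#'   whose perturbed simulation failed carry `NA` and a flag.
#' @export
local_sensitivity <- function(drug, metabolite, parameters,
                              perturbation = 0.1,
                              output = c("parent", "metabolite"),
                              dose_mg = 50, fed = FALSE, t_end = 96,
                              individual = build_reference_individual(),
                              options = solver_options(rtol = 1e-8, atol = 1e-10)) {
  output <- match.arg(output)
  if (perturbation <= 0 || perturbation > 0.5)
    stop("perturbation must lie in (0, 0.5]")
  reg <- oral_regimen(dose_mg, 1, 24, fed = fed)
  auc_of <- function(d, m) {
    sim <- simulate_pbpk(d, m, individual, reg, t_end = t_end,
                         options = options)
    analyte <- if (output == "parent") d$name else m$name
    auc_linlog(sim$conc$time_h, sim$conc[[analyte]])
  }
  base <- auc_of(drug, metabolite)
  rows <- lapply(parameters, function(p) {
    coef <- tryCatch({
      v0 <- if (startsWith(p, "metabolite:"))
        get_drug_parameter(metabolite, sub("^metabolite:", "", p))
      else get_drug_parameter(drug, p)
      up <- apply_paths(drug, metabolite, p, v0 * (1 + perturbation))
      dn <- apply_paths(drug, metabolite, p, v0 * (1 - perturbation))
      (auc_of(up$drug, up$metabolite) - auc_of(dn$drug, dn$metabolite)) /
        base / (2 * perturbation)
    }, error = function(e) NA_real_)
    data.frame(parameter = p, coefficient = coef,
               perturbation = perturbation,
               failed = is.na(coef))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
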