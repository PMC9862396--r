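#' @title Compound parameters, ISEF correction, ionization and partitioning
#' @name drug_model
NULL

#' Construct a compound parameter set
#'
#' @param name Compound label.
#' @param molecular_weight g/mol, > 0.
#' @param logP Octanol--water log partition coefficient.
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param solubility_mg_per_L Aqueous solubility (diagnostic only; the
#'   dissolution model is the Weibull specification).
#' @param pka List of `list(value=, type=)` entries, type `"base"` or
#'   `"acid"`.
#' @param specific_intestinal_permeability_cm_s Transcellular intestinal
#'   permeability (cm/s) driving luminal uptake.
#' @param specific_organ_permeability_cm_s Organ permeability, carried for
#'   completeness; inert under the default perfusion-limited distribution.
#' @param renal_plasma_clearance_mL_min_kg Renal plasma clearance
#'   (parent).
#' @param total_hepatic_plasma_clearance_mL_min_kg Lumped hepatic plasma
#'   clearance (metabolite only).
#' @param reactions `data.frame(enzyme, product, clint)` with clint in
#'   uL/min/pmol recombinant enzyme.
#' @param dissolution List with `fasted` and/or `fed` entries, each
#'   `list(t50_h=, shape=)`.
#' @param extra Free-form list kept on the object (e.g. in-vitro
#'   provenance).
#' @return Object of class `drug_parameters`.
#' @export
drug_parameters <- function(name, molecular_weight, logP, fu_plasma,
                            solubility_mg_per_L = NA_real_,
                            pka = list(),
                            specific_intestinal_permeability_cm_s = NA_real_,
                            specific_organ_permeability_cm_s = NA_real_,
                            renal_plasma_clearance_mL_min_kg = 0,
                            total_hepatic_plasma_clearance_mL_min_kg = 0,
                            reactions = empty_reactions(),
                            dissolution = list(),
                            extra = list()) {
  drug <- structure(list(
    name = name,
    molecular_weight = molecular_weight,
    logP = logP,
    fu_plasma = fu_plasma,
    solubility_mg_per_L = solubility_mg_per_L,
    pka = pka,
    specific_intestinal_permeability_cm_s = specific_intestinal_permeability_cm_s,
    specific_organ_permeability_cm_s = specific_organ_permeability_cm_s,
    renal_plasma_clearance_mL_min_kg = renal_plasma_clearance_mL_min_kg,
    total_hepatic_plasma_clearance_mL_min_kg = total_hepatic_plasma_clearance_mL_min_kg,
    reactions = reactions,
    dissolution = dissolution,
    extra = extra), class = "drug_parameters")
  validate_drug_parameters(drug)
  drug
}

empty_reactions <- function() {
  data.frame(enzyme = character(), product = character(),
             clint = numeric(), stringsAsFactors = FALSE)
}

validate_drug_parameters <- function(drug) {
  stopifnot(inherits(drug, "drug_parameters"))
  if (!is.numeric(drug$molecular_weight) || drug$molecular_weight <= 0)
    stop("molecular_weight must be > 0")
  if (drug$fu_plasma <= 0 || drug$fu_plasma > 1)
    stop("fu_plasma must lie in (0, 1]")
  if (drug$renal_plasma_clearance_mL_min_kg < 0 ||
      drug$total_hepatic_plasma_clearance_mL_min_kg < 0)
    stop("clearances must be >= 0")
  rx <- drug$reactions
  if (nrow(rx)) {
    if (!all(rx$enzyme %in% c("CYP3A4", "CYP2C19")))
      stop("reaction enzyme must be CYP3A4 or CYP2C19")
    if (!all(rx$product %in% c("M1", "other")))
      stop("reaction product must be 'M1' or 'other'")
    if (any(rx$clint < 0)) stop("reaction clint must be >= 0")
  }
  for (d in drug$dissolution) {
    if (d$t50_h <= 0 || d$shape <= 0)
      stop("dissolution t50 and shape must be > 0")
  }
  invisible(drug)
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters> %s: MW %.2f, logP %.2f, fu %.3f, %d reaction(s)\n",
              x$name, x$molecular_weight, x$logP, x$fu_plasma,
              nrow(x$reactions)))
  invisible(x)
}

# Pull a clint value by enzyme/product; 0 if the reaction is absent.
reaction_clint <- function(drug, enzyme, product) {
  rx <- drug$reactions
  hit <- rx$enzyme == enzyme & rx$product == product
  if (!any(hit)) return(0)
  rx$clint[hit][1]
}

#' Intersystem extrapolation factor correction
#'
#' Rescales a recombinant-enzyme intrinsic clearance to the human liver
#' microsome scale: `clint_hlm = clint_rcyp * isef`.
#'
#' @param clint_rcyp Intrinsic clearance in the recombinant system
#'   (uL/min/pmol), >= 0.
#' @param isef Intersystem extrapolation factor, >= 0.
#' @return Corrected intrinsic clearance (uL/min/pmol).
#' @examples
#' isef_correct(0.614, 0.25)  # 0.1535
#' @export
isef_correct <- function(clint_rcyp, isef) {
  if (any(clint_rcyp < 0) || any(isef < 0))
    stop("clint_rcyp and isef must be >= 0")
  clint_rcyp * isef
}

#' Henderson--Hasselbalch fraction ionized
#'
#' For a base the ionized (protonated) fraction is
#' `1 / (1 + 10^(pH - pKa))`; for an acid it is `1 / (1 + 10^(pKa - pH))`.
#' Used for solubility diagnostics; the dissolution model itself is the
#' fitted Weibull specification.
#'
#' @param pH Ambient pH in `[0, 14]`.
#' @param pka Dissociation constant.
#' @param type `"base"` or `"acid"`.
#' @return Fraction ionized in `[0, 1]`.
#' @examples
#' ionization_fraction(5.2, 5.2, "base")  # 0.5
#' @export
ionization_fraction <- function(pH, pka, type = c("base", "acid")) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  type <- match.arg(type)
  if (type == "base") 1 / (1 + 10^(pH - pka)) else 1 / (1 + 10^(pka - pH))
}

#' Tissue-to-plasma partition coefficients
#'
#' Predicts one Kp per organ from lipophilicity, plasma protein binding
#' and bundled tissue composition, using a published tissue-composition
#' method.  `"poulin-theil"` applies the neutral-lipid/phospholipid/water
#' partitioning equation with a tissue unbound fraction estimated from
#' plasma binding (adipose uses the unbound-plasma form).
#' `"berezhkovskiy"` is the variant that applies the plasma unbound
#' fraction uniformly.  Blood pools (arterial, venous) have Kp 1 by
#' definition.  Per-organ overrides may be supplied.
#'
#' @param drug `drug_parameters`.
#' @param individual `individual` (organ set; composition comes from the
#'   bundled composition table).
#' @param method `"poulin-theil"` (default) or `"berezhkovskiy"`.
#' @param overrides Optional named vector of organ -> Kp replacing the
#'   computed values.
#' @return Named numeric vector of positive Kp values in engine organ
#'   order, with attribute `method`.
#' @export
partition_coefficients <- function(drug, individual,
                                   method = c("poulin-theil", "berezhkovskiy"),
                                   overrides = NULL) {
  method <- match.arg(method)
  validate_drug_parameters(drug)
  comp <- read_tissue_composition()
  P <- 10^drug$logP
  fu <- drug$fu_plasma
  pl <- comp[comp$organ == "plasma", ]
  den <- P * pl$f_neutral_lipid + (0.3 * P + 0.7) * pl$f_phospholipid +
    pl$f_water
  fu_t <- 1 / (1 + 0.5 * (1 - fu) / fu)   # tissue binding at half plasma strength
  kp <- vapply(ORGAN_ORDER, function(org) {
    if (org %in% c("arterial", "venous")) return(1)
    row <- comp[comp$organ == org, ]
    if (!nrow(row)) stop("no composition entry for organ ", org)
    num <- P * row$f_neutral_lipid + (0.3 * P + 0.7) * row$f_phospholipid +
      row$f_water
    ratio <- num / den
    if (method == "berezhkovskiy") ratio * fu
    else if (org == "adipose") ratio * fu       # adipose: fu_tissue ~ 1
    else ratio * fu / fu_t
  }, numeric(1))
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(kp))
    if (length(bad)) stop("Kp override for unknown organ: ",
                          paste(bad, collapse = ", "))
    kp[names(overrides)] <- overrides
  }
  if (any(kp <= 0)) stop("partition coefficients must be positive")
  attr(kp, "method") <- method
  kp
}
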