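#' @title Virtual-individual physiology
#' @description Builders for the reference adult physiology consumed by the
#'   ODE engine: organ volumes, blood flows, tissue composition, enzyme
#'   expression, and log-normal population sampling.
#' @name physiology
NULL

# Canonical organ order used throughout the engine (C and R right-hand
# sides index organs by position, so this order is load-bearing).
ORGAN_ORDER <- c("adipose", "bone", "brain", "heart", "kidney", "muscle",
                 "skin", "rest", "gut", "spleen", "liver", "lung",
                 "arterial", "venous")

# Reference body weight (kg) of the bundled physiology table.  It is the
# weight implied by the renal plasma clearance conversion used for
# tegoprazan (0.297 mL/min/kg corresponding to 1.31 L/h).
REFERENCE_WEIGHT_KG <- 73.5

tp_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tegopbpk")
  if (!nzchar(path)) stop("bundled resource not found: ", file)
  path
}

read_physiology_table <- function(path = tp_extdata("physiology_reference.tsv")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(ORGAN_ORDER, tab$organ)
  if (length(missing)) stop("physiology table lacks organs: ",
                            paste(missing, collapse = ", "))
  tab[match(ORGAN_ORDER, tab$organ), , drop = FALSE]
}

read_tissue_composition <- function(path = tp_extdata("tissue_composition.tsv")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

default_enzyme_table <- function(path = tp_extdata("enzymes.yaml")) {
  cfg <- yaml::read_yaml(path)
  rows <- lapply(cfg$enzymes, function(e) {
    data.frame(enzyme = e$enzyme, organ = e$organ,
               reference_concentration = e$reference_concentration_umol_L,
               relative_expression = e$relative_expression,
               kdeg = e$kdeg_per_h, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  validate_enzyme_table(tab)
  tab
}

validate_enzyme_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (any(tab$reference_concentration < 0))
    stop("enzyme reference_concentration must be >= 0")
  if (any(tab$kdeg <= 0)) stop("enzyme kdeg must be > 0")
  if (!all(tab$enzyme %in% c("CYP3A4", "CYP2C19")))
    stop("unknown enzyme in expression table")
  invisible(tab)
}

#' Build a virtual individual scaled from the bundled reference adult
#'
#' Organ volumes scale linearly with body weight; blood flows (and cardiac
#' output) scale allometrically with weight^0.75.  Enzyme tissue
#' concentrations are weight-invariant, so total enzyme amounts scale with
#' organ volume.
#'
#' @param weight Body weight in kg (20--200).
#' @param sex `"male"` or `"female"` (label only; the bundled reference is
#'   a male table).
#' @param age Age in years (label only).
#' @param enzymes Enzyme-expression table; defaults to the bundled,
#'   mass-balance-calibrated abundances.
#' @param physiology Optional replacement physiology table (same layout as
#'   the bundled `physiology_reference.tsv`).
#' @return An object of class `individual`: organ table (`organs`),
#'   `cardiac_output` (L/h), enzyme table, demographic fields, and
#'   multiplier slots used by population sampling.
#' @examples
#' ind <- build_reference_individual()
#' sum(ind$organs$flow_L_per_h[!ind$organs$organ %in% c("lung", "arterial", "venous")])
#' ind$cardiac_output
#' @export
build_reference_individual <- function(weight = REFERENCE_WEIGHT_KG,
                                       sex = "male", age = 30,
                                       enzymes = default_enzyme_table(),
                                       physiology = NULL) {
  if (!is.numeric(weight) || length(weight) != 1 || is.na(weight) ||
      weight < 20 || weight > 200)
    stop("weight must be a single value in [20, 200] kg")
  tab <- if (is.null(physiology)) read_physiology_table() else physiology
  sv <- weight / REFERENCE_WEIGHT_KG        # volume scale
  sq <- sv^0.75                             # flow scale
  organs <- data.frame(
    organ = tab$organ,
    volume_L = tab$volume_L * sv,
    flow_L_per_h = tab$flow_L_per_h * sq,
    water_fraction = tab$water_fraction,
    lipid_fraction = tab$lipid_fraction,
    protein_fraction = tab$protein_fraction,
    stringsAsFactors = FALSE)
  co <- organs$flow_L_per_h[organs$organ == "lung"]
  # Force exact flow conservation: the 'rest' organ absorbs rounding.
  non_lung <- !organs$organ %in% c("lung", "arterial", "venous")
  drift <- co - sum(organs$flow_L_per_h[non_lung])
  organs$flow_L_per_h[organs$organ == "rest"] <-
    organs$flow_L_per_h[organs$organ == "rest"] + drift
  ind <- structure(list(
    sex = sex, age = age, weight = weight,
    bmi = weight / 1.75^2,
    organs = organs,
    cardiac_output = co,
    enzymes = enzymes,
    multipliers = c(cyp3a4_abundance = 1, cyp2c19_abundance = 1,
                    cardiac_output = 1, fu_plasma = 1)),
    class = "individual")
  validate_individual(ind)
  ind
}

validate_individual <- function(ind) {
  stopifnot(inherits(ind, "individual"))
  org <- ind$organs
  if (any(org$volume_L <= 0)) stop("organ volumes must be positive")
  if (any(org$flow_L_per_h < 0)) stop("organ blood flows must be non-negative")
  fr <- c(org$water_fraction, org$lipid_fraction, org$protein_fraction)
  if (any(fr < 0 | fr > 1)) stop("composition fractions must lie in [0, 1]")
  non_lung <- !org$organ %in% c("lung", "arterial", "venous")
  rel <- abs(sum(org$flow_L_per_h[non_lung]) - ind$cardiac_output) /
    ind$cardiac_output
  if (rel > 1e-6) stop("organ flows do not conserve cardiac output")
  invisible(ind)
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> %s, %g y, %.1f kg, CO %.1f L/h, %d organs\n",
              x$sex, x$age, x$weight, x$cardiac_output, nrow(x$organs)))
  invisible(x)
}

#' Enzyme synthesis rate at turnover steady state
#'
#' The zero-order synthesis rate that balances first-order degradation so
#' that `dE/dt = Rsyn - kdeg * E` has steady state `E = reference
#' concentration`.
#'
#' @param reference_concentration Baseline enzyme concentration
#'   (umol enzyme / L tissue).
#' @param kdeg First-order degradation rate constant (1/h), > 0.
#' @return Synthesis rate in umol/L/h.
#' @examples
#' enzyme_baseline(4.0, 0.02)  # 0.08
#' @export
enzyme_baseline <- function(reference_concentration, kdeg) {
  if (any(reference_concentration < 0))
    stop("reference_concentration must be >= 0")
  if (any(!is.finite(kdeg)) || any(kdeg <= 0)) stop("kdeg must be > 0")
  reference_concentration * kdeg
}

#' Sample a virtual population with log-normal parameter variability
#'
#' Each entry of `variability` is a coefficient of variation applied as an
#' independent log-normal multiplier (geometric mean 1) to the matching
#' parameter.  Supported names: `weight`, `cardiac_output`,
#' `cyp3a4_abundance`, `cyp2c19_abundance`, `fu_plasma`.  The output is a
#' pure function of `(n, seed, variability)`.
#'
#' @param n Number of individuals (>= 1).
#' @param seed Integer RNG seed.
#' @param variability Named numeric vector of CVs (>= 0).
#' @param base Template individual (default: bundled reference adult).
#' @return List of `individual` objects.
#' @examples
#' pop <- sample_population(3, seed = 1, variability = c(weight = 0.1))
#' vapply(pop, function(i) i$weight, numeric(1))
#' @export
sample_population <- function(n, seed,
                              variability = c(cyp3a4_abundance = 0.3,
                                              cyp2c19_abundance = 0.3),
                              base = build_reference_individual()) {
  if (n < 1) stop("n must be >= 1")
  if (length(variability) && (is.null(names(variability)) ||
                              any(!nzchar(names(variability)))))
    stop("variability must be a named vector of CVs")
  if (any(variability < 0)) stop("negative CV in variability")
  allowed <- c("weight", "cardiac_output", "cyp3a4_abundance",
               "cyp2c19_abundance", "fu_plasma")
  bad <- setdiff(names(variability), allowed)
  if (length(bad)) stop("unsupported variability parameter(s): ",
                        paste(bad, collapse = ", "))
  with_preserved_seed({
    set.seed(as.integer(seed))
    lapply(seq_len(n), function(i) {
      ind <- base
      for (p in names(variability)) {
        cv <- variability[[p]]
        mult <- if (cv > 0) lognormal_multiplier(1, cv) else 1
        if (p == "weight") {
          ind <- build_reference_individual(weight = base$weight * mult,
                                            sex = base$sex, age = base$age,
                                            enzymes = base$enzymes)
        } else if (p == "cardiac_output") {
          sel <- ind$organs$organ != "arterial" & ind$organs$organ != "venous"
          ind$organs$flow_L_per_h[sel] <- ind$organs$flow_L_per_h[sel] * mult
          ind$cardiac_output <- ind$cardiac_output * mult
          ind$multipliers[["cardiac_output"]] <- mult
        } else {
          ind$multipliers[[p]] <- mult
        }
      }
      ind
    })
  })
}

# Log-normal multipliers with geometric mean 1 and coefficient of
# variation cv (sdlog^2 = log(1 + cv^2)).
lognormal_multiplier <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))
}

# Run code with the global RNG state restored afterwards, so that seeded
# package internals do not perturb the caller's random stream.
with_preserved_seed <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
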