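#' @title Configuration files, dataset I/O and provenance
#' @name cli_io
NULL

require_keys <- function(cfg, keys, path) {
  for (k in keys)
    if (is.null(cfg[[k]]))
      stop(sprintf("config %s: missing required key '%s'", path, k))
  invisible(cfg)
}

#' Load a compound configuration file
#'
#' Reads a YAML compound file (see the bundled `tegoprazan.yaml` /
#' `m1.yaml` under `inst/extdata`) into a validated `drug_parameters`
#' object.  Schema violations raise an error naming the offending key.
#'
#' @param path File path.
#' @return `drug_parameters`.
#' @export
load_drug_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  require_keys(cfg, c("name", "molecular_weight", "logP", "fu_plasma"), path)
  rx <- if (is.null(cfg$reactions)) empty_reactions() else
    do.call(rbind, lapply(cfg$reactions, function(r) {
      require_keys(r, c("enzyme", "product", "clint"), path)
      data.frame(enzyme = r$enzyme, product = r$product, clint = r$clint,
                 stringsAsFactors = FALSE)
    }))
  dis <- lapply(cfg$dissolution %||% list(), function(d) {
    require_keys(d, c("t50_h", "shape"), path)
    list(t50_h = d$t50_h, shape = d$shape)
  })
  drug <- drug_parameters(
    name = cfg$name,
    molecular_weight = cfg$molecular_weight,
    logP = cfg$logP,
    fu_plasma = cfg$fu_plasma,
    solubility_mg_per_L = cfg$solubility_mg_per_L %||% NA_real_,
    pka = cfg$pka %||% list(),
    specific_intestinal_permeability_cm_s =
      cfg$specific_intestinal_permeability_cm_s %||% NA_real_,
    specific_organ_permeability_cm_s =
      cfg$specific_organ_permeability_cm_s %||% NA_real_,
    renal_plasma_clearance_mL_min_kg =
      cfg$renal_plasma_clearance_mL_min_kg %||% 0,
    total_hepatic_plasma_clearance_mL_min_kg =
      cfg$total_hepatic_plasma_clearance_mL_min_kg %||% 0,
    reactions = rx,
    dissolution = dis,
    extra = cfg$in_vitro_reference %||% list())
  drug
}

#' Write a compound configuration file
#'
#' Inverse of [load_drug_config()]: the written file reloads to an object
#' whose numeric entries round-trip bit-exactly.
#'
#' @param drug `drug_parameters`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_config <- function(drug, path) {
  validate_drug_parameters(drug)
  cfg <- list(
    name = drug$name,
    molecular_weight = drug$molecular_weight,
    logP = drug$logP,
    fu_plasma = drug$fu_plasma)
  if (!is.na(drug$solubility_mg_per_L))
    cfg$solubility_mg_per_L <- drug$solubility_mg_per_L
  if (length(drug$pka)) cfg$pka <- drug$pka
  if (!is.na(drug$specific_intestinal_permeability_cm_s))
    cfg$specific_intestinal_permeability_cm_s <-
      drug$specific_intestinal_permeability_cm_s
  if (!is.na(drug$specific_organ_permeability_cm_s))
    cfg$specific_organ_permeability_cm_s <-
      drug$specific_organ_permeability_cm_s
  if (drug$renal_plasma_clearance_mL_min_kg > 0)
    cfg$renal_plasma_clearance_mL_min_kg <-
      drug$renal_plasma_clearance_mL_min_kg
  if (drug$total_hepatic_plasma_clearance_mL_min_kg > 0)
    cfg$total_hepatic_plasma_clearance_mL_min_kg <-
      drug$total_hepatic_plasma_clearance_mL_min_kg
  if (nrow(drug$reactions))
    cfg$reactions <- lapply(seq_len(nrow(drug$reactions)), function(i)
      list(enzyme = drug$reactions$enzyme[i],
           product = drug$reactions$product[i],
           clint = drug$reactions$clint[i]))
  if (length(drug$dissolution)) cfg$dissolution <- drug$dissolution
  if (length(drug$extra)) cfg$in_vitro_reference <- drug$extra
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Load a perpetrator configuration file
#'
#' @param path YAML file with a `mechanism` block (`mbi`: `KI_umol_L`,
#'   `kinact_per_h`; `induction`: `Emax`, `EC50_umol_L`) and
#'   `own_kinetics` (one-compartment parameters or a forcing table file).
#' @return `perpetrator_spec`.
#' @export
load_perpetrator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  require_keys(cfg, c("name", "mechanism", "own_kinetics"), path)
  own <- cfg$own_kinetics
  if (!is.null(own$forcing_table)) {
    own <- utils::read.delim(file.path(dirname(path), own$forcing_table))
  } else {
    require_keys(own, c("molecular_weight", "ka_per_h", "volume_L",
                        "clearance_L_per_h", "fu_plasma"), path)
  }
  if (cfg$mechanism == "mbi") {
    require_keys(cfg, c("KI_umol_L", "kinact_per_h"), path)
    perpetrator_spec(cfg$name, "mbi", KI = cfg$KI_umol_L,
                     kinact = cfg$kinact_per_h, own_kinetics = own)
  } else if (cfg$mechanism == "induction") {
    require_keys(cfg, c("Emax", "EC50_umol_L"), path)
    perpetrator_spec(cfg$name, "induction", Emax = cfg$Emax,
                     EC50 = cfg$EC50_umol_L, own_kinetics = own)
  } else stop(sprintf("config %s: unknown mechanism '%s'", path,
                      cfg$mechanism))
}

#' Read and write observed datasets
#'
#' Delimited text with columns `study_id`, `analyte`, `time_h`,
#' `conc_ng_mL`, `regimen`, `fed`; the dosing design is carried in
#' comment header lines so that a write/read round trip reproduces the
#' dataset exactly.
#'
#' @param ds `observed_dataset`.
#' @param path File path.
#' @return [write_observed_dataset()] returns `path` invisibly;
#'   [read_observed_dataset()] returns an `observed_dataset`.
#' @export
write_observed_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "observed_dataset"))
  des <- attr(ds, "design")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dose_mg: %.17g", des$dose_mg),
    sprintf("# n_doses: %d", des$n_doses),
    sprintf("# interval_h: %.17g", des$interval_h),
    sprintf("# fed: %s", des$fed),
    sprintf("# excluded_from_fit: %s", isTRUE(attr(ds, "excluded_from_fit")))),
    con)
  tab <- data.frame(study_id = ds$study_id, analyte = ds$analyte,
                    time_h = sprintf("%.17g", ds$records$time_h),
                    conc_ng_mL = sprintf("%.17g", ds$records$conc_ng_mL),
                    regimen = sprintf("%gmg x%d q%gh", des$dose_mg,
                                      des$n_doses, des$interval_h),
                    fed = ds$fed_state)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_observed_dataset
#' @export
read_observed_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  design <- list(dose_mg = as.numeric(pick("dose_mg")),
                 n_doses = as.integer(pick("n_doses")),
                 interval_h = as.numeric(pick("interval_h")),
                 fed = as.logical(pick("fed")))
  observed_dataset(tab$study_id[1], tab$analyte[1],
                   data.frame(time_h = tab$time_h,
                              conc_ng_mL = tab$conc_ng_mL),
                   design, fed_state = tab$fed[1],
                   excluded_from_fit = as.logical(pick("excluded_from_fit")))
}

#' Write a simulation result as delimited text
#'
#' Long-format table `time_h, analyte, plasma_ng_per_mL` plus a
#' pathway-amount table, both stamped with provenance (package version,
#' configuration hash).
#'
#' @param result `simulation_result`.
#' @param path Output path for the concentration table; the pathway table
#'   goes to `<path>.pathways`.
#' @param seed Seed to record in the provenance stamp.
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path, seed = NA) {
  stopifnot(inherits(result, "simulation_result"))
  analytes <- setdiff(names(result$conc), "time_h")
  long <- do.call(rbind, lapply(analytes, function(a)
    data.frame(time_h = result$conc$time_h, analyte = a,
               plasma_ng_per_mL = result$conc[[a]])))
  stamp <- provenance_stamp(result$parms, seed)
  for (p in c(path, paste0(path, ".pathways"))) {
    con <- file(p, "w")
    writeLines(sprintf("# %s: %s", names(stamp), unlist(stamp)), con)
    utils::write.table(if (p == path) long else result$pathways, con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    close(con)
  }
  invisible(path)
}

provenance_stamp <- function(object, seed = NA) {
  list(package = "tegopbpk",
       version = as.character(utils::packageVersion("tegopbpk")),
       config_hash = rlang::hash(object),
       seed = seed)
}

#' Load a pipeline configuration
#'
#' A pipeline config ties together compound, perpetrator and physiology
#' files plus solver settings and seeds.  Every referenced file must
#' exist at load time; defaults are applied for absent optional keys and
#' reported in the `defaults_applied` attribute.
#'
#' @param path YAML pipeline configuration.
#' @return List of loaded components (class `pipeline_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  require_keys(cfg, "drug", path)
  base <- dirname(path)
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  defaults <- character()
  getd <- function(key, default) {
    if (is.null(cfg[[key]])) {
      defaults <<- c(defaults, key)
      default
    } else cfg[[key]]
  }
  drug <- load_drug_config(resolve(cfg$drug))
  metabolite <- if (!is.null(cfg$metabolite))
    load_drug_config(resolve(cfg$metabolite)) else NULL
  perpetrator <- if (!is.null(cfg$perpetrator))
    load_perpetrator_config(resolve(cfg$perpetrator)) else NULL
  out <- structure(list(
    drug = drug, metabolite = metabolite, perpetrator = perpetrator,
    individual = build_reference_individual(
      weight = getd("weight_kg", REFERENCE_WEIGHT_KG)),
    seed = getd("seed", 20230104),
    solver = do.call(solver_options, getd("solver", list())),
    output_dir = getd("output_dir", ".")),
    class = "pipeline_config")
  attr(out, "defaults_applied") <- defaults
  out
}
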