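#' @title Synthetic clinical-study generator
#' @description Generates observed-like concentration-time datasets with
#'   known ground truth, emulating the kind of digitized clinical corpus
#'   (mean profiles over an extensive dose range, single and repeated
#'   dosing, fasted and fed arms) against which the model is developed and
#'   evaluated.
#' @name synthetic_data
NULL

#' Describe a synthetic study design
#'
#' @param dose_mg Dose per administration (50--400 mg modelled range).
#' @param n_doses,interval_h Repeated-dosing pattern.
#' @param fed Logical fed state (fed doses come with a meal event).
#' @param n_subjects Number of virtual subjects contributing to the mean
#'   profile.
#' @param sampling_times Sampling times (h) relative to the last dose for
#'   repeated dosing, absolute for a single dose; dense early sampling
#'   resolves Cmax.
#' @param residual_cv Proportional (log-normal) residual error CV.
#' @param lloq Lower limit of quantification (ng/mL); mean concentrations
#'   below it are censored (dropped, with the count recorded).
#' @param seed Study-level RNG seed.
#' @param variability Named CVs passed to [sample_population()].
#' @return Object of class `study_design`.
#' @export
study_design <- function(dose_mg, n_doses = 1, interval_h = 24, fed = FALSE,
                         n_subjects = 12,
                         sampling_times = c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6,
                                            8, 12, 24),
                         residual_cv = 0.2, lloq = 1, seed = 1,
                         variability = c(cyp3a4_abundance = 0.3,
                                         cyp2c19_abundance = 0.3)) {
  if (dose_mg < 25 || dose_mg > 800)
    stop("dose outside the simulable range")
  if (residual_cv < 0) stop("residual_cv must be >= 0")
  if (is.unsorted(sampling_times)) stop("sampling times must be sorted")
  structure(list(dose_mg = dose_mg, n_doses = n_doses,
                 interval_h = interval_h, fed = fed,
                 n_subjects = n_subjects, sampling_times = sampling_times,
                 residual_cv = residual_cv, lloq = lloq,
                 seed = as.integer(seed), variability = variability),
            class = "study_design")
}

#' Construct an observed dataset
#'
#' The container mirrors the delimited-text exchange format: one analyte,
#' sorted nonnegative sampling times, concentrations in ng/mL, with the
#' generating design attached as attributes.
#'
#' @param study_id Study label.
#' @param analyte Analyte name.
#' @param records `data.frame(time_h, conc_ng_mL)`.
#' @param design `study_design` (or a compatible list with `dose_mg`,
#'   `n_doses`, `interval_h`, `fed`).
#' @param fed_state `"fasted"` or `"fed"`.
#' @param excluded_from_fit Flag honoured by [fit()] (e.g. the metabolite
#'   arm of a DDI-layout study).
#' @return Object of class `observed_dataset`.
#' @export
observed_dataset <- function(study_id, analyte, records, design,
                             fed_state = if (isTRUE(design$fed)) "fed" else "fasted",
                             excluded_from_fit = FALSE) {
  stopifnot(all(c("time_h", "conc_ng_mL") %in% names(records)))
  if (any(records$time_h < 0)) stop("sampling times must be >= 0")
  if (is.unsorted(records$time_h)) stop("records must be sorted by time")
  if (any(records$conc_ng_mL < 0)) stop("concentrations must be >= 0")
  ds <- structure(list(study_id = study_id, analyte = analyte,
                       fed_state = fed_state,
                       records = records, m = nrow(records)),
                  class = "observed_dataset")
  attr(ds, "design") <- design
  attr(ds, "excluded_from_fit") <- excluded_from_fit
  ds
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat(sprintf("<observed_dataset> %s / %s (%s), m = %d\n",
              x$study_id, x$analyte, x$fed_state, x$m))
  invisible(x)
}

#' Generate one synthetic study
#'
#' Simulates per-subject profiles for a design (physiology sampled with
#' the design's variability), applies multiplicative log-normal residual
#' error with the design CV to each subject's samples, averages across
#' subjects into the study-mean profile, and censors mean concentrations
#' below the LLOQ.  Output is deterministic per seed, and the generating
#' truth is stored alongside the data.
#'
#' @param drug,metabolite Generating `drug_parameters` (the ground
#'   truth).
#' @param design `study_design`.
#' @param individual Template physiology.
#' @param perpetrator,perpetrator_regimen Optional co-administered
#'   perpetrator, for DDI-layout studies.
#' @param study_id Label (default derived from the design).
#' @param options [solver_options()].
#' @return Object of class `synthetic_study`: `datasets` (one
#'   `observed_dataset` per analyte), `truth` (generating parameters,
#'   design, individuals), `censored` counts.
#' @export
generate_study <- function(drug, metabolite, design,
                           individual = build_reference_individual(),
                           perpetrator = NULL, perpetrator_regimen = NULL,
                           study_id = NULL,
                           options = solver_options(rtol = 1e-6, atol = 1e-9)) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(study_id))
    study_id <- sprintf("SYN-%03dmg-x%d-%s", design$dose_mg, design$n_doses,
                        if (design$fed) "fed" else "fasted")
  pop <- sample_population(design$n_subjects, design$seed,
                           variability = design$variability,
                           base = individual)
  reg <- oral_regimen(design$dose_mg, design$n_doses, design$interval_h,
                      design$fed)
  offset <- (design$n_doses - 1) * design$interval_h
  times <- offset + design$sampling_times
  t_end <- max(times) + 1
  analytes <- c(drug$name, if (!is.null(metabolite)) metabolite$name)
  profiles <- lapply(pop, function(ind) {
    sim <- simulate_pbpk(drug, metabolite, ind, reg, t_end = t_end,
                         perpetrator = perpetrator,
                         perpetrator_regimen = perpetrator_regimen,
                         options = modifyList(options, list(
                           dt = 0.25, extra_times = times)))
    vapply(analytes, function(a)
      stats::approx(sim$conc$time_h, sim$conc[[a]], xout = times)$y,
      numeric(length(times)))
  })
  censored <- stats::setNames(integer(length(analytes)), analytes)
  datasets <- list()
  with_preserved_seed({
    set.seed(design$seed + 1L)
    for (a in analytes) {
      mat <- vapply(profiles, function(m) m[, a], numeric(length(times)))
      mat <- matrix(mat, nrow = length(times))
      if (design$residual_cv > 0) {
        noise <- matrix(lognormal_multiplier(length(mat), design$residual_cv),
                        nrow = nrow(mat))
        mat <- mat * noise
      }
      mean_conc <- rowMeans(mat)
      keep <- mean_conc >= design$lloq
      censored[[a]] <- sum(!keep)
      rec <- data.frame(time_h = design$sampling_times[keep],
                        conc_ng_mL = mean_conc[keep])
      datasets[[a]] <- observed_dataset(study_id, a, rec, design)
    }
  })
  structure(list(study_id = study_id, datasets = datasets,
                 truth = list(drug = drug, metabolite = metabolite,
                              design = design, individual = individual),
                 censored = censored),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s: %s\n", x$study_id,
              paste(names(x$datasets), collapse = ", ")))
  invisible(x)
}

#' Emulate the full training/test study corpus
#'
#' Builds 19 synthetic studies spanning 50--400 mg, single and repeated
#' dosing, fasted and fed arms, partitioned into 10 training and 9 test
#' studies.  One training study follows a DDI layout (victim dosed twice
#' daily with a co-administered CYP3A4 inactivator); its metabolite
#' dataset is flagged `excluded_from_fit`, mirroring the exclusion rule
#' applied to such arms during model development.
#'
#' @param drug,metabolite Generating `drug_parameters`.
#' @param seed Suite-level seed; per-study seeds are derived from it.
#' @param individual Template physiology.
#' @param n_subjects Subjects per study.
#' @param residual_cv Residual error CV shared by all studies.
#' @param options [solver_options()].
#' @return List of 19 `synthetic_study` objects, each with a `role`
#'   attribute `"training"` or `"test"`.
#' @export
emulate_training_suite <- function(drug, metabolite, seed = 20230104,
                                   individual = build_reference_individual(),
                                   n_subjects = 12, residual_cv = 0.2,
                                   options = solver_options(rtol = 1e-6,
                                                            atol = 1e-9)) {
  single <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
  multi <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)
  plans <- list(
    list(dose = 50,  n = 1, tau = 24, fed = FALSE, role = "training"),
    list(dose = 100, n = 1, tau = 24, fed = FALSE, role = "training"),
    list(dose = 200, n = 1, tau = 24, fed = FALSE, role = "training"),
    list(dose = 400, n = 1, tau = 24, fed = FALSE, role = "training"),
    list(dose = 50,  n = 1, tau = 24, fed = TRUE,  role = "training"),
    list(dose = 100, n = 1, tau = 24, fed = TRUE,  role = "training"),
    list(dose = 50,  n = 7, tau = 24, fed = FALSE, role = "training"),
    list(dose = 100, n = 7, tau = 24, fed = FALSE, role = "training"),
    list(dose = 50,  n = 10, tau = 12, fed = FALSE, role = "training",
         ddi = TRUE),
    list(dose = 200, n = 5, tau = 24, fed = TRUE,  role = "training"),
    list(dose = 50,  n = 1, tau = 24, fed = FALSE, role = "test"),
    list(dose = 100, n = 1, tau = 24, fed = FALSE, role = "test"),
    list(dose = 200, n = 1, tau = 24, fed = FALSE, role = "test"),
    list(dose = 400, n = 1, tau = 24, fed = FALSE, role = "test"),
    list(dose = 50,  n = 5, tau = 24, fed = TRUE,  role = "test"),
    list(dose = 100, n = 5, tau = 12, fed = FALSE, role = "test"),
    list(dose = 100, n = 7, tau = 24, fed = TRUE,  role = "test"),
    list(dose = 200, n = 1, tau = 24, fed = TRUE,  role = "test"),
    list(dose = 400, n = 3, tau = 24, fed = FALSE, role = "test"))
  clari <- load_perpetrator_config(tp_extdata("clarithromycin.yaml"))
  studies <- lapply(seq_along(plans), function(i) {
    pl <- plans[[i]]
    des <- study_design(pl$dose, pl$n, pl$tau, pl$fed,
                        n_subjects = n_subjects,
                        sampling_times = if (pl$n == 1) single else multi,
                        residual_cv = residual_cv,
                        seed = (as.integer(seed) + 7L * i) %% .Machine$integer.max)
    if (isTRUE(pl$ddi)) {
      n_perp <- ceiling(pl$n * pl$tau / 8) + 1
      st <- generate_study(drug, metabolite, des,
                           individual = individual,
                           perpetrator = clari,
                           perpetrator_regimen = oral_regimen(500, n_perp, 8),
                           study_id = sprintf("SYN-%02d-DDI", i),
                           options = options)
      if (!is.null(metabolite))
        attr(st$datasets[[metabolite$name]], "excluded_from_fit") <- TRUE
      st$ddi_layout <- TRUE
      st
    } else {
      st <- generate_study(drug, metabolite, des, individual = individual,
                           study_id = sprintf("SYN-%02d", i),
                           options = options)
      st$ddi_layout <- FALSE
      st
    }
  })
  for (i in seq_along(studies)) attr(studies[[i]], "role") <- plans[[i]]$role
  studies
}
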