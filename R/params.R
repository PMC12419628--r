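# Model parameters, condition description, scenario configuration, parameter
# ranges. A scenario plus a seed fully determines a run.

# Metadata for the 30 sensitivity parameters. `kind` drives validation:
#   prob    -- in [0, 1]
#   nonneg  -- >= 0
#   pos     -- > 0
#   ge1     -- >= 1
# `integer` fields must additionally be integral (and >= 1 where kind is ge1).
.param_meta <- function() {
  data.frame(
    name = c(
      "encounter_period",
      "encounter_aware_determiner",
      "patient_activate_determiner",
      "patient_dispirit_determiner",
      "patient_network_edges",
      "patient_influence_across_prop",
      "patient_influence_become_aware_probability",
      "patient_influence_activation_probability",
      "clinician_network_edges",
      "clinician_influence_across_prop",
      "clinician_influence_become_aware_probability",
      "clinician_influence_activation_probability",
      "clinician_dispirit_probability",
      "shared_knowledge_initial",
      "shared_knowledge_half_life",
      "patient_shared_knowledge_contrib_determiner",
      "clinician_shared_knowledge_contrib_determiner",
      "enhanced_registry_initial_per_patient",
      "enhanced_registry_analysis_period",
      "enhanced_registry_record_per_commons_item",
      "potential_phenotype_response_info_from_sk_unit",
      "phenotype_realization_numeric",
      "patient_response_info_half_life",
      "patient_response_info_increase_numeric",
      "patient_response_info_acceleration_from_sk_unit",
      "maximal_patient_response_info_acceleration_from_sk",
      "selection_efficiency_maximum",
      "evaluation_accuracy_minimum_praxis",
      "patient_engagement_degree_participating",
      "clinician_engagement_degree_participating"),
    kind = c(
      "ge1", "prob", "prob", "prob",
      "nonneg", "prob", "prob", "prob",
      "nonneg", "prob", "prob", "prob", "prob",
      "nonneg", "pos", "prob", "prob",
      "nonneg", "ge1", "pos",
      "nonneg", "prob", "pos", "prob", "nonneg", "nonneg",
      "ge1", "prob", "prob", "prob"),
    integer = c(
      TRUE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      TRUE, FALSE, FALSE, FALSE,
      TRUE, TRUE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Names of the 30 model parameters
#'
#' The sensitivity parameters of the LHN model, in their canonical order.
#'
#' @return Character vector of length 30.
#' @export
param_names <- function() .param_meta()$name

#' Default parameter ranges
#'
#' The packaged sampling ranges used for sensitivity analysis, solution-space
#' grids, and (through their midpoints) the default model parameters.
#' Probabilities and fractions span \[0, 1\]; half-lives span 4--260 steps
#' (one month to five years at a weekly step); selection efficiency spans
#' 10--1000 and the zero-praxis misjudgment probability 0.001--0.2, the spans
#' exercised by the factorial intervention experiment. All ranges can be
#' overridden via a YAML ranges file (see [load_ranges()]).
#'
#' @return A named list of ranges; each element has `lower`, `upper`,
#'   `dist` (`"uniform"` or `"triangle"`) and, for triangle ranges, `mode`.
#' @export
default_ranges <- function() {
  rng <- function(lo, hi) list(lower = lo, upper = hi, dist = "uniform")
  r <- list(
    encounter_period = rng(11, 13),
    encounter_aware_determiner = rng(0, 1),
    patient_activate_determiner = rng(0, 0.3),
    patient_dispirit_determiner = rng(0, 0.2),
    patient_network_edges = rng(0, 10),
    patient_influence_across_prop = rng(0, 1),
    patient_influence_become_aware_probability = rng(0, 0.3),
    patient_influence_activation_probability = rng(0, 1),
    clinician_network_edges = rng(1, 7),
    clinician_influence_across_prop = rng(0, 1),
    clinician_influence_become_aware_probability = rng(0, 0.15),
    clinician_influence_activation_probability = rng(0, 0.6),
    clinician_dispirit_probability = rng(0, 0.1),
    shared_knowledge_initial = rng(0, 50),
    shared_knowledge_half_life = rng(52, 208),
    patient_shared_knowledge_contrib_determiner = rng(0.08, 0.18),
    clinician_shared_knowledge_contrib_determiner = rng(0.09, 0.16),
    enhanced_registry_initial_per_patient = rng(0, 10),
    enhanced_registry_analysis_period = rng(6, 18),
    enhanced_registry_record_per_commons_item = rng(18, 30),
    potential_phenotype_response_info_from_sk_unit = rng(0, 0.1),
    phenotype_realization_numeric = rng(0, 1),
    patient_response_info_half_life = rng(13, 130),
    patient_response_info_increase_numeric = rng(0.05, 0.5),
    patient_response_info_acceleration_from_sk_unit = rng(0, 0.05),
    maximal_patient_response_info_acceleration_from_sk = rng(0, 2),
    selection_efficiency_maximum = rng(10, 1000),
    evaluation_accuracy_minimum_praxis = rng(0.001, 0.2),
    patient_engagement_degree_participating = rng(0, 1),
    clinician_engagement_degree_participating = rng(0, 1))
  stopifnot(identical(names(r), param_names()))
  r
}

#' Load parameter ranges from a YAML file
#'
#' @param path Path to a YAML file mapping parameter names to
#'   `lower`/`upper` (and optionally `dist`, `mode`) entries. Entries not
#'   present fall back to [default_ranges()].
#' @return A named list of ranges (same shape as [default_ranges()]).
#' @export
load_ranges <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_ranges()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown parameter(s) in ranges file: ",
         paste(unknown, collapse = ", "))
  for (nm in names(raw)) {
    e <- raw[[nm]]
    bad <- setdiff(names(e), c("lower", "upper", "dist", "mode"))
    if (length(bad))
      stop("unknown key(s) in range '", nm, "': ", paste(bad, collapse = ", "))
    base[[nm]][names(e)] <- e
    if (is.null(base[[nm]]$dist)) base[[nm]]$dist <- "uniform"
  }
  validate_ranges(base)
}

validate_ranges <- function(ranges) {
  missing <- setdiff(param_names(), names(ranges))
  if (length(missing))
    stop("missing range(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(ranges), param_names())
  if (length(extra))
    stop("unknown range name(s): ", paste(extra, collapse = ", "))
  if (anyDuplicated(names(ranges)))
    stop("duplicate range names")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r$lower) || !is.numeric(r$upper) || r$lower >= r$upper)
      stop("range '", nm, "': lower must be < upper")
    if (!r$dist %in% c("uniform", "triangle"))
      stop("range '", nm, "': dist must be 'uniform' or 'triangle'")
    if (r$dist == "triangle") {
      if (is.null(r$mode) || r$mode < r$lower || r$mode > r$upper)
        stop("range '", nm, "': triangle mode must lie in [lower, upper]")
    }
  }
  ranges[param_names()]
}

#' Midpoint parameter set
#'
#' Every parameter set to the midpoint `(lower + upper) / 2` of its range
#' (for triangle ranges too: the midpoint of the support, not the mode),
#' with integer-valued parameters rounded to the nearest integer. This is
#' the baseline used when exploring the solution space along two parameters
#' with all others held constant.
#'
#' @param ranges A ranges list as returned by [default_ranges()].
#' @return An `lhn_params` object.
#' @export
midpoint_params <- function(ranges = default_ranges()) {
  ranges <- validate_ranges(ranges)
  meta <- .param_meta()
  vals <- lapply(seq_len(nrow(meta)), function(i) {
    r <- ranges[[meta$name[i]]]
    m <- (r$lower + r$upper) / 2
    if (meta$integer[i]) round(m) else m
  })
  names(vals) <- meta$name
  do.call(lhn_params, vals)
}

#' Construct a model parameter set
#'
#' All 30 model parameters, defaulting to the midpoints of the packaged
#' ranges ([default_ranges()]). Probabilities with "annual" semantics
#' (peer influence, clinician burnout) are converted internally to per-step
#' rates with [annual_to_step_probability()].
#'
#' @param ... Named parameter overrides; names must be parameter names.
#' @return An `lhn_params` object (a validated named list).
#' @export
lhn_params <- function(...) {
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all parameters must be named")
  unknown <- setdiff(names(dots), param_names())
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(names(dots)))
    stop("duplicate parameter(s): ",
         paste(unique(names(dots)[duplicated(names(dots))]), collapse = ", "))
  p <- .midpoint_defaults()
  p[names(dots)] <- lapply(dots, as.numeric)
  structure(p, class = "lhn_params")
}

# Midpoints of default_ranges(), hand-evaluated once to avoid constructor
# recursion; consistency with midpoint_params() is asserted in the tests.
.midpoint_defaults <- function() {
  list(
    encounter_period = 12,
    encounter_aware_determiner = 0.5,
    patient_activate_determiner = 0.15,
    patient_dispirit_determiner = 0.1,
    patient_network_edges = 5,
    patient_influence_across_prop = 0.5,
    patient_influence_become_aware_probability = 0.15,
    patient_influence_activation_probability = 0.5,
    clinician_network_edges = 4,
    clinician_influence_across_prop = 0.5,
    clinician_influence_become_aware_probability = 0.075,
    clinician_influence_activation_probability = 0.3,
    clinician_dispirit_probability = 0.05,
    shared_knowledge_initial = 25,
    shared_knowledge_half_life = 130,
    patient_shared_knowledge_contrib_determiner = 0.13,
    clinician_shared_knowledge_contrib_determiner = 0.125,
    enhanced_registry_initial_per_patient = 5,
    enhanced_registry_analysis_period = 12,
    enhanced_registry_record_per_commons_item = 24,
    potential_phenotype_response_info_from_sk_unit = 0.05,
    phenotype_realization_numeric = 0.5,
    patient_response_info_half_life = 71.5,
    patient_response_info_increase_numeric = 0.275,
    patient_response_info_acceleration_from_sk_unit = 0.025,
    maximal_patient_response_info_acceleration_from_sk = 1,
    selection_efficiency_maximum = 505,
    evaluation_accuracy_minimum_praxis = 0.1005,
    patient_engagement_degree_participating = 0.5,
    clinician_engagement_degree_participating = 0.5)
}

#' Construct a condition description
#'
#' The health-condition constants held fixed in the sensitivity analysis:
#' phenotype/treatment structure and the health-status dynamics (pull toward
#' the current treatment's target, natural-history drift, relapse, noise).
#' Defaults give a mean treatment target of 0.5, so that uninformed random
#' treatment selection is approximately health-neutral while good (poor)
#' selection moves the cohort up (down).
#'
#' @param n_phenotypes Number of patient phenotypes (integer >= 1).
#' @param n_treatments Number of available treatments (integer >= 2).
#' @param responsiveness_kappa Per-step pull of health toward the current
#'   treatment's target, in (0, 1\].
#' @param natural_history_drift Signed per-step health drift.
#' @param relapse_probability Per-step relapse probability in \[0, 1\].
#' @param relapse_magnitude Health lost at a relapse, in \[0, 1\].
#' @param variability_sd SD of per-step Gaussian health noise (>= 0).
#' @param best_target,worst_target Health targets of the best- and
#'   worst-matched treatment, in \[0, 1\], `best_target > worst_target`.
#' @param improvement_tolerance Decline tolerated over an encounter period
#'   before the treatment is judged as not working (health units, >= 0).
#' @return An `lhn_condition` object.
#' @export
lhn_condition <- function(n_phenotypes = 4,
                          n_treatments = 5,
                          responsiveness_kappa = 0.05,
                          natural_history_drift = 0,
                          relapse_probability = 0.0555,
                          relapse_magnitude = 0.15,
                          variability_sd = 0.01,
                          best_target = 0.85,
                          worst_target = 0.25,
                          improvement_tolerance = 0.08) {
  structure(list(
    n_phenotypes = n_phenotypes,
    n_treatments = n_treatments,
    responsiveness_kappa = responsiveness_kappa,
    natural_history_drift = natural_history_drift,
    relapse_probability = relapse_probability,
    relapse_magnitude = relapse_magnitude,
    variability_sd = variability_sd,
    best_target = best_target,
    worst_target = worst_target,
    improvement_tolerance = improvement_tolerance), class = "lhn_condition")
}

.validate_condition <- function(cond) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cond$n_phenotypes >= 1 && cond$n_phenotypes == round(cond$n_phenotypes),
      sprintf("n_phenotypes: must be an integer >= 1 (got %s)", cond$n_phenotypes))
  chk(cond$n_treatments >= 2 && cond$n_treatments == round(cond$n_treatments),
      sprintf("n_treatments: must be an integer >= 2 (got %s)", cond$n_treatments))
  chk(cond$responsiveness_kappa >= 0 && cond$responsiveness_kappa <= 1,
      sprintf("responsiveness_kappa: must be in [0, 1] (got %s)", cond$responsiveness_kappa))
  chk(cond$relapse_probability >= 0 && cond$relapse_probability <= 1,
      sprintf("relapse_probability: must be in [0, 1] (got %s)", cond$relapse_probability))
  chk(cond$relapse_magnitude >= 0 && cond$relapse_magnitude <= 1,
      sprintf("relapse_magnitude: must be in [0, 1] (got %s)", cond$relapse_magnitude))
  chk(cond$variability_sd >= 0,
      sprintf("variability_sd: must be >= 0 (got %s)", cond$variability_sd))
  chk(cond$improvement_tolerance >= 0,
      sprintf("improvement_tolerance: must be >= 0 (got %s)", cond$improvement_tolerance))
  chk(cond$best_target >= 0 && cond$best_target <= 1 &&
      cond$worst_target >= 0 && cond$worst_target <= 1 &&
      cond$best_target > cond$worst_target,
      sprintf("best_target/worst_target: need 0 <= worst < best <= 1 (got %s, %s)",
              cond$best_target, cond$worst_target))
  errs
}

#' Validate a model parameter set
#'
#' Checks every field invariant (probabilities in \[0, 1\], half-lives
#' positive, `selection_efficiency_maximum >= 1`, integer fields integral)
#' and reports *all* violations at once, each naming the offending field and
#' value.
#'
#' @param params An `lhn_params` object.
#' @param condition Optionally, an `lhn_condition` to validate alongside.
#' @return `params`, invisibly unchanged, if everything holds.
#' @export
validate_params <- function(params, condition = NULL) {
  meta <- .param_meta()
  errs <- character()
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      errs <- c(errs, sprintf("%s: must be a single finite number", nm))
      next
    }
    ok <- switch(meta$kind[i],
      prob = v >= 0 && v <= 1,
      nonneg = v >= 0,
      pos = v > 0,
      ge1 = v >= 1)
    if (!ok) {
      bound <- switch(meta$kind[i],
        prob = "in [0, 1]", nonneg = ">= 0", pos = "> 0", ge1 = ">= 1")
      errs <- c(errs, sprintf("%s: must be %s (got %s)", nm, bound, v))
    }
    if (meta$integer[i] && is.finite(v) && v != round(v))
      errs <- c(errs, sprintf("%s: must be an integer (got %s)", nm, v))
  }
  if (!is.null(condition)) errs <- c(errs, .validate_condition(condition))
  if (length(errs))
    stop("invalid parameters:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(params)
}

.levels3 <- c("low", "medium", "high")

#' Construct a scenario configuration
#'
#' The single source of truth for a run: model parameters, condition
#' description, cohort layout, time horizon, per-care-center intervention
#' levels, initial engagement seeding, cohort-exit rules, and the seed.
#'
#' @param params An `lhn_params` object.
#' @param condition An `lhn_condition` object.
#' @param n_care_centers,clinicians_per_center,patients_per_clinician Cohort
#'   layout (all >= 1). Defaults: 4 x 5 x 10 = 200 patients.
#' @param horizon_steps Number of simulated steps (weekly steps; 260 = 5
#'   years). `0` yields only the baseline metrics row.
#' @param steps_per_year Steps per year used to convert annual probabilities.
#' @param pvp_level,er_level Pre-visit-planning and enhanced-registry level
#'   per care center: `"low"`, `"medium"` or `"high"`; a scalar is recycled
#'   to all centers.
#' @param closed_cohort If `TRUE` (default, and the setting of all reference
#'   experiments) no patient enters or leaves.
#' @param seed_engagement Initial engagement seeding: list with
#'   `patient_frac`, `clinician_frac`, `patient_level` and
#'   `clinician_level`, and `patient_owning_frac` (a small nucleus of
#'   founding patients at 'owning'). Seeded clinicians default to founding
#'   champions at 'owning'; seeded patients to 'participating'. All other
#'   agents start unaware.
#' @param initial_iri_max Upper bound of the uniform initial individual
#'   response information patients bring from pre-enrollment illness
#'   experience (0 disables the endowment).
#' @param exit_rules Config-gated cohort-exit thresholds; disabled by
#'   default (closed cohort).
#' @param seed Integer RNG seed for the run.
#' @return An `lhn_scenario` object.
#' @export
lhn_scenario <- function(params = lhn_params(),
                         condition = lhn_condition(),
                         n_care_centers = 4,
                         clinicians_per_center = 5,
                         patients_per_clinician = 10,
                         horizon_steps = 260,
                         steps_per_year = 52,
                         pvp_level = "high",
                         er_level = "medium",
                         closed_cohort = TRUE,
                         seed_engagement = list(patient_frac = 0.12,
                                                clinician_frac = 0.30,
                                                patient_level = "participating",
                                                clinician_level = "owning",
                                                patient_owning_frac = 0.03),
                         initial_iri_max = 0.4,
                         exit_rules = list(enabled = FALSE,
                                           upper = 0.95,
                                           lower = 0.05,
                                           consecutive = 8,
                                           annual_exit_probability = 0),
                         seed = 1L) {
  scn <- structure(list(
    params = params,
    condition = condition,
    n_care_centers = n_care_centers,
    clinicians_per_center = clinicians_per_center,
    patients_per_clinician = patients_per_clinician,
    horizon_steps = horizon_steps,
    steps_per_year = steps_per_year,
    pvp_level = pvp_level,
    er_level = er_level,
    closed_cohort = closed_cohort,
    seed_engagement = seed_engagement,
    initial_iri_max = initial_iri_max,
    exit_rules = exit_rules,
    seed = seed), class = "lhn_scenario")
  validate_scenario(scn)
}

#' Validate a scenario configuration
#'
#' @param scn An `lhn_scenario` object.
#' @return The scenario, with intervention levels recycled per center.
#' @export
validate_scenario <- function(scn) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  for (f in c("n_care_centers", "clinicians_per_center", "patients_per_clinician"))
    chk(is.numeric(scn[[f]]) && scn[[f]] >= 1 && scn[[f]] == round(scn[[f]]),
        sprintf("%s: must be an integer >= 1 (got %s)", f, scn[[f]]))
  chk(is.numeric(scn$horizon_steps) && scn$horizon_steps >= 0 &&
      scn$horizon_steps == round(scn$horizon_steps),
      sprintf("horizon_steps: must be an integer >= 0 (got %s)", scn$horizon_steps))
  chk(is.numeric(scn$steps_per_year) && scn$steps_per_year >= 1,
      sprintf("steps_per_year: must be >= 1 (got %s)", scn$steps_per_year))
  nc <- scn$n_care_centers
  for (f in c("pvp_level", "er_level")) {
    lv <- scn[[f]]
    if (length(lv) == 1) lv <- rep(lv, nc)
    chk(length(lv) == nc && all(lv %in% .levels3),
        sprintf("%s: must be low/medium/high, scalar or one per care center", f))
    scn[[f]] <- lv
  }
  se <- scn$seed_engagement
  lvl_ok <- function(x) isTRUE(x %in% c("unaware", "aware", "participating",
                                        "contributing", "owning"))
  chk(is.list(se) && all(c("patient_frac", "clinician_frac", "patient_level",
                           "clinician_level") %in% names(se)) &&
      se$patient_frac >= 0 && se$patient_frac <= 1 &&
      se$clinician_frac >= 0 && se$clinician_frac <= 1 &&
      lvl_ok(se$patient_level) && lvl_ok(se$clinician_level) &&
      !is.null(se$patient_owning_frac) &&
      se$patient_owning_frac >= 0 && se$patient_owning_frac <= 1,
      "seed_engagement: needs fractions in [0,1] and valid levels")
  chk(is.numeric(scn$initial_iri_max) && scn$initial_iri_max >= 0 &&
      scn$initial_iri_max <= 1,
      sprintf("initial_iri_max: must be in [0, 1] (got %s)", scn$initial_iri_max))
  chk(is.numeric(scn$seed) && length(scn$seed) == 1 && is.finite(scn$seed),
      "seed: must be a single finite number")
  if (length(errs))
    stop("invalid scenario:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  validate_params(scn$params, scn$condition)
  scn
}

# ---- scenario I/O ----------------------------------------------------------

.scenario_to_list <- function(scn) {
  list(
    params = unclass(scn$params),
    condition = unclass(scn$condition),
    n_care_centers = scn$n_care_centers,
    clinicians_per_center = scn$clinicians_per_center,
    patients_per_clinician = scn$patients_per_clinician,
    horizon_steps = scn$horizon_steps,
    steps_per_year = scn$steps_per_year,
    pvp_level = scn$pvp_level,
    er_level = scn$er_level,
    closed_cohort = scn$closed_cohort,
    seed_engagement = scn$seed_engagement,
    initial_iri_max = scn$initial_iri_max,
    exit_rules = scn$exit_rules,
    seed = scn$seed)
}

#' Write a scenario configuration to YAML
#'
#' @param scn An `lhn_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  scn <- validate_scenario(scn)
  yaml::write_yaml(.scenario_to_list(scn), path, precision = 15)
  invisible(path)
}

#' Load a scenario configuration from YAML or JSON
#'
#' Unspecified keys take the packaged defaults; unknown keys are rejected
#' (typo protection) with their full key path.
#'
#' @param path Path to a YAML (or JSON) scenario file, or a YAML string.
#' @return An `lhn_scenario` object.
#' @export
load_scenario <- function(path) {
  raw <- if (is.character(path) && length(path) == 1 &&
             !file.exists(path) && grepl("[:\n]", path)) {
    yaml::yaml.load(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  base <- lhn_scenario()
  top_known <- names(.scenario_to_list(base))
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  merge_block <- function(cur, new, path) {
    bad <- setdiff(names(new), names(cur))
    if (length(bad))
      stop("unknown scenario key(s): ",
           paste(paste0(path, ".", bad), collapse = ", "))
    for (nm in names(new)) {
      if (!is.numeric(new[[nm]]) && !is.character(new[[nm]]) &&
          !is.logical(new[[nm]]))
        stop("bad type at key ", path, ".", nm)
      cur[[nm]] <- new[[nm]]
    }
    cur
  }
  scn <- base
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm %in% c("params", "condition", "seed_engagement", "exit_rules")) {
      scn[[nm]][] <- merge_block(unclass(scn[[nm]]), v, nm)
    } else {
      scn[[nm]] <- v
    }
  }
  validate_scenario(scn)
}

#' @export
print.lhn_scenario <- function(x, ...) {
  cat(sprintf(
    "<lhn_scenario> %d centers x %d clinicians x %d patients, horizon %d steps, seed %s\n",
    x$n_care_centers, x$clinicians_per_center, x$patients_per_clinician,
    x$horizon_steps, format(x$seed)))
  cat("  pvp:", paste(x$pvp_level, collapse = "/"),
      " er:", paste(x$er_level, collapse = "/"), "\n")
  invisible(x)
}

#' @export
print.lhn_params <- function(x, ...) {
  cat("<lhn_params>\n")
  for (nm in names(x)) cat(sprintf("  %-52s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
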