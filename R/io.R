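# Output writing (CSV/JSON), run manifests, and the miniature single-
# mechanism fixture scenarios used by the test suite.

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the standard outputs of a run
#'
#' Writes `timeseries.csv` (one row per step), `outcomes.json` and
#' `manifest.json` (scenario echo, seed, package version, file inventory
#' with MD5 checksums) into `dir`.
#'
#' @param run An `lhn_run` from [simulate_lhn()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "lhn_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- file.path(dir, "timeseries.csv")
  oc <- file.path(dir, "outcomes.json")
  .write_csv(run$metrics, ts)
  jsonlite::write_json(unclass(run$outcomes), oc, auto_unbox = TRUE,
                       digits = NA)
  files <- c(ts, oc)
  manifest <- list(
    scenario = .scenario_to_list(run$scenario),
    seed = run$seed,
    package = "lhnsim",
    version = as.character(utils::packageVersion("lhnsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Write a sensitivity experiment to CSV
#'
#' `design.csv` (LHS rows joined with outcomes) and `prcc.csv`
#' (parameter, outcome, coefficient and, when available, CI bounds).
#'
#' @param sens An `lhn_sensitivity` from [run_sensitivity()].
#' @param dir Output directory.
#' @return Files written, invisibly.
#' @export
write_sensitivity_outputs <- function(sens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- sens$outcomes$row
  design <- cbind(sens$design[ok, , drop = FALSE], sens$outcomes)
  f1 <- .write_csv(design, file.path(dir, "design.csv"))
  pr <- do.call(rbind, lapply(names(sens$prcc), function(oc) {
    d <- sens$prcc[[oc]]
    d$outcome <- oc
    d
  }))
  f2 <- .write_csv(pr, file.path(dir, "prcc.csv"))
  invisible(c(f1, f2))
}

#' Miniature single-mechanism fixture scenarios
#'
#' Each fixture freezes all but one mechanism so tests can check it against
#' a closed-form or replayable oracle:
#' * `"frozen"` -- every probability, drift, noise and gain zero: nothing
#'   may change over the whole run.
#' * `"two-patient"` -- one center, one clinician, two patients; minimal
#'   encounter bookkeeping.
#' * `"contagion-star"` -- peer influence only (no encounters within the
#'   horizon, health dynamics frozen).
#' * `"commons-only"` -- contributions only: every agent seeded at owning,
#'   engagement transitions and health dynamics frozen, so commons items
#'   are a pure Bernoulli process over encounters.
#'
#' @param kind Fixture name.
#' @param seed Scenario seed.
#' @param dir If non-`NULL`, the scenario is also written there as
#'   `<kind>.yaml`.
#' @return An `lhn_scenario`.
#' @export
make_fixtures <- function(kind = c("frozen", "two-patient", "contagion-star",
                                   "commons-only"),
                          seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  frozen_params <- lhn_params(
    encounter_period = 5,
    encounter_aware_determiner = 0, patient_activate_determiner = 0,
    patient_dispirit_determiner = 0,
    patient_network_edges = 0, clinician_network_edges = 0,
    patient_influence_across_prop = 0, clinician_influence_across_prop = 0,
    patient_influence_become_aware_probability = 0,
    patient_influence_activation_probability = 0,
    clinician_influence_become_aware_probability = 0,
    clinician_influence_activation_probability = 0,
    clinician_dispirit_probability = 0,
    shared_knowledge_initial = 0, shared_knowledge_half_life = 10,
    patient_shared_knowledge_contrib_determiner = 0,
    clinician_shared_knowledge_contrib_determiner = 0,
    enhanced_registry_initial_per_patient = 0,
    enhanced_registry_analysis_period = 10,
    enhanced_registry_record_per_commons_item = 10,
    potential_phenotype_response_info_from_sk_unit = 0,
    phenotype_realization_numeric = 0,
    patient_response_info_half_life = 10,
    patient_response_info_increase_numeric = 0,
    patient_response_info_acceleration_from_sk_unit = 0,
    maximal_patient_response_info_acceleration_from_sk = 0,
    selection_efficiency_maximum = 1,
    evaluation_accuracy_minimum_praxis = 0,
    patient_engagement_degree_participating = 0,
    clinician_engagement_degree_participating = 0)
  frozen_condition <- lhn_condition(
    responsiveness_kappa = 0, natural_history_drift = 0,
    relapse_probability = 0, relapse_magnitude = 0, variability_sd = 0)
  no_seeding <- list(patient_frac = 0, clinician_frac = 0,
                     patient_level = "owning", clinician_level = "owning",
                     patient_owning_frac = 0)
  scn <- switch(kind,
    "frozen" = lhn_scenario(
      params = frozen_params, condition = frozen_condition,
      n_care_centers = 2, clinicians_per_center = 2,
      patients_per_clinician = 5, horizon_steps = 52,
      pvp_level = "low", er_level = "low",
      seed_engagement = no_seeding, initial_iri_max = 0, seed = seed),
    "two-patient" = lhn_scenario(
      params = frozen_params, condition = frozen_condition,
      n_care_centers = 1, clinicians_per_center = 1,
      patients_per_clinician = 2, horizon_steps = 20,
      pvp_level = "high", er_level = "low",
      seed_engagement = no_seeding, initial_iri_max = 0, seed = seed),
    "contagion-star" = {
      p <- frozen_params
      p$patient_network_edges <- 2
      p$patient_influence_become_aware_probability <- 0.5
      p$encounter_period <- 1000  # no encounters within the horizon
      lhn_scenario(
        params = p, condition = frozen_condition,
        n_care_centers = 1, clinicians_per_center = 2,
        patients_per_clinician = 25, horizon_steps = 52,
        pvp_level = "low", er_level = "low",
        seed_engagement = list(patient_frac = 0.02, clinician_frac = 0,
                               patient_level = "owning",
                               clinician_level = "owning",
                               patient_owning_frac = 0),
        initial_iri_max = 0, seed = seed)
    },
    "commons-only" = {
      p <- frozen_params
      p$patient_shared_knowledge_contrib_determiner <- 1
      p$clinician_shared_knowledge_contrib_determiner <- 1
      lhn_scenario(
        params = p, condition = frozen_condition,
        n_care_centers = 1, clinicians_per_center = 2,
        patients_per_clinician = 5, horizon_steps = 50,
        pvp_level = "low", er_level = "low",
        seed_engagement = list(patient_frac = 1, clinician_frac = 1,
                               patient_level = "owning",
                               clinician_level = "owning",
                               patient_owning_frac = 0),
        initial_iri_max = 0, seed = seed)
    })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_scenario(scn, file.path(dir, paste0(kind, ".yaml")))
  }
  scn
}
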