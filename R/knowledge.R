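# The knowledge commons, the enhanced registry, the information stocks
# (phenotype response information PRI, individual response information IRI),
# engagement-gated access, pre-visit-planning caps, and praxis.
#
# The commons is a pool of exchangeable knowledge items whose usefulness
# decays exponentially; its effective stock S(t) = sum_i 2^(-(t - t_i)/hl)
# is maintained incrementally (decay the stock each step, add new items at
# age zero).

#' Pre-visit-planning cap
#'
#' PVP constrains the effectiveness of individual and phenotype response
#' information: the cap is the maximum usable fraction of each.
#'
#' @param pvp_level `"low"`, `"medium"` or `"high"` (vectorized).
#' @return Cap in \[0, 1\]: low 0.2, medium 0.5, high 1.0.
#' @export
pvp_cap <- function(pvp_level) {
  caps <- c(low = 0.2, medium = 0.5, high = 1.0)
  bad <- !pvp_level %in% names(caps)
  if (any(bad))
    stop("unknown PVP level(s): ", paste(unique(pvp_level[bad]), collapse = ", "))
  unname(caps[pvp_level])
}

#' Decay an exponentially aging stock
#'
#' @param S Stock (>= 0).
#' @param half_life Half-life in steps (> 0).
#' @param dt Elapsed steps (>= 0).
#' @return `S * 2^(-dt / half_life)`.
#' @export
decay_stock <- function(S, half_life, dt) {
  stopifnot(all(S >= 0), half_life > 0, dt >= 0)
  S * 2^(-dt / half_life)
}

#' Knowledge contribution at an encounter
#'
#' An agent at level contributing or owning adds one item to the commons
#' with probability `contrib_determiner`; less engaged agents contribute
#' nothing. Vectorized over agents.
#'
#' @param level Engagement level(s) 0..4.
#' @param contrib_determiner Per-encounter contribution probability.
#' @return Integer item count(s), 0 or 1 per agent.
#' @export
contribute_knowledge <- function(level, contrib_determiner) {
  n <- length(level)
  as.integer(level >= 3L & stats::runif(n) < contrib_determiner)
}

#' Engagement-gated information access fraction
#'
#' Fraction of available response information an agent can access, anchored
#' at the 'participating' level by the degree parameter `d`:
#' unaware 0, aware `0.25 d`, participating `d`, contributing
#' `min(1, 1.5 d)`, owning `min(1, 2 d)`.
#'
#' @param level Engagement level(s) 0..4.
#' @param degree_participating Access fraction at 'participating', in \[0, 1\].
#' @return Access fraction(s) in \[0, 1\].
#' @export
access_fraction <- function(level, degree_participating) {
  d <- degree_participating
  mult <- c(0, 0.25, 1, 1.5, 2)[level + 1L]
  pmin(1, mult * d)
}

#' Enhanced-registry boost of clinician access at the encounter
#'
#' At ER level `"high"`, clinical data are available in real time at the
#' encounter, substituting for engagement-gated retrieval: effective
#' clinician access is floored at the 'participating' degree. Other levels
#' leave access unchanged.
#'
#' @param er_level `"low"`, `"medium"` or `"high"` (vectorized).
#' @param clinician_access Engagement-gated access fraction(s).
#' @param degree_participating Clinician access degree at 'participating'.
#' @return Effective clinician access fraction(s).
#' @export
er_encounter_boost <- function(er_level, clinician_access, degree_participating) {
  ifelse(er_level == "high", pmax(clinician_access, degree_participating),
         clinician_access)
}

#' Update phenotype response information at an encounter
#'
#' Accessible knowledge is `A = S * phenotype_realization * mean(access)`;
#' the encounter closes a fraction `g = 1 - exp(-u * A)` of the remaining
#' PRI gap: `PRI' = 1 - (1 - PRI) (1 - g)`. Monotone, bounded in
#' \[PRI, 1\]; PRI has no intrinsic decay (phenotype knowledge ages only
#' through the commons stock).
#'
#' @param pri Current PRI in \[0, 1\] (vectorized).
#' @param S Commons effective stock.
#' @param phenotype_realization Fraction of commons knowledge applicable to
#'   any one phenotype.
#' @param u PRI gain rate per unit of accessible shared knowledge.
#' @param mean_access Mean of patient and clinician access fractions.
#' @return Updated PRI.
#' @export
update_pri <- function(pri, S, phenotype_realization, u, mean_access) {
  A <- S * phenotype_realization * mean_access
  g <- 1 - exp(-u * A)
  1 - (1 - pri) * (1 - g)
}

#' Update individual response information
#'
#' IRI decays every step with half-life `patient_response_info_half_life`.
#' At an encounter it additionally gains
#' `delta * (1 + a) * mean_access`, capped at 1, where
#' `a = min(max_accel, accel_per_unit * S)` is the shared-knowledge
#' acceleration. The gain is scaled by the patient/clinician mean access
#' fraction: individual response information is coproduced, so how much of
#' it is actually captured depends on both parties' engagement.
#'
#' @param iri Current IRI in \[0, 1\] (vectorized).
#' @param S Commons effective stock.
#' @param params An `lhn_params`.
#' @param at_encounter Logical: apply the encounter increment?
#' @param dt Steps of decay to apply (0 for none).
#' @param mean_access Mean access fraction (used only at encounters).
#' @return Updated IRI.
#' @export
update_iri <- function(iri, S, params, at_encounter = FALSE, dt = 0,
                       mean_access = 1) {
  if (dt > 0)
    iri <- iri * 2^(-dt / params$patient_response_info_half_life)
  if (at_encounter) {
    a <- min(params$maximal_patient_response_info_acceleration_from_sk,
             params$patient_response_info_acceleration_from_sk_unit * S)
    iri <- pmin(1, iri + params$patient_response_info_increase_numeric *
                  (1 + a) * mean_access)
  }
  iri
}

#' Compute praxis
#'
#' Praxis -- the knowledge actually available for treatment decision making
#' -- is the equal-weight mean of the capped information stocks:
#' `PRI_eff = min(PRI * mean_access, pvp_cap)`,
#' `IRI_eff = min(IRI, pvp_cap)`,
#' `praxis = 0.5 PRI_eff + 0.5 IRI_eff`, clipped to \[0, 1\].
#'
#' @param pri,iri Information stocks in \[0, 1\] (vectorized).
#' @param mean_access Mean patient/clinician access fraction.
#' @param cap Pre-visit-planning cap ([pvp_cap()]).
#' @param weight_pri Weight of the PRI component (default 0.5).
#' @return Praxis in \[0, 1\].
#' @export
compute_praxis <- function(pri, iri, mean_access, cap, weight_pri = 0.5) {
  pri_eff <- pmin(pri * mean_access, cap)
  iri_eff <- pmin(iri, cap)
  pmin(1, pmax(0, weight_pri * pri_eff + (1 - weight_pri) * iri_eff))
}

#' Registry accumulation / analysis step
#'
#' Care centers at ER level medium or high upload one record per clinical
#' encounter. When the analysis countdown reaches zero, the records
#' accumulated since the last analysis are converted to
#' `floor(records / enhanced_registry_record_per_commons_item)` commons
#' items and the counter resets. ER level low uploads nothing and produces
#' nothing.
#'
#' @param registry List with `er_level`, `record_count`,
#'   `records_since_last_analysis`, `steps_until_analysis`.
#' @param encounters_this_step Number of encounters at this center.
#' @param params An `lhn_params`.
#' @return List with updated `registry` and `items` produced this step.
#' @export
registry_step <- function(registry, encounters_this_step, params) {
  items <- 0L
  if (registry$er_level %in% c("medium", "high")) {
    registry$record_count <- registry$record_count + encounters_this_step
    registry$records_since_last_analysis <-
      registry$records_since_last_analysis + encounters_this_step
  }
  registry$steps_until_analysis <- registry$steps_until_analysis - 1L
  if (registry$steps_until_analysis <= 0L) {
    if (registry$er_level %in% c("medium", "high")) {
      items <- as.integer(floor(registry$records_since_last_analysis /
                                  params$enhanced_registry_record_per_commons_item))
    }
    registry$records_since_last_analysis <- 0
    registry$steps_until_analysis <- as.integer(params$enhanced_registry_analysis_period)
  }
  list(registry = registry, items = items)
}
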