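# The clinical encounter: perceive the change in health status (evaluation
# accuracy), decide whether to switch treatment, select a treatment
# (selection efficiency), and the per-step health-status dynamics.

#' Evaluation error probability
#'
#' The probability that patient and clinician misjudge whether health
#' improved since the last encounter: `error = e0 * (1 - praxis^2)`, where
#' `e0 = evaluation_accuracy_minimum_praxis` is the misjudgment probability
#' at zero praxis (the "reversed" accuracy axis: larger is worse). The
#' praxis response is concave: misjudgment falls off slowly at first and
#' only consolidated knowledge drives it toward zero; full praxis gives
#' perfect evaluation.
#'
#' @param praxis Praxis in \[0, 1\] (vectorized).
#' @param e0 Misjudgment probability at zero praxis, in \[0, 1\].
#' @return Error probability in \[0, 1\].
#' @export
evaluation_error <- function(praxis, e0) {
  e0 * (1 - praxis^2)
}

#' Perceive whether health improved
#'
#' The true verdict is `true_delta > -tolerance`: a treatment that holds
#' health within the tolerance band (absorbing step-to-step noise and
#' recoverable relapses) counts as working, while one under which health
#' genuinely declines does not. With probability `error_p` the verdict is
#' flipped.
#'
#' @param true_delta Health change since the last encounter (vectorized).
#' @param error_p Evaluation error probability.
#' @param tolerance Decline tolerated before a treatment is judged as not
#'   working (default 0.05, about the noise accumulated over an encounter
#'   period).
#' @return Logical: perceived as improved.
#' @export
perceive_improvement <- function(true_delta, error_p, tolerance = 0.05) {
  truth <- true_delta > -tolerance
  flip <- stats::runif(length(true_delta)) < error_p
  truth != flip
}

#' Selection efficiency at a given praxis
#'
#' Linear interpolation between no skill and the maximum:
#' `E = 1 + (E_max - 1) * praxis`, so `E = 1` at zero praxis (uniform
#' choice downstream) and `E = E_max` at praxis 1.
#'
#' @param praxis Praxis in \[0, 1\] (vectorized).
#' @param E_max `selection_efficiency_maximum` (>= 1).
#' @return Selection efficiency in \[1, E_max\].
#' @export
selection_efficiency <- function(praxis, E_max) {
  1 + (E_max - 1) * praxis
}

#' Select a treatment by rank-weighted sampling
#'
#' Candidates are all treatments at the first encounter, or all but the
#' current treatment at a switch. Ranking candidates by target health
#' (1 = best), the rank-r candidate among m gets weight
#' `E^((m - r)/(m - 1))` -- the best candidate weight `E`, the worst
#' weight 1 -- and one is sampled proportionally. `E = 1` is uniform;
#' `E -> Inf` is degenerate at the best candidate.
#'
#' @param targets Target health per treatment for the patient's phenotype.
#' @param current Current treatment index, or `NA`/`0` for none.
#' @param E Selection efficiency (>= 1).
#' @return Chosen treatment index.
#' @export
select_treatment <- function(targets, current = NA, E = 1) {
  nt <- length(targets)
  cand <- seq_len(nt)
  if (!is.na(current) && current > 0) cand <- cand[cand != current]
  m <- length(cand)
  if (m == 0) stop("empty candidate set")
  if (m == 1) return(cand)
  r <- rank(-targets[cand], ties.method = "first")
  w <- E^((m - r) / (m - 1))
  cand[sample.int(m, 1, prob = w)]
}

# Vectorized treatment selection for the engine. `ph`, `cur`, `prx` are
# aligned vectors over the patients selecting this step; `targets`/`ranks`
# are the phenotype x treatment matrices. Sampling proportional to the rank
# weights is done with the Gumbel-max trick so one runif matrix serves all
# patients.
.select_treatments_vec <- function(ph, cur, prx, targets, ranks, E_max) {
  ns <- length(ph)
  nt <- ncol(targets)
  E <- selection_efficiency(prx, E_max)
  rnk <- ranks[ph, , drop = FALSE]
  has_cur <- !is.na(cur) & cur > 0
  rc <- rep(Inf, ns)
  if (any(has_cur))
    rc[has_cur] <- rnk[cbind(which(has_cur), cur[has_cur])]
  adj <- rnk - (rnk > rc)                    # rank among candidates
  m <- ifelse(has_cur, nt - 1L, nt)
  ex <- (m - adj) / pmax(m - 1L, 1L)
  lw <- log(E) * ex                          # ns-vector recycled down columns
  g <- -log(-log(matrix(stats::runif(ns * nt), ns, nt)))
  sc <- lw + g
  if (any(has_cur))
    sc[cbind(which(has_cur), cur[has_cur])] <- -Inf
  max.col(sc, ties.method = "first")
}

#' One step of health-status dynamics
#'
#' `h' = clip(h + kappa (target - h) + drift + N(0, sd) - relapse, 0, 1)`,
#' where the relapse indicator is Bernoulli(`relapse_probability`) scaled by
#' `relapse_magnitude`. Health is pulled toward the current treatment's
#' target, so a well-matched treatment raises health and a poorly matched
#' one lowers it, bounded in \[0, 1\].
#'
#' @param h Current health in \[0, 1\] (vectorized).
#' @param target Target health of the current treatment (same length; pass
#'   `h` itself for untreated patients to disable the pull).
#' @param condition An `lhn_condition`.
#' @return Updated health.
#' @export
health_step <- function(h, target, condition) {
  n <- length(h)
  noise <- if (condition$variability_sd > 0)
    stats::rnorm(n, 0, condition$variability_sd) else numeric(n)
  relapse <- if (condition$relapse_probability > 0) {
    p_rel <- condition$relapse_probability * pmin(1.2, pmax(0, (1.1 - h) / 0.6)^2)
    (stats::runif(n) < p_rel) * condition$relapse_magnitude
  } else numeric(n)
  reserve <- pmax(0.3, 4 * h^2)
  pmin(1, pmax(0, h + condition$responsiveness_kappa * reserve * (target - h) +
                 condition$natural_history_drift + noise - relapse))
}

#' Run a single clinical encounter
#'
#' Reference single-patient encounter, executing the stages in order:
#' engagement update, knowledge access (PRI/IRI with the ER boost), praxis,
#' perception of improvement, treatment selection when warranted (first
#' encounter, or health not perceived as improved), knowledge
#' contributions, registry record, and bookkeeping. The simulation engine
#' runs the same stages vectorized over all patients due in a step.
#'
#' @param patient List with `health`, `engagement`, `pri`, `iri`,
#'   `treatment` (0 for none), `health_at_last_encounter`, `phenotype`.
#' @param clinician List with `engagement`.
#' @param commons List with `S` (effective stock) and `items` (cumulative).
#' @param registry Registry list (see [registry_step()]); its `er_level`
#'   and the center's `pvp_level` gate the encounter.
#' @param pvp_level PVP level of the care center.
#' @param params An `lhn_params`.
#' @param condition An `lhn_condition` (unused here; health evolves in the
#'   engine's per-step dynamics, kept for interface symmetry).
#' @param targets Target-health row for the patient's phenotype.
#' @return List with updated `patient`, `commons`, `registry` and an
#'   `outcome` record (praxis used, perceived/switched flags, treatments,
#'   contributions).
#' @export
run_encounter <- function(patient, clinician, commons, registry, pvp_level,
                          params, condition, targets) {
  p <- params
  # 1. engagement
  patient$engagement <- encounter_engagement_update(patient$engagement,
                                                    clinician$engagement, p)
  # 2. knowledge access
  acc_p <- access_fraction(patient$engagement,
                           p$patient_engagement_degree_participating)
  acc_c <- er_encounter_boost(registry$er_level,
                              access_fraction(clinician$engagement,
                                              p$clinician_engagement_degree_participating),
                              p$clinician_engagement_degree_participating)
  macc <- (acc_p + acc_c) / 2
  patient$pri <- update_pri(patient$pri, commons$S,
                            p$phenotype_realization_numeric,
                            p$potential_phenotype_response_info_from_sk_unit,
                            macc)
  patient$iri <- update_iri(patient$iri, commons$S, p, at_encounter = TRUE,
                            dt = 0, mean_access = macc)
  # 3. praxis
  prx <- compute_praxis(patient$pri, patient$iri, macc, pvp_cap(pvp_level))
  # 4. perception
  err <- evaluation_error(prx, p$evaluation_accuracy_minimum_praxis)
  delta <- patient$health - patient$health_at_last_encounter
  perceived <- perceive_improvement(delta, err)
  # 5. selection
  old_tx <- patient$treatment
  first <- is.na(old_tx) || old_tx == 0
  switched <- FALSE
  if (first || !perceived) {
    E <- selection_efficiency(prx, p$selection_efficiency_maximum)
    patient$treatment <- select_treatment(targets,
                                          if (first) NA else old_tx, E)
    switched <- !first
  }
  # 6. contributions + registry record
  c_pat <- contribute_knowledge(patient$engagement,
                                p$patient_shared_knowledge_contrib_determiner)
  c_cl <- contribute_knowledge(clinician$engagement,
                               p$clinician_shared_knowledge_contrib_determiner)
  commons$S <- commons$S + c_pat + c_cl
  commons$items <- commons$items + c_pat + c_cl
  if (registry$er_level %in% c("medium", "high")) {
    registry$record_count <- registry$record_count + 1L
    registry$records_since_last_analysis <-
      registry$records_since_last_analysis + 1L
  }
  # 7. bookkeeping
  patient$health_at_last_encounter <- patient$health
  patient$praxis <- prx
  list(patient = patient, commons = commons, registry = registry,
       outcome = list(praxis = prx, perceived_improved = perceived,
                      switched = switched, old_treatment = old_tx,
                      new_treatment = patient$treatment,
                      contributed_patient = c_pat,
                      contributed_clinician = c_cl))
}
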