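# The simulation engine: seeded per-step orchestration and metric
# collection. A run is a deterministic function of (scenario, seed); all
# randomness flows from one RNG stream seeded at run start.
#
# Per-step stage order:
#   1. commons decay + IRI decay
#   2. clinical encounters due this step (patient order shuffled per step),
#      then the per-step health dynamics
#   3. peer influence (patients, then clinicians)
#   4. clinician burnout
#   5. registry analysis if due
#   6. metrics row (state at step end)

#' Simulate one LHN run
#'
#' @param scenario An `lhn_scenario`. The scenario's `seed` controls all
#'   randomness; the same scenario yields bit-identical metrics.
#' @return An object of class `lhn_run`: list with `metrics` (one data
#'   frame row per step, 0..horizon), `outcomes` (see [compute_outcomes()]),
#'   `scenario`, `seed`.
#' @export
simulate_lhn <- function(scenario) {
  scn <- validate_scenario(scenario)
  set.seed(scn$seed)
  p <- scn$params
  cond <- scn$condition
  spy <- scn$steps_per_year
  pop <- build_population(scn)
  npat <- pop$n_patients; ncl <- pop$n_clinicians; ncent <- pop$n_centers
  M <- pop$effect$targets; Rk <- pop$effect$ranks
  pat_center <- pop$pat_center; pat_clin <- pop$pat_clin
  phen <- pop$phenotype

  # converted per-step probabilities
  p_aw_pat <- annual_to_step_probability(p$patient_influence_become_aware_probability, spy)
  p_act_pat <- annual_to_step_probability(p$patient_influence_activation_probability, spy)
  p_aw_cl <- annual_to_step_probability(p$clinician_influence_become_aware_probability, spy)
  p_act_cl <- annual_to_step_probability(p$clinician_influence_activation_probability, spy)
  p_burn <- annual_to_step_probability(p$clinician_dispirit_probability, spy)
  df_sk <- 2^(-1 / p$shared_knowledge_half_life)
  df_iri <- 2^(-1 / p$patient_response_info_half_life)
  cap_center <- pvp_cap(scn$pvp_level)
  er_lvl <- scn$er_level
  er_rec <- er_lvl %in% c("medium", "high")   # uploads records
  er_high <- er_lvl == "high"
  d_pat <- p$patient_engagement_degree_participating
  d_cl <- p$clinician_engagement_degree_participating
  period <- as.integer(p$encounter_period)
  an_period <- as.integer(p$enhanced_registry_analysis_period)

  # mutable state
  health <- pop$health0
  eng_pat <- pop$eng_pat0
  eng_cl <- pop$eng_cl0
  iri <- pop$iri0
  pri <- numeric(npat)
  tx <- integer(npat)                         # 0 = no treatment yet
  h_last <- health
  praxis_last <- numeric(npat)
  next_enc <- pop$next_enc0
  active <- rep(TRUE, npat)
  S <- p$shared_knowledge_initial
  items <- p$shared_knowledge_initial
  rec_since <- ifelse(er_rec, p$enhanced_registry_initial_per_patient *
                        tabulate(pat_center, ncent), 0)
  rec_count <- rec_since
  exit_cfg <- scn$exit_rules
  exits_on <- isTRUE(exit_cfg$enabled) && !isTRUE(scn$closed_cohort)
  if (exits_on) {
    consec_hi <- integer(npat); consec_lo <- integer(npat)
    p_exit <- annual_to_step_probability(exit_cfg$annual_exit_probability, spy)
  }

  horizon <- scn$horizon_steps
  mcols <- c("step", "n_active", "mean_health", "median_health", "mean_praxis",
             "commons_stock", "commons_items", "mean_target", "frac_best_tx",
             paste0("pat_eng_", 0:4), paste0("clin_eng_", 0:4))
  metrics <- matrix(NA_real_, nrow = horizon + 1, ncol = length(mcols),
                    dimnames = list(NULL, mcols))
  snap <- function(t) {
    a <- active
    trt <- a & tx > 0L
    mt <- if (any(trt)) mean(M[cbind(phen[trt], tx[trt])]) else NA_real_
    fb <- if (any(trt)) mean(Rk[cbind(phen[trt], tx[trt])] == 1L) else 0
    c(t, sum(a), mean(health[a]), stats::median(health[a]),
      mean(praxis_last[a]), S, items, mt, fb,
      tabulate(eng_pat[a] + 1L, 5L), tabulate(eng_cl + 1L, 5L))
  }
  metrics[1, ] <- snap(0)

  for (t in seq_len(horizon)) {
    # 1. decay
    S <- S * df_sk
    iri <- iri * df_iri
    # 2. encounters
    due <- which(next_enc == 0L & active)
    if (length(due)) {
      due <- due[sample.int(length(due))]
      nd <- length(due)
      cl <- pat_clin[due]
      ce <- pat_center[due]
      cl_eng <- eng_cl[cl]
      pe <- encounter_engagement_update(eng_pat[due], cl_eng, p)
      eng_pat[due] <- pe
      acc_p <- access_fraction(pe, d_pat)
      acc_c <- access_fraction(cl_eng, d_cl)
      boost <- er_high[ce]
      if (any(boost)) acc_c[boost] <- pmax(acc_c[boost], d_cl)
      macc <- (acc_p + acc_c) / 2
      pri[due] <- update_pri(pri[due], S, p$phenotype_realization_numeric,
                             p$potential_phenotype_response_info_from_sk_unit,
                             macc)
      iri[due] <- update_iri(iri[due], S, p, at_encounter = TRUE,
                             mean_access = macc)
      prx <- compute_praxis(pri[due], iri[due], macc, cap_center[ce])
      praxis_last[due] <- prx
      err <- evaluation_error(prx, p$evaluation_accuracy_minimum_praxis)
      perceived <- perceive_improvement(health[due] - h_last[due], err,
                                        cond$improvement_tolerance)
      need <- tx[due] == 0L | !perceived
      if (any(need)) {
        sel <- due[need]
        tx[sel] <- .select_treatments_vec(phen[sel], tx[sel], prx[need],
                                          M, Rk, p$selection_efficiency_maximum)
      }
      c_pat <- contribute_knowledge(pe, p$patient_shared_knowledge_contrib_determiner)
      c_cl <- contribute_knowledge(cl_eng, p$clinician_shared_knowledge_contrib_determiner)
      new_items <- sum(c_pat) + sum(c_cl)
      S <- S + new_items
      items <- items + new_items
      if (any(er_rec)) {
        enc_ct <- tabulate(ce, ncent) * er_rec
        rec_since <- rec_since + enc_ct
        rec_count <- rec_count + enc_ct
      }
      h_last[due] <- health[due]
      next_enc[due] <- period
    }
    next_enc <- next_enc - 1L
    # health dynamics (treated patients pulled toward their target)
    tgt <- health
    treated <- tx > 0L & active
    if (any(treated)) tgt[treated] <- M[cbind(phen[treated], tx[treated])]
    health[active] <- health_step(health[active], tgt[active], cond)
    # 3. peer influence (snapshot semantics inside the pass)
    eng_pat <- .influence_pass(eng_pat, pop$net_pat$edges, p_aw_pat, p_act_pat)
    eng_cl <- .influence_pass(eng_cl, pop$net_cl$edges, p_aw_cl, p_act_cl)
    # 4. burnout
    eng_cl <- clinician_burnout_step(eng_cl, p$clinician_dispirit_probability, spy)
    # 5. registry analysis
    if (t %% an_period == 0L && any(er_rec)) {
      k <- floor(rec_since / p$enhanced_registry_record_per_commons_item) * er_rec
      got <- sum(k)
      S <- S + got
      items <- items + got
      rec_since[] <- 0
    }
    # cohort exits (disabled in the closed-cohort reference experiments)
    if (exits_on) {
      consec_hi <- ifelse(active & health > exit_cfg$upper, consec_hi + 1L, 0L)
      consec_lo <- ifelse(active & health < exit_cfg$lower, consec_lo + 1L, 0L)
      out <- active & (consec_hi >= exit_cfg$consecutive |
                       consec_lo >= exit_cfg$consecutive |
                       stats::runif(npat) < p_exit)
      active[out] <- FALSE
    }
    # 6. metrics
    metrics[t + 1, ] <- snap(t)
  }

  metrics <- as.data.frame(metrics)
  metrics$step <- as.integer(metrics$step)
  run <- structure(list(metrics = metrics, scenario = scn, seed = scn$seed),
                   class = "lhn_run")
  run$outcomes <- compute_outcomes(metrics)
  run
}

#' Compute run outcomes from a metrics table
#'
#' The three study outcomes over the run:
#' * `health` -- cumulative average change in health status: final minus
#'   baseline of the patient-mean health trajectory;
#' * `praxis` -- cumulative average change in praxis (same construction);
#' * `knowledge` -- cumulative increase in the number of items in the
#'   commons: final minus initial *effective* stock (items age out of
#'   usefulness exponentially, so the commons counts decayed items);
#' plus `items_added` (cumulative items ever contributed, which ignores
#' decay) and `median_final_health`.
#'
#' @param metrics A metrics data frame from [simulate_lhn()] (>= 1 row).
#' @return A list of class `lhn_outcomes`.
#' @export
compute_outcomes <- function(metrics) {
  if (inherits(metrics, "lhn_run")) metrics <- metrics$metrics
  stopifnot(nrow(metrics) >= 1)
  first <- metrics[1, ]
  last <- metrics[nrow(metrics), ]
  structure(list(
    health = last$mean_health - first$mean_health,
    praxis = last$mean_praxis - first$mean_praxis,
    knowledge = last$commons_stock - first$commons_stock,
    items_added = last$commons_items - first$commons_items,
    median_final_health = last$median_health), class = "lhn_outcomes")
}

#' @export
print.lhn_outcomes <- function(x, ...) {
  cat(sprintf(paste0(
    "<lhn_outcomes> health %+0.4f  praxis %+0.4f  knowledge %+0.1f",
    "  items_added %d  median final health %0.3f\n"),
    x$health, x$praxis, x$knowledge, as.integer(x$items_added),
    x$median_final_health))
  invisible(x)
}

#' @export
print.lhn_run <- function(x, ...) {
  cat(sprintf("<lhn_run> seed %s, %d steps\n", format(x$seed),
              nrow(x$metrics) - 1L))
  print(x$outcomes)
  invisible(x)
}

#' Run a seeded ensemble of replicates
#'
#' Replicate `k` runs the scenario with seed `base_seed + k`; per-outcome
#' mean, SD and median summarize the ensemble.
#'
#' @param scenario An `lhn_scenario`.
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base seed; replicate seeds are `base_seed + 1..n`.
#' @return List of class `lhn_ensemble` with `outcomes` (one data frame row
#'   per replicate) and `summary`.
#' @export
run_ensemble <- function(scenario, n_replicates, base_seed = scenario$seed) {
  stopifnot(n_replicates >= 1)
  rows <- lapply(seq_len(n_replicates), function(k) {
    scenario$seed <- base_seed + k
    o <- simulate_lhn(scenario)$outcomes
    data.frame(replicate = k, seed = base_seed + k,
               health = o$health, praxis = o$praxis,
               knowledge = o$knowledge, items_added = o$items_added,
               median_final_health = o$median_final_health)
  })
  outcomes <- do.call(rbind, rows)
  vars <- c("health", "praxis", "knowledge", "items_added",
            "median_final_health")
  summary <- data.frame(
    outcome = vars,
    mean = vapply(outcomes[vars], mean, 0),
    sd = vapply(outcomes[vars], stats::sd, 0),
    median = vapply(outcomes[vars], stats::median, 0),
    row.names = NULL)
  summary$sd[is.na(summary$sd)] <- 0
  structure(list(outcomes = outcomes, summary = summary,
                 n_replicates = n_replicates, base_seed = base_seed),
            class = "lhn_ensemble")
}
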