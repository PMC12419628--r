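# Engagement-level transitions. Levels are the ordinal ladder
# unaware = 0, aware = 1, participating = 2, contributing = 3, owning = 4.
# Encounter-driven transitions use per-encounter probabilities
# ("determiners"); peer influence and burnout use annual probabilities
# converted to per-step rates.

#' Engagement level labels
#' @return Named integer vector mapping labels to levels 0..4.
#' @export
engagement_levels <- function() {
  c(unaware = 0L, aware = 1L, participating = 2L,
    contributing = 3L, owning = 4L)
}

#' Convert an annual probability to a per-step probability
#'
#' `p_step = 1 - (1 - p_annual)^(1 / steps_per_year)`, so that compounding
#' the per-step probability over a year reproduces the annual one.
#' `p_annual = 1` maps to `p_step = 1`.
#'
#' @param p_annual Annual probability in \[0, 1\] (vectorized).
#' @param steps_per_year Steps per year (>= 1).
#' @return Per-step probability.
#' @export
annual_to_step_probability <- function(p_annual, steps_per_year) {
  stopifnot(all(p_annual >= 0 & p_annual <= 1), steps_per_year >= 1)
  1 - (1 - p_annual)^(1 / steps_per_year)
}

#' Encounter-driven patient engagement update
#'
#' An unaware patient meeting a clinician who is at least aware becomes
#' aware with probability `encounter_aware_determiner`. Otherwise, a
#' patient meeting a strictly more engaged clinician moves up one level
#' with probability `patient_activate_determiner`, and a patient meeting a
#' strictly less engaged clinician moves down one level with probability
#' `patient_dispirit_determiner`. At most one transition per encounter.
#' Vectorized over patients.
#'
#' @param patient_level,clinician_level Integer levels in 0..4.
#' @param params An `lhn_params` (only the three determiners are used).
#' @return New patient level(s).
#' @export
encounter_engagement_update <- function(patient_level, clinician_level, params) {
  n <- length(patient_level)
  u <- stats::runif(n)
  up_aware <- patient_level == 0L & clinician_level >= 1L &
    u < params$encounter_aware_determiner
  up_act <- patient_level > 0L & clinician_level > patient_level &
    u < params$patient_activate_determiner
  down <- clinician_level < patient_level &
    u < params$patient_dispirit_determiner
  as.integer(patient_level + up_aware + up_act - down)
}

# One peer-influence pass over an undirected edge list (2-column matrix).
# Snapshot semantics: qualification uses the levels at entry, so no cascade
# can propagate within a single step. An agent with at least one strictly
# more engaged neighbor gets a single Bernoulli trial (degree does not stack):
# unaware agents use p_aware, engaged agents below the top level use p_activate.
.influence_pass <- function(levels, edges, p_aware, p_activate) {
  if (is.null(edges) || nrow(edges) == 0 || (p_aware <= 0 && p_activate <= 0))
    return(levels)
  l1 <- levels[edges[, 1]]
  l2 <- levels[edges[, 2]]
  q <- logical(length(levels))
  q[edges[l1 < l2, 1]] <- TRUE
  q[edges[l2 < l1, 2]] <- TRUE
  cand <- which(q)
  if (!length(cand)) return(levels)
  p <- ifelse(levels[cand] == 0L, p_aware, p_activate)
  rise <- stats::runif(length(cand)) < p
  levels[cand] <- levels[cand] + as.integer(rise)
  levels
}

#' Peer-influence step over an influence network
#'
#' For every agent with at least one strictly more engaged neighbor, one
#' Bernoulli trial per step: unaware agents become aware with the per-step
#' become-aware probability, already-aware agents move up one level with
#' the per-step activation probability. Transitions are resolved against a
#' snapshot of levels at step start; there is no downward peer influence.
#'
#' @param levels Integer levels 0..4.
#' @param edges 2-column integer edge matrix (undirected).
#' @param become_aware_p_annual,activation_p_annual Annual probabilities.
#' @param steps_per_year Steps per year.
#' @return Updated levels.
#' @export
influence_step <- function(levels, edges, become_aware_p_annual,
                           activation_p_annual, steps_per_year) {
  .influence_pass(levels, edges,
                  annual_to_step_probability(become_aware_p_annual, steps_per_year),
                  annual_to_step_probability(activation_p_annual, steps_per_year))
}

#' Clinician burnout step
#'
#' Each clinician above unaware independently drops one level with the
#' per-step probability converted from `dispirit_p_annual`. Burnout is
#' applied every step at the converted rate rather than as an annual batch
#' event, avoiding synchronization artifacts.
#'
#' @param levels Integer clinician levels 0..4.
#' @param dispirit_p_annual Annual burnout probability.
#' @param steps_per_year Steps per year.
#' @return Updated levels.
#' @export
clinician_burnout_step <- function(levels, dispirit_p_annual, steps_per_year) {
  p <- annual_to_step_probability(dispirit_p_annual, steps_per_year)
  if (p <= 0) return(levels)
  drop <- levels > 0L & stats::runif(length(levels)) < p
  as.integer(levels - drop)
}
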