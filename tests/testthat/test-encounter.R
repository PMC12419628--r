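# The clinical encounter: evaluation, perception, treatment selection,
# health dynamics.

test_that("evaluation error interpolates from e0 at zero praxis to 0 at full praxis", {
  expect_equal(evaluation_error(1, 0.2), 0)
  expect_equal(evaluation_error(0, 0.2), 0.2)
  expect_equal(evaluation_error(0.7, 0), 0)
  # concave in praxis, monotone decreasing
  e <- evaluation_error(seq(0, 1, 0.1), 0.2)
  expect_true(all(diff(e) < 0))
  expect_gt(evaluation_error(0.5, 0.2), 0.2 * 0.5)
})

test_that("perception flips the true verdict with the error probability", {
  set.seed(2)
  expect_true(perceive_improvement(0.1, 0))
  expect_false(perceive_improvement(0.1, 1))
  # declines within the tolerance band count as working
  expect_true(perceive_improvement(-0.03, 0, tolerance = 0.05))
  expect_false(perceive_improvement(-0.05, 0, tolerance = 0.05))
  n <- 10000
  freq <- mean(perceive_improvement(rep(-0.06, n), 0.2, tolerance = 0.05))
  expect_lt(abs(freq - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("selection efficiency interpolates linearly between 1 and the maximum", {
  expect_equal(selection_efficiency(0, 1000), 1)
  expect_equal(selection_efficiency(1, 1000), 1000)
  expect_equal(selection_efficiency(0.5, 1000), 500.5)
})

test_that("treatment selection weights follow the geometric rank rule", {
  targets <- c(0.2, 0.8, 0.5)   # ranks: 3, 1, 2
  set.seed(8)
  n <- 50000
  # m = 3 candidates, E = 4 -> weights (4, 2, 1) on ranks (1, 2, 3)
  draws <- replicate(n, select_treatment(targets, current = NA, E = 4))
  freq <- tabulate(draws, 3) / n
  probs <- c(1 / 7, 4 / 7, 2 / 7)   # by treatment index
  for (i in 1:3)
    expect_lt(abs(freq[i] - probs[i]), 3 * sqrt(probs[i] * (1 - probs[i]) / n))
})

test_that("E = 1 is uniform and huge E is degenerate at the best candidate", {
  targets <- seq(0.9, 0.1, length.out = 5)
  set.seed(9)
  n <- 50000
  draws <- replicate(n, select_treatment(targets, current = 1, E = 1))
  counts <- tabulate(draws, 5)
  expect_equal(counts[1], 0)   # current excluded
  # chi-square uniformity over the 4 candidates
  expect_gt(chisq.test(counts[2:5])$p.value, 0.001)
  draws2 <- replicate(2000, select_treatment(targets, current = 5, E = 1e9))
  expect_gte(mean(draws2 == 1), 0.999)
  # single alternative is forced
  expect_equal(select_treatment(c(0.3, 0.7), current = 2, E = 10), 1)
  expect_error(select_treatment(0.5, current = 1, E = 2), "empty candidate")
})

test_that("vectorized engine selection agrees with the scalar rule in distribution", {
  targets <- matrix(c(0.85, 0.55, 0.25), 1)   # one phenotype, 3 treatments
  ranks <- matrix(c(1L, 2L, 3L), 1)
  set.seed(10)
  n <- 30000
  picks <- lhnsim:::.select_treatments_vec(rep(1L, n), rep(3L, n),
                                           rep(0.5, n), targets, ranks,
                                           E_max = 7)
  expect_false(any(picks == 3L))
  # E = 4, m = 2 candidates: weights (4, 1)
  freq <- mean(picks == 1L)
  expect_lt(abs(freq - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("health dynamics have the declared fixed points and bounds", {
  frozen <- lhn_condition(responsiveness_kappa = 0, natural_history_drift = 0,
                          relapse_probability = 0, variability_sd = 0)
  h <- c(0, 0.25, 0.8, 1)
  expect_equal(health_step(h, rep(0.5, 4), frozen), h)
  # at the target with no drag the state is stationary
  active <- lhn_condition(natural_history_drift = 0, relapse_probability = 0,
                          variability_sd = 0)
  expect_equal(health_step(0.6, 0.6, active), 0.6)
  # pull moves toward the target, scaled by the reserve
  up <- health_step(0.3, 0.9, active)
  expect_gt(up, 0.3); expect_lt(up, 0.9)
  dn <- health_step(0.8, 0.2, active)
  expect_lt(dn, 0.8); expect_gt(dn, 0.2)
  # always clipped to [0, 1]
  wild <- lhn_condition(natural_history_drift = -0.9)
  expect_gte(min(health_step(runif(100), runif(100), wild)), 0)
})

test_that("run_encounter executes the staged contract", {
  p <- lhn_params(encounter_aware_determiner = 1,
                  patient_shared_knowledge_contrib_determiner = 1,
                  clinician_shared_knowledge_contrib_determiner = 1,
                  evaluation_accuracy_minimum_praxis = 0)
  cond <- lhn_condition()
  targets <- c(0.85, 0.7, 0.55, 0.4, 0.25)
  commons <- list(S = 10, items = 10)
  registry <- list(er_level = "medium", record_count = 0,
                   records_since_last_analysis = 0, steps_until_analysis = 5L)
  patient <- list(health = 0.5, engagement = 0L, pri = 0, iri = 0,
                  treatment = 0L, health_at_last_encounter = 0.5,
                  phenotype = 1L)
  clinician <- list(engagement = 4L)
  set.seed(30)
  out <- run_encounter(patient, clinician, commons, registry, "high",
                       p, cond, targets)
  # first encounter always assigns a treatment
  expect_gt(out$patient$treatment, 0)
  expect_false(out$outcome$switched)
  # unaware patient became aware (determiner 1, engaged clinician)
  expect_equal(out$patient$engagement, 1L)
  # owning clinician contributed (determiner 1); unaware patient cannot
  expect_equal(out$outcome$contributed_clinician, 1L)
  expect_equal(out$outcome$contributed_patient, 0L)
  expect_equal(out$commons$S, 11)
  expect_equal(out$registry$record_count, 1L)
  expect_equal(out$patient$health_at_last_encounter, 0.5)

  # perceived improvement keeps the treatment
  patient2 <- list(health = 0.7, engagement = 2L, pri = 0.5, iri = 0.5,
                   treatment = 4L, health_at_last_encounter = 0.5,
                   phenotype = 1L)
  out2 <- run_encounter(patient2, clinician, commons, registry, "high",
                        p, cond, targets)
  expect_equal(out2$patient$treatment, 4L)
  expect_false(out2$outcome$switched)
  expect_true(out2$outcome$perceived_improved)

  # not improved (beyond tolerance) with zero error switches away
  patient3 <- list(health = 0.3, engagement = 2L, pri = 0.5, iri = 0.5,
                   treatment = 4L, health_at_last_encounter = 0.6,
                   phenotype = 1L)
  out3 <- run_encounter(patient3, clinician, commons, registry, "high",
                        p, cond, targets)
  expect_true(out3$outcome$switched)
  expect_false(out3$patient$treatment == 4L)
})

test_that("higher selection ceiling never hurts and worse evaluation never helps", {
  base <- small_scenario(horizon = 80)
  mean_h <- function(field, value) {
    scn <- base
    scn$params[[field]] <- value
    ens_mean(scn, "health", n = 12, base_seed = 900)
  }
  lo_sel <- mean_h("selection_efficiency_maximum", 10)
  hi_sel <- mean_h("selection_efficiency_maximum", 1000)
  expect_gt(hi_sel, lo_sel - 0.02)
  good_eval <- mean_h("evaluation_accuracy_minimum_praxis", 0.001)
  bad_eval <- mean_h("evaluation_accuracy_minimum_praxis", 0.2)
  expect_gt(good_eval, bad_eval - 0.02)
})
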