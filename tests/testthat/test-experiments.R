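# Experiment harnesses: Latin hypercube sampling, PRCC and its bootstrap,
# the sensitivity runner, grid explorer, factorial experiment.

test_that("LHS stratifies every margin and respects ranges", {
  des <- lhs_sample(default_ranges(), n = 10, seed = 3)
  u <- des$unit
  for (j in seq_len(ncol(u)))
    expect_equal(sort(floor(u[, j] * 10)), 0:9)  # one draw per decile
  X <- des$design
  rg <- default_ranges()
  for (nm in names(rg)) {
    expect_true(all(X[[nm]] >= rg[[nm]]$lower - 1e-9))
    expect_true(all(X[[nm]] <= rg[[nm]]$upper + 1e-9))
  }
  # integer parameters are integral
  expect_true(all(X$encounter_period == round(X$encounter_period)))
  # deterministic under seed
  des2 <- lhs_sample(default_ranges(), n = 10, seed = 3)
  expect_identical(des$design, des2$design)
})

test_that("triangle sampling matches the distribution's moments", {
  rg <- default_ranges()
  rg$phenotype_realization_numeric <- list(lower = 0, upper = 1,
                                           dist = "triangle", mode = 0.5)
  x <- lhs_sample(rg, n = 10000, seed = 5)$design$phenotype_realization_numeric
  # symmetric triangle(0, 1, 1/2): mean 1/2, var 1/24
  expect_lt(abs(mean(x) - 0.5), 3 * sqrt(1 / 24 / 10000))
  expect_equal(stats::var(x), 1 / 24, tolerance = 0.05)
  # asymmetric quantiles
  expect_equal(qtriangle(c(0, 1), 2, 6, 3), c(2, 6))
  expect_equal(qtriangle(0.25, 0, 1, 0.5), sqrt(0.125))
})

test_that("LHS margins pass a KS test against their target CDF", {
  rg <- default_ranges()
  x <- lhs_sample(rg, n = 10000, seed = 9)$design$selection_efficiency_maximum
  expect_gt(stats::ks.test(x, "punif", 10, 1000)$p.value, 0.001)
})

test_that("PRCC agrees with the normal-equations oracle to 1e-10", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(runif(50 * 5), 50, 5,
                dimnames = list(NULL, paste0("p", 1:5)))
    y <- runif(50)
    got <- prcc(X, y)
    expect_equal(got$prcc, prcc_oracle(X, y), tolerance = 1e-10)
  }
})

test_that("PRCC is exactly 1 for a rank-monotone single driver", {
  set.seed(12)
  X <- matrix(runif(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- exp(3 * X[, 1])           # strictly increasing in p1 only
  got <- suppressWarnings(prcc(X, y))
  expect_equal(got$prcc[1], 1, tolerance = 1e-12)
  # given p1 the outcome is deterministic, so the other partials are
  # undefined (flagged NA), never silently zero
  expect_true(all(is.na(got$prcc[-1])))
})

test_that("null parameters have near-zero PRCC and signs follow construction", {
  set.seed(13)
  n <- 1000
  X <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("p", 1:5)))
  y <- rnorm(n)
  expect_true(all(abs(prcc(X, y)$prcc) < 0.1))     # ~3/sqrt(n) scale
  y2 <- qnorm(X[, 1]) - X[, 2]^3 + 0.1 * rnorm(n)  # monotone up in p1, down in p2
  got <- prcc(X, y2)
  expect_gt(got$prcc[1], 0.5)
  expect_lt(got$prcc[2], -0.5)
})

test_that("PRCC is invariant under strictly monotone transforms", {
  set.seed(14)
  X <- matrix(runif(120 * 4), 120, 4, dimnames = list(NULL, paste0("p", 1:4)))
  y <- X[, 1] - X[, 3] + 0.3 * runif(120)
  base <- prcc(X, y)$prcc
  X2 <- X
  X2[, 1] <- exp(5 * X2[, 1])
  X2[, 3] <- log(X2[, 3] + 0.01)
  expect_equal(prcc(X2, y^3)$prcc, base, tolerance = 1e-12)
})

test_that("PRCC guards degenerate inputs", {
  X <- cbind(a = runif(30), b = rep(1, 30))
  expect_error(prcc(X, runif(30)), "constant column")
  X2 <- cbind(a = runif(30), b = runif(30))
  expect_warning(out <- prcc(X2, rep(2, 30)), "undefined")
  expect_true(all(is.na(out$prcc)))
})

test_that("bootstrap CIs cover the point estimate and collapse when exact", {
  set.seed(15)
  X <- matrix(runif(150 * 3), 150, 3, dimnames = list(NULL, paste0("p", 1:3)))
  y <- X[, 1] - 0.4 * X[, 2] + 0.1 * rnorm(150)
  ci <- prcc_bootstrap_ci(X, y, n_boot = 40)
  expect_true(all(ci$ci_lo <= ci$prcc + 1e-12 & ci$prcc <= ci$ci_hi + 1e-12))
  expect_equal(unique(ci$alpha), 0.05 / 3)
  # an exact rank identity has zero resampling variance: CI collapses to 1
  y1 <- exp(X[, 1])
  ci1 <- suppressWarnings(prcc_bootstrap_ci(X, y1, n_boot = 20))
  expect_equal(ci1$ci_lo[1], 1, tolerance = 1e-9)
  expect_equal(ci1$ci_hi[1], 1, tolerance = 1e-9)
})

test_that("bootstrap CIs cover a large-n reference PRCC", {
  set.seed(16)
  # reference from a large sample of the same generative model
  gen <- function(n) {
    X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, paste0("p", 1:3)))
    list(X = X, y = X[, 1] - 0.5 * X[, 2] + 0.2 * rnorm(n))
  }
  big <- gen(20000)
  ref <- prcc(big$X, big$y)$prcc
  hits <- 0
  for (r in 1:20) {
    d <- gen(150)
    ci <- prcc_bootstrap_ci(d$X, d$y, n_boot = 60)
    if (all(ci$ci_lo <= ref & ref <= ci$ci_hi)) hits <- hits + 1
  }
  # Bonferroni 95% joint intervals over 3 parameters: expect high coverage
  expect_gte(hits, 14)
})

test_that("a small sensitivity run has the full shape contract", {
  tmpl <- small_scenario(horizon = 26)
  sens <- run_sensitivity(n_samples = 40, template = tmpl, seed = 21)
  expect_equal(dim(sens$design), c(40, 30))
  expect_equal(nrow(sens$outcomes), 40)
  expect_named(sens$prcc, c("health", "praxis", "knowledge"))
  for (d in sens$prcc) expect_equal(nrow(d), 30)
  expect_equal(sens$n_failed, 0)
  d <- withr::local_tempdir()
  write_sensitivity_outputs(sens, d)
  expect_true(file.exists(file.path(d, "design.csv")))
  pr <- utils::read.csv(file.path(d, "prcc.csv"))
  expect_equal(nrow(pr), 90)
})

test_that("fewer encounters mean less knowledge (mechanism sign check)", {
  tmpl <- small_scenario(horizon = 52)
  tmpl$params$patient_shared_knowledge_contrib_determiner <- 0.5
  tmpl$params$clinician_shared_knowledge_contrib_determiner <- 0.5
  k <- function(period) {
    scn <- tmpl
    scn$params$encounter_period <- period
    ens_mean(scn, "items_added", n = 8, base_seed = 300)
  }
  expect_gt(k(6), k(20))
})

test_that("grid explorer covers the requested lattice at midpoints", {
  g <- grid_explore("selection_efficiency_maximum",
                    "evaluation_accuracy_minimum_praxis",
                    n_increments = 2, outcome = "health",
                    template = small_scenario(horizon = 26),
                    seed = 5, replicates_per_cell = 2)
  expect_equal(nrow(g), 4)
  expect_setequal(g$x, c(10, 1000))
  expect_setequal(round(g$y, 4), c(0.001, 0.2))
  expect_true(all(is.finite(g$mean)))
  expect_error(grid_explore("encounter_period", "encounter_period"),
               "x_param != y_param", fixed = TRUE)
})

test_that("factorial experiment yields 27 cells with the preset coordinates", {
  fac <- factorial_experiment(template = small_scenario(horizon = 26),
                              n_replicates = 2, seed = 4)
  expect_equal(nrow(fac), 27)
  expect_equal(nrow(unique(fac[, c("lhn", "pvp", "er")])), 27)
  expect_true(all(is.finite(fac$median_health)))
  tb <- lhn_level_preset("selection_sweep")
  expect_equal(tb$selection_efficiency_maximum, c(10, 100, 1000))
  mt <- lhn_level_preset("regime_anchors")
  expect_equal(mt$evaluation_accuracy_minimum_praxis, c(0.20, 0.10, 0.001))
})
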