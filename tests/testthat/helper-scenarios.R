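# Shared miniature scenarios. Everything is generated in code; the frozen
# fixture is the null-dynamics baseline, small_scenario a fast but fully
# active configuration.

small_scenario <- function(seed = 1L, horizon = 52L, ...) {
  lhn_scenario(n_care_centers = 2, clinicians_per_center = 2,
               patients_per_clinician = 5, horizon_steps = horizon,
               seed = seed, ...)
}

# Ensemble mean of one outcome over n seeded replicates.
ens_mean <- function(scenario, outcome, n = 10, base_seed = 100) {
  mean(run_ensemble(scenario, n, base_seed = base_seed)$outcomes[[outcome]])
}

# Brute-force PRCC oracle: rank transform, then explicit normal-equations
# residualization, independent of the package's QR path.
prcc_oracle <- function(X, y) {
  rX <- apply(as.matrix(X), 2, rank)
  ry <- rank(y)
  vapply(seq_len(ncol(rX)), function(j) {
    Z <- cbind(1, rX[, -j, drop = FALSE])
    bx <- solve(t(Z) %*% Z, t(Z) %*% rX[, j])
    by <- solve(t(Z) %*% Z, t(Z) %*% ry)
    stats::cor(rX[, j] - Z %*% bx, ry - Z %*% by)
  }, 0)
}
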