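# The three experiment harnesses: Latin hypercube sensitivity analysis with
# partial rank correlation coefficients (PRCC) and bootstrap confidence
# intervals; solution-space contour grids; and the 3x3x3 factorial
# intervention experiment.

#' Triangle distribution quantile function
#'
#' @param p Probabilities in \[0, 1\].
#' @param a,b Lower and upper limits (`a < b`).
#' @param mode Mode, in \[a, b\].
#' @return Quantiles.
#' @export
qtriangle <- function(p, a, b, mode) {
  stopifnot(a < b, mode >= a, mode <= b)
  Fc <- (mode - a) / (b - a)
  ifelse(p < Fc,
         a + sqrt(p * (b - a) * (mode - a)),
         b - sqrt((1 - p) * (b - a) * (b - mode)))
}

#' Latin hypercube sample of the parameter space
#'
#' Stratified-permuted sampling: per column, exactly one draw falls in each
#' of the n equal-probability strata of the marginal (uniform or triangle,
#' per the ranges file), mapped through the inverse CDF. Integer-valued
#' parameters are rounded after transformation.
#'
#' @param ranges Ranges list (see [default_ranges()]).
#' @param n Number of samples (>= 2).
#' @param seed RNG seed for the design.
#' @return List of class `lhn_lhs` with `design` (n x 30 data frame),
#'   `unit` (the underlying \[0,1\] hypercube), `ranges`, `seed`.
#' @export
lhs_sample <- function(ranges = default_ranges(), n, seed = 1L) {
  ranges <- validate_ranges(ranges)
  stopifnot(n >= 2)
  set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  meta <- .param_meta()
  x <- matrix(NA_real_, n, length(ranges),
              dimnames = list(NULL, names(ranges)))
  for (j in seq_along(ranges)) {
    r <- ranges[[j]]
    x[, j] <- if (r$dist == "triangle")
      qtriangle(u[, j], r$lower, r$upper, r$mode)
    else
      stats::qunif(u[, j], r$lower, r$upper)
    if (meta$integer[match(names(ranges)[j], meta$name)])
      x[, j] <- round(x[, j])
  }
  structure(list(design = as.data.frame(x), unit = u,
                 ranges = ranges, seed = seed), class = "lhn_lhs")
}

#' Partial rank correlation coefficients
#'
#' Rank-transform every column of `X` and `y` (average ranks for ties);
#' for each parameter j, the PRCC is the Pearson correlation between the
#' residuals of rank(X_j) regressed on the ranks of all other columns and
#' the residuals of rank(y) regressed on the same -- the standard
#' double-residualization (Iman--Conover) formulation.
#'
#' @param X Design matrix or data frame (n x p, n >= p + 2, no constant
#'   column).
#' @param y Outcome vector of length n.
#' @return Data frame with `parameter` and `prcc`; a singular residual
#'   regression yields `NA` with a warning, never a silent 0.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); np <- ncol(X)
  stopifnot(n == length(y), n >= np + 2)
  const <- apply(X, 2, function(col) min(col) == max(col))
  if (any(const))
    stop("constant column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  rX <- apply(X, 2, rank)
  ry <- rank(y)
  out <- numeric(np)
  degenerate <- min(y) == max(y)
  for (j in seq_len(np)) {
    if (degenerate) { out[j] <- NA_real_; next }
    q <- qr(cbind(1, rX[, -j, drop = FALSE]))
    ex <- qr.resid(q, rX[, j])
    ey <- qr.resid(q, ry)
    if (stats::sd(ex) < 1e-12 || stats::sd(ey) < 1e-12) {
      out[j] <- NA_real_
    } else {
      out[j] <- stats::cor(ex, ey)
    }
  }
  if (anyNA(out))
    warning("undefined PRCC (singular residual regression) for: ",
            paste(colnames(X)[is.na(out)], collapse = ", "))
  data.frame(parameter = colnames(X), prcc = out, row.names = NULL)
}

#' Bootstrap confidence intervals for PRCCs
#'
#' Resamples rows with replacement `n_boot` times and reports per-parameter
#' percentile intervals at the Bonferroni-corrected level
#' `1 - base_alpha / family_size`.
#'
#' @param X,y As in [prcc()].
#' @param n_boot Bootstrap replicates (default 100).
#' @param family_size Bonferroni family size (default `ncol(X)`).
#' @param base_alpha Family-wise alpha (default 0.05).
#' @param max_retries Redraws allowed for degenerate bootstrap samples.
#' @return Data frame with `parameter`, `prcc`, `ci_lo`, `ci_hi`,
#'   `n_boot`, `alpha` (the per-parameter alpha after correction).
#' @export
prcc_bootstrap_ci <- function(X, y, n_boot = 100, family_size = ncol(X),
                              base_alpha = 0.05, max_retries = 20) {
  X <- as.matrix(X)
  point <- prcc(X, y)
  n <- nrow(X)
  boot <- matrix(NA_real_, n_boot, ncol(X))
  for (b in seq_len(n_boot)) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (any(apply(Xb, 2, function(col) min(col) == max(col)))) next
      boot[b, ] <- suppressWarnings(prcc(Xb, y[idx])$prcc)
      break
    }
  }
  alpha <- base_alpha / family_size
  qs <- apply(boot, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    stats::quantile(col, probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })
  data.frame(parameter = point$parameter, prcc = point$prcc,
             ci_lo = pmin(qs[1, ], point$prcc),
             ci_hi = pmax(qs[2, ], point$prcc),
             n_boot = n_boot, alpha = alpha, row.names = NULL)
}

# Apply one LHS design row to a scenario template.
.apply_row <- function(template, row) {
  pr <- template$params
  pr[names(row)] <- as.numeric(row)
  template$params <- structure(pr, class = "lhn_params")
  template
}

#' LHS-PRCC sensitivity experiment
#'
#' Draws an LHS design over the 30 parameters, runs one seeded simulation
#' per row (row k uses `seed + k`), computes the three study outcomes
#' (health, praxis, knowledge) per run, and reports PRCCs (with optional
#' bootstrap CIs) of every parameter against every outcome.
#'
#' @param ranges Ranges list.
#' @param n_samples Number of LHS rows (the reference experiment uses 1000).
#' @param template Scenario template supplying all held-constant fields.
#' @param seed Base seed (design and per-row run seeds derive from it).
#' @param n_boot Bootstrap replicates for CIs; 0 skips CIs.
#' @return List of class `lhn_sensitivity`: `design`, `outcomes` (data
#'   frame: row, seed, health, praxis, knowledge, items_added), `prcc`
#'   (named list of data frames per outcome), `n_failed`.
#' @export
run_sensitivity <- function(ranges = default_ranges(), n_samples = 1000,
                            template = lhn_scenario(), seed = 1L,
                            n_boot = 0) {
  des <- lhs_sample(ranges, n_samples, seed = seed)
  X <- des$design
  rows <- vector("list", n_samples)
  failed <- logical(n_samples)
  for (k in seq_len(n_samples)) {
    scn <- .apply_row(template, X[k, ])
    scn$seed <- seed + k
    o <- tryCatch(simulate_lhn(scn)$outcomes, error = function(e) NULL)
    if (is.null(o)) { failed[k] <- TRUE; next }
    rows[[k]] <- data.frame(row = k, seed = seed + k, health = o$health,
                            praxis = o$praxis, knowledge = o$knowledge,
                            items_added = o$items_added)
  }
  if (any(failed))
    warning(sum(failed), " simulation row(s) failed and were excluded")
  outcomes <- do.call(rbind, rows[!failed])
  Xok <- X[!failed, , drop = FALSE]
  res <- lapply(c(health = "health", praxis = "praxis",
                  knowledge = "knowledge"), function(oc) {
    if (n_boot > 0) prcc_bootstrap_ci(Xok, outcomes[[oc]], n_boot = n_boot)
    else prcc(Xok, outcomes[[oc]])
  })
  structure(list(design = X, outcomes = outcomes, prcc = res,
                 n_failed = sum(failed), seed = seed),
            class = "lhn_sensitivity")
}

#' Solution-space grid exploration
#'
#' Two parameters take `n_increments` evenly spaced values spanning their
#' ranges (endpoints included) while all other parameters sit at their
#' range midpoints; each grid cell reports the mean (and SD) of the chosen
#' outcome over seeded replicate runs. The reference plots use 41 x 41 =
#' 1,681 cells.
#'
#' @param x_param,y_param Parameter names (distinct, both in `ranges`).
#' @param ranges Ranges list.
#' @param n_increments Grid points per axis (default 41).
#' @param outcome `"health"`, `"praxis"` or `"knowledge"`.
#' @param template Scenario template.
#' @param seed Base seed.
#' @param replicates_per_cell Replicate runs per cell (default 3).
#' @return Data frame of class `lhn_grid`: `x`, `y`, `mean`, `sd`, `n`.
#' @export
grid_explore <- function(x_param, y_param, ranges = default_ranges(),
                         n_increments = 41,
                         outcome = c("health", "praxis", "knowledge"),
                         template = lhn_scenario(), seed = 1L,
                         replicates_per_cell = 3) {
  outcome <- match.arg(outcome)
  ranges <- validate_ranges(ranges)
  stopifnot(x_param != y_param,
            x_param %in% names(ranges), y_param %in% names(ranges))
  meta <- .param_meta()
  axis <- function(nm) {
    v <- seq(ranges[[nm]]$lower, ranges[[nm]]$upper, length.out = n_increments)
    if (meta$integer[match(nm, meta$name)]) v <- round(v)
    v
  }
  xs <- axis(x_param); ys <- axis(y_param)
  base <- template
  base$params <- midpoint_params(ranges)
  cells <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  mu <- numeric(nrow(cells)); sdv <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    scn <- base
    scn$params[[x_param]] <- cells$x[i]
    scn$params[[y_param]] <- cells$y[i]
    vals <- vapply(seq_len(replicates_per_cell), function(r) {
      scn$seed <- seed + (i - 1) * replicates_per_cell + r
      simulate_lhn(scn)$outcomes[[outcome]]
    }, 0)
    mu[i] <- mean(vals)
    sdv[i] <- if (length(vals) > 1) stats::sd(vals) else 0
  }
  structure(data.frame(x = cells$x, y = cells$y, mean = mu, sd = sdv,
                       n = replicates_per_cell),
            class = c("lhn_grid", "data.frame"),
            x_param = x_param, y_param = y_param, outcome = outcome)
}

#' Level presets for the factorial intervention experiment
#'
#' Two coordinate sets for the low/medium/high network-functioning
#' settings (selection efficiency maximum, zero-praxis misjudgment
#' probability). `"selection_sweep"` (10/0.001, 100/0.01, 1000/0.01) keeps
#' evaluation nearly perfect and sweeps the selection ceiling;
#' `"regime_anchors"` (10/0.20, 200/0.10, 1000/0.001) co-varies both levers
#' and anchors the declining / stable / improving health regimes of the
#' solution-space contours.
#'
#' @param preset `"selection_sweep"` or `"regime_anchors"`.
#' @return Data frame with `lhn`, `selection_efficiency_maximum`,
#'   `evaluation_accuracy_minimum_praxis`.
#' @export
lhn_level_preset <- function(preset = c("selection_sweep", "regime_anchors")) {
  preset <- match.arg(preset)
  if (preset == "selection_sweep")
    data.frame(lhn = c("low", "medium", "high"),
               selection_efficiency_maximum = c(10, 100, 1000),
               evaluation_accuracy_minimum_praxis = c(0.001, 0.01, 0.01))
  else
    data.frame(lhn = c("low", "medium", "high"),
               selection_efficiency_maximum = c(10, 200, 1000),
               evaluation_accuracy_minimum_praxis = c(0.20, 0.10, 0.001))
}

#' 3x3x3 factorial intervention experiment
#'
#' Crosses network functioning (low/medium/high, per the chosen preset) with
#' pre-visit planning and enhanced-registry levels (low/medium/high each,
#' applied to every care center). All other parameters sit at their range
#' midpoints. Each of the 27 cells reports the ensemble median (and SD) of
#' the median final patient health over seeded replicates.
#'
#' @param template Scenario template.
#' @param levels LHN level table ([lhn_level_preset()]).
#' @param n_replicates Replicates per cell (default 30).
#' @param seed Base seed.
#' @param ranges Ranges whose midpoints supply held-constant parameters.
#' @return Data frame of class `lhn_factorial`: `lhn`, `pvp`, `er`,
#'   `median_health`, `sd`, `n`.
#' @export
factorial_experiment <- function(template = lhn_scenario(),
                                 levels = lhn_level_preset("selection_sweep"),
                                 n_replicates = 30, seed = 1L,
                                 ranges = default_ranges()) {
  need <- c("lhn", "selection_efficiency_maximum",
            "evaluation_accuracy_minimum_praxis")
  if (!all(need %in% names(levels)) || nrow(levels) != 3)
    stop("levels must define selection efficiency and evaluation accuracy ",
         "for the three LHN levels")
  base <- template
  base$params <- midpoint_params(ranges)
  grid <- expand.grid(lhn = levels$lhn, pvp = .levels3, er = .levels3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  med <- numeric(nrow(grid)); sdv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    lv <- levels[levels$lhn == grid$lhn[i], ]
    scn <- base
    scn$params$selection_efficiency_maximum <- lv$selection_efficiency_maximum
    scn$params$evaluation_accuracy_minimum_praxis <-
      lv$evaluation_accuracy_minimum_praxis
    scn$pvp_level <- rep(grid$pvp[i], scn$n_care_centers)
    scn$er_level <- rep(grid$er[i], scn$n_care_centers)
    vals <- vapply(seq_len(n_replicates), function(r) {
      scn$seed <- seed + (i - 1) * n_replicates + r
      simulate_lhn(scn)$outcomes$median_final_health
    }, 0)
    med[i] <- stats::median(vals)
    sdv[i] <- if (length(vals) > 1) stats::sd(vals) else 0
  }
  structure(data.frame(lhn = grid$lhn, pvp = grid$pvp, er = grid$er,
                       median_health = med, sd = sdv, n = n_replicates),
            class = c("lhn_factorial", "data.frame"))
}
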