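# Population construction: care centers, clinicians, patients, the
# phenotype x treatment effectiveness structure, and influence networks.
# Everything is generated from the scenario and the current RNG state.

#' Build the phenotype x treatment effectiveness matrix
#'
#' Per phenotype, treatment target-health values are the evenly spaced grid
#' from `best_target` down to `worst_target`, assigned to the treatments by
#' an independent random permutation per phenotype. Within each row the
#' targets are therefore strictly distinct and the treatment ranking total.
#'
#' @param condition An `lhn_condition`.
#' @return A list with `targets` (phenotype x treatment matrix of target
#'   health values) and `ranks` (same shape; 1 = best treatment).
#' @export
build_condition_matrix <- function(condition) {
  np <- condition$n_phenotypes
  nt <- condition$n_treatments
  grid <- seq(condition$best_target, condition$worst_target, length.out = nt)
  targets <- t(vapply(seq_len(np),
                      function(i) grid[sample.int(nt)],
                      numeric(nt)))
  ranks <- t(apply(-targets, 1, rank))
  storage.mode(ranks) <- "integer"
  list(targets = targets, ranks = ranks)
}

#' Build an undirected influence network
#'
#' Configuration-model style: `round(n_agents * edges_per_agent / 2)` pair
#' draws. Each drawn edge is an across-center edge with probability
#' `across_prop` (two distinct centers, one endpoint each), otherwise a
#' within-center edge. Self-loops and duplicate edges are dropped; a
#' single-center population falls back to within-center edges.
#'
#' @param ids_by_center List of integer agent-id vectors, one per center.
#' @param edges_per_agent Expected edges per agent (>= 0).
#' @param across_prop Fraction of edges crossing care centers, in \[0, 1\].
#' @return A list with `edges` (2-column integer matrix, each row an
#'   undirected edge) and `across` (logical flag per edge).
#' @export
build_influence_network <- function(ids_by_center, edges_per_agent, across_prop) {
  n_centers <- length(ids_by_center)
  sizes <- lengths(ids_by_center)
  n <- sum(sizes)
  n_edges <- round(n * edges_per_agent / 2)
  empty <- list(edges = matrix(integer(0), 0, 2), across = logical(0))
  if (n_edges == 0 || n < 2) return(empty)
  multi <- sum(sizes >= 2) > 0
  across <- stats::runif(n_edges) < across_prop
  if (n_centers < 2) across[] <- FALSE
  a <- integer(n_edges); b <- integer(n_edges)
  eligible_within <- which(sizes >= 2)
  for (i in seq_len(n_edges)) {
    if (across[i]) {
      cs <- sample.int(n_centers, 2)
      a[i] <- ids_by_center[[cs[1]]][sample.int(sizes[cs[1]], 1)]
      b[i] <- ids_by_center[[cs[2]]][sample.int(sizes[cs[2]], 1)]
    } else {
      if (!length(eligible_within)) { a[i] <- NA; next }
      cc <- if (length(eligible_within) == 1) eligible_within else
        eligible_within[sample.int(length(eligible_within), 1)]
      pair <- sample.int(sizes[cc], 2)
      a[i] <- ids_by_center[[cc]][pair[1]]
      b[i] <- ids_by_center[[cc]][pair[2]]
    }
  }
  keep <- !is.na(a) & a != b
  a <- a[keep]; b <- b[keep]; across <- across[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(cbind(lo, hi))
  list(edges = cbind(lo[!dup], hi[!dup]), across = across[!dup])
}

#' Build the full population for a scenario
#'
#' Patients are assigned to care centers and, within a center, to a
#' clinician; phenotypes are uniform at random; initial health is
#' Uniform(0.3, 0.7); all agents start unaware except the seeded fractions,
#' which start at the configured seeding level; each patient's first
#' encounter falls uniformly within the first encounter period. Uses the
#' current RNG state (callers seed it), so the same seed reproduces the
#' same population.
#'
#' @param scenario A validated `lhn_scenario`.
#' @return A list describing patients, clinicians, the effectiveness
#'   structure and both influence networks.
#' @export
build_population <- function(scenario) {
  p <- scenario$params
  nc <- scenario$n_care_centers
  ncl <- nc * scenario$clinicians_per_center
  npat <- ncl * scenario$patients_per_clinician
  cl_center <- rep(seq_len(nc), each = scenario$clinicians_per_center)
  pat_clin <- rep(seq_len(ncl), each = scenario$patients_per_clinician)
  pat_center <- cl_center[pat_clin]
  cond <- scenario$condition
  eff <- build_condition_matrix(cond)
  phen <- sample.int(cond$n_phenotypes, npat, replace = TRUE)
  health0 <- stats::runif(npat, 0.3, 0.7)
  # patients start with some knowledge of their own treatment response
  # accumulated before enrollment
  iri0 <- if (scenario$initial_iri_max > 0)
    stats::runif(npat, 0, scenario$initial_iri_max) else numeric(npat)
  lev_names <- c("unaware", "aware", "participating", "contributing", "owning")
  seed_lev_pat <- match(scenario$seed_engagement$patient_level, lev_names) - 1L
  seed_lev_cl <- match(scenario$seed_engagement$clinician_level, lev_names) - 1L
  eng_pat <- integer(npat)
  k <- round(scenario$seed_engagement$patient_frac * npat)
  if (k > 0) eng_pat[sample.int(npat, k)] <- seed_lev_pat
  ko <- round(scenario$seed_engagement$patient_owning_frac * npat)
  if (ko > 0) eng_pat[sample.int(npat, ko)] <- 4L
  eng_cl <- integer(ncl)
  kc <- round(scenario$seed_engagement$clinician_frac * ncl)
  if (kc > 0) eng_cl[sample.int(ncl, kc)] <- seed_lev_cl
  next_enc <- sample.int(p$encounter_period, npat, replace = TRUE) - 1L
  pat_ids_by_center <- split(seq_len(npat), pat_center)
  cl_ids_by_center <- split(seq_len(ncl), cl_center)
  net_pat <- build_influence_network(pat_ids_by_center,
                                     p$patient_network_edges,
                                     p$patient_influence_across_prop)
  net_cl <- build_influence_network(cl_ids_by_center,
                                    p$clinician_network_edges,
                                    p$clinician_influence_across_prop)
  list(
    n_patients = npat, n_clinicians = ncl, n_centers = nc,
    pat_center = pat_center, pat_clin = pat_clin,
    cl_center = cl_center,
    phenotype = phen, health0 = health0, iri0 = iri0,
    eng_pat0 = eng_pat, eng_cl0 = eng_cl,
    next_enc0 = next_enc,
    effect = eff,
    net_pat = net_pat, net_cl = net_cl)
}

#' Dump a population as a data frame (one row per agent)
#'
#' Debug/regression view: id, kind, center, clinician, phenotype, initial
#' health and engagement.
#'
#' @param pop A population as returned by [build_population()].
#' @return A data frame.
#' @export
population_frame <- function(pop) {
  rbind(
    data.frame(id = seq_len(pop$n_patients), kind = "patient",
               center = pop$pat_center, clinician = pop$pat_clin,
               phenotype = pop$phenotype, health0 = pop$health0,
               engagement0 = pop$eng_pat0),
    data.frame(id = seq_len(pop$n_clinicians), kind = "clinician",
               center = pop$cl_center, clinician = NA_integer_,
               phenotype = NA_integer_, health0 = NA_real_,
               engagement0 = pop$eng_cl0))
}
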