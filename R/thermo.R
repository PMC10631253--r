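# Boltzmann statistics over competing transition states, the coverage-based
# conformer selection, the TS2-vs-TS1 energy check, and pure-TST product
# percentages.

#' Boltzmann populations of competing transition states
#'
#' Weights are proportional to `exp(-ddG / (R T))` with
#' `R = 1.98720425e-3 kcal mol^-1 K^-1`; energies are shifted so the lowest
#' member has relative barrier 0, making the weights invariant under any
#' common energy shift.
#'
#' @param energies numeric vector of Gibbs free energies (kcal/mol) on a
#'   common reference; names, if present, become member labels.
#' @param temperature temperature in K.
#' @return an object of class `boltzmann_ensemble` with a `members` data frame
#'   (`label`, `ddG`, `weight`), sorted by increasing relative barrier.
#' @export
boltzmann_weights <- function(energies, temperature = 298.15) {
  if (!length(energies)) .stop_validation("empty energy list")
  if (any(!is.finite(energies))) .stop_validation("non-finite energy")
  if (!is.finite(temperature) || temperature <= 0)
    .stop_validation("temperature must be positive")
  labels <- names(energies)
  if (is.null(labels)) labels <- paste0("member", seq_along(energies))
  ddg <- energies - min(energies)
  ord <- order(ddg, labels)
  ddg <- ddg[ord]; labels <- labels[ord]
  w <- exp(-ddg / (.const$R_kcal * temperature))
  w <- w / sum(w)
  structure(list(
    members = data.frame(label = labels, ddG = unname(ddg),
                         weight = unname(w), stringsAsFactors = FALSE),
    temperature = temperature
  ), class = "boltzmann_ensemble")
}

#' @export
print.boltzmann_ensemble <- function(x, ...) {
  cat("<boltzmann_ensemble> ", nrow(x$members), " members at ",
      x$temperature, " K\n", sep = "")
  print(transform(x$members, ddG = round(ddG, 3), weight = round(weight, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Restrict an ensemble to its leading Boltzmann coverage
#'
#' Returns the smallest low-energy prefix whose cumulative population reaches
#' the requested coverage, re-normalized to sum to one. Members tied in
#' relative barrier with the member at the coverage boundary are all kept, so
#' the result does not depend on input order. The lowest-energy member is
#' always retained.
#'
#' @param ensemble a [boltzmann_weights()] result.
#' @param coverage fraction in (0, 1]; default 0.99.
#' @return a `boltzmann_ensemble` over the retained members.
#' @export
select_top_coverage <- function(ensemble, coverage = 0.99) {
  stopifnot(inherits(ensemble, "boltzmann_ensemble"))
  if (!is.finite(coverage) || coverage <= 0 || coverage > 1)
    .stop_validation("coverage must be in (0, 1]")
  m <- ensemble$members
  cum <- cumsum(m$weight)
  k <- which(cum >= coverage - 1e-12)[1]
  if (is.na(k)) k <- nrow(m)
  # include members tied with the boundary one
  k <- max(which(m$ddG <= m$ddG[k] + 1e-12))
  kept <- m[seq_len(k), , drop = FALSE]
  kept$weight <- kept$weight / sum(kept$weight)
  structure(list(members = kept, temperature = ensemble$temperature),
            class = "boltzmann_ensemble")
}

#' Energy check deciding between dynamic and TST treatment of a branch
#'
#' The stream analysis is trusted for a branch only when every second
#' transition state downstream of the first one lies strictly below it in
#' Gibbs free energy (trajectories then have enough energy to pass over the
#' intermediate without equilibrating). An empty TS2 list (all channels
#' barrierless) passes vacuously. Equality is sent to the TST fallback as the
#' conservative branch.
#'
#' @param ts1 the branch's TS1 [stationary_point()].
#' @param downstream_ts2s list of TS2 [stationary_point()]s (may be empty).
#' @return an object of class `method_decision` with fields `pathway_label`,
#'   `method` (`"VRAI"` or `"TST_fallback"`) and `reason`.
#' @export
energy_check <- function(ts1, downstream_ts2s = list()) {
  stopifnot(inherits(ts1, "stationary_point"))
  if (ts1$role != "TS1" && ts1$role != "TS0")
    .stop_validation("energy_check expects a TS1 (or TS0), got ", ts1$role)
  if (!length(downstream_ts2s)) {
    return(structure(list(pathway_label = ts1$label, method = "VRAI",
                          reason = "no second transition states (barrierless channels)"),
                     class = "method_decision"))
  }
  g1 <- ts1$gibbs_free_energy
  offending <- Filter(function(sp) sp$gibbs_free_energy >= g1, downstream_ts2s)
  if (!length(offending)) {
    structure(list(pathway_label = ts1$label, method = "VRAI",
                   reason = "all second transition states lie below the first"),
              class = "method_decision")
  } else {
    labs <- vapply(offending, `[[`, "", "label")
    structure(list(pathway_label = ts1$label, method = "TST_fallback",
                   reason = paste0("TS2 not below TS1: ",
                                   paste(labs, collapse = ", "))),
              class = "method_decision")
  }
}

#' @export
print.method_decision <- function(x, ...) {
  cat("<method_decision> ", x$pathway_label, ": ", x$method,
      " (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Product percentages under transition state theory only
#'
#' Branch populations over the TS1 conformers come from Boltzmann weighting
#' with the leading-coverage selection; within each branch the TS2 conformers
#' are weighted the same way and pruned at the same coverage. Barrierless
#' direct channels carry the full population of their branch. Percentages per
#' product identity are the pathway-population sums, scaled to 100.
#'
#' @param network a [reaction_network()].
#' @param temperature temperature in K.
#' @param coverage Boltzmann coverage fraction applied at the TS1 level and
#'   within each branch.
#' @return a `product_distribution` (see [run_selectivity_pipeline()]).
#' @export
tst_product_percentages <- function(network, temperature = 298.15,
                                    coverage = 0.99) {
  stopifnot(inherits(network, "reaction_network"))
  cfg <- run_config(temperature_K = temperature, coverage_fraction = coverage,
                    mode = "tst_only")
  run_selectivity_pipeline(network, cfg)
}
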