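# Full selectivity pipeline: per-branch method decision, stream or TST branch
# resolution, population x ratio flow aggregation, and comparison with
# experiment.

#' Pipeline run configuration
#'
#' @param temperature_K temperature in K (> 0).
#' @param coverage_fraction Boltzmann coverage retained at the TS1 level and
#'   within each branch, in (0, 1].
#' @param width_model `"zero_point"` or `"thermal"` harmonic stream width.
#' @param bond_threshold_A initial bond-difference selection threshold
#'   (Angstrom, > 0).
#' @param mode `"with_vrai"` (dynamics-aware) or `"tst_only"`.
#' @param seed optional integer seed (trajectory-oracle commands only).
#' @return an object of class `run_config`.
#' @export
run_config <- function(temperature_K = 298.15, coverage_fraction = 0.99,
                       width_model = c("zero_point", "thermal"),
                       bond_threshold_A = 0.3,
                       mode = c("with_vrai", "tst_only"), seed = NULL) {
  width_model <- match.arg(width_model)
  mode <- match.arg(mode)
  if (!is.numeric(temperature_K) || !is.finite(temperature_K) ||
      temperature_K <= 0)
    .stop_validation("temperature_K must be a positive number")
  if (!is.numeric(coverage_fraction) || !is.finite(coverage_fraction) ||
      coverage_fraction <= 0 || coverage_fraction > 1)
    .stop_validation("coverage_fraction must lie in (0, 1]")
  if (!is.numeric(bond_threshold_A) || !is.finite(bond_threshold_A) ||
      bond_threshold_A <= 0)
    .stop_validation("bond_threshold_A must be a positive number")
  structure(list(temperature_K = temperature_K,
                 coverage_fraction = coverage_fraction,
                 width_model = width_model,
                 bond_threshold_A = bond_threshold_A,
                 mode = mode, seed = seed),
            class = "run_config")
}

# resolve one TS1 branch into per-product fractions
.resolve_branch <- function(net, ts1_lab, cfg) {
  roles <- .roles(net)
  ts1 <- net$points[[ts1_lab]]
  kids <- .children(net, ts1_lab)
  direct <- kids[roles[kids] == "product"]
  int_lab <- .intermediate_of(net, ts1_lab)

  if (is.null(int_lab)) {
    # all channels barrierless: the single product takes the full branch
    return(list(fractions = stats::setNames(1, direct),
                decision = energy_check(ts1, list())))
  }
  ts2_labs <- .ts2s_of(net, int_lab)
  ts2s <- net$points[ts2_labs]

  tst_branch <- function(decision) {
    if (!length(ts2s))
      .stop_validation("branch via ", ts1_lab, " has no second transition ",
                       "states; its channels cannot be resolved by TST")
    ens <- boltzmann_weights(
      stats::setNames(vapply(ts2s, `[[`, 0, "gibbs_free_energy"), ts2_labs),
      cfg$temperature_K)
    ens <- select_top_coverage(ens, cfg$coverage_fraction)
    fr <- stats::setNames(numeric(0), character(0))
    for (i in seq_len(nrow(ens$members))) {
      prod <- .product_of_ts2(net, ens$members$label[i])
      fr[prod] <- (if (prod %in% names(fr)) fr[[prod]] else 0) +
        ens$members$weight[i]
    }
    list(fractions = fr, decision = decision)
  }

  if (cfg$mode == "tst_only")
    return(tst_branch(structure(list(pathway_label = ts1_lab, method = "TST",
                                     reason = "tst_only mode"),
                                class = "method_decision")))

  decision <- energy_check(ts1, unname(ts2s))
  if (decision$method == "TST_fallback") return(tst_branch(decision))

  prods <- .reachable_products(net, int_lab)
  if (length(prods) < 1L)
    .stop_validation("intermediate ", int_lab, " reaches no product")
  if (length(prods) == 1L)
    return(list(fractions = stats::setNames(1, prods), decision = decision))

  # channel barrier heights, for the degenerate-pair fallback
  ce <- stats::setNames(rep(NA_real_, length(prods)), prods)
  for (t2 in ts2_labs) {
    p <- .product_of_ts2(net, t2)
    g <- net$points[[t2]]$gibbs_free_energy
    if (is.na(ce[[p]]) || g < ce[[p]]) ce[[p]] <- g
  }
  res <- predict_multi_product_ratio(
    ts1, net$points[[int_lab]], net$points[prods],
    temperature = cfg$temperature_K,
    config = list(bond_threshold_A = cfg$bond_threshold_A,
                  width_model = cfg$width_model,
                  channel_energies = ce[!is.na(ce)]))
  list(fractions = res$fractions, decision = decision, vrai = res)
}

#' Run the full selectivity pipeline
#'
#' Populations of the first transition states come from Boltzmann weighting
#' with leading-coverage selection. In `"with_vrai"` mode each retained branch
#' is resolved by the energy check into either a trajectory-stream partition
#' over all products reachable from its intermediate, or a TST fallback over
#' its second transition states; barrierless direct channels carry their full
#' branch weight. When the network declares a dynamic complexation stage
#' (`ts0_stage`), a stream analysis at TS0 first partitions the flow among the
#' stage's branch targets, and TS1 conformers (matched by stereodescriptor)
#' are weighted within each family. In `"tst_only"` mode every branch is
#' resolved by TST. Final percentages are pathway-population sums per product
#' identity, scaled to 100.
#'
#' @param network a [reaction_network()].
#' @param config a [run_config()].
#' @return an object of class `product_distribution`: percentages per product
#'   identity, per-pathway flows, method decisions, and the mean absolute
#'   error versus experiment when the network carries experimental
#'   percentages.
#' @export
run_selectivity_pipeline <- function(network, config = run_config()) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(config, "run_config"))
  ts1s <- .ts1_labels(network)
  if (!length(ts1s)) .stop_validation("network has no TS1")

  # TS1 populations, optionally partitioned by a dynamic TS0 stage
  ts0_flow <- NULL
  g1 <- stats::setNames(
    vapply(network$points[ts1s], `[[`, 0, "gibbs_free_energy"), ts1s)
  use_ts0 <- !is.null(network$ts0_stage) &&
    isTRUE(network$ts0_stage$dynamic %||% TRUE) &&
    config$mode == "with_vrai"
  if (use_ts0) {
    st <- network$ts0_stage
    targets <- .children(network, st$int1)
    targets <- targets[startsWith(.roles(network)[targets], "INT")]
    if (length(targets) < 2L)
      .stop_validation("ts0_stage requires at least two branch targets ",
                       "downstream of ", st$int1)
    res0 <- predict_multi_product_ratio(
      network$points[[st$ts0]], network$points[[st$int1]],
      network$points[targets], temperature = config$temperature_K,
      config = list(bond_threshold_A = config$bond_threshold_A,
                    width_model = config$width_model))
    fam_of_target <- vapply(network$points[targets], `[[`, "", "stereochem")
    ts0_flow <- list(stage = st$ts0, fractions = res0$fractions,
                     families = fam_of_target)
    pop <- stats::setNames(numeric(length(ts1s)), ts1s)
    for (ti in seq_along(targets)) {
      fam <- fam_of_target[[ti]]
      members <- ts1s[vapply(network$points[ts1s], `[[`, "", "stereochem") == fam]
      if (!length(members))
        .stop_validation("no TS1 with stereodescriptor '", fam,
                         "' for ts0_stage branch ", targets[ti])
      ens <- select_top_coverage(boltzmann_weights(g1[members],
                                                   config$temperature_K),
                                 config$coverage_fraction)
      pop[ens$members$label] <- pop[ens$members$label] +
        res0$fractions[[targets[ti]]] * ens$members$weight
    }
  } else {
    ens <- select_top_coverage(boltzmann_weights(g1, config$temperature_K),
                               config$coverage_fraction)
    pop <- stats::setNames(numeric(length(ts1s)), ts1s)
    pop[ens$members$label] <- ens$members$weight
  }

  catalog <- .catalog(network)
  contrib <- stats::setNames(numeric(nrow(catalog)), catalog$label)
  flows <- list(); decisions <- list()
  for (lab in ts1s) {
    if (pop[[lab]] <= 0) next
    br <- .resolve_branch(network, lab, config)
    decisions[[lab]] <- br$decision
    contribs <- pop[[lab]] * br$fractions
    for (p in names(contribs)) contrib[[p]] <- contrib[[p]] + contribs[[p]]
    flows[[lab]] <- list(ts1_label = lab, ts1_population = unname(pop[[lab]]),
                         branch_fractions = br$fractions,
                         contributions = contribs)
  }

  total <- sum(contrib)
  if (total <= 0) .stop_validation("no flow reached any product")
  pct_label <- 100 * contrib / total
  pct <- stats::setNames(numeric(0), character(0))
  for (k in unique(catalog$key))
    pct[k] <- sum(pct_label[catalog$label[catalog$key == k]])

  mae <- if (!is.null(network$experimental))
    .mae(pct, network$experimental) else NULL

  structure(list(percentages = pct,
                 percentages_by_label = pct_label,
                 pathway_flows = flows,
                 ts0_flow = ts0_flow,
                 method_per_pathway = decisions,
                 mae_vs_experiment = mae,
                 experimental = network$experimental,
                 config = config,
                 catalog = catalog),
            class = "product_distribution")
}

.mae <- function(calculated, experimental) {
  missing_in_calc <- setdiff(names(experimental), names(calculated))
  missing_in_exp <- setdiff(names(calculated), names(experimental))
  if (length(missing_in_calc) || length(missing_in_exp))
    .stop_validation(
      "product catalogs differ",
      if (length(missing_in_calc))
        paste0("; absent from calculation: ",
               paste(missing_in_calc, collapse = ", ")) else "",
      if (length(missing_in_exp))
        paste0("; absent from experiment: ",
               paste(missing_in_exp, collapse = ", ")) else "")
  mean(abs(calculated - experimental[names(calculated)]))
}

#' Mean absolute error versus experimental percentages
#'
#' @param distribution a [run_selectivity_pipeline()] result, or a named
#'   numeric vector of calculated percentages.
#' @param experimental named numeric vector of experimental percentages over
#'   the same product catalog.
#' @return the mean over products of `|calculated - experimental|`, in
#'   percentage points.
#' @export
mae_vs_experiment <- function(distribution, experimental) {
  calc <- if (inherits(distribution, "product_distribution"))
    distribution$percentages else distribution
  .mae(calc, experimental)
}

#' @export
print.product_distribution <- function(x, ...) {
  cat("Product distribution (", x$config$mode, " mode, ",
      x$config$temperature_K, " K)\n", sep = "")
  has_exp <- !is.null(x$experimental)
  for (k in names(x$percentages)) {
    cat(sprintf("  %-28s %7.2f %%", k, x$percentages[[k]]))
    if (has_exp && k %in% names(x$experimental))
      cat(sprintf("   (exp %6.2f %%)", x$experimental[[k]]))
    cat("\n")
  }
  if (!is.null(x$mae_vs_experiment))
    cat(sprintf("  MAE vs experiment: %.2f percentage points\n",
                x$mae_vs_experiment))
  invisible(x)
}

#' @export
summary.product_distribution <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPathway flows:\n")
  for (fl in x$pathway_flows) {
    meth <- x$method_per_pathway[[fl$ts1_label]]$method
    cat(sprintf("  %-16s population %6.2f %%  [%s]\n", fl$ts1_label,
                100 * fl$ts1_population, meth))
    for (p in names(fl$branch_fractions))
      cat(sprintf("      -> %-20s %6.2f %% of branch\n", p,
                  100 * fl$branch_fractions[[p]]))
  }
  if (!is.null(x$ts0_flow)) {
    cat(sprintf("  complexation stage %s partition:\n", x$ts0_flow$stage))
    for (t in names(x$ts0_flow$fractions))
      cat(sprintf("      -> %-20s %6.2f %%\n", t,
                  100 * x$ts0_flow$fractions[[t]]))
  }
  invisible(x)
}

#' @export
coef.product_distribution <- function(object, ...) object$percentages

#' @export
as.data.frame.product_distribution <- function(x, ...) {
  d <- data.frame(product = names(x$percentages),
                  calculated_pct = unname(x$percentages),
                  stringsAsFactors = FALSE)
  if (!is.null(x$experimental))
    d$experimental_pct <- unname(x$experimental[d$product])
  d
}

#' @export
plot.product_distribution <- function(x, ...) {
  d <- as.data.frame(x)
  if (!is.null(x$experimental)) {
    m <- rbind(calculated = d$calculated_pct,
               experimental = d$experimental_pct)
    graphics::barplot(m, beside = TRUE, names.arg = d$product,
                      legend.text = rownames(m), ylab = "percentage",
                      las = 2, ...)
  } else {
    graphics::barplot(d$calculated_pct, names.arg = d$product,
                      ylab = "percentage", las = 2, ...)
  }
  invisible(x)
}

#' Sankey edge list of a pipeline run
#'
#' Exports the flow diagram as a `(source, target, flow)` table in percent:
#' total population into each retained first transition state, and each
#' branch's contributions into the products.
#'
#' @param distribution a [run_selectivity_pipeline()] result.
#' @return a data frame with columns `source`, `target`, `flow_pct`.
#' @export
sankey_edges <- function(distribution) {
  stopifnot(inherits(distribution, "product_distribution"))
  rows <- list()
  for (fl in distribution$pathway_flows) {
    rows[[length(rows) + 1L]] <- data.frame(
      source = "population", target = fl$ts1_label,
      flow_pct = 100 * fl$ts1_population, stringsAsFactors = FALSE)
    for (p in names(fl$contributions))
      rows[[length(rows) + 1L]] <- data.frame(
        source = fl$ts1_label, target = p,
        flow_pct = 100 * fl$contributions[[p]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
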