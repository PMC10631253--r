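# Reaction networks: the directed pathway graph from first transition states
# through intermediates to labelled products.

#' Construct a reaction network
#'
#' Points are [stationary_point()] objects; edges are directed links among
#' them. Recognized edge patterns (by the roles of their endpoints):
#' `TS1 -> INT*` (a branch's intermediate), `INT* -> TS2/TS3`,
#' `TS2/TS3 -> product`, `INT* -> product` (post-intermediate channel without
#' a resolved second transition state), `TS1 -> product` (barrierless direct
#' channel) and `TS0 -> INT1` (pre-equilibrium stage). A branch's channel kind
#' is `"via_TS2"` when it runs through an intermediate and
#' `"barrierless_direct"` when its TS1 connects straight to a product.
#'
#' @param points list of [stationary_point()] objects.
#' @param edges two-column matrix/data.frame of labels (`from`, `to`), or a
#'   list of length-2 character vectors.
#' @param experimental optional named numeric vector of experimental product
#'   percentages, keyed by product identity (`"species (stereochem)"`).
#' @param ts0_stage optional list `list(ts0 =, int1 =, dynamic = TRUE)`
#'   declaring a dynamically resolved complexation stage upstream of the TS1
#'   conformers.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(points, edges, experimental = NULL,
                             ts0_stage = NULL) {
  if (!length(points)) .stop_validation("network has no stationary points")
  if (!all(vapply(points, inherits, TRUE, "stationary_point")))
    .stop_validation("all points must be stationary_point objects")
  labels <- vapply(points, `[[`, "", "label")
  if (anyDuplicated(labels))
    .stop_validation("duplicate labels: ",
                     paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(points) <- labels

  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) != 2L) .stop_validation("edges must have two columns")
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)

  dangling <- setdiff(c(edges$from, edges$to), labels)
  if (length(dangling))
    .stop_validation("edge references unknown point(s): ",
                     paste(unique(dangling), collapse = ", "))

  # atom-order consistency: the projection math assumes a common atom mapping
  symref <- points[[1]]$geometry$symbols
  for (p in points) {
    if (!identical(p$geometry$symbols, symref))
      .stop_validation("atom-symbol sequence of ", p$label,
                       " differs from ", points[[1]]$label,
                       "; all points must share one atom ordering")
  }

  .check_acyclic(labels, edges)

  roles <- vapply(points, `[[`, "", "role")
  prod_labels <- labels[roles == "product"]
  ref_as_product <- edges$to[roles[match(edges$to, labels)] == "product"]
  missing_prod <- setdiff(ref_as_product, prod_labels)
  if (length(missing_prod))
    .stop_validation("edge points to non-catalog product: ",
                     paste(missing_prod, collapse = ", "))

  net <- structure(list(points = points, edges = edges,
                        experimental = experimental,
                        ts0_stage = ts0_stage),
                   class = "reaction_network")

  # every TS1 has exactly one downstream intermediate unless all channels
  # are barrierless_direct
  for (lab in labels[roles == "TS1"]) {
    kids <- .children(net, lab)
    if (!length(kids))
      .stop_validation("TS1 ", lab, " has no outgoing channel")
    kroles <- roles[match(kids, labels)]
    ints <- kids[startsWith(kroles, "INT")]
    prods <- kids[kroles == "product"]
    if (length(ints) > 1L)
      .stop_validation("TS1 ", lab, " has ", length(ints),
                       " downstream intermediates; expected one")
    if (!length(ints) && length(prods) != length(kids))
      .stop_validation("TS1 ", lab, " children must be one intermediate ",
                       "and/or direct products")
    if (!length(ints) && length(prods) > 1L)
      .stop_validation("TS1 ", lab, " has several barrierless channels but ",
                       "no intermediate to resolve them")
  }

  cat_keys <- .catalog(net)$key
  if (!is.null(experimental)) {
    bad <- setdiff(names(experimental), cat_keys)
    if (length(bad))
      .stop_validation("experimental percentages for unknown product(s): ",
                       paste(bad, collapse = ", "))
  }
  if (!is.null(ts0_stage)) {
    for (f in c("ts0", "int1")) {
      if (is.null(ts0_stage[[f]]) || !ts0_stage[[f]] %in% labels)
        .stop_validation("ts0_stage$", f, " must name a network point")
    }
  }
  net
}

.check_acyclic <- function(labels, edges) {
  indeg <- stats::setNames(integer(length(labels)), labels)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  queue <- labels[indeg == 0L]
  seen <- 0L
  adj <- split(edges$to, edges$from)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != length(labels))
    .stop_validation("the reaction network contains a cycle")
  invisible(TRUE)
}

#' @export
print.reaction_network <- function(x, ...) {
  roles <- vapply(x$points, `[[`, "", "role")
  cat("<reaction_network> ", length(x$points), " points (",
      sum(roles == "TS1"), " TS1, ", sum(startsWith(roles, "INT")), " INT, ",
      sum(roles %in% c("TS2", "TS3")), " TS2/TS3, ",
      sum(roles == "product"), " products), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

.children <- function(net, label) net$edges$to[net$edges$from == label]
.roles <- function(net) vapply(net$points, `[[`, "", "role")

.ts1_labels <- function(net) {
  r <- .roles(net)
  names(net$points)[r == "TS1"]
}

.intermediate_of <- function(net, ts1_label) {
  kids <- .children(net, ts1_label)
  kr <- .roles(net)[kids]
  ints <- kids[startsWith(kr, "INT")]
  if (length(ints)) ints[[1]] else NULL
}

# second transition states attached to an intermediate
.ts2s_of <- function(net, int_label) {
  kids <- .children(net, int_label)
  kids[.roles(net)[kids] %in% c("TS2", "TS3")]
}

# all products reachable downstream of a label (DFS)
.reachable_products <- function(net, label) {
  roles <- .roles(net)
  out <- character(0); stack <- .children(net, label)
  seen <- character(0)
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (roles[[v]] == "product") out <- c(out, v)
    else stack <- c(stack, .children(net, v))
  }
  unique(out)
}

# product point fed by a TS2 (exactly one expected)
.product_of_ts2 <- function(net, ts2_label) {
  kids <- .children(net, ts2_label)
  prods <- kids[.roles(net)[kids] == "product"]
  if (length(prods) != 1L)
    .stop_validation("TS2 ", ts2_label, " must feed exactly one product, ",
                     "found ", length(prods))
  prods
}

# product catalog: data.frame(label, species, stereochem, key)
.catalog <- function(net) {
  roles <- .roles(net)
  prods <- net$points[roles == "product"]
  data.frame(
    label = vapply(prods, `[[`, "", "label"),
    species = vapply(prods, `[[`, "", "species"),
    stereochem = vapply(prods, `[[`, "", "stereochem"),
    key = vapply(prods, .product_key, ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Load a reaction network from a YAML description
#'
#' The YAML file lists every stationary point (geometry file, role, energy,
#' optional modes file and stereochemistry), the edge list, optional
#' experimental percentages and an optional `ts0_stage` block. File paths are
#' resolved relative to the YAML file. Energies are converted to kcal/mol
#' (Hartree inputs via 627.5095) and shifted to a common zero at the
#' lowest-energy point.
#'
#' @param config_path path to the network YAML file.
#' @return a [reaction_network()].
#' @export
load_network <- function(config_path) {
  if (!file.exists(config_path)) .stop_parse("network file not found: ", config_path)
  cfg <- tryCatch(yaml::read_yaml(config_path),
                  error = function(e) .stop_parse("cannot parse ", config_path,
                                                  ": ", conditionMessage(e)))
  base <- dirname(normalizePath(config_path))
  if (is.null(cfg$points) || !length(cfg$points))
    .stop_validation("network config has no points")
  global_unit <- cfg$energy_unit

  units <- vapply(cfg$points, function(p) {
    u <- if (!is.null(p$energy_unit)) p$energy_unit else global_unit
    if (is.null(u)) NA_character_ else as.character(u)
  }, "")
  declared <- unique(units[!is.na(units)])
  if (any(is.na(units)) && length(declared) > 0L)
    .stop_validation("mixed energy units: some points declare a unit (",
                     paste(declared, collapse = ", "),
                     ") and others declare none; set a global energy_unit")
  units[is.na(units)] <- "kcal/mol"
  bad_units <- setdiff(unique(units), c("kcal/mol", "hartree"))
  if (length(bad_units))
    .stop_validation("unknown energy unit(s): ", paste(bad_units, collapse = ", "))

  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  points <- vector("list", length(cfg$points))
  for (i in seq_along(cfg$points)) {
    p <- cfg$points[[i]]
    for (f in c("label", "role", "xyz", "energy"))
      if (is.null(p[[f]]))
        .stop_validation("point ", i, " missing required field '", f, "'")
    geom <- read_xyz(resolve(p$xyz))
    e <- as.numeric(p$energy)
    if (units[i] == "hartree") e <- e * .const$hartree_kcal
    modes <- NULL
    if (!is.null(p$modes)) {
      dialect <- p$modes_dialect
      if (is.null(dialect))
        dialect <- if (grepl("\\.json$", p$modes)) "sidecar_json" else "gaussian_log"
      modes <- read_frequency_data(resolve(p$modes), dialect = dialect,
                                   geometry = geom)
    }
    points[[i]] <- stationary_point(
      label = p$label, role = p$role, geometry = geom, gibbs_free_energy = e,
      modes = modes, stereochem = p$stereochem, species = p$species)
  }

  # common zero: the lowest-energy point
  e0 <- min(vapply(points, `[[`, 0, "gibbs_free_energy"))
  points <- lapply(points, function(sp) {
    sp$gibbs_free_energy <- sp$gibbs_free_energy - e0
    sp
  })

  edges <- lapply(cfg$edges, function(e) c(e[[1]], e[[2]]))
  experimental <- if (!is.null(cfg$experimental)) unlist(cfg$experimental)
  reaction_network(points, edges, experimental = experimental,
                   ts0_stage = cfg$ts0_stage)
}
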