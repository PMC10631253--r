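# Dynamic-selectivity core: 2D bond-difference reduction of the PES,
# orientation of the imaginary eigenvector, harmonic trajectory-stream width,
# and Gaussian partition of the stream among two or more products.
#
# Working picture: reactive trajectories leave the first transition state as a
# stream directed along its imaginary eigenvector; on the reduced 2D surface
# the stream is a Gaussian of width sigma (from the real modes) centred where
# the eigenvector, scaled to the TS-intermediate separation, lands. The ridge
# separating the product valleys passes through the intermediate along the
# bisector of the two intermediate-to-product directions; the product ratio is
# the Gaussian mass on either side of the ridge.

#' Select the bond coordinates that span the bifurcation
#'
#' Returns every atom pair whose interatomic distance differs by more than
#' `threshold` between any two product geometries, or between a product and
#' the transition-state geometry. If fewer than two pairs pass, the threshold
#' is halved (up to six times) until at least two do.
#'
#' @param int_geom intermediate [geometry()] (atom-order reference).
#' @param product_geoms list of product geometries.
#' @param ts_geom transition-state geometry.
#' @param threshold initial bond-difference threshold in Angstrom.
#' @return an object of class `bond_coordinate_set` with fields `pairs`
#'   (m x 2 index matrix), `threshold` (the final value used) and `source`
#'   (which structure comparison drove each pair's selection).
#' @export
select_bond_coordinates <- function(int_geom, product_geoms, ts_geom,
                                    threshold = 0.3) {
  geoms <- c(product_geoms, list(ts_geom))
  n <- n_atoms(int_geom)
  for (g in geoms)
    if (n_atoms(g) != n)
      .stop_validation("geometries disagree on atom count")
  pairs <- .all_pairs(n)
  dmat <- vapply(geoms, .pair_distances, numeric(nrow(pairs)), pairs = pairs)
  np <- length(product_geoms)
  labs <- c(paste0("P", seq_len(np)), "TS")
  # max spread between any two products, or a product and the TS
  cmp <- utils::combn(np + 1L, 2L)
  keep_cmp <- cmp[, cmp[1, ] <= np, drop = FALSE]  # excludes TS-vs-TS (none)
  spread <- matrix(0, nrow(pairs), ncol(keep_cmp))
  for (k in seq_len(ncol(keep_cmp)))
    spread[, k] <- abs(dmat[, keep_cmp[1, k]] - dmat[, keep_cmp[2, k]])
  best <- apply(spread, 1L, max)
  thr <- threshold
  for (h in 0:6) {
    sel <- best > thr
    if (sum(sel) >= 2L) {
      src <- apply(spread[sel, , drop = FALSE], 1L, which.max)
      return(structure(list(
        pairs = pairs[sel, , drop = FALSE],
        threshold = thr,
        source = paste(labs[keep_cmp[1, src]], labs[keep_cmp[2, src]],
                       sep = "|")
      ), class = "bond_coordinate_set"))
    }
    thr <- thr / 2
  }
  .stop_validation("structures are geometrically identical on every atom ",
                   "pair (no bond difference above ",
                   signif(threshold / 2^6, 3), " A); cannot build a 2D ",
                   "projection")
}

#' @export
print.bond_coordinate_set <- function(x, ...) {
  cat("<bond_coordinate_set> ", nrow(x$pairs), " atom pairs at threshold ",
      signif(x$threshold, 3), " A\n", sep = "")
  invisible(x)
}

.bond_vector <- function(geom, coords) .pair_distances(geom, coords$pairs)

#' Project stationary points onto the 2D bifurcation plane
#'
#' Each structure is mapped to the vector of its selected bond distances; the
#' plane is spanned by the Gram-Schmidt orthonormalization of the two
#' intermediate-to-product displacement vectors in that bond-distance space,
#' with the intermediate at the origin.
#'
#' @param ts transition-state [geometry()] (or [stationary_point()]).
#' @param int intermediate geometry.
#' @param products named list of exactly two product geometries.
#' @param coords a [select_bond_coordinates()] result.
#' @return an object of class `projected_pes_2d` with the 2D positions of the
#'   transition state and products, the separation vector `g_vec` from the
#'   transition state to the intermediate, and the orthonormal `basis` in
#'   bond-distance space.
#' @export
project_to_2d <- function(ts, int, products, coords) {
  as_geom <- function(x) if (inherits(x, "stationary_point")) x$geometry else x
  ts <- as_geom(ts); int <- as_geom(int)
  products <- lapply(products, as_geom)
  if (length(products) != 2L)
    .stop_validation("the 2D projection takes exactly two products")
  if (is.null(names(products)) || any(!nzchar(names(products))))
    names(products) <- paste0("P", seq_along(products))

  d_int <- .bond_vector(int, coords)
  d_ts <- .bond_vector(ts, coords)
  v <- lapply(products, function(g) .bond_vector(g, coords) - d_int)
  n1 <- sqrt(sum(v[[1]]^2)); n2 <- sqrt(sum(v[[2]]^2))
  if (n1 < 1e-10 || n2 < 1e-10)
    .stop_validation("a product coincides with the intermediate in the ",
                     "selected bond coordinates")
  e1 <- v[[1]] / n1
  w <- v[[2]] - sum(v[[2]] * e1) * e1
  if (sqrt(sum(w * w)) / n2 < sin(pi / 180))
    .stop_validation("degenerate basis: the two intermediate-to-product ",
                     "directions are parallel within 1 degree; no resolvable ",
                     "bifurcation plane")
  e2 <- w / sqrt(sum(w * w))
  basis <- cbind(e1, e2)
  proj <- function(dvec) as.numeric(crossprod(basis, dvec - d_int))
  pp <- t(vapply(products, function(g) proj(.bond_vector(g, coords)),
                 numeric(2)))
  ts2 <- proj(d_ts)
  structure(list(
    origin = c(0, 0),
    ts_position = ts2,
    product_positions = pp,
    g_vec = c(0, 0) - ts2,
    basis = basis,
    d_int = d_int,
    pairs = coords$pairs
  ), class = "projected_pes_2d")
}

#' @export
print.projected_pes_2d <- function(x, ...) {
  cat("<projected_pes_2d> TS at (", paste(sprintf("%.4f", x$ts_position),
      collapse = ", "), "); products: ",
      paste(rownames(x$product_positions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# bond-rate conversion: rate of change of each selected bond length per unit
# Cartesian displacement along `dir` (an N x 3 unit pattern), at geometry ref
.bond_rates <- function(dir, ref_geom, pairs) {
  i <- pairs[, 1]; j <- pairs[, 2]
  dv <- ref_geom$coords[j, , drop = FALSE] - ref_geom$coords[i, , drop = FALSE]
  dlen <- sqrt(rowSums(dv * dv))
  u <- dv / dlen
  rel <- dir[j, , drop = FALSE] - dir[i, , drop = FALSE]
  rowSums(rel * u)
}

#' Orient the imaginary eigenvector on the 2D plane
#'
#' Converts the transition state's imaginary-mode displacement to bond-length
#' rates over the selected pairs, projects it into the bifurcation plane,
#' normalizes it and fixes its sign so that it points from the transition
#' state toward the intermediate side (`a . g >= 0`).
#'
#' @param ts a [stationary_point()] with exactly one imaginary mode.
#' @param plane a [project_to_2d()] result.
#' @param coords the [select_bond_coordinates()] result used for the plane.
#' @return unit 2D vector `a_vec`.
#' @export
orient_imaginary_mode <- function(ts, plane, coords) {
  stopifnot(inherits(ts, "stationary_point"))
  if (is.null(ts$modes)) .stop_validation(ts$label, " carries no normal modes")
  im <- which(ts$modes$frequencies < 0)
  if (length(im) != 1L)
    .stop_validation(ts$label, " must have exactly one imaginary mode, found ",
                     length(im))
  cart <- .mode_cartesian(ts$modes$displacements[[im]], ts$modes$convention,
                          ts$geometry$masses)
  b <- .bond_rates(cart$dir, ts$geometry, coords$pairs)
  bn <- sqrt(sum(b * b))
  if (bn < 1e-12)
    .stop_validation("imaginary mode of ", ts$label, " has zero net component ",
                     "on every selected bond (orthogonal to the plane)")
  p2 <- as.numeric(crossprod(plane$basis, b))
  if (sqrt(sum(p2 * p2)) < 1e-8 * bn)
    .stop_validation("imaginary mode of ", ts$label, " is orthogonal to the ",
                     "bifurcation plane")
  a <- p2 / sqrt(sum(p2 * p2))
  if (sum(a * plane$g_vec) < 0) a <- -a
  a
}

#' Harmonic width of the trajectory stream
#'
#' Each real mode contributes a 1D harmonic width
#' `sigma_k = sqrt(hbar / (2 mu_k omega_k))` (zero-point) or
#' `sqrt(kB T / (mu_k omega_k^2))` (thermal), with `mu_k` the mode's reduced
#' mass and `omega_k` its angular frequency. The mode's Cartesian displacement
#' is mapped through the same bond-rate projection as the imaginary mode, and
#' its in-plane component perpendicular to `a_vec`, scaled by `sigma_k`,
#' contributes in quadrature to the stream width.
#'
#' @param ts a [stationary_point()] with at least one real mode.
#' @param plane a [project_to_2d()] result.
#' @param coords the matching [select_bond_coordinates()] result.
#' @param temperature temperature in K (thermal model only).
#' @param width_model `"zero_point"` (default) or `"thermal"`.
#' @param a_vec oriented imaginary-mode direction; computed via
#'   [orient_imaginary_mode()] when omitted.
#' @return an object of class `stream_width` with fields `sigma` (Angstrom)
#'   and `per_mode_contributions` (frequency, contribution in Angstrom^2).
#' @export
stream_width <- function(ts, plane, coords, temperature = 298.15,
                         width_model = c("zero_point", "thermal"),
                         a_vec = NULL) {
  width_model <- match.arg(width_model)
  stopifnot(inherits(ts, "stationary_point"))
  if (is.null(a_vec)) a_vec <- orient_imaginary_mode(ts, plane, coords)
  re <- which(ts$modes$frequencies > 0)
  if (!length(re)) .stop_validation(ts$label, " has no real modes")
  n_a <- c(-a_vec[2], a_vec[1])
  contr <- numeric(length(re))
  for (k in seq_along(re)) {
    m <- re[k]
    cart <- .mode_cartesian(ts$modes$displacements[[m]], ts$modes$convention,
                            ts$geometry$masses)
    om <- .omega_red(ts$modes$frequencies[m])
    sig_k <- if (width_model == "zero_point")
      sqrt(.const$hbar_red / (2 * cart$reduced_mass * om))
    else
      sqrt(.const$R_kcal * temperature / (cart$reduced_mass * om^2))
    b <- .bond_rates(cart$dir, ts$geometry, coords$pairs)
    p2 <- as.numeric(crossprod(plane$basis, b))
    contr[k] <- (sum(p2 * n_a) * sig_k)^2
  }
  s2 <- sum(contr)
  if (s2 <= 0 || sqrt(s2) < 1e-12)
    .stop_validation("all real modes of ", ts$label, " are orthogonal to the ",
                     "in-plane direction perpendicular to the stream; the ",
                     "stream width is zero and the ratio undefined")
  structure(list(
    sigma = sqrt(s2),
    per_mode_contributions = data.frame(
      frequency_cm1 = ts$modes$frequencies[re], contribution_A2 = contr)
  ), class = "stream_width")
}

#' @export
print.stream_width <- function(x, ...) {
  cat("<stream_width> sigma = ", sprintf("%.5f", x$sigma), " A from ",
      nrow(x$per_mode_contributions), " real mode(s)\n", sep = "")
  invisible(x)
}

.new_selectivity_result <- function(fractions, method, diagnostics) {
  fractions <- fractions / sum(fractions)
  structure(list(fractions = fractions, method = method,
                 diagnostics = diagnostics),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat("<selectivity_result> [", x$method, "]\n", sep = "")
  for (nm in names(x$fractions))
    cat(sprintf("  %-24s %7.3f %%\n", nm, 100 * x$fractions[[nm]]))
  invisible(x)
}

#' Partition the trajectory stream between two products
#'
#' The ridge line passes through the intermediate (the plane origin) along
#' the bisector of the two intermediate-to-product directions. The stream
#' centre is the transition-state position displaced along the oriented
#' imaginary eigenvector by the transition-state-to-intermediate separation.
#' The first product receives the standard-normal mass `Phi(delta / sigma)`,
#' where `delta` is the signed perpendicular distance from the stream centre
#' to the ridge (positive toward the first product).
#'
#' @param plane a [project_to_2d()] result with two products.
#' @param a_vec oriented imaginary-mode direction from
#'   [orient_imaginary_mode()].
#' @param width a [stream_width()] result.
#' @return a `selectivity_result` with per-product fractions and diagnostics
#'   (`delta`, `sigma`, per-product angles in degrees).
#' @export
predict_two_product_ratio <- function(plane, a_vec, width) {
  stopifnot(inherits(plane, "projected_pes_2d"), inherits(width, "stream_width"))
  pp <- plane$product_positions
  if (nrow(pp) != 2L)
    .stop_validation("two-product partition requires exactly two products")
  nrm <- sqrt(rowSums(pp * pp))
  if (any(nrm < 1e-10))
    .stop_validation("a product sits at zero distance from the intermediate")
  u1 <- pp[1, ] / nrm[1]; u2 <- pp[2, ] / nrm[2]
  ridge <- u1 + u2
  rl <- sqrt(sum(ridge * ridge))
  if (rl < 1e-12)
    .stop_validation("product directions are anti-parallel; the ridge ",
                     "bisector is undefined")
  ridge <- ridge / rl
  n <- c(-ridge[2], ridge[1])
  if (sum(n * u1) < 0) n <- -n
  centre <- plane$ts_position + a_vec * sqrt(sum(plane$g_vec^2))
  delta <- sum(centre * n)
  f1 <- if (delta == 0) 0.5 else stats::pnorm(delta / width$sigma)
  fr <- c(f1, 1 - f1)
  names(fr) <- rownames(pp)
  ang <- function(u) acos(max(-1, min(1, sum(a_vec * u)))) * 180 / pi
  .new_selectivity_result(fr, "VRAI", list(
    delta = delta, sigma = width$sigma,
    angles_deg = stats::setNames(c(ang(u1), ang(u2)), rownames(pp)),
    stream_centre = centre, a_vec = a_vec, g_vec = plane$g_vec,
    ts_position = plane$ts_position, product_positions = pp,
    bond_pairs = plane$pairs,
    per_mode_contributions = width$per_mode_contributions
  ))
}

# log-odds of product A over product B from a pairwise stream partition
.pair_log_odds <- function(ts, intermediate, pA, pB, temperature, width_model,
                           threshold) {
  geoms <- list(pA$geometry, pB$geometry)
  names(geoms) <- c(pA$label, pB$label)
  coords <- select_bond_coordinates(intermediate$geometry, geoms,
                                    ts$geometry, threshold)
  plane <- project_to_2d(ts$geometry, intermediate$geometry, geoms, coords)
  a <- orient_imaginary_mode(ts, plane, coords)
  w <- stream_width(ts, plane, coords, temperature, width_model, a_vec = a)
  res <- predict_two_product_ratio(plane, a, w)
  z <- res$diagnostics$delta / res$diagnostics$sigma
  list(log_odds = stats::pnorm(z, log.p = TRUE) -
                  stats::pnorm(-z, log.p = TRUE),
       result = res)
}

#' Partition the trajectory stream among two or more products
#'
#' For two products this is exactly the pairwise partition. For more, a
#' reference product is fixed (the one whose intermediate-to-product direction
#' in bond-distance space is most anti-parallel to the
#' transition-state-to-intermediate separation; ties broken lexicographically
#' by label) and a pairwise analysis of every other product against the
#' reference yields odds that are normalized into fractions. A pair whose
#' projection plane is degenerate falls back to Boltzmann weighting of the two
#' channels (using `config$channel_energies`, kcal/mol, when provided; equal
#' weighting otherwise), recorded in the diagnostics.
#'
#' @param ts the shared first transition state ([stationary_point()], one
#'   imaginary mode).
#' @param intermediate the shared intermediate.
#' @param products list of at least two product [stationary_point()]s.
#' @param temperature temperature in K.
#' @param config optional list: `bond_threshold_A` (default 0.3),
#'   `width_model` (default `"zero_point"`), `channel_energies` (named,
#'   kcal/mol, for the degenerate-pair fallback).
#' @return a `selectivity_result` over all products.
#' @export
predict_multi_product_ratio <- function(ts, intermediate, products,
                                        temperature = 298.15,
                                        config = list()) {
  if (length(products) < 2L)
    .stop_validation("need at least two products")
  threshold <- config$bond_threshold_A %||% 0.3
  width_model <- config$width_model %||% "zero_point"
  labs <- vapply(products, `[[`, "", "label")
  names(products) <- labs

  if (length(products) == 2L) {
    return(.pair_log_odds(ts, intermediate, products[[1]], products[[2]],
                          temperature, width_model, threshold)$result)
  }

  # reference product: direction most anti-parallel to g in bond space
  geoms <- lapply(products, `[[`, "geometry")
  coords_all <- select_bond_coordinates(intermediate$geometry, geoms,
                                        ts$geometry, threshold)
  d_int <- .bond_vector(intermediate$geometry, coords_all)
  d_ts <- .bond_vector(ts$geometry, coords_all)
  gfull <- d_int - d_ts
  gfull <- gfull / sqrt(sum(gfull * gfull))
  dots <- vapply(products, function(p) {
    v <- .bond_vector(p$geometry, coords_all) - d_int
    sum(v * gfull) / sqrt(sum(v * v))
  }, 0)
  ord <- order(dots, labs)  # lexicographic tie-break
  ref_lab <- labs[ord[1]]
  ref <- products[[ref_lab]]

  log_odds <- stats::setNames(numeric(length(products)), labs)
  pair_diag <- list(); fallbacks <- character(0)
  for (lab in setdiff(labs, ref_lab)) {
    po <- tryCatch(
      .pair_log_odds(ts, intermediate, products[[lab]], ref,
                     temperature, width_model, threshold),
      dynaselect_validation_error = function(e) e)
    if (inherits(po, "condition")) {
      ce <- config$channel_energies
      lo <- if (!is.null(ce) && all(c(lab, ref_lab) %in% names(ce)))
        -(ce[[lab]] - ce[[ref_lab]]) / (.const$R_kcal * temperature)
      else 0
      log_odds[lab] <- lo
      fallbacks <- c(fallbacks, lab)
      pair_diag[[lab]] <- list(fallback = "TST",
                               reason = conditionMessage(po))
    } else {
      log_odds[lab] <- po$log_odds
      pair_diag[[lab]] <- po$result$diagnostics[c("delta", "sigma")]
    }
  }
  f <- exp(log_odds - max(log_odds))
  f <- f / sum(f)
  .new_selectivity_result(f, "VRAI", list(
    reference_product = ref_lab,
    pairwise = pair_diag,
    tst_fallback_pairs = fallbacks
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
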