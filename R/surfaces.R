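# Analytic bifurcating model surfaces, their embedding into a toy molecular
# system, and the quasi-classical trajectory oracle.
#
# Surface family (reduced units: kcal/mol, Angstrom, amu). With t = y / L:
#
#   V(x, y) = Eb (2 t^3 - 3 t^2) + (1 - w(t)) * k1 x^2 / 2 + w(t) * u(x - xc)
#
# The first term is a cubic descent from a saddle at the origin down to the
# well line at y = L. Before the valley-ridge region the transverse motion is
# a soft harmonic channel (force constant k1) centred on the axis; a C^2
# quintic ramp w(t), switching on at the declared valley-ridge-inflection
# position, replaces it by a double (or triple) transverse well u centred at
# xc = asymmetry * half-separation. Because the ramp's first and second
# derivatives vanish at t = 1, every well and inter-well saddle sits exactly
# on the well line and is known in closed form; a Newton polish confirms them
# to 1e-10. The harmonic entry channel transports the zero-point Gaussian
# stream unchanged (a coherent state of the transverse mode), which is the
# regime the stream-partition analysis assumes; asymmetry displaces the
# bifurcation geometry rather than applying a persistent transverse force.
# The energy zero is the outer well bottom.

.smootherstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (u * (u * 6 - 15) + 10)
}
.smootherstep_d1 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  30 * u^2 * (u - 1)^2
}
.smootherstep_d2 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  60 * u * (2 * u - 1) * (u - 1)
}

#' Construct an analytic bifurcating model surface
#'
#' A two-dimensional potential with a single first-order saddle upstream of a
#' valley-ridge region, beyond which the path bifurcates into two (or three)
#' product wells. All stationary points are available in closed form and are
#' Newton-polished to a gradient norm below 1e-10. The energy zero is the
#' outer well bottom.
#'
#' @param barrier_height drop from the saddle to the well line, kcal/mol.
#' @param well_separation distance between the two outer wells, Angstrom.
#' @param asymmetry dimensionless lateral offset of the bifurcation region,
#'   as a fraction of the half-separation; 0 gives an exactly mirror-symmetric
#'   surface.
#' @param vri_position distance (Angstrom) from the saddle at which the
#'   valley-ridge region switches on.
#' @param path_length distance (Angstrom) from the saddle to the well line.
#' @param ts_mode_force_const transverse force constant of the entry channel,
#'   kcal/mol/A^2 (sets the real-mode frequency of the saddle).
#' @param well_depth depth of the outer wells below the well line, kcal/mol.
#' @param mass effective mass of both coordinates, amu (default: the reduced
#'   mass of a carbon-carbon stretch, matching the molecular embedding).
#' @param n_wells 2 (bifurcation) or 3 (central channel plus two outer wells).
#' @return an object of class `bifurcating_surface` with analytic potential,
#'   gradient and Hessian accessors and cached stationary points.
#' @export
make_surface <- function(barrier_height = 15, well_separation = 1.6,
                         asymmetry = 0, vri_position = 1.0, path_length = 2.0,
                         ts_mode_force_const = 0.5, well_depth = 8,
                         mass = 6.0055, n_wells = 2) {
  if (!n_wells %in% c(2L, 3L))
    .stop_validation("n_wells must be 2 or 3 (a single well has no ",
                     "bifurcation)")
  if (barrier_height <= 0) .stop_validation("barrier_height must be > 0")
  if (well_separation <= 0) .stop_validation("well_separation must be > 0")
  if (well_depth <= 0) .stop_validation("well_depth must be > 0")
  if (ts_mode_force_const <= 0) .stop_validation("ts_mode_force_const must be > 0")
  if (mass <= 0) .stop_validation("mass must be > 0")
  if (vri_position <= 0 || vri_position >= path_length)
    .stop_validation("vri_position must lie strictly between the saddle ",
                     "and the well line")
  if (abs(asymmetry) > 0.95)
    .stop_validation("asymmetry must lie in [-0.95, 0.95]")

  Eb <- barrier_height; L <- path_length; xm <- well_separation / 2
  xc <- asymmetry * xm; k1 <- ts_mode_force_const; D <- well_depth
  ton <- vri_position / L

  if (n_wells == 2L) {
    kw <- 4 * D / xm^2; q <- D / xm^4
    u_fun <- function(xi) { xi2 <- xi * xi; q * xi2 * xi2 - 0.5 * kw * xi2 }
    u_d1 <- function(xi) { xi2 <- xi * xi; 4 * q * xi2 * xi - kw * xi }
    u_d2 <- function(xi) { xi2 <- xi * xi; 12 * q * xi2 - kw }
    well_xi <- c(-xm, xm); well_labels <- c("P1", "P2")
    saddle_xi <- 0
  } else {
    # triple well: three equal Gaussian dips at 0 and +/- xm, so the channel
    # spacing and the well curvature (D / wg^2) are controlled independently
    wg <- 0.4 * xm
    gpos <- c(-xm, 0, xm)
    u_fun <- function(xi) {
      v <- 0
      for (p in gpos) v <- v - D * exp(-(xi - p)^2 / (2 * wg^2))
      v
    }
    u_d1 <- function(xi) {
      v <- 0
      for (p in gpos) v <- v + D * (xi - p) / wg^2 * exp(-(xi - p)^2 / (2 * wg^2))
      v
    }
    u_d2 <- function(xi) {
      v <- 0
      for (p in gpos) {
        e <- exp(-(xi - p)^2 / (2 * wg^2))
        v <- v + D * e / wg^2 * (1 - (xi - p)^2 / wg^2)
      }
      v
    }
    well_xi <- c(0, -xm, xm); well_labels <- c("P1", "P2", "P3")
    saddle_xi <- c(-xm / 2, xm / 2)
  }
  offset <- 0   # set below so that the energy zero is the deepest well bottom

  Vfun <- function(x, y) {
    t <- y / L; w <- .smootherstep((t - ton) / (1 - ton))
    Eb * (2 * t^3 - 3 * t^2) + (1 - w) * 0.5 * k1 * x^2 + w * u_fun(x - xc) +
      offset
  }
  Gfun <- function(x, y) {
    t <- y / L; uu <- (t - ton) / (1 - ton)
    w <- .smootherstep(uu); wd <- .smootherstep_d1(uu) / (1 - ton)
    xi <- x - xc
    gx <- (1 - w) * k1 * x + w * u_d1(xi)
    gy <- (Eb * (6 * t^2 - 6 * t) + wd * (u_fun(xi) - 0.5 * k1 * x^2)) / L
    cbind(gx, gy, deparse.level = 0)
  }
  Hfun <- function(x, y) {
    t <- y / L; uu <- (t - ton) / (1 - ton)
    w <- .smootherstep(uu)
    wd <- .smootherstep_d1(uu) / (1 - ton)
    wdd <- .smootherstep_d2(uu) / (1 - ton)^2
    xi <- x - xc
    vxx <- (1 - w) * k1 + w * u_d2(xi)
    vxy <- wd * (-k1 * x + u_d1(xi)) / L
    vyy <- (Eb * (12 * t - 6) + wdd * (u_fun(xi) - 0.5 * k1 * x^2)) / L^2
    matrix(c(vxx, vxy, vxy, vyy), 2, 2)
  }

  newton <- function(p0) {
    p <- p0
    for (i in 1:60) {
      g <- as.numeric(Gfun(p[1], p[2]))
      if (sqrt(sum(g * g)) < 1e-12) break
      p <- p - solve(Hfun(p[1], p[2]), g)
    }
    g <- as.numeric(Gfun(p[1], p[2]))
    if (sqrt(sum(g * g)) > 1e-10)
      .stop_validation("stationary-point refinement did not converge")
    p
  }

  ts <- newton(c(0, 0))
  wells <- t(vapply(well_xi, function(xi) newton(c(xc + xi, L)), numeric(2)))
  rownames(wells) <- well_labels
  saddles <- t(vapply(saddle_xi, function(xi) newton(c(xc + xi, L)), numeric(2)))
  if (any(stats::dist(wells[, 1]) < 1e-6))
    .stop_validation("well refinement collapsed two wells onto each other; ",
                     "the parameter combination has no bifurcation")
  for (i in seq_len(nrow(wells))) {
    ev <- eigen(Hfun(wells[i, 1], wells[i, 2]), symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev <= 0))
      .stop_validation("declared well ", well_labels[i],
                       " is not a local minimum")
  }
  for (i in seq_len(nrow(saddles))) {
    ev <- eigen(Hfun(saddles[i, 1], saddles[i, 2]), symmetric = TRUE,
                only.values = TRUE)$values
    if (sum(ev < 0) != 1L)
      .stop_validation("inter-well stationary point is not a first-order saddle")
  }
  offset <- Eb - min(vapply(seq_len(nrow(wells)), function(i)
    u_fun(wells[i, 1] - xc), 0))

  # computed valley-ridge inflection: transverse curvature on the ridge path
  ridge_xi <- if (n_wells == 2L) 0 else saddle_xi[1]
  cfun <- function(y) {
    w <- .smootherstep((y / L - ton) / (1 - ton))
    (1 - w) * k1 + w * u_d2(ridge_xi)
  }
  vri_y <- stats::uniroot(cfun, c(vri_position, L * 0.999999),
                          tol = 1e-12)$root

  structure(list(
    params = list(barrier_height = Eb, well_separation = well_separation,
                  asymmetry = asymmetry, vri_position = vri_position,
                  path_length = L, ts_mode_force_const = k1,
                  well_depth = D, mass = mass, n_wells = n_wells),
    potential = Vfun, gradient = Gfun, hessian = Hfun,
    ts = ts, intermediate_ref = c(xc, vri_position),
    wells = wells, well_labels = well_labels, saddles = saddles,
    vri_computed = c(xc + ridge_xi, vri_y),
    mass = mass, offset = offset
  ), class = "bifurcating_surface")
}

#' @export
print.bifurcating_surface <- function(x, ...) {
  p <- x$params
  cat("<bifurcating_surface> ", p$n_wells, " wells, barrier ",
      p$barrier_height, " kcal/mol, separation ", p$well_separation,
      " A, asymmetry ", p$asymmetry, "\n", sep = "")
  invisible(x)
}

# saddle normal modes of the 2D surface: frequencies (cm^-1, imaginary
# negative) and unit eigendirections, with the unstable one oriented toward
# the intermediate side
.surface_saddle_modes <- function(surface) {
  H <- surface$hessian(surface$ts[1], surface$ts[2]) / surface$mass
  e <- eigen(H, symmetric = TRUE)
  iim <- which.min(e$values); ire <- which.max(e$values)
  a <- e$vectors[, iim]
  gv <- surface$intermediate_ref - surface$ts
  if (sum(a * gv) < 0) a <- -a
  list(
    imag_dir = a,
    imag_freq = -.const$cm1_per_redfreq * sqrt(-e$values[iim]),
    real_dir = e$vectors[, ire],
    real_freq = .const$cm1_per_redfreq * sqrt(e$values[ire]),
    omega_real = sqrt(e$values[ire])
  )
}

#' Embed a model surface as a toy molecular input bundle
#'
#' Maps the two surface coordinates onto two interatomic distances of a
#' synthetic four-atom system (two far-apart carbon diatoms: the first bond
#' carries the reaction coordinate, the second the transverse coordinate) and
#' writes a complete, self-contained pipeline input set: XYZ geometries for
#' the transition state, the valley-ridge reference intermediate and the
#' product wells; analytic-Hessian normal-mode sidecars (plus a synthetic
#' frequency log for the transition state); and a network YAML. Gibbs free
#' energies equal the potential values.
#'
#' @param surface a [make_surface()] result.
#' @param dir output directory (created if needed).
#' @return a list with `network_path`, the emitted `files`, the ground-truth
#'   reactive atom `pairs`, and the product `labels`.
#' @export
embed_as_molecule <- function(surface, dir) {
  stopifnot(inherits(surface, "bifurcating_surface"))
  m_c <- .atomic_weights[["C"]]
  if (abs(surface$mass - m_c / 2) > 1e-9)
    .stop_validation("the molecular embedding uses carbon diatoms; the ",
                     "surface mass must equal ", m_c / 2,
                     " amu (a C-C stretch reduced mass)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  R1 <- 1.5; R2 <- 2.5; SEP <- 40   # base bond lengths and fragment spacing
  geom_at <- function(p) {
    x <- p[1]; y <- p[2]
    geometry(rep("C", 4), rbind(
      c(0, 0, 0), c(R1 + y, 0, 0),
      c(0, SEP, 0), c(R2 + x, SEP, 0)))
  }
  # analytic Cartesian Hessian at a surface-stationary point via the chain
  # rule (the distance-curvature term vanishes because the surface gradient
  # is zero there)
  modes_at <- function(p, structure_type) {
    Hs <- surface$hessian(p[1], p[2])
    Jx <- numeric(12); Jy <- numeric(12)
    Jy[1] <- -1; Jy[4] <- 1    # d(bond 1-2)
    Jx[7] <- -1; Jx[10] <- 1   # d(bond 3-4)
    H <- Hs[1, 1] * tcrossprod(Jx) + Hs[2, 2] * tcrossprod(Jy) +
      Hs[1, 2] * (tcrossprod(Jx, Jy) + tcrossprod(Jy, Jx))
    masses <- rep(m_c, 4)
    invsq <- 1 / sqrt(rep(masses, each = 3))
    Hmw <- H * tcrossprod(invsq)
    e <- eigen(Hmw, symmetric = TRUE)
    keep <- which(abs(e$values) > 1e-8)
    freqs <- ifelse(e$values[keep] >= 0,
                    .const$cm1_per_redfreq * sqrt(pmax(e$values[keep], 0)),
                    -.const$cm1_per_redfreq * sqrt(-pmin(e$values[keep], 0)))
    disps <- lapply(keep, function(k)
      matrix(e$vectors[, k], ncol = 3, byrow = TRUE))
    ord <- order(freqs)
    normal_modes(freqs[ord], disps[ord], convention = "mass_weighted")
  }

  pts <- list(
    list(label = "TS1", role = "TS1", p = surface$ts, modes = TRUE,
         mtype = "ts"),
    list(label = "INT", role = "INT2", p = surface$intermediate_ref,
         modes = FALSE)
  )
  for (i in seq_along(surface$well_labels))
    pts[[length(pts) + 1L]] <- list(
      label = surface$well_labels[i], role = "product",
      p = surface$wells[i, ], modes = TRUE, mtype = "minimum")

  files <- character(0)
  ypts <- list()
  for (pt in pts) {
    g <- geom_at(pt$p)
    xyz <- file.path(dir, paste0(pt$label, ".xyz"))
    write_xyz(g, xyz, comment = paste0("synthetic embedded fixture ",
                                       pt$label))
    files <- c(files, xyz)
    entry <- list(label = pt$label, role = pt$role,
                  xyz = basename(xyz),
                  energy = surface$potential(pt$p[1], pt$p[2]))
    if (isTRUE(pt$modes)) {
      md <- modes_at(pt$p, pt$mtype)
      sc <- file.path(dir, paste0(pt$label, "_modes.json"))
      write_mode_sidecar(md, sc)
      files <- c(files, sc)
      entry$modes <- basename(sc)
      entry$modes_dialect <- "sidecar_json"
      if (pt$label == "TS1") {
        lg <- file.path(dir, "TS1_freq.log")
        write_synthetic_gaussian_log(g, md, lg)
        files <- c(files, lg)
      }
    }
    if (pt$role == "product") entry$species <- pt$label
    ypts[[length(ypts) + 1L]] <- entry
  }

  edges <- c(list(list("TS1", "INT")),
             lapply(surface$well_labels, function(w) list("INT", w)))
  net <- list(energy_unit = "kcal/mol", points = ypts, edges = edges)
  network_path <- file.path(dir, "network.yaml")
  yaml::write_yaml(net, network_path)
  files <- c(files, network_path)
  list(network_path = network_path, files = files,
       pairs = rbind(c(1L, 2L), c(3L, 4L)),
       labels = surface$well_labels)
}

#' Quasi-classical trajectory ensemble on a model surface
#'
#' Initial positions are displaced from the saddle along its real mode by a
#' harmonic draw matching `width_model` (zero-point Wigner widths or classical
#' thermal widths); momenta combine the matching real-mode draw with a forward
#' half-Gaussian thermal momentum along the oriented imaginary mode. Each
#' trajectory is integrated by velocity Verlet at a fixed step (at most 0.1 fs
#' equivalent, further reduced automatically for stiff wells) until it first
#' enters the capture radius of a product well; energy is monitored over the
#' whole integration. Draws use a counter-based scheme keyed by
#' `(seed, trajectory index)` so results are independent of execution order.
#'
#' @param surface a [make_surface()] result.
#' @param n number of trajectories.
#' @param seed integer seed.
#' @param temperature temperature in K (forward momentum and thermal widths).
#' @param width_model `"zero_point"` or `"thermal"`.
#' @param dt integration step in reduced time units (default 5e-4, about
#'   0.024 fs).
#' @param max_time integration horizon in reduced time units.
#' @param capture_radius basin capture radius (Angstrom); default half the
#'   well half-separation.
#' @param reflect_transverse flip the sign of the transverse draws (used to
#'   verify mirror symmetry of the oracle).
#' @return an object of class `trajectory_ensemble_result`: per-basin counts
#'   and fractions over decided trajectories, the undecided count, a warning
#'   flag when more than 20 percent are undecided, and the maximum relative
#'   energy drift.
#' @export
trajectory_oracle <- function(surface, n, seed, temperature = 298.15,
                              width_model = c("zero_point", "thermal"),
                              dt = 5e-4, max_time = 30,
                              capture_radius = NULL,
                              reflect_transverse = FALSE) {
  width_model <- match.arg(width_model)
  stopifnot(inherits(surface, "bifurcating_surface"))
  if (n < 1) .stop_validation("n must be at least 1")
  m <- surface$mass
  sm <- .surface_saddle_modes(surface)
  om <- sm$omega_real
  if (width_model == "zero_point") {
    sx <- sqrt(.const$hbar_red / (2 * m * om))
    sp <- sqrt(.const$hbar_red * m * om / 2)
  } else {
    sx <- sqrt(.const$R_kcal * temperature / (m * om^2))
    sp <- sqrt(m * .const$R_kcal * temperature)
  }
  p_fwd <- sqrt(m * .const$R_kcal * temperature)

  # step small enough that the Verlet energy oscillation stays within 1e-6
  # of the total energy in the stiffest well
  om_max <- max(vapply(seq_len(nrow(surface$wells)), function(i) {
    H <- surface$hessian(surface$wells[i, 1], surface$wells[i, 2]) / m
    sqrt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
  }, 0), om)
  dt <- min(dt, 2e-3 / om_max)
  n_steps <- ceiling(max_time / dt)

  Z <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    set.seed((seed * 10007 + i) %% 2147483647L)
    Z[i, ] <- stats::rnorm(3)
  }
  if (reflect_transverse) Z[, 1:2] <- -Z[, 1:2]

  pos <- cbind(surface$ts[1] + Z[, 1] * sx * sm$real_dir[1],
               surface$ts[2] + Z[, 1] * sx * sm$real_dir[2])
  vel <- cbind((Z[, 2] * sp * sm$real_dir[1] +
                  abs(Z[, 3]) * p_fwd * sm$imag_dir[1]) / m,
               (Z[, 2] * sp * sm$real_dir[2] +
                  abs(Z[, 3]) * p_fwd * sm$imag_dir[2]) / m)
  E0 <- surface$potential(pos[, 1], pos[, 2]) +
    0.5 * m * (vel[, 1]^2 + vel[, 2]^2)

  rcap <- capture_radius %||% (surface$params$well_separation / 4)
  wells <- surface$wells
  basin <- integer(n); alive <- rep(TRUE, n)
  drift <- numeric(n)
  acc <- -surface$gradient(pos[, 1], pos[, 2]) / m
  half <- 0.5 * dt
  y_floor <- surface$ts[2] - 0.5 * surface$params$path_length
  for (st in seq_len(n_steps)) {
    if (!any(alive)) break
    ia <- which(alive)
    vel[ia, ] <- vel[ia, ] + half * acc[ia, ]
    pos[ia, ] <- pos[ia, ] + dt * vel[ia, ]
    acc[ia, ] <- -surface$gradient(pos[ia, 1], pos[ia, 2]) / m
    vel[ia, ] <- vel[ia, ] + half * acc[ia, ]
    for (b in seq_len(nrow(wells))) {
      d2 <- (pos[ia, 1] - wells[b, 1])^2 + (pos[ia, 2] - wells[b, 2])^2
      hit <- ia[d2 < rcap^2]
      if (length(hit)) {
        basin[hit] <- b
        alive[hit] <- FALSE
        ia <- setdiff(ia, hit)
      }
    }
    # rare recrossers escaping upstream stay undecided (frozen where caught)
    esc <- ia[pos[ia, 2] < y_floor]
    if (length(esc)) alive[esc] <- FALSE
  }
  Ef <- surface$potential(pos[, 1], pos[, 2]) +
    0.5 * m * (vel[, 1]^2 + vel[, 2]^2)
  drift <- abs(Ef - E0) / abs(E0)
  drift[!is.finite(drift)] <- NA_real_

  labels <- surface$well_labels
  counts <- stats::setNames(tabulate(basin, nbins = nrow(wells)), labels)
  undecided <- sum(basin == 0L)
  decided <- n - undecided
  fractions <- if (decided > 0) counts / decided else counts * NA_real_
  structure(list(
    n_trajectories = n, seed = seed,
    basins = basin,
    basin_counts = counts, fractions = fractions,
    undecided_count = undecided,
    step_cap_warning = undecided > 0.2 * n,
    max_energy_drift = max(drift[basin > 0]),
    dt = dt, width_model = width_model, temperature = temperature
  ), class = "trajectory_ensemble_result")
}

#' @export
print.trajectory_ensemble_result <- function(x, ...) {
  cat("<trajectory_ensemble_result> ", x$n_trajectories, " trajectories (",
      x$undecided_count, " undecided), seed ", x$seed, "\n", sep = "")
  for (b in names(x$basin_counts))
    cat(sprintf("  %-6s %6d  (%.2f %%)\n", b, x$basin_counts[[b]],
                100 * x$fractions[[b]]))
  if (x$step_cap_warning)
    cat("  warning: more than 20% of trajectories undecided\n")
  invisible(x)
}
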