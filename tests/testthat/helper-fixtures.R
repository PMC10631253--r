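# In-code fixtures shared across the test files. Everything is generated at
# test time; nothing binary ships with the package.

# trivial shared geometry for networks whose tests exercise only energetics
toy_geom <- function(d = 1.0) {
  geometry(c("C", "O"), rbind(c(0, 0, 0), c(d, 0, 0)))
}

toy_sp <- function(label, role, G, stereochem = NULL, species = NULL) {
  stationary_point(label, role, toy_geom(), G,
                   stereochem = stereochem, species = species)
}

# two independent branches: TS1_A -> INT_A -> TS2_A -> A, same for B
net_two_branches <- function(e1 = 0, e2 = 1, e_ts2 = -5,
                             experimental = NULL) {
  pts <- list(
    toy_sp("TS1_A", "TS1", e1), toy_sp("INT_A", "INT2", e1 - 8),
    toy_sp("TS2_A", "TS2", e_ts2), toy_sp("A", "product", -20, species = "A"),
    toy_sp("TS1_B", "TS1", e2), toy_sp("INT_B", "INT2", e2 - 8),
    toy_sp("TS2_B", "TS2", e_ts2), toy_sp("B", "product", -20, species = "B"))
  edges <- list(c("TS1_A", "INT_A"), c("INT_A", "TS2_A"), c("TS2_A", "A"),
                c("TS1_B", "INT_B"), c("INT_B", "TS2_B"), c("TS2_B", "B"))
  reaction_network(pts, edges, experimental = experimental)
}

# one TS1 branching over two TS2s to products A and B
net_one_ts1 <- function(e_ts2a = -5, e_ts2b = -5) {
  pts <- list(
    toy_sp("TS1", "TS1", 0), toy_sp("INT", "INT2", -8),
    toy_sp("TS2_A", "TS2", e_ts2a), toy_sp("A", "product", -20, species = "A"),
    toy_sp("TS2_B", "TS2", e_ts2b), toy_sp("B", "product", -20, species = "B"))
  edges <- list(c("TS1", "INT"), c("INT", "TS2_A"), c("TS2_A", "A"),
                c("INT", "TS2_B"), c("TS2_B", "B"))
  reaction_network(pts, edges)
}

# random multi-branch TST network for property tests
random_tst_network <- function(rng_n_ts1 = 1:4, rng_n_ts2 = 1:3,
                               n_products = 3) {
  n_ts1 <- sample(rng_n_ts1, 1)
  prods <- paste0("PR", seq_len(n_products))
  pts <- lapply(prods, function(p) toy_sp(p, "product", -30, species = p))
  edges <- list()
  for (i in seq_len(n_ts1)) {
    t1 <- paste0("TS1_", i); int <- paste0("INT_", i)
    pts <- c(pts, list(toy_sp(t1, "TS1", stats::runif(1, 0, 3)),
                       toy_sp(int, "INT2", -10)))
    edges <- c(edges, list(c(t1, int)))
    for (j in seq_len(sample(rng_n_ts2, 1))) {
      t2 <- paste0("TS2_", i, "_", j)
      pts <- c(pts, list(toy_sp(t2, "TS2", stats::runif(1, -6, -2))))
      edges <- c(edges, list(c(int, t2),
                             c(t2, sample(prods, 1))))
    }
  }
  reaction_network(pts, edges)
}

# two far-apart diatoms: bond 1-2 and bond 3-4 are independent coordinates.
# d12/d34 give the two bond lengths directly.
probe_geom <- function(d12, d34, masses = rep(1, 4),
                       symbols = rep("H", 4)) {
  geometry(symbols, rbind(c(0, 0, 0), c(d12, 0, 0),
                          c(0, 40, 0), c(d34, 40, 0)), masses = masses)
}

# displacement pattern moving one atom of one bond along the bond axis
probe_mode_disp <- function(bond = c("d12", "d34")) {
  bond <- match.arg(bond)
  m <- matrix(0, 4, 3)
  if (bond == "d12") m[2, 1] <- 1 else m[4, 1] <- 1
  m
}

# a minimal stationary-point system where the projection factors are exactly
# one: imaginary mode along bond 3-4, one real mode along bond 1-2
probe_system <- function(real_freq = 3000, imag_freq = -500,
                         masses = rep(1, 4)) {
  ts_g <- probe_geom(1.5, 0.6, masses)
  int_g <- probe_geom(1.5, 1.6, masses)
  p1_g <- probe_geom(2.5, 1.6, masses)   # differs along bond 1-2
  p2_g <- probe_geom(1.5, 2.6, masses)   # differs along bond 3-4
  modes <- normal_modes(
    c(imag_freq, real_freq),
    list(probe_mode_disp("d34"), probe_mode_disp("d12")),
    convention = "mass_weighted")
  ts <- stationary_point("TS", "TS1", ts_g, 0, modes = modes)
  list(ts = ts, int_g = int_g, p1_g = p1_g, p2_g = p2_g)
}

# plane + width built directly, for closed-form partition checks
manufactured_plane <- function(p1 = c(-1, 1), p2 = c(1, 1),
                               ts = c(0, -1)) {
  pp <- rbind(P1 = p1, P2 = p2)
  structure(list(origin = c(0, 0), ts_position = ts,
                 product_positions = pp, g_vec = -ts,
                 basis = diag(2), d_int = c(0, 0),
                 pairs = rbind(c(1L, 2L), c(3L, 4L))),
            class = "projected_pes_2d")
}

manufactured_width <- function(sigma) {
  structure(list(sigma = sigma,
                 per_mode_contributions = data.frame(
                   frequency_cm1 = 1000, contribution_A2 = sigma^2)),
            class = "stream_width")
}

# rigid motion applied to a stationary point (rotating mode displacements too)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid_motion <- function(sp, R, shift) {
  sp$geometry$coords <- sp$geometry$coords %*% t(R) +
    matrix(shift, nrow(sp$geometry$coords), 3, byrow = TRUE)
  if (!is.null(sp$modes))
    sp$modes$displacements <- lapply(sp$modes$displacements,
                                     function(m) m %*% t(R))
  sp
}

permute_atoms <- function(sp, perm) {
  sp$geometry$coords <- sp$geometry$coords[perm, , drop = FALSE]
  sp$geometry$symbols <- sp$geometry$symbols[perm]
  sp$geometry$masses <- sp$geometry$masses[perm]
  if (!is.null(sp$modes))
    sp$modes$displacements <- lapply(sp$modes$displacements,
                                     function(m) m[perm, , drop = FALSE])
  sp
}

# embedded fixture bundle for a given surface, loaded as a network
embedded_network <- function(surface, subdir) {
  d <- file.path(tempdir(), "dynaselect-fixtures", subdir)
  emb <- embed_as_molecule(surface, d)
  list(net = load_network(emb$network_path), emb = emb)
}
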