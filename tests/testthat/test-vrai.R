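# The dynamic-selectivity core: bond selection, 2D projection, mode
# orientation, stream width and the Gaussian partition.

test_that("bond selection finds exactly the changing bonds", {
  # two products differing in one C-O and one C-C distance
  pa <- probe_geom(1.4, 1.5, symbols = c("C", "O", "C", "C"),
                   masses = atomic_masses(c("C", "O", "C", "C")))
  pb <- probe_geom(2.8, 2.6, symbols = c("C", "O", "C", "C"),
                   masses = atomic_masses(c("C", "O", "C", "C")))
  sel <- select_bond_coordinates(pa, list(pa, pb), pa, threshold = 0.3)
  expect_equal(sel$pairs, rbind(c(1L, 2L), c(3L, 4L)),
               ignore_attr = TRUE)
  expect_equal(sel$threshold, 0.3)
})

test_that("threshold halves until at least two pairs pass", {
  pa <- probe_geom(1.5, 1.5)
  pb <- probe_geom(1.75, 1.71)   # differences 0.25 and 0.21, below 0.3
  sel <- select_bond_coordinates(pa, list(pa, pb), pa, threshold = 0.3)
  expect_equal(nrow(sel$pairs), 2L)
  expect_equal(sel$threshold, 0.15)
})

test_that("geometrically identical structures are a degenerate input", {
  g <- probe_geom(1.5, 1.5)
  expect_error(select_bond_coordinates(g, list(g, g), g),
               "identical", class = "dynaselect_validation_error")
})

test_that("the fixture generator's reactive pairs are recovered", {
  surf <- make_surface(asymmetry = 0.25)
  d <- withr::local_tempdir()
  emb <- embed_as_molecule(surf, d)
  int_g <- read_xyz(file.path(d, "INT.xyz"))
  ts_g <- read_xyz(file.path(d, "TS1.xyz"))
  prods <- lapply(emb$labels, function(l) read_xyz(file.path(d, paste0(l, ".xyz"))))
  sel <- select_bond_coordinates(int_g, prods, ts_g)
  expect_equal(sel$pairs, emb$pairs, ignore_attr = TRUE)
})

test_that("projection places the intermediate at the origin and is isometric
          enough (a contraction of bond-space distances)", {
  sys <- probe_system()
  sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                 sys$ts$geometry)
  pl <- project_to_2d(sys$ts, sys$int_g,
                      list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
  expect_equal(pl$origin, c(0, 0))
  expect_equal(pl$g_vec, -pl$ts_position)
  expect_equal(crossprod(pl$basis), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # contraction: projected pairwise distances never exceed bond-space ones
  geoms <- list(sys$ts$geometry, sys$int_g, sys$p1_g, sys$p2_g)
  dvecs <- lapply(geoms, function(g)
    sqrt(rowSums((g$coords[sel$pairs[, 1], ] - g$coords[sel$pairs[, 2], ])^2)))
  pos <- rbind(pl$ts_position, c(0, 0), pl$product_positions)
  for (i in 1:3) for (j in (i + 1):4) {
    full <- sqrt(sum((dvecs[[i]] - dvecs[[j]])^2))
    proj <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    expect_lte(proj, full + 1e-12)
  }
})

test_that("mirror-symmetric products project to symmetric positions", {
  fx <- embedded_network(make_surface(), "sym-proj")
  pts <- fx$net$points
  sel <- select_bond_coordinates(pts$INT$geometry,
                                 lapply(pts[c("P1", "P2")], `[[`, "geometry"),
                                 pts$TS1$geometry)
  pl <- project_to_2d(pts$TS1$geometry, pts$INT$geometry,
                      lapply(pts[c("P1", "P2")], `[[`, "geometry"), sel)
  r <- unname(sqrt(rowSums(pl$product_positions^2)))
  expect_equal(r[1], r[2], tolerance = 1e-8)
  u1 <- pl$product_positions[1, ] / r[1]
  u2 <- pl$product_positions[2, ] / r[2]
  bis <- (u1 + u2); bis <- bis / sqrt(sum(bis^2))
  expect_equal(sum(u1 * bis), sum(u2 * bis), tolerance = 1e-8)
})

test_that("nearly parallel product directions are a degenerate basis", {
  g0 <- probe_geom(1.5, 1.5)
  p1 <- probe_geom(2.5, 1.5)
  p2 <- probe_geom(3.5, 1.5)   # same direction as p1 from the intermediate
  sel <- select_bond_coordinates(g0, list(p1, p2), g0)
  expect_error(project_to_2d(g0, g0, list(P1 = p1, P2 = p2), sel),
               "parallel within 1 degree",
               class = "dynaselect_validation_error")
})

test_that("the imaginary mode is oriented toward the intermediate side", {
  sys <- probe_system()
  sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                 sys$ts$geometry)
  pl <- project_to_2d(sys$ts, sys$int_g,
                      list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
  a <- orient_imaginary_mode(sys$ts, pl, sel)
  expect_gte(sum(a * pl$g_vec), 0)
  # flipping the stored displacement must give the same oriented vector
  flipped <- sys$ts
  flipped$modes$displacements[[1]] <- -flipped$modes$displacements[[1]]
  expect_equal(orient_imaginary_mode(flipped, pl, sel), a)
})

test_that("a mode with no net component on any selected bond errors", {
  sys <- probe_system()
  # displacement perpendicular to both bond axes
  perp <- matrix(0, 4, 3); perp[2, 2] <- 1
  sys$ts$modes$displacements[[1]] <- perp
  sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                 sys$ts$geometry)
  pl <- project_to_2d(sys$ts, sys$int_g,
                      list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
  expect_error(orient_imaginary_mode(sys$ts, pl, sel),
               "zero net component", class = "dynaselect_validation_error")
})

test_that("zero-point widths match the closed-form harmonic values", {
  # sqrt(hbar / (2 mu omega)) at (3000 cm^-1, 1 amu) = 0.0749 A, evaluated
  # independently in SI units; the 1000 cm^-1 case scales by sqrt(3)
  for (case in list(list(f = 3000, sig = 0.0749),
                    list(f = 1000, sig = 0.1298))) {
    sys <- probe_system(real_freq = case$f)
    sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                   sys$ts$geometry)
    pl <- project_to_2d(sys$ts, sys$int_g,
                        list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
    w <- stream_width(sys$ts, pl, sel)
    expect_equal(w$sigma, case$sig, tolerance = 1e-3)
    expect_equal(sum(w$per_mode_contributions$contribution_A2), w$sigma^2,
                 tolerance = 1e-10)
  }
})

test_that("doubling every frequency shrinks zero-point widths by sqrt(2)", {
  sys1 <- probe_system(real_freq = 700)
  sys2 <- probe_system(real_freq = 1400)
  sel <- select_bond_coordinates(sys1$int_g, list(sys1$p1_g, sys1$p2_g),
                                 sys1$ts$geometry)
  pl <- project_to_2d(sys1$ts, sys1$int_g,
                      list(P1 = sys1$p1_g, P2 = sys1$p2_g), sel)
  w1 <- stream_width(sys1$ts, pl, sel)
  w2 <- stream_width(sys2$ts, pl, sel)
  expect_equal(w1$sigma / w2$sigma, sqrt(2), tolerance = 1e-12)
})

test_that("thermal widths follow the classical harmonic formula", {
  sys <- probe_system(real_freq = 300)
  sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                 sys$ts$geometry)
  pl <- project_to_2d(sys$ts, sys$int_g,
                      list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
  wz <- stream_width(sys$ts, pl, sel, width_model = "thermal",
                     temperature = 298.15)
  # independent evaluation in SI units: sqrt(kB T / (mu omega^2))
  om <- 2 * pi * 2.99792458e10 * 300
  sig_si <- sqrt(1.380649e-23 * 298.15 / (1.66053906660e-27 * om^2)) * 1e10
  expect_equal(wz$sigma, sig_si, tolerance = 1e-6)
})

test_that("the Gaussian partition reproduces standard-normal masses", {
  wd <- manufactured_width(0.2)
  # delta = 0: the stream centre sits on the ridge
  pl <- manufactured_plane()
  res0 <- predict_two_product_ratio(pl, c(0, 1), wd)
  expect_identical(unname(res0$fractions), c(0.5, 0.5))
  # delta = sigma: Phi(1) = 0.8413
  s <- 0.2
  a <- c(-s, sqrt(1 - s^2))
  res1 <- predict_two_product_ratio(pl, a, wd)
  expect_equal(unname(res1$fractions[["P1"]]), 0.8413, tolerance = 5e-4)
  # delta = 3 sigma: at least 99.8 % to P1
  s3 <- 0.6
  res3 <- predict_two_product_ratio(pl, c(-s3, sqrt(1 - s3^2)), wd)
  expect_gte(res3$fractions[["P1"]], 0.998)
})

test_that("swapping the product labels swaps the fractions exactly", {
  sys <- probe_system(real_freq = 800)
  int_sp <- stationary_point("INT", "INT2", sys$int_g, -8)
  p1 <- stationary_point("PA", "product", sys$p1_g, -20)
  p2 <- stationary_point("PB", "product", sys$p2_g, -20)
  r12 <- predict_multi_product_ratio(sys$ts, int_sp, list(p1, p2))
  r21 <- predict_multi_product_ratio(sys$ts, int_sp, list(p2, p1))
  expect_identical(r12$fractions[["PA"]], r21$fractions[["PA"]])
  expect_identical(r12$fractions[["PB"]], r21$fractions[["PB"]])
})

test_that("the multi-product path reduces exactly to the pairwise one", {
  sys <- probe_system(real_freq = 800)
  int_sp <- stationary_point("INT", "INT2", sys$int_g, -8)
  p1 <- stationary_point("P1", "product", sys$p1_g, -20)
  p2 <- stationary_point("P2", "product", sys$p2_g, -20)
  multi <- predict_multi_product_ratio(sys$ts, int_sp, list(p1, p2))
  sel <- select_bond_coordinates(sys$int_g, list(sys$p1_g, sys$p2_g),
                                 sys$ts$geometry, 0.3)
  pl <- project_to_2d(sys$ts$geometry, sys$int_g,
                      list(P1 = sys$p1_g, P2 = sys$p2_g), sel)
  a <- orient_imaginary_mode(sys$ts, pl, sel)
  w <- stream_width(sys$ts, pl, sel, a_vec = a)
  direct <- predict_two_product_ratio(pl, a, w)
  expect_identical(unname(multi$fractions), unname(direct$fractions))
})

test_that("symmetric side channels of a three-way split get equal shares", {
  fx <- embedded_network(make_surface(n_wells = 3, well_separation = 0.45,
                                      well_depth = 3), "sym3")
  pts <- fx$net$points
  res <- predict_multi_product_ratio(pts$TS1, pts$INT,
                                     pts[c("P1", "P2", "P3")])
  expect_equal(res$fractions[["P2"]], res$fractions[["P3"]],
               tolerance = 1e-9)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
})

test_that("fractions respond continuously to tiny TS displacements", {
  fx <- embedded_network(make_surface(asymmetry = 0.3), "cont")
  pts <- fx$net$points
  base <- predict_multi_product_ratio(pts$TS1, pts$INT, pts[c("P1", "P2")])
  set.seed(4)
  for (i in 1:5) {
    ts2 <- pts$TS1
    ts2$geometry$coords <- ts2$geometry$coords +
      matrix(stats::runif(12, -1e-4, 1e-4), 4, 3)
    pert <- predict_multi_product_ratio(ts2, pts$INT, pts[c("P1", "P2")])
    expect_lt(max(abs(pert$fractions - base$fractions)), 1e-2)
  }
})
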