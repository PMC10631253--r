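# Model surfaces, the molecular embedding and the trajectory oracle.

test_that("stationary points are genuine and correctly classified", {
  for (surf in list(make_surface(asymmetry = 0.3),
                    make_surface(n_wells = 3, well_separation = 0.45,
                                 well_depth = 3, asymmetry = 0.1))) {
    pts <- rbind(ts = surf$ts, surf$wells, surf$saddles)
    for (i in seq_len(nrow(pts))) {
      g <- surf$gradient(pts[i, 1], pts[i, 2])
      expect_lt(sqrt(sum(g^2)), 1e-8)
    }
    ev_ts <- eigen(surf$hessian(surf$ts[1], surf$ts[2]),
                   symmetric = TRUE, only.values = TRUE)$values
    expect_identical(sum(ev_ts < 0), 1L)
    for (i in seq_len(nrow(surf$wells))) {
      ev <- eigen(surf$hessian(surf$wells[i, 1], surf$wells[i, 2]),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev > 0))
    }
  }
})

test_that("the analytic Hessian matches finite differences", {
  surf <- make_surface(asymmetry = 0.2)
  h <- 1e-5
  set.seed(2)
  for (i in 1:5) {
    x <- stats::runif(1, -0.8, 0.8); y <- stats::runif(1, 0.1, 1.9)
    H <- surf$hessian(x, y)
    num <- matrix(0, 2, 2)
    gp <- surf$gradient(c(x + h, x, x), c(y, y + h, y))
    gm <- surf$gradient(c(x - h, x, x), c(y, y - h, y))
    num[, 1] <- (gp[1, ] - gm[1, ]) / (2 * h)
    num[, 2] <- (gp[2, ] - gm[2, ]) / (2 * h)
    expect_equal(H, (num + t(num)) / 2, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("the symmetric saddle's unstable mode lies along the axis", {
  surf <- make_surface(asymmetry = 0)
  H <- surf$hessian(surf$ts[1], surf$ts[2])
  e <- eigen(H, symmetric = TRUE)
  unstable <- e$vectors[, which.min(e$values)]
  expect_equal(abs(unstable), c(0, 1), tolerance = 1e-12)
})

test_that("single-well parameter combinations are rejected", {
  expect_error(make_surface(n_wells = 1), "bifurcation",
               class = "dynaselect_validation_error")
  expect_error(make_surface(well_separation = -1), "well_separation",
               class = "dynaselect_validation_error")
})

test_that("the embedded fixture passes io validation with one imaginary mode", {
  d <- withr::local_tempdir()
  emb <- embed_as_molecule(make_surface(asymmetry = 0.2), d)
  geom <- read_xyz(file.path(d, "TS1.xyz"))
  nm <- read_frequency_data(file.path(d, "TS1_modes.json"), "sidecar_json",
                            geometry = geom, structure_type = "ts")
  expect_identical(sum(nm$frequencies < 0), 1L)
  net <- load_network(file.path(d, "network.yaml"))
  expect_s3_class(net, "reaction_network")
})

test_that("embedded bond distances reproduce the surface coordinates", {
  surf <- make_surface(asymmetry = 0.25)
  d <- withr::local_tempdir()
  embed_as_molecule(surf, d)
  bond <- function(file, i, j) {
    g <- read_xyz(file.path(d, file))
    sqrt(sum((g$coords[i, ] - g$coords[j, ])^2))
  }
  # differences of emitted bond lengths equal surface-coordinate differences
  expect_equal(bond("P1.xyz", 1, 2) - bond("TS1.xyz", 1, 2),
               unname(surf$wells["P1", 2] - surf$ts[2]), tolerance = 1e-8)
  expect_equal(bond("P1.xyz", 3, 4) - bond("TS1.xyz", 3, 4),
               unname(surf$wells["P1", 1] - surf$ts[1]), tolerance = 1e-8)
  expect_equal(bond("INT.xyz", 3, 4) - bond("TS1.xyz", 3, 4),
               unname(surf$intermediate_ref[1] - surf$ts[1]),
               tolerance = 1e-8)
})

test_that("the oracle is deterministic and independent of execution order", {
  surf <- make_surface(asymmetry = 0.3)
  o1 <- trajectory_oracle(surf, n = 150, seed = 9)
  o2 <- trajectory_oracle(surf, n = 150, seed = 9)
  expect_identical(o1$basin_counts, o2$basin_counts)
  # counter-based draws: the first 100 trajectories of a 150-run equal a
  # 100-run with the same seed
  o3 <- trajectory_oracle(surf, n = 100, seed = 9)
  expect_identical(o3$basins, o1$basins[1:100])
})

test_that("trajectories conserve energy to one part in a million", {
  surf <- make_surface(asymmetry = 0.2)
  o <- trajectory_oracle(surf, n = 100, seed = 3)
  expect_lt(o$max_energy_drift, 1e-6)
})

test_that("reflecting the surface and the draw stream swaps the basins", {
  op <- trajectory_oracle(make_surface(asymmetry = 0.35), n = 200, seed = 13)
  om <- trajectory_oracle(make_surface(asymmetry = -0.35), n = 200, seed = 13,
                          reflect_transverse = TRUE)
  expect_identical(unname(op$basin_counts),
                   unname(rev(om$basin_counts)))
})

test_that("a strongly offset stream commits almost fully to one product", {
  # offset >= 3 sigma of the (stiffer) entry channel
  surf <- make_surface(asymmetry = 0.67, ts_mode_force_const = 4)
  o <- trajectory_oracle(surf, n = 500, seed = 21)
  expect_gte(o$fractions[["P1"]], 0.99)
})

test_that("the full pipeline on the symmetric fixture gives exactly 50/50", {
  fx <- embedded_network(make_surface(), "sym-pipe")
  dist <- run_selectivity_pipeline(fx$net, run_config())
  expect_equal(unname(dist$percentages[c("P1", "P2")]), c(50, 50),
               tolerance = 1e-6)
})
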