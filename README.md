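# dynaselect

Dynamics-aware prediction of chemo- and stereoselectivity from
quantum-chemistry stationary points.

## Why

Some reactions cannot be explained by transition state theory (TST): after
the first transition state the potential energy surface bifurcates (a
valley–ridge inflection), or a shallow intermediate connects a high first
barrier to much lower second barriers. Trajectories then fly through the
post-TS region without equilibrating and the product ratio is set by
*reaction dynamics* — which side of the downstream ridge the stream of
trajectories lands on — not by the second barriers. Quasi-classical
molecular dynamics resolves such cases but costs orders of magnitude more
than the optimizations themselves. `dynaselect` is for computational
chemists who already have the stationary points (geometries, Gibbs free
energies, harmonic frequencies of TS1, the intermediate, and the products)
and want the dynamic selectivity in seconds.

## The model

The surface is reduced to 2D using the bond distances that change between
products (threshold 0.3 Å, halved as needed). On that plane, reactive
trajectories leave TS1 as a Gaussian stream: its direction **ā** is the
projected imaginary eigenvector (oriented toward the intermediate,
**ā** · **ḡ** ≥ 0, where **ḡ** is the TS1→intermediate separation), and its
width is the quadrature sum of the harmonic widths of the real modes,
σ_k = √(ħ / 2 μ_k ω_k) (zero-point, default) or √(k_B T / μ_k ω_k²)
(thermal), each projected perpendicular to **ā**. The ridge between two
product valleys runs through the intermediate along the bisector of the two
intermediate→product directions; with δ the signed distance from the stream
centre (TS1 position + **ā**·|**ḡ**|) to the ridge,

    fraction(P1) = Φ(δ / σ),

the standard-normal mass on P1's side. More than two products sharing one
TS1 and intermediate are handled pairwise against a deterministic reference
product, combining the pairwise odds. Branch-level results are composed with
Boltzmann populations of the TS1 (and TS2) conformers — pruned to the
low-energy 99 % of the distribution — after an energy check per branch:
the stream analysis is used only where every TS2 lies strictly below TS1;
otherwise that branch falls back to TST. Percentages per product identity
are the population-weighted sums, and `mae_vs_experiment()` scores them in
percentage points.

The package also ships its own validation instruments: analytic bifurcating
model surfaces with tunable asymmetry (`make_surface()`), an embedding into
a synthetic four-atom molecule that emits a complete XYZ + mode-sidecar +
network-YAML input bundle (`embed_as_molecule()`), and a quasi-classical
velocity-Verlet trajectory oracle on the analytic surface
(`trajectory_oracle()`).

## Worked example

Build a tilted bifurcating surface, emit its molecular input bundle, run the
full pipeline, and compare with 2000 real trajectories:

```r
library(dynaselect)
surf <- make_surface(asymmetry = 0.4)          # ridge offset, 0.4 x half-separation
emb  <- embed_as_molecule(surf, "fixture-dir") # XYZ + sidecars + network.yaml
net  <- load_network(emb$network_path)
fit  <- run_selectivity_pipeline(net, run_config())
summary(fit)
#> Product distribution (with_vrai mode, 298.15 K)
#>   P1                              85.75 %
#>   P2                              14.25 %
#>
#> Pathway flows:
#>   TS1              population 100.00 %  [VRAI]
#>       -> P1                    85.75 % of branch
#>       -> P2                    14.25 % of branch

trajectory_oracle(surf, n = 2000, seed = 1)
#> <trajectory_ensemble_result> 2000 trajectories (3 undecided), seed 1
#>   P1       1698  (85.03 %)
#>   P2        299  (14.97 %)
```

The stream partition (85.8 % / 14.2 %) agrees with the trajectory ensemble
(85.0 % / 15.0 %) to under a percentage point: the tilt displaces the
downstream ridge by δ ≈ 1.07 σ, and Φ(1.07) of the zero-point stream falls
into the P1 valley. Conformer statistics use the same machinery everywhere:

```r
boltzmann_weights(c("TS1(RS-1)" = 0, "TS1(SR-2)" = 1.0), 298.15)
#> <boltzmann_ensemble> 2 members at 298.15 K
#>      label ddG weight
#>  TS1(RS-1)   0 0.8439
#>  TS1(SR-2)   1 0.1561
```

Real systems enter through the same `load_network()` door: a YAML file
listing each stationary point (XYZ geometry, Gibbs free energy in kcal/mol
or Hartree, optional frequency sidecar or Gaussian-style log, stereo
descriptor) plus the edge list TS1 → intermediate → TS2 → product, with
optional barrierless channels, a dynamic TS0 complexation stage, and
experimental percentages.

A command-line wrapper is included (`inst/scripts/dynaselect`) with
subcommands `run`, `compare`, `fixtures`, `oracle` and `validate`; every
result JSON embeds the resolved configuration and input checksums.

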