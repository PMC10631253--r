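---
title: "Predicting dynamically controlled selectivity from stationary points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dynamically controlled selectivity from stationary points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transition state theory (TST) explains selectivity by comparing barrier
heights: the pathway through the lowest first transition state wins, and
competing channels populate according to their Boltzmann factors. Some
reactions defeat this picture. When a potential energy surface bifurcates
after the first transition state — a valley becomes a ridge at a
valley-ridge inflection (VRI), or a shallow intermediate connects a high
first barrier to much lower second barriers — trajectories fly over the
post-TS region without equilibrating, and the product ratio is set by where
the *stream of trajectories* goes, not by the second barriers. Asymmetric
catalysis with chiral oxazaborolidinium ion (COBI) catalysts provides
striking examples: near-identical substrates give ketone-, epoxide- or
aldehyde-dominated mixtures depending on remote catalyst substituents, and
TST predictions can rank the wrong major product entirely.

Quasi-classical molecular dynamics resolves such cases but at enormous cost
(thousands of gradient evaluations per trajectory, hundreds of trajectories
per channel). This package implements the cheap alternative: a
*trajectory-stream analysis* that needs only the stationary points a
selectivity study already computes — geometries, Gibbs free energies and
harmonic frequencies of the first transition state (TS1), the downstream
intermediate and the products.

## The stream-partition model

All analysis happens on a two-dimensional reduction of the surface built
from *bond differences*:

1. **Coordinate selection.** Every atom pair whose interatomic distance
   changes by more than a threshold (default 0.3 Å) between any two product
   geometries, or between a product and the TS1 geometry, becomes a
   coordinate. If fewer than two pairs qualify, the threshold is halved (up
   to six times). 0.3 Å separates forming/breaking bonds from vibrational
   jitter at typical amplitudes; the halving fallback handles late or early
   transition states with subtle geometry changes.
2. **Projection.** Each structure maps to its vector of selected bond
   lengths. The plane is the Gram–Schmidt orthonormalization of the two
   intermediate→product displacement vectors in that bond-length space, with
   the intermediate at the origin. Bond lengths are invariant under rotation,
   translation and consistent atom renumbering, so the analysis inherits
   those invariances (property-tested under randomized rigid motions and
   permutations).
3. **Direction.** The TS1 imaginary eigenvector is converted to bond-length
   *rates* (for pair *(i, j)*, the component of the relative atomic
   displacement along the bond axis), projected into the plane, normalized
   to the unit vector **a**, and oriented so that it points from TS1 toward
   the intermediate (**a** · **g** ≥ 0, where **g** runs from the TS1
   projection to the intermediate).
4. **Width.** Each real mode *k* of TS1 contributes a harmonic width
   σ<sub>k</sub> = √(ħ / 2 μ<sub>k</sub> ω<sub>k</sub>) (zero-point, the
   default — matching how quasi-classical trajectories are initialized) or
   √(k<sub>B</sub>T / μ<sub>k</sub> ω<sub>k</sub>²) (thermal), with
   μ<sub>k</sub> the mode's reduced mass. The mode pattern goes through the
   same bond-rate projection, and its in-plane component perpendicular to
   **a**, scaled by σ<sub>k</sub>, adds in quadrature to the stream width σ.
5. **Partition.** The ridge separating the two product valleys is drawn
   through the intermediate along the bisector of the two
   intermediate→product directions. The stream centre is the TS1 position
   displaced along **a** by |**g**|. With δ the signed perpendicular
   distance from the centre to the ridge (positive toward product 1),
   product 1 receives the Gaussian mass Φ(δ/σ). δ = 0 reports exactly
   50/50.

This concrete geometry — stream centre, ridge-as-bisector, Gaussian
partition — is this package's normative reconstruction of a method whose
published description is a sketch; every formula above is therefore part of
this package's contract and is pinned by closed-form tests
(Φ(1) = 84.13/15.87 at δ = σ; σ = 0.0749 Å for a 3000 cm⁻¹, 1 amu mode).

### More than two products

When more than two products share one intermediate and TS1, a reference
product *r* is fixed — the one whose intermediate→product direction is most
anti-parallel to **g** in bond space, ties broken lexicographically by label
so the result is deterministic. Every other product *p* is analysed pairwise
against *r* in the (*p*, *r*) plane, the pairwise fractions become odds
o<sub>p</sub> = f(p)/f(r) (accumulated in log space so extreme splits do not
overflow), and the final fractions are the normalized odds. A pair whose
projection plane degenerates (parallel directions) falls back to Boltzmann
weighting of the two channel barriers and is flagged in the diagnostics.

The pairwise scheme has a structural blind spot, documented here
deliberately: for a symmetric three-way split it always returns 1/3 each,
because each pairwise ridge passes through the stream centre. Trajectory
ensembles agree with that only when the channels are *quasi-degenerate* —
separated by less than about 1.5 stream widths — which is the regime the
three-well validation fixture occupies (well separation 0.45 Å against
σ ≈ 0.30 Å). For widely separated channels the forming central valley
adiabatically squeezes the stream and concentrates flux in the central
product, an effect a frozen-width model cannot represent. Multi-channel
predictions for widely separated channels should be treated as qualitative.

## From branch ratios to product percentages

The pipeline (`run_selectivity_pipeline()`) composes the stream analysis
with conformer statistics:

* TS1 conformer populations come from Boltzmann weighting of ΔΔG‡ at the run
  temperature (default 298.15 K, R = 1.98720425×10⁻³ kcal mol⁻¹ K⁻¹),
  pruned to the low-energy set that carries 99 % of the population and
  renormalized. The same 99 % rule applies within each branch's TS2
  conformers. Ties at the coverage boundary are all retained so the result
  is order-independent.
* Each retained branch passes an **energy check**: the stream analysis is
  trusted only if every TS2 lies *strictly below* TS1 in Gibbs free energy
  (equality conservatively fails), or if the branch is barrierless;
  otherwise the branch falls back to TST over its TS2 conformers.
* Branch resolutions multiply the TS1 populations and sum per product
  identity (species + stereodescriptor), scaled to 100. Flow is conserved at
  every node (Sankey property, tested to 1e-9), and channels cut by the
  99 % rule contribute exactly zero rather than being redistributed.
* Networks may declare a dynamically resolved complexation stage: a stream
  analysis at TS0 over the stereoisomeric adducts partitions flow among
  stereochemical families before the TS1-level statistics, composed by
  sequential multiplication. Channels through a stable late intermediate are
  modelled by listing its eventual products as additional products of the
  TS1-level multi-way analysis.
* `tst_only` mode skips all dynamics and reproduces pure TST percentages.

`mae_vs_experiment()` scores a distribution against experimental
percentages as the mean absolute error in percentage points over the full
product catalog.

## The synthetic surface family and the trajectory oracle

Validation needs ground truth that does not depend on the machinery under
test. `make_surface()` builds an analytic 2D potential (energies kcal/mol,
lengths Å, masses amu):

V(x, y) = E<sub>b</sub>(2t³ − 3t²) + (1 − w(t)) k₁x²/2 + w(t) u(x − x_c),
  t = y/L,

a cubic descent of E<sub>b</sub> (default 15 kcal/mol) from a saddle at the
origin to the well line at y = L (default 2 Å), a soft harmonic entry
channel (k₁ = 0.5 kcal mol⁻¹ Å⁻², a ~31 cm⁻¹ transverse mode), and a
double well u (quartic, wells ±0.8 Å, depth 8 kcal/mol) or Gaussian triple
well switched on by a C² quintic ramp w(t) at the declared VRI position
(default 1 Å). Because the ramp's first two derivatives vanish at the well
line, every well and inter-well saddle sits exactly on y = L in closed form;
a Newton polish verifies all stationary points to a gradient norm of 1e-10,
and an independent finite-difference Hessian cross-check runs in the tests.
Asymmetry is a lateral offset x_c of the bifurcation region (a fraction of
the well half-separation): the harmonic entry channel transports the
zero-point Gaussian stream *unchanged* (it is a stationary Wigner packet of
that mode), so the offset displaces the ridge relative to the stream exactly
as the partition model assumes. An early design that implemented asymmetry
as a distributed transverse tilt force was rejected: it violates the
ballistic-stream assumption that defines the method's domain, and no static
analysis can track it.

`embed_as_molecule()` maps (x, y) onto the two bond lengths of a synthetic
four-atom system (two carbon diatoms 40 Å apart, so no spectator distance
varies above the selection threshold), writing XYZ files, analytic-Hessian
mode sidecars (and a synthetic frequency log exercising the log parser) and
a network YAML — a complete, download-free input bundle whose ground-truth
reactive pairs are recorded. The surface mass (6.0055 amu) is the C–C
stretch reduced mass so the embedded vibrational analysis and the 2D oracle
agree exactly.

`trajectory_oracle()` integrates quasi-classical trajectories directly on
the 2D surface (deliberately independent of the projection machinery):
initial transverse position/momentum drawn from the saddle's harmonic
distribution matching the width model, forward momentum half-Gaussian
thermal along the oriented unstable eigenvector, velocity-Verlet at ≤ 0.024
fs-equivalent (auto-reduced for stiff wells so per-trajectory energy drift
stays below 10⁻⁶ of the initial total energy), counter-based draws keyed by
(seed, trajectory index) so results do not depend on execution order. A
trajectory is decided when it first enters the capture radius (half the
well half-separation) of a well; on a conservative 2D surface a
kinetic-energy criterion can never latch (the drop always exceeds the well
depth), so first entry is the standard and correct basin assignment. Rare
recrossers that escape upstream stay undecided and are excluded from the
fractions.

### What the synthetic conditions do and do not show

The study conditions are fixed: seven asymmetries from −0.6 to 0.6 (splits
from ~6/94 to ~94/6), 2000 trajectories per setting, zero-point widths,
298.15 K. Under them the stream partition tracks the ensemble within 5
percentage points (the acceptance suite recomputes this, typically finding
~1 point). The surfaces satisfy the method's assumptions *by construction*:
a single reactive funnel, harmonic entry, geometric asymmetry. Passing these
tests therefore shows the reconstruction is internally correct and tracks
real dynamics in the method's stated domain; it does not certify accuracy on
real PESs with anharmonic entry channels, mode mixing, or strong transverse
forces between TS1 and the ridge — for those, the published benchmark
remains quasi-classical MD. The external benchmark against deposited DFT
data for the five COBI reaction systems is wired into the test suite but
requires the (non-redistributable, ~binary) deposited bundle; without it
that one check reports as failed rather than silently passing.

## Numerical and design choices

* Energies are stored in kcal/mol; Hartree inputs convert by 627.5095.
  Network energies are re-zeroed at the lowest point — only differences
  matter, and shift invariance is property-tested.
* Normal-mode displacements are accepted in mass-weighted or
  Cartesian-normalized (log-file) conventions, tagged at read time, and
  converted to the mass-weighted form for analysis; reduced masses are
  recomputed from the displacements and atomic masses rather than trusted
  from input.
* Degenerate inputs fail loudly, never silently: identical product
  geometries, product directions parallel within 1°, a mode orthogonal to
  the plane (< 1e-8 of its bond-space norm), zero stream width, products at
  zero distance from the intermediate.
* The δ = 0 tie reports exactly 50/50. Extreme splits use log-space odds.
* Atom indices are 0-based nowhere: user-facing pairs are 1-based matrices,
  matching chemistry convention.
* Gaussian-style logs: the high-precision (per-coordinate) frequency block
  is preferred when present; the standard three-mode block is the fallback.
  The synthetic log writer emits extended digits so analytic eigenvectors
  survive the round trip — it is a parser fixture, not a log forger.
* Where the stream width is measured is genuinely open in the method's
  sketch (at TS1, or at the intermediate). This implementation evaluates it
  at TS1 and transports it unchanged to the ridge; the harmonic-channel
  argument above is why that transport is exact in the validation family.
  Likewise the multi-product composition is taken as pairwise-with-reference
  rather than a simultaneous n-way partition; both choices are recorded
  here as this package's contract.

## Problem sizes

The default validation sizes — 2000 trajectories per oracle setting, seven
sweep settings, 200 cases per randomized-invariant family — keep the full
suite around two minutes and the acceptance script around one, while the
binomial noise of a 2000-trajectory fraction (±1.1 points at 50 %) stays
well inside the 5-point agreement band being tested.
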