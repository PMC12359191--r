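---
title: "Multiscale blood/parenchyma dosimetry of the liver: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale blood/parenchyma dosimetry of the liver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Internal dosimetry traditionally treats an organ as a homogeneous mixture
of parenchyma and blood. For radiopharmaceuticals this hides a distinction
that matters clinically: activity circulating in blood and activity bound
in tissue deliver different doses to each other and to themselves, and the
ranges of therapeutic alpha and beta particles (tens of micrometers to
millimeters) are comparable to vessel calibers. A full geometric model of
an organ's vasculature down to the capillaries is computationally
impossible, but the liver has a special structure that makes a two-scale
factorization natural: outside of vessels thicker than roughly 100 µm, the
parenchyma is a quasi-periodic packing of hexagonal lobules whose internal
vasculature (the sinusoids) is the same everywhere.

`vasodose` therefore models the organ at two scales and couples them
mathematically:

* a **macroscale** organ model containing the explicit vessel trees, with
  two regions: vessel blood `LBM` and composite tissue `LCTM` (parenchyma
  plus all sub-resolution blood). Transport here uses *escape* boundaries:
  energy leaving the organ is lost.
* a **microscale** unit cell (the lobule) partitioned into pure blood
  `LBmu` (central vein, portal arteries and veins, sinusoids) and pure
  parenchyma `LP` (bile ducts and canaliculi, space of Disse, Kupffer
  cells, hepatocytes). Transport here uses *reflective* boundaries: the
  cell stands for an infinite tiling of the composite region.

With `phi_j(rT <- rS)` the absorbed fraction at scale `j`, the coupled
absorbed fractions are

```
phi(LP <- LB)   = phi_M(LCTM <- LBM) * mLP/mLCTM * mLBM/mLB
                + phi_mu(LP <- LBmu) * phi_M(LCTM <- LCTM) * mLBmu/mLB
phi(LB <- LP)   = phi_mu(LBmu <- LP) * phi_M(LCTM <- LCTM)
                + phi_M(LBM <- LCTM)
phi(LP <- LP)   = phi_mu(LP <- LP) * phi_M(LCTM <- LCTM)
phi(LB <- LB)   = [phi_M(LBM <- LBM) + phi_M(LCTM <- LBM) * mLBmu/mLCTM] * mLBM/mLB
                + [phi_M(LBM <- LCTM) * mLBmu/mLCTM
                   + phi_mu(LBmu <- LBmu) * phi_M(LCTM <- LCTM)] * mLBmu/mLB
```

and `Phi = phi / m_target` (per kg). Three assumptions power these
formulas: (i) the microscale blood and parenchyma are uniformly dispersed
through `LCTM`, so energy landing in the composite splits between them by
mass; (ii) their densities and compositions are close enough that mass
ratios equal energy-partition ratios (the package warns when supplied
densities differ by more than 2%); (iii) the factor
`phi_M(LCTM <- LCTM)` correctly restores, at the macroscale, the organ
escape that the reflective microscale run cannot see.

### A conservation caveat in the blood self-dose

The published form of the micro-source-to-macro-vessel term scales
`phi_M(LBM <- LCTM)` by `mLBmu/mLCTM`. Under assumption (i) a source
confined to the microscale blood has the *same* macroscale emission
density as a source uniform in the whole composite, so reciprocity and
whole-liver energy conservation require that term unscaled — exactly how
the analogous parenchyma-source term is used in `phi(LB <- LP)`. With the
scaled term, summing all four coupled quantities for no-escape inputs
leaves a deficit of exactly `w_mu * phi_M(LBM <- LCTM) * (1 -
mLBmu/mLCTM)`. `blood_self()` implements the published form by default
(`micro_to_macro = "published"`) and offers the conservation-exact variant
(`"conservative"`); the difference is bounded by `phi_M(LBM <- LCTM)`,
which is negligible whenever particle range is small compared to
inter-vessel spacing — the regime where the microscale model matters in
the first place. The conservation property test asserts exactness for the
conservative variant and the closed-form deficit for the published one.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| Murray exponent | 3 | — | classical minimum-work bifurcation law; the flow rule is equal flow per terminal |
| minimum vessel radius | 0.1 | mm | macroscale resolution limit (~100 µm); growth refuses configurations whose terminal radii would fall below it rather than clipping (clipping would break the Murray identity) |
| boundary voxel spacing | 0.3 | mm | organ masks are rasterized at this isotropic pitch |
| wrap offset | 10% of min radius | mm | undersizing applied before wrapping and restored by the offset surface; the reference value is user-defined, unstated |
| cylinder tessellation | 32 radial | — | sub-0.7% polygonal volume deficit |
| sinusoid diameter | 16 | µm | stated anatomical caliber; the only fixed lobule dimension |
| lobule apothem / height | 433 / 800 | µm | center-to-vertex ≈ 0.5 mm, the classical stylized-lobule scale; other radii (central vein, portal vessels, Disse thickness) are *solved from the target mass fractions*, not set |
| Kupffer circumradius | 7 | µm | must fit the 8 µm lumen; cells are icosahedra |
| bile canaliculus radius | 4 | µm | deliberately oversized against anatomy (~1 µm) for meshability; the mass fraction, not the caliber, is the constrained quantity |
| photon volume-fraction threshold | 0.150 | MeV | above it, reflective micro-model photon AFs equal component volume fractions, so simulated micro AFs are replaced by volume fractions |
| mass closure tolerance | 0.05 | g | reference mass tables carry 0.01–0.02 g rounding residues |

## What the generators emulate — and what they do not

**Vessel trees.** Growth is sequential constrained-constructive
optimization: uniformly sampled terminals attach to the existing tree at
the split minimizing locally added tube volume, junction positions are
optimized derivative-free, and every tentative insertion re-audits the
whole tree for capsule clearance (radii of ancestor edges grow as
terminals accumulate, so earlier checks alone would not guarantee a clean
final tree). The result reproduces the statistical look of an arterial
tree — Murray-consistent radii, non-increasing calibers, intersection
freedom — but has no hemodynamics: no pressure/flow solution, no
bifurcation-angle physiology beyond the volume cost, and equal flow per
terminal. Terminal counts, not vessel counts, are configured; a binary
tree yields about `2T - 1` segments for `T` terminals.

**The lobule.** All components are analytic primitives (cylinders, tubes,
icosahedra) packed deterministically in mirror-symmetric radial fans, with
total sinusoid length scaled so each component's mass fraction matches its
target essentially exactly; Kupffer cells are the only stochastic
ingredient. Real lobules have tortuous, anastomosing sinusoids, irregular
cell shapes and biological variability; none of that is represented. A
green geometry test therefore establishes that the *mass bookkeeping and
symmetry contracts* hold, not that the geometry is anatomically realistic.
Because Kupffer placement is random, the mirror-symmetry property of the
tiled rectangular cell is exact only for the deterministic components; the
symmetry test runs with a zero Kupffer target.

**The toy transport.** Charged particles travel a single straight track of
CSDA range length and deposit uniformly along it (constant LET — no Bragg
peak, no straggling, no multiple scattering, no secondaries); photons
deposit their full energy at the first interaction sampled by Woodcock
tracking against a single total attenuation coefficient per material
(kerma approximation, no scatter transport). Region lookup is a voxelized
label grid (64³ default; convergence should be checked when changing
geometry scale). These simplifications preserve exactly the properties the
coupling needs — energy conservation under reflective boundaries,
volume-proportional deposition in uniform media, monotone escape with
range — so a green two-scale-oracle test establishes that the *coupling
formalism* is implemented correctly, not that the absorbed fractions are
physically accurate. Production absorbed-fraction tables can be imported
via the CSV schema instead.

## Numerical choices

* **Tetrahedron sampling** follows the acceptance/rejection procedure
  exactly as specified (volumes normalized by the maximum as thresholds),
  with a Walker alias-table fast path behind a flag, tested for
  distributional equivalence (chi-square). Barycentric weights are drawn
  from the open interval (0, 1), so their sum can never vanish and each
  point's weights sum to 1 by construction.
* **Wrapping** replaces alpha wrapping by isosurfacing the minimum capsule
  signed-distance field at full (offset-restored) radii with marching
  tetrahedra on a translation-invariant 6-tet cube decomposition; shared
  edge keys make the output closed and 2-manifold by construction, and the
  result is verified watertight. Boolean union uses exact fast paths for
  duplicate and disjoint inputs and implicit (grid SDF) union only for
  genuinely overlapping groups.
* **SAF interpolation** uses monotone cubic Hermite (Fritsch–Carlson)
  interpolation on a log10 energy axis — SAF curves span decades of energy
  and a linear axis would waste the monotone-preservation property at the
  low end; the axis choice is switchable (`log_energy = FALSE`).
  Extrapolation is refused.
* **Published range/attenuation data** are transcribed at printed
  precision (2 significant figures), which is not strictly monotone;
  isotonic regression enforces monotonicity before log-log interpolation.
* **Determinism**: every stochastic operation takes a seed; the transport
  engine uses its own xorshift128+ stream seeded from it, so results are
  reproducible across platforms independent of R's RNG state.
* **Degenerate inputs**: zero-length segments are rejected; antiparallel
  rotation axes fall back to a fixed perpendicular axis with angle pi;
  collinear bifurcation anchors return the radius²-weighted midpoint (with
  a message); near-zero-volume tetrahedra are tolerated (they simply never
  win the volume-proportional selection).

## Design choices on genuinely open points

* The material assignment of the lobule follows the blood/bile/interstitial
  classification of the accompanying text (`lobule_component_materials("text")`);
  the published material table instead lists the sinusoids with the
  plasma/lymph composition and the bile canaliculi with blood. Both
  assignments are supported; the text rule is the default because it is the
  physiologically coherent one.
* The printed hepatocyte/Kupffer composition is not reproducible by simple
  mass balance on the published component tables; `solve_cell_composition()`
  therefore reports its per-element residuals against the printed row
  rather than asserting agreement.
* The two-scale acceptance oracle uses a 5.87 MeV alpha and a 30.6 keV
  electron. The electron energy is chosen inside the regime the microscale
  model exists for (range ≈ 18 µm, comparable to the micro vessel caliber
  and small against inter-vessel spacing); at ranges comparable to the
  inter-vessel spacing the published blood-self-dose form's conservation
  deficit (above) grows beyond the oracle's 5% band, which is a property of
  the formalism, not of this implementation.
* The acceptance-report targets are deterministic bookkeeping quantities;
  the stochastic acceptance criteria run inside the test suite with fixed
  seeds and per-run seed offsets (reusing one seed across runs would
  correlate their noise and distort the 3-sigma comparisons).

## Known limitations

* Vessel walls are not modeled (short-range particles would see slightly
  lower parenchyma absorbed fractions if they were).
* The lobule is sex-independent and healthy-adult; no lymphatics, stellate
  or endothelial cells, no histology-informed randomness.
* The toy transport's electron model is the same straight-CSDA track as
  the alpha model — crude for electrons, whose paths are genuinely
  tortuous; imported Monte Carlo tables should be preferred for any
  physical conclusion.
* Whole-liver sums `phi(L <- LB)` and `phi(L <- LP)` are approximately
  equal only at low energy; both sides are reported rather than asserted
  equal, and their divergence with energy is expected (greater escape for
  blood sources concentrated near the organ surface).
* No mesoscale tier: the framework assumes the macroscale minimum caliber
  and the microscale maximum caliber meet, as they do in the liver.
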