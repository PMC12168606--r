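---
title: "Modelling glycerol-water solvation structure against X-ray scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glycerol-water solvation structure against X-ray scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Freeze-avoiding beetle larvae survive arctic winters by dehydrating and
replacing body water with glycerol. Whether their hemolymph can freeze is a
question about *water clusters*: infrared spectroscopy places the smallest
ice-forming cluster at roughly 275 water molecules, so a glycerol-water
mixture in which no connected water network reaches that size cannot
nucleate ice. cryostruct provides the modelling chain needed to ask that
question of X-ray total-scattering data: atomistic Monte Carlo models of
glycerol-water mixtures, forward calculation of the X-ray structure factor
S(Q), empirical-potential refinement against a measured pattern,
composition calibration of unknown patterns, and cluster/coordination
analysis of the resulting ensembles.

## The model

Molecules are semi-rigid: a rigid skeleton built from a reference geometry
(bond lengths and angles held exactly by rigid-body propagation) plus, for
glycerol, three rotatable C-O-H hydroxyl groups. The energy is

* intermolecular Lennard-Jones (Lorentz-Berthelot combining) and
  shifted-force Coulomb terms under the minimum-image convention, truncated
  at `min(9 A, L/2)`;
* tabulated *empirical* pair potentials over the heavy atom types (C, OG,
  OW), zero until refinement switches them on, bounded by an amplitude cap;
* intramolecular harmonic bond terms (constant under the rigid moves; they
  make `total_energy()` well defined for distorted input).

Charges and Lennard-Jones parameters are the OPLS-derived glycerol set used
by published neutron-refinement work on glycerol-water together with SPC/E
water; every value and its source is listed in
`inst/extdata/forcefield_glycerol_water.yaml`. Temperature enters through
Metropolis acceptance `min(1, exp(-dE/kT))` and through the density model.

Mixture densities interpolate the pure-component molar volumes (water
0.997, glycerol 1.261 g/cm^3 at 298 K) with a symmetric negative excess
volume (default minimum -0.45 cm^3/mol) so that intermediate compositions
are denser than ideal mixing — refined models at ideal-solution densities
are known to develop unphysical voids — and linear thermal expansivities
so the liquid densifies on cooling.

Ewald summation is deliberately not used: the observables this package
targets (first-shell coordination, 3.2-3.5 A contact counting, cluster
connectivity) are short-ranged, and shifted-force truncation at 8-9 A
reproduces them at a fraction of the cost in desk-scale boxes.

## Packing

Boxes are packed dilute and compressed. Molecules start on a jittered
lattice with random orientations at about 78% of the target density,
where thermal Metropolis moves under a purely repulsive soft-sphere
potential (charges off) resolve the initial overlaps easily; molecule
centres are then scaled toward the target box edge in eight small steps
with relaxation in between, and cold polishing blocks push the closest
contacts past 1.5 A (escalating the soft-sphere diameter, then
reheating, if a contact resists). Naive random insertion with rejection
cannot place 14-atom glycerol molecules at liquid density, and both
greedy overlap-descent and direct relaxation at full density jam
intermittently; compression from a valid dilute configuration is
reliable across seeds and stays deterministic under the seed.

## Scattering transforms

Pair distribution functions are shell-normalized histograms over ensemble
snapshots. `coordination_number()` integrates `4 pi rho r^2 g(r)` using
exact shell volumes, so a histogram integrates back to the exact mean
neighbour count (a simple-cubic lattice gives n = 6 identically). The
X-ray structure factor is the Faber-Ziman combination of element partials
(including intramolecular pairs) with five-Gaussian analytic form factors,
normalized by the squared mean form factor. `sq_to_gr()` applies a Lorch
window by default (resolution about `pi/Q_max`, i.e. ~0.14 A at the
default 23 1/A range); its inverse uses no window. The real-space
functions follow the convention that g and G oscillate around 1;
`apply_low_r_correction()` zeroes G below 1.2 A, which removes
long-wavelength reduction artefacts and, incidentally, the water O-H bond
peak; `gr_to_tr()` forms T(r) = 4 pi r rho G(r). The printed form of that
definition in the source literature ("4 pi r r G(r)") is dimensionally
inconsistent and is read as the standard rho-weighted definition here.

## Empirical-potential refinement

`refine_empirical_potential()` sine-transforms the misfit
S_model - S_target to real space, scales it by `feedback * kT`, adds it to
every heavy-pair empirical potential and clips at the amplitude cap. A
positive real-space misfit (model over-structured at r) becomes a
repulsive perturbation there. Zero misfit yields exactly zero update, and
a zero cap pins the potentials at zero. The scheme's fidelity is defined
behaviourally — a target generated from a known perturbed potential must
be recovered with strictly decreasing misfit over refinement cycles (see
`tests/testthat/test-refinement.R`) — not by matching any particular
implementation's internals. The functional basis is the tabulated grid
itself rather than a Poisson-function expansion; with the Lorch-damped
update and the cap this is the simplest stable variant.

## Composition calibration

Glycerol's intramolecular C1-C2 / C-O bond-distance peak near 1.5 A is the
only real-space feature below 1.8 A that survives the low-r correction,
and its prominence in a normalized pattern is directly proportional to
glycerol content. "Prominence" is the signal integrated above the linear
chord across a search window: the chord removes the flank of neighbouring
features, a convex flank integrates to zero, and — unlike a pointwise
maximum — the integral is linear in the signal, so zero-mean noise does
not bias it. Two statistics are available:

* `prominence` (default): absolute prominence of the bond peak. Nearly
  noise-free (the peak is intramolecular) but presumes the pattern is on a
  correct absolute S(Q) scale.
* `ratio`: prominence normalized by the first intermolecular O-O peak
  (2.65-3.15 A), self-normalizing against scale errors but substantially
  noisier at desk-scale box sizes, because the O-O peak carries quenched
  configuration-to-configuration variance. The two-bond C1-C3 window
  (2.2-2.65 A) is available as the cross-check estimator.

`estimate_composition()` iterates assumed composition -> density ->
reduction -> statistic -> calibration curve until self-consistent. In this
package's reduction the density cancels exactly in both statistics, so the
loop converges in at most two iterations; it is retained because the
workflow is defined for reductions where normalization does depend on the
assumed composition. Calibration curves are monotone Hyman-spline fits and
refuse non-monotone or duplicated standards; inversion clamps to the
calibrated range rather than extrapolating.

The chitin-like exoskeleton background is modelled as two Gaussians at 1.3
and 1.9 1/A. When the subtraction scale is unknown it is fitted by least
squares on high-passed signals (a running-mean detrend suppresses the
broad liquid features); because liquid and chitin features overlap in
width, the fit is biased low by a roughly constant offset and is clamped
at zero — it ranks contamination levels correctly but should be treated
as indicative. Supply the scale when it is known.

## Water clusters and hydrogen bonds

Two waters are connected when their oxygens lie within 3.5 A
(minimum-image); clusters are connected components (union-find), checked
against a brute-force BFS oracle in the tests. A hydrogen bond is any
intermolecular O-O contact within 3.2 A — a distance-only criterion,
appropriate to X-ray data that carry almost no hydrogen information.
`hbonds_per_glycerol()` counts OG-OG plus OG-OW contacts per glycerol per
snapshot (equivalent to integrating the partials to the cutoff, which the
tests assert to < 0.05) and reports the across-snapshot spread, which is
the reported uncertainty. The dehydration threshold is located by
simulating a composition series, taking the ensemble mean of the
per-snapshot maximum cluster size at each composition, and interpolating
(piecewise-linearly in composition) where it crosses 275 molecules.
Spatial density maps accumulate neighbour sites in a fixed molecular frame
(water: z along the dipole bisector, x in the molecular plane; glycerol: z
along C1-C3, x toward C2); any fixed convention suffices for lobe
detection, and the map integral equals the shell coordination number by
construction.

## Problem sizes and numerical choices

Desk-scale defaults, chosen so every result in the test-suite and the
acceptance script regenerates in minutes on one core:

* mixture and pure-glycerol boxes: 200-300 molecules, 1200 equilibration
  sweeps, 50 snapshots 3 sweeps apart;
* water-rich boxes: 200 molecules, 2400 equilibration sweeps (the
  tetrahedral network develops slowly under single-molecule moves; the
  O-O coordination number stabilises only after ~2000 sweeps);
* the cluster-threshold series: 48/56/63 mol% water with 700/1000/1000
  water molecules, 450 equilibration sweeps, interaction cutoff 8 A. The
  275-molecule criterion is meaningful only when the box holds well over
  that many waters, hence the ≥1000-water boxes near the crossing; the
  bonding-crossover analysis reuses the same ensembles;
* calibration fixtures: 100-molecule boxes; snapshots for calibration are
  taken 10 sweeps apart where decorrelation matters.

Move sizes auto-tune during equilibration toward 30-50% acceptance.
Packing, equilibration, production and noise all draw from streams derived
from one master seed; identical seeds give bit-identical results.

## What the synthetic data do and do not emulate

The generator reproduces the *structure* of the measurement problem:
standards at the experimental mole ratios, Gaussian noise at a relative
level typical of counting statistics, a chitin-like diffuse background
with its two broad peaks, and cooling series with densities from the
mixture model. It does not emulate 2D detector effects, Compton or
fluorescence backgrounds, attenuation, or real chitin crystallography, and
its "measurements" come from the same force field as the models fitted to
them. Passing closed-loop tests therefore demonstrates the pipeline's
internal consistency and statistical calibration — not force-field
accuracy against real larvae.

## Known limitations

* The hydrogen-bond count per glycerol converges to ~5.8-6.0 under the
  reference potentials with the 3.2 A distance criterion. That is
  consistent with the neutron-refinement literature (5.7 +/- 1.5) but
  higher than the 4.2 +/- 1.2 that X-ray-refined larval models report;
  reproducing the lower value appears to require refinement against
  measured larval patterns, which are not publicly deposited. The package
  reports what the reference model gives.
* For the same reason the OG-OG/OG-OW coordination crossover falls near
  ~60 mol% water in the reference model, above the ~48 mol% of
  data-refined models, while the 275-molecule cluster crossing lands near
  its reported ~56 mol%.
* Glycerol's skeleton is rigid in one conformer; backbone conformational
  disorder is not sampled.
* Single-molecule Monte Carlo equilibrates local structure but not
  long-wavelength composition fluctuations; microsegregation length scales
  beyond ~1 nm are outside desk-scale box sizes anyway.
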