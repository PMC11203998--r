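---
title: "Funnel metadynamics on toy ligand-binding systems: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Funnel metadynamics on toy ligand-binding systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelmetad)
```

## The problem and the model

Funnel metadynamics estimates protein-ligand binding free energies by
combining three ingredients: (i) well-tempered metadynamics, which deposits
repulsive Gaussians ("hills") along a small set of collective variables so
the ligand repeatedly crosses the binding barrier; (ii) a cone-plus-cylinder
("funnel") restraint that confines the unbound ligand to a thin cylinder of
solvent above the site, keeping the unbound volume small so binding and
unbinding stay reversible on simulation timescales; and (iii) multiple
concurrently running walkers that share one bias, reading each other's hills.

This package implements that protocol at desk scale. The all-atom force
field is replaced by closed-form toy potentials whose projected free
energies are known by quadrature, so every stage of the machinery --
integrator, hill bookkeeping, restraints, reweighting, frame extraction,
contact analysis -- can be validated against an independent oracle rather
than against another simulation.

### Collective variables

* **CV1** (nm): the mass-weighted centre of mass of the ligand's heavy
  beads, projected on the funnel axis measured from the anchor
  (`cv_funnel_projection()`). The funnel frame also supplies the radial
  distance used by the restraint.
* **CV2** (dimensionless): a contact-map distance (`cmdist()`) built from
  rational switching functions `s(r) = (1 - x^n)/(1 - x^m)`,
  `x = (r - d0)/r0`, with defaults `d0 = 0`, `r0 = 1` nm, `n = 6`,
  `m = 12`. Two variants are provided because the printed form of the
  deviation -- `sum(s_ref^2) - sum(s^2)`, a difference of sums of squares --
  is permutation-insensitive and can go negative, while the conventional
  contact-map distance is the sum of squared deviations. The difference-of-
  sums form is the default; the `squared_difference` variant is selectable
  in `contact_map_spec()` and the choice is recorded in every result. Their
  disagreement under permuted contacts is demonstrated in the test suite.

The removable singularity of the switching function at `r = d0 + r0` is
evaluated by a third-order series inside a guard band of `1e-4 r0`; outside
the band the rational form is used. The band is wider than the obvious
round-off scale because the rational form loses up to six digits to
cancellation well before `|x - 1|` reaches machine precision, which would
otherwise break the package's 1e-6 relative gradient accuracy contract.

### Funnel geometry and restraints

`funnel_geometry()` defaults to the binding-protocol constants: cone
half-angle 0.35 rad, cone-to-cylinder switch at `z_cc = 2.0` nm, cylinder
radius 1.0 Å, axial upper wall at 5.5 nm with `kappa = 35,100` kJ/mol/nm²
(read as kJ mol⁻¹ nm⁻²; the lateral wall reuses the same stiffness, which
is never printed separately and is configurable). The radius profile is the
classic linear cone plus cylinder,
`R(z) = (z_cc - z) tan(alpha) + R_cyl` for `z <= z_cc`, constant after; the
kink at `z_cc` is intentional and the walls are C¹ at onset. A lower axial
guard wall at `z = 0` closes the sampling domain behind the anchor --
without it a walker can drift behind the binding site into a region the
original all-atom system excludes sterically.

The steered (moving) restraint is a piecewise-linear schedule of harmonic
centre and stiffness on CV1. Two presets encode both readings of the
original pull schedule: `"hold"` reaches 4.5 nm and 1000 kJ/mol/nm² at 5 ns
and holds; `"release"` additionally relaxes the spring to zero at 10 ns.
The source protocol states both a 7 ns total time and a 10 ns release
point, which cannot both be taken literally, so the schedule type accepts
arbitrary keyframes and ships the two presets rather than guessing.

### Well-tempered deposition and the shared ledger

Hills have initial height 2.0 kJ/mol, width 0.1 nm on CV1 (0.5 on CV2),
deposition every 500 steps, bias factor `gamma = 20` at 310 K. The height
law is `h = h0 exp(-V(s)/(kB (gamma - 1) T))` with `V(s)` the bias already
accumulated at the deposition point. Two numerical paths exist for `V`:

* **direct summation** over the ledger, truncated at 6 sigma per hill --
  used for the height law itself so that replaying a ledger record-by-record
  reproduces every stored height to <= 1e-12 kJ/mol
  (`replay_hill_heights()`), the determinism contract of the shared-bias
  protocol;
* a **grid cache** holding the exact value, first and second derivative at
  nodes spaced sigma/8, interpolated with a two-point quintic Hermite rule
  -- used for forces during propagation. Quintic (rather than cubic)
  interpolation at sigma/8 keeps the cache within ~1e-7 kJ/mol of direct
  summation; a cubic rule at the same spacing would err at the 1e-3 level
  and violate the 1e-6 agreement contract.

Multiple walkers are serviced round-robin one deposition stride at a time
against one shared ledger, so each walker sees all hills deposited by the
others before its next segment -- eventual consistency within one stride,
mirroring shared-hills-file semantics. Each walker draws from its own
counter-based RNG stream keyed by (seed, walker id), so adding walkers
never perturbs existing streams. Ten walkers start at 1.6 nm and step 0.3
nm apart along the axis (`walker_start_positions()`); the sixth walker
(id 5, counting from zero) starts at 3.1 nm.

### Integration

`langevin_step()` and the compiled engine implement BAOAB splitting
(default; accurate configurational averages at comparatively large steps)
and overdamped Euler-Maruyama with `D = kT/(m gamma_f)`. Time steps are
chosen by the landscape, not inherited from the all-atom protocol: the
package warns when a single-step displacement exceeds half the potential's
smallest feature length. The toy runs below use 2 fs-equivalent steps of
0.002 ps (1D) and 0.001 ps (3D; the 35,100 kJ/mol/nm² walls set the
stiffest frequency). Unbiased sampling is validated against the Boltzmann
marginal (KS < 0.05), the analytic harmonic variance `kT/k`, free-diffusion
MSD, and a configurational-temperature estimator within 2% of target.

## Toy systems and what they do (and do not) emulate

* `build_double_well_1d(a, b)`: `U = a(x^2-1)^2 + bx`. With `a = 5`,
  `b = 1` kJ/mol at 310 K the basin free-energy difference is 1.7299 kJ/mol
  by quadrature -- the 1D validation target for the well-tempered estimator.
* `build_funnel_pocket_3d(D, sigma, k_floor)`: a Gaussian well of depth `D`
  at the funnel anchor plus a harmonic floor for `z < 0`. Defaults `D = 20`
  kJ/mol and `sigma = 0.3` nm give a binding well of roughly peptide scale
  relative to `kT = 2.58` kJ/mol, deep enough that unbiased escape is rare
  but shallow enough that a desk-scale biased run converges; the floor
  stiffness 1000 kJ/mol/nm² merely keeps the ligand on the `z >= 0` side.
  The potential vanishes along the axis, so the funnel-space free energy is
  flat over the solvated cylinder by construction -- the qualitative
  signature of a correct funnel setup.
* `synth_contact_trajectory()`: frames of a bead complex in which contacts
  (nearest heavy pair inside 5 Å) and water mediation (a water bead within
  4 / 3.3 / 2.6 Å of the nearest heavy atom of both partners) are placed
  geometrically according to recorded Bernoulli draws. The per-tier draws
  are nested (a single uniform against non-increasing tier probabilities),
  so tier monotonicity holds exactly, and every downstream frequency equals
  a stored count -- the analysis pipeline is tested against ground truth,
  not statistics.

What the toys do **not** emulate: all-atom integrin geometry, force-field
chemistry, explicit solvent structure, CV2-driven binding-mode multiplicity
(the 3D toy has one bound mode), or the microsecond timescales of the real
system. A green validation here certifies the machinery -- bias
bookkeeping, estimators, analyses -- not the biology; applying the package
to real trajectories replaces the toy stages but reuses everything
downstream of the COLVAR/HILLS files.

## Free-energy estimators

Two independent routes recover free energies from a run:

1. **From the bias**: `F(s) = -(gamma/(gamma-1)) V(s)`, min-normalised
   (`fes_from_bias()`). Basin differences are quoted as averages over the
   final 20% of the deposition history, which damps the residual bias
   oscillation.
2. **By reweighting** (`reweight_fes()`): frame weights
   `w ∝ exp(+V(s_frame)/kT)` against a *static* bias, then a fixed-width
   weighted histogram, `F = -kT log p`, min-normalised, unvisited bins
   flagged. Counts live at bin centres and no kernel smoothing is applied --
   smoothing would leak probability across the 10 kJ/mol extraction cutoff.
   With zero bias the estimator reduces bit-exactly to the empirical
   histogram, and it is invariant to adding a constant to the bias; both
   identities are asserted in the tests.

A single end-of-run bias snapshot carries the late-time well-tempered
fluctuation, which does not decay with run length; on the 3D system that
left a seed-dependent RMSE of up to ~1.9 kJ/mol against quadrature. The
package therefore reweights frames from the trailing 30% of the run against
the bias **time-averaged over that same window** (`time_averaged_ledger()`,
a uniform average over ledger prefixes, implemented as fractional hill
weights). This remains a static, deterministic bias -- time-dependent
estimators stay out of scope -- and brings the RMSE to 0.2-0.7 kJ/mol under
the standard conditions below.

Bound frames are extracted by the conjunction of a CV-space box and the
free-energy cutoff (`extract_bound_frames()`), because the extraction rule
combines both "close to the minimum in CV space" and "within 10 kJ/mol of
the lowest point"; either filter can be disabled (cutoff `Inf`, or a
full-grid box). Exact ties in `locate_minimum()` resolve to the
lexicographically smallest grid index. The cutoff applies to whichever
surface the caller supplies -- the CV-space FES or the funnel-space one --
since the original account does not pin that down; the drivers use the
funnel-axis surface.

## Standard study conditions (problem sizes)

The validation runs use, as the package's standard toy-scale conditions:

* 1D double well: overdamped, dt 0.002 ps, 5e6 steps, hills every 500
  steps, three seeds; ΔF averaged over the final 20% of hills. Observed
  |error| vs quadrature ~0.05-0.12 kJ/mol (tolerance 0.5).
* Multi-walker consistency: 4 walkers x 1.25e6 steps vs 1 walker x 5e6
  steps, same seed base; observed ΔF difference ~0.08 kJ/mol (tolerance 1).
* 3D funnel pocket: 10 walkers x 6e6 BAOAB steps, dt 0.001 ps, friction
  5 ps⁻¹; reweighting window as above. Observed RMSE vs soft-wall
  quadrature over visited z in [0.2, 4.5] nm: 0.2-0.7 kJ/mol (tolerance 1);
  plateau spread over z in [3, 5] nm: ~0.5 kJ/mol (tolerance 1).
* Reweighting cross-check: harmonic well under a known static Gaussian
  bias, 1e5 decorrelated samples; weighted-ECDF KS distance vs the analytic
  Boltzmann CDF ~0.006 (tolerance 0.05).

The quadrature oracle (`reference_fes()`) integrates each z-slice with an
adaptive rule at relative tolerance 1e-8, reducing radially symmetric
potentials to a 1D radial integral exactly and falling back to an adaptive
2D rule otherwise. Its `walls = "soft"` option includes the harmonic
lateral-wall energy in the slice integral; the hard `r <= R(z)` boundary is
the documented default, but the soft oracle is the faithful reference for
simulations, whose walls are soft -- at `kappa = 35,100` the difference is
~0.5 kJ/mol in the narrow cylinder and would otherwise be misread as
estimator error.

## Structural analyses

Contacts are residue-level: a group is in contact when ANY heavy ligand
bead is within 5 Å (inclusive) of ANY heavy group bead; hydrogens and
waters never count. Water mediation measures the water-oxygen bead against
the **nearest heavy atom** of each partner (the original account does not
say which atom; nearest-heavy is the choice here, flagged as such), and a
frame counts at a tier only if one water satisfies both partners
simultaneously -- which makes the 4 / 3.3 / 2.6 Å fractions monotone by
construction, an invariant asserted on every report.

`kabsch_align()` is a proper-rotation least-squares superposition
(reflections excluded, collinear selections rejected);
`reference_distance()` reports atom or group-COM distances after an
explicit alignment selection, in Å. Helicity uses a backbone-dihedral
window -- phi in [-100, -30], psi in [-77, -17] degrees, configurable --
rather than a full secondary-structure assignment, whose exact criterion
the source defers to supplementary material; the window is documented so
results are reproducible even though absolute helicity percentages are
criterion-dependent.

## Interfaces and determinism

COLVAR and HILLS files are whitespace tables with a `#! FIELDS` header,
written at 17 significant digits so round trips are bit-exact; unknown
columns are preserved, malformed lines are rejected with their line number,
and non-monotone per-walker hill times warn. Trajectories are XYZ (Å on
disk, nm in memory), complexes minimal PDB, frame-index files 0-based (R
functions return 1-based indices). Every pipeline stage writes a manifest
with the configuration hash, seed and package version; re-running a stage
from its manifest reproduces its artifacts bit-exact apart from wall-clock
metadata.

## Known limitations

* The compiled engine biases CV1 only; CV2-biased dynamics is available
  through the pure-R reference walker (`run_walker()` with a `cmdist` CV),
  which is validated by gradient and counting tests but is not built for
  multi-million-step runs.
* Final-window reweighting assumes the bias is quasi-static over the
  trailing window; systems with much slower orthogonal relaxation would
  need time-dependent estimators, which are deliberately out of scope.
* The funnel-space 2D reweighting (funnel-plane coordinates) shares all
  code paths with the 1D case through `reweight_fes()` but the acceptance
  validation is against the 1D axial marginal, where the quadrature oracle
  is exact.
* Well-tempered convergence diagnostics are limited to ΔF-vs-time traces;
  no block-error analysis is provided.
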