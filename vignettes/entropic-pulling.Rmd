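---
title: "Entropic pulling by Hsp70 and chaperone-assisted import: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropic pulling by Hsp70 and chaperone-assisted import: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(entropull)
```

## The physical problem

Most mitochondrial proteins are synthesized in the cytosol and imported
post-translationally through the TOM/TIM pore. On the matrix side, Hsp70
chaperones bind the emerging chain at short recognition sites. Because a
bound Hsp70 is bulky, it cannot follow the substrate back toward the
membrane: its excluded volume removes part of the substrate's conformational
space near the wall. The shorter the imported segment, the larger the loss,
so chaperone binding creates a free-energy gradient along the import
coordinate — an effective *entropic pulling* force — on top of the pure
blocking ("Brownian ratchet") effect.

`entropull` quantifies this in two stages:

1. **Pulling profile.** A coarse-grained model (one bead per residue,
   centred on the C-alpha position) of an `n`-residue substrate whose
   residue `n` is tethered at the origin of a flat wall at `z = 0`, with a
   two-domain chaperone clamped onto residues 1–7. Equilibrium sampling with
   the chaperone *transparent* to the wall estimates the fraction `f(n)` of
   configurations in which no chaperone bead crosses the wall. That fraction
   is an estimator of the partition-function ratio of the chaperone-bound
   system to the unconstrained one, so the free-energy penalty is
   `dFc(n) = -ln f(n)` (in units of `kBT`). Its negative slope along `n`,
   converted with `kBT` at 300 K and 3.8 Å of contour per residue
   (≈ 10.9 pN per `kBT`/residue), is the pulling force.

2. **Import kinetics.** A one-dimensional Metropolis Monte Carlo walk of the
   number `n_in` of imported residues on the landscape
   `F_import(n_in) = F_u(n_in) + dFc(n_in - n_B)`, where
   `F_u(n_in) = F_max / (1 + exp[5 - 10 (n_in - 10)/delta_n])` is a
   sigmoidal unfolding free energy and `n_B` is the position of the bound
   binding site nearest the pore. First-passage times to `n_in = L` are
   reported in attempted MC steps.

This separation is justified by timescales: substrate reconfiguration
(~100 ns) is vastly faster than import (minutes), and pore-proximal ATP
hydrolysis makes chaperone binding effectively instantaneous and
irreversible on the import timescale.

## The coarse-grained model

* **Excluded volume.** All non-bonded bead pairs interact through a purely
  repulsive Lennard-Jones potential in the WCA form — truncated at its
  minimum `2^(1/6) sigma` and shifted to zero — with `sigma = 3.8` Å and
  `epsilon = 3 kBT`. The WCA dialect makes "repulsive" literal and the
  cutoff parameter-free.
* **Bonds.** Consecutive beads (substrate chain, interdomain linker, and the
  linker's two anchor bonds into the domains) are harmonic with rest length
  3.8 Å and stiffness `k = 100 kBT/Å^2`. The stiffness is not a measured
  quantity; it is chosen stiff enough that bond fluctuations (~0.1 Å) do not
  soften the excluded-volume geometry, yet remain easily sampleable. It is
  exposed in the configuration.
* **Local potentials.** The default substrate model is a freely-jointed
  excluded-volume chain (bending and torsion terms zero). A configurable
  cosine stand-in, `k_b (1 + cos theta)` per bond angle and
  `k_t (1 + cos phi)` per dihedral, can be switched on for sensitivity
  checks; it is a declared stand-in for sequence-specific local potentials,
  not a calibrated force field. Glycine/proline-free substrates are assumed
  throughout, and with the default (zeroed) coefficients the chain's Kuhn
  length is the bond length itself.
* **Chaperone.** The nucleotide-binding domain (NBD) and the
  substrate-binding domain (SBD) are rigid bead bodies; the 9-residue
  interdomain linker is flexible. Geometries come either from a CA-only PDB
  read (`load_chaperone_ca()`, default intervals NBD 4–387, SBD 397–603,
  linker 388–396) or from `build_synthetic_chaperone()`: two lattice-filled
  spheres of radius 25 Å (NBD) and 20 Å (SBD) — declared approximations of
  the two DnaK domains — 4 Å apart, with an overall extent of ~92 Å.
* **Clamp.** The bound heptapeptide is represented by seven clamp sites in
  an extended conformation (3.8 Å spacing) laid tangentially on the SBD
  surface patch that faces away from the NBD, 2 Å above it. Substrate
  residues 1–7 are snapped onto these sites and move rigidly with the SBD
  (a rigid clamp, not a harmonic restraint — the restraint stiffness is not
  a measured quantity, and a rigid clamp keeps the ensemble unambiguous).
  The same placement rule is used for loaded structures, because the
  peptide-bound SBD arrangement is known only qualitatively.
* **Wall.** The membrane is a zero-thickness plane at `z = 0` acting on
  substrate bead centres only, as a hard constraint (proposals below it are
  rejected and counted). A chaperone or linker bead centre strictly below
  `z = 0` flags the configuration as overlapping; the boundary `z = 0`
  itself does not overlap. Residue `n` is pinned exactly at the origin
  rather than harmonically restrained, again to avoid an arbitrary
  stiffness.

## Sampling

The default sampler is Metropolis Monte Carlo with six move classes:
Gaussian single-bead displacements and crankshaft rotations of the free
substrate beads, *pivot* moves that rotate the whole matrix-side head
(substrate beads up to a random chain position plus the entire chaperone)
about that position, rotations of the whole chaperone assembly (SBD, clamped
heptapeptide, NBD and linker as one piece) about the pore-side end of the
clamp, rigid NBD moves about its linker anchor, and linker bead
displacements. The rotation centres are chosen so that pure rotations
stretch no bond. All proposals are symmetric, so `min(1, exp(-dE))`
acceptance gives detailed balance with respect to `exp(-E/kBT)` over
wall-legal substrate configurations, with the chaperone free to cross the
wall.

Two of these classes exist specifically to keep the slow collective
coordinates mixing: pivots use the full angle range because the global
orientation of the ~90 Å complex relative to the wall otherwise decorrelates
over ~10^4 sweeps, and the assembly rotation is the only efficient move for
the orientation of the chaperone relative to the chain direction at the
clamp (rotating the SBD alone tears its linker anchor bond and is almost
never accepted). Move sizes for the bead and rigid-body moves default to
acceptance rates of roughly 20–70%.

Each recorded frame contributes one 0/1 indicator (non-overlap). The
fraction estimate is the indicator mean; its statistical error comes from
block averaging with block-size doubling. A plateau is declared at the
smallest block size where the error estimate changes by less than 5% across
two *consecutive* doublings — a single quiet doubling is not accepted,
because the block-error curve of this system rises slowly over several
decades and a one-step rule fires far too early — and the reported error is
never smaller than the estimate at the largest block size that still has 32
blocks. If no plateau is reached before fewer than eight blocks remain, the
largest-block error is reported and flagged. Because even guarded block
analysis can miss correlation times comparable to the trace length,
`sample_profile()` runs two independent chains per grid point and takes the
larger of the combined block error and the between-replicate standard error.

An overdamped Langevin (Brownian dynamics) mode propagates the same energy
function with free-draining mobilities (`D = kBT * damping / m` per bead,
with the average residue mass; rigid units get net-force/torque updates with
`1/N` and `1/sum(r^2)` scalings). It exists purely as a cross-check of the
Metropolis ensemble: the Euler integrator needs a ~2 fs timestep to stay
stable against the stiff bond and WCA curvature, it has no force expressions
for the optional cosine potentials, and the clamped residues' wall
constraint is enforced by rejecting rigid updates that would cross it.

The equilibrium estimate `f(n) ~ Z70(n)/Z(n)` is operational: the sampled
ensemble keeps chaperone–substrate excluded volume on, and the denominator
is the same ensemble with the wall constraint on the chaperone ignored.
Whether the reference partition function should instead be fully
chaperone-free is ambiguous in the underlying model description; the
operational definition is what the overlap-counting estimator measures, and
it is the one implemented.

## The pulling profile

`build_profile()` assembles `dFc(n) = -ln f(n)` for `n = 8..26` (an exposed
binding site needs eight imported residues) with delta-method errors
`err(dFc) = err(f)/f`. `profile_value()` interpolates linearly inside the
grid; beyond `n = 26` the profile continues at its last value (zero residual
force — the force has decayed strongly by then and binding sites recur every
~35 residues, so larger arguments are routine in stage 2); below `n = 8`,
with a chaperone bound, the profile acts as a hard retrotranslocation wall.
`pulling_force()` uses central finite differences (one-sided at the edges)
and converts to pN with the conversion constant evaluated from the Boltzmann
constant at run time. The profile stores absolute `-ln f` values, not values
shifted to zero at `n = 26`.

## Import simulation

The walker starts at `n_in = 0` with a reflecting origin. Every attempted
step counts one MC timestep; no acceptance-rate rescaling is applied by
default because observed acceptance exceeds 95% in all standard runs (a
rescaling option exists and is checked in the tests to change acceleration
ratios by less than their errors). A site at `n_B` binds its chaperone as
soon as `n_in >= n_B + 8` — the first argument at which the pulling profile
is defined — instantly and irreversibly; only the bound site nearest the
pore contributes, both as pulling term and as hard wall. The ratchet-only
mode keeps the wall at the same threshold but drops the pulling term, so
assisted vs ratchet-only is an apples-to-apples comparison.

Ensembles draw 25 independent binding-site maps and run 10 realisations
each. Site maps place consecutive gaps i.i.d. from `1 + geometric(1/35)`
(mean exactly 35 residues, the experimentally observed site frequency; only
the mean is constrained by data, and the memoryless law adds no further
assumptions). The first position is drawn as one more gap from the terminus,
so a terminal site is possible but never forced. The independent statistical
unit is the site distribution: ensemble standard errors are computed over
per-distribution means. Runs that hit the step cap (default 10^9 attempted
steps) are excluded from means with a loud warning and a count; barrier
heights whose unassisted times exceed the cap are instead obtained from the
exponential fit of `ln tau0` vs `F_max` over the directly simulated range
(`fit_exponential_extrapolation()`).

## What the synthetic generator does and does not emulate

The synthetic chaperone reproduces the two-domain architecture, realistic
Hsp70 domain dimensions, a flexible linker, and a surface clamp — the
features the entropic-pulling mechanism depends on (bulk near a wall,
clamp-to-bulk geometry). It does not reproduce the aspherical domain shapes,
the peptide-groove orientation of the substrate-bound SBD, or any
sequence-specific flexibility;
quantitative profile values therefore carry a geometry-stand-in uncertainty
of order tens of percent, which is why the initial-force check is run with a
±35% band. Passing tests show the *mechanism* and the pipeline's
statistics are right; absolute profile values for the real DnaK structure
require feeding the experimental coordinates to `load_chaperone_ca()`.

## Numerical choices and problem sizes

* Default profile runs use 4x10^5 sweeps per `n` (~10^7 attempted moves per
  grid point, one indicator frame per sweep, 10% equilibration), split over
  two independent chains; ensembles use the full 25 x 10 design. These sizes give initial-force errors well
  below the tolerance band and acceleration-ratio errors of a few percent.
* Rigid units are stored as local-frame coordinates plus an orthonormal
  pose, so intra-domain distances are exact by construction; poses are
  re-orthonormalised every 512 compositions.
* The compiled sampler uses its own deterministic RNG (splitmix-seeded
  xoshiro256+ with explicit bit-level uniform and Box-Muller normal draws),
  so traces are reproducible from the seed across platforms and independent
  of R's RNG state. All stage seeds derive from one master seed.
* Coincident beads (r = 0) report infinite energy; fractions of exactly
  zero refuse to produce a free energy (only a lower bound exists) and the
  profile builder says so.
* The lattice toy (self-avoiding chain on the 2D square lattice with a rigid
  obstacle and a wall line) is exactly enumerable for chains of up to 12
  beads and validates the overlap-fraction estimator end to end; first-
  passage times are validated against the absorbing-Markov-chain linear
  solve `tau = (I - Q)^{-1} 1`.

## Known limitations

* The chaperone geometry is a stand-in; see above.
* Attractive interactions, hydrophobicity, electrostatics and nucleotide-
  state conformational changes are out of scope; the pore is a structureless
  hole in a flat wall.
* Multiple simultaneously contributing chaperones are not modelled (nearest
  bound site only), and chaperone exchange kinetics are collapsed into
  instant irreversible binding.
* MC timesteps are not converted to wall-clock time; only ratios of import
  times are meaningful.
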