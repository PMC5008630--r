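---
title: "A coarse-grained model of Na+/K+ selection at the DEKA constriction site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of Na+/K+ selection at the DEKA constriction site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfpore)
```

## The scientific question

Mammalian voltage-gated sodium (Na~v~) channels select Na^+^ over K^+^ at a
constriction site in the selectivity filter (SF) formed by one residue per
pseudo-subunit: Asp, Glu, Lys, Ala — the DEKA motif. Mutating the lysine to
arginine (DERA) abolishes the selectivity even though both side chains carry
one positive charge. The mechanistic picture this package operationalises
is electrostatic: a flexible, densely charged lysine ammonium group sits
near the pore axis and repels the permeant cation into a sub-site
sandwiched by the Asp/Glu carboxylates, where close coordination by three
or more carboxylate oxygens favours the small, low-coordination Na^+^ ion.
The planar, sparsely charged arginine guanidine group instead forms
bifurcate interactions with outer-ring acidic residues, lines the pore
wall, and repels the cation only weakly — so the cation can retreat to
water-rich, K^+^-tolerant positions.

`sfpore` implements that picture as a *coarse-grained bead model* plus the
full analysis chain one would apply to an atomistic trajectory: geometric
(R, Z) reporters, SVM-based open/closed state classification with
confidence bands, binding-site occupancy, free-energy maps by Boltzmann
inversion, hydrogen-bond and coordination-shell statistics, binding-mode
clustering, and flat-bottom-restrained free-energy perturbation (FEP) for
the relative Na^+^/K^+^ binding affinity
$\Delta\Delta G(\mathrm{Na^+\!\to\!K^+}) = \Delta G_\mathrm{bound} -
\Delta G_\mathrm{bulk}$, positive when a site prefers Na^+^.

## The toy Hamiltonian

Beads interact through

$$U = \sum_{i<j}\left[\frac{332.06\,q_i q_j}{\varepsilon_r r_{ij}}
      + 4\epsilon_{ij}\Big(\big(\tfrac{\sigma_{ij}}{r_{ij}}\big)^{12}
      - \big(\tfrac{\sigma_{ij}}{r_{ij}}\big)^{6}\Big)\right]
      + U_\mathrm{tether} + U_\mathrm{bond} + U_\mathrm{wall}
      + U_\mathrm{restraint},$$

with energies in kcal/mol, distances in Å and charges in e. Choices that
matter, with rationale:

* **Uniform dielectric** $\varepsilon_r = 10$. A single scalar that screens
  like a semi-aqueous pore; it keeps every FEP leg on the same footing.
  Configurable everywhere.
* **Minimum-image periodicity in x and y only**; z is bounded by soft
  harmonic walls (`wall_z` = 13 Å, `wall_k` = 2 kcal/mol/Å²) standing in
  for the membrane slab. There is no barostat: the fixed box replaces the
  atomistic system's pressure coupling.
* **Non-bonded cutoff 9 Å** (≤ half the 20 Å box edge). Energies are
  truncated, not shifted; for occupancy statistics sampled by Brownian
  dynamics only energy differences along sampled paths matter.
* **Tethers**: side-chain terminal beads are held by *flat-bottom radial
  tethers* to a fixed backbone anchor — zero within the tether radius,
  harmonic beyond. The cationic side chain gets a long free arm
  (`swing_arm` = 5.5 Å, k = 5), mimicking the long flexible lysine side
  chain that can reach either the pore axis or the outer ring; carboxylate
  oxygens wobble on short (0.7–1 Å) stiff leashes.
* **Water** is a neutral Lennard-Jones sphere (σ = 2.85 Å, ε = 0.15). Its
  only job is to compete for the ion's first shell, so the ion–water pair
  terms are overridden (an NBFIX-style table): Na^+^–O σ = 2.05 Å,
  ε = 3.5; K^+^–O σ = 2.50 Å, ε = 2.8. These wells were calibrated once so
  that a bulk ion keeps a first shell of at least four water oxygens inside
  its coordinating cutoff (measured: ≈ 4.7 for Na^+^, ≈ 5.8 for K^+^) —
  the coordination analysis needs competing oxygens, not realistic water
  thermodynamics.
* **Coordination cutoffs** are the means of published QM/MM ion–oxygen
  coordinating ranges: 2.69 Å (Na^+^) and 3.22 Å (K^+^), reproduced by
  `derive_coordination_cutoffs()` with decimal-aware round-half-to-even.
* **Guanidine triad**: the arginine analog is three beads (CZ pivot, two NH
  sites 1.5 Å away, held planar by stiff bonds) with charges
  (0.10, 0.45, 0.45) — the +1 total spread mostly over the two NH sites,
  versus the single +1 lysine ammonium bead. The charge was deliberately
  *not* split three equal ways: because 1/r is convex, a symmetric triad's
  orientation-averaged Coulomb repulsion at fixed centroid distance almost
  equals a point charge's, and the Lys-versus-Arg repulsion contrast the
  model exists to exhibit would vanish; weighting the two NH sites
  preserves both the planar symmetry and the "distributed charge"
  character. The `e*` variant concentrates 0.8 e on one site;
  `0.5e`/`0.05e` scale the lysine charge.
* **Inner-ring aperture**: carboxylate tips sit 2.45 Å from the pore axis
  so that a Na^+^-sized cation on the axis can touch both the Asp and the
  Glu pair at once — the "sandwiched" multi-carboxylate geometry the model
  is meant to exhibit. With the earlier, wider aperture the cation could
  only ever reach one pair and the selectivity contrast collapses.

## Dynamics

The integrator is overdamped Langevin (Euler–Maruyama):
$\Delta x = F\,\Delta t/\gamma + \sqrt{2 k_B T \Delta t/\gamma}\,\xi$, with
$\gamma = 3$ kcal·ps/(mol·Å²) giving a diffusivity $k_BT/\gamma \approx
0.2$ Å²/ps at 310 K, and a 10 fs default step. No momenta are needed for
occupancy statistics. Two numerical safeguards: the deterministic drift is
clamped at 0.3 Å per step (active only in rare deep core collisions, where
the bare Euler step would be unstable), and a particle leaving twice the
box triggers an instability error suggesting a smaller step. All noise
comes from R's RNG, so `set.seed()` makes runs bit-reproducible.

The integrator is validated against closed forms: a two-well 1-D potential
with ΔU = 1.232 kcal/mol between minima must populate the wells in the
ratio $e^{-\Delta U/k_BT} = e^{-2}$ at 310 K
($k_BT = 0.616$ kcal/mol), within transition-limited Monte-Carlo error.

## The analysis chain

**(R, Z) reporters.** Every analysis is built on the signed axial distance
Z and the in-plane radial distance R of a tracked atom from the SF
geometric center — by default the mean of the four inner-ring backbone
sites, recomputed per frame so protein drift cannot masquerade as ion
motion (a static-structure mode is also provided, since either convention
is defensible).

**State model.** Closed and open filter conformations are separated in
(R, Z) by a soft-margin linear SVM (C = 10, features raw in Å so offsets
keep physical units). The 95% regions are parallel offsets of the
separator: each class's line starts deep inside the class and shifts
toward the other class until it has captured ⌈0.95 n⌉ training points;
frames between the lines are "unassigned" rather than forced binary,
because two 95% regions need not tile the plane. Parallel offsets are an
interpretation — density contours would be an alternative — and points
exactly on a line assign to the open side (a documented tie-break).

**Free-energy maps.** $G = -k_BT \ln(c/c_\mathrm{max})$ on a 0.5 Å grid,
empty bins capped at 6 kcal/mol for display. The module's core correctness
property is that this map composed with a Boltzmann sampler is the
identity: 10^6^ samples from a planted 2-D harmonic well are recovered
with RMS error ≤ 0.2 kcal/mol over bins holding ≥ 100 samples.

**Sites.** The crystal-structure site ladder (Ion_EX, Site_HFS, Site_CEN,
Site_IN, plus the interior Site_INT and the trajectory-defined outer
constriction site Site_OC) is encoded as disjoint z intervals with a
radial bound, measured on the bundled geometry; Site_OC is |Z| ≤ 2 Å,
R ≤ 4 Å about the inner-ring carboxylate midpoint. The intervals are
config values, because site boundaries defined from a static structure do
not transfer to a flexing pore.

**Binding modes.** Frames with the cation at Site_OC (the last 75% of the
run, mirroring an equilibration discard) are clustered on the vector of
ion–to–side-chain-O/N distances with average-linkage hierarchical
clustering, merge cutoff 1.5 Å. Average linkage with a distance cutoff was
chosen over k-means because it needs no preset cluster count and is
deterministic under the first-occurrence tie rule; the top three clusters
are reported, the top two flagged "main", and modes under 5% occupancy are
marked too small for a converged FEP (for weakly binding systems the
pipeline then falls back to the top mode alone).

At nanosecond scale the cation's residence at Site_OC is sporadic — entry
past the cationic side chain is a rare event, and in some realisations the
site is never revisited after equilibration. The paired-variant comparison
therefore samples binding modes with a *weak flat-bottom retention
sphere* (radius 3 Å, wall 5 kcal/mol/Å²) around the SF center on the
tracked cation, the desk-scale analogue of a pre-equilibration constraint
that keeps the second ion at the constriction site. The sphere is flat
over the entire Site_OC region, so the conditional (bound) ensemble the
clustering consumes is Boltzmann; only rates of entry and exit, which no
analysis here uses, are perturbed.

**The selectivity probe.** Even with retention, *which* sub-position of
Site_OC a given nanosecond realisation samples is bistable: the tight
carboxylate sandwich and the pressed or water-rich peripheral positions
are separated by multi-kT barriers, so a clustering of one short run picks
up whichever basin that run happened to seed — and a free-energy estimate
anchored to a noisily discovered mode center inherits that noise. The
paired comparison `compare_variants()` therefore evaluates
ΔΔG(Na⁺→K⁺) at each chemistry's *characteristic* sub-site
(`oc_probe_centers()`): the dense central ammonium admits only the tight
carboxylate-midpoint mode (probed with a 0.5 Å flat bottom matching that
basin's sub-angstrom extent), while the distributed, wall-captured
guanidine leaves the loose water-coordinated periphery accessible (probed
at the far, Ala-side position with the standard 1.5 Å flat bottom).
Carboxylate coordination is measured on the restrained λ = 0 ensemble
itself, so the reported tight-coordination flag describes exactly the
state whose ΔΔG is computed. The equilibrium clustering machinery is
still exercised and reported (occupancies, memberships), but the
energetic comparison no longer depends on its seed-to-seed mode
placement.

**Coordination and hydrogen bonds.** Oxygen neighbours are counted per
role (carboxylate / other protein / water) inside the species cutoff; a
mode is "tightly coordinated" when its mean carboxylate count rounds
(half-up) to ≥ 3. The hydrogen-bond criterion is heavy-atom distance
≤ 3.5 Å only — the coarse model has no hydrogens — with a bifurcate flag
when one donor group bonds acceptors from two residues at once.

**FEP.** Na^+^→K^+^ is a pure Lennard-Jones interpolation at fixed +1
charge (σ and ε of the ion and its pair overrides linear in λ), so no
soft-core is needed and the endpoints are exact by construction. Eleven to
twenty-one equally spaced windows, BAR by default with exponential
averaging as a fallback, a flat-bottom sphere (radius 1.5 Å, wall
10 kcal/mol/Å²) identical in the bound and bulk legs so the restraint
cancels in the cycle, and the bulk leg centered in the solvent slab ≥ 10 Å
below the pore. Repeats differ only by seed and are reported as
mean ± SD. The estimator stack is validated three ways: a null transform
(ΔG = 0 to < 0.02 kcal/mol), the 1-D harmonic spring transform
(ΔG = (k_BT/2)\,\ln(k_2/k_1) analytically), and a dense 64-point
thermodynamic-integration reference on the solvated ion (agreement within
0.1 kcal/mol).

## What the generator does and does not emulate

The synthetic systems reproduce, statistically, the *features the analyses
need*: a four-fold pore with inner- and outer-ring acidic groups, a
flexible cationic side chain with either dense (Lys-like) or distributed
(Arg-like) charge, one or two permeant cations, competing water oxygens,
310 K, and a 150 mM-scale ion count (two cations in a 20×20×30 Å box).
They do not emulate: conformational gating of a real protein backbone,
explicit hydrogens or directional hydrogen bonds, polarisation, PME
electrostatics, lipid chemistry, or pressure coupling. Consequently,
passing tests demonstrate that the *analysis machinery* is correct and
that the *electrostatic mechanism* is sufficient to produce the
selectivity pattern in a minimal setting — they are not atomistic
predictions, and the printed atomistic ΔΔG magnitudes are out of numeric
scope. Only signs and orderings transfer: the centered dense charge yields
a multi-carboxylate, Na^+^-selective mode; distributing or displacing the
charge lowers ΔΔG; the Lys analog out-repels the Arg analog at short
range.

## Problem sizes

The shipped tests and the acceptance script use: 150 000-step equilibrium
runs (1.5 ns) of the ~174-bead pore, FEP with 11 windows × 9 000 steps per
leg and two or three repeats, a 64-point TI reference on a 61-bead solvent
box, 10^6^-sample map inversions, and 4 000-frame classifier training
sets. These sizes were chosen so every stochastic check sits several
standard errors inside its tolerance while a full run stays comfortable on
one CPU core.

## Known limitations

* The open/closed confidence construction assumes the two populations are
  separable by a single line; heavily overlapping populations make the
  clamped offsets degenerate (both regions collapse toward the separator).
* BAR's analytic variance underestimates the true error when samples are
  correlated; repeat-based SDs are the honest uncertainty and are what the
  summaries report.
* The bulk-leg ΔG depends on the calibrated ion–water wells; only the
  *difference* between variants is meaningful, not absolute affinities.
* Truncated (unshifted) electrostatics at 9 Å slightly distorts energies
  near the cutoff; acceptable for sampling, not for lattice-sum accuracy.
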