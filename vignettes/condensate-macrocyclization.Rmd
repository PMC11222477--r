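---
title: "Reactive coarse-grained modelling of macrocyclization in peptide condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive coarse-grained modelling of macrocyclization in peptide condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crxn)
```

## The scientific problem

Biomolecular condensates formed by liquid-liquid phase separation (LLPS)
concentrate small molecules and can thereby redirect chemical reactions.
A well-studied experimental system is the oxidative macrocyclization of
benzene-1,3-dithiol: in bulk water the dithiol oligomerizes through
disulfide (S-S) bonds into small rings, mostly trimers; inside a peptide
coacervate the local reactant concentration is an order of magnitude
higher, and the product distribution shifts toward larger macrocycles.
The condensate-forming species is a short synthetic sticker-spacer
peptide (a leucine-phenylalanine dipeptide on each side of a disulfide
spacer) whose phase behaviour is pH-switchable: with protonated,
positively charged termini the peptide stays dissolved; deprotonated
(neutral) termini allow the stickers to drive LLPS.

`crxn` re-creates this physics at desk scale: a reduced reactive
coarse-grained (CG) model with a Langevin-dynamics engine, plus the full
analysis pipeline -- ring-size census, consumption kinetics, slab density
profiles and partition coefficients, incoherent intermediate scattering
functions (ISFs) with AIC model selection, umbrella sampling with WHAM,
and the arithmetic of the experimental partition assay. The package is
not a quantitative stand-in for a chemically detailed force field: its
purpose is to reproduce the *mechanistic* phenomenology (pH-switched
LLPS, preferential partitioning, concentration-driven ring-size shift,
reversibility controlled by an effective well depth) with components
small enough to be tested against closed-form oracles.

## The reduced model

Units are GROMACS-style reduced-physical units -- nm, ps, amu, kJ/mol --
so that the literature parameters carry over verbatim: kT = 2.494 kJ/mol
at 300 K, a 1.1 nm nonbonded cutoff, and 10-20 fs timesteps.

**Peptide.** A 6-bead linear chain L-F-S-S-F-L (bonds 0.38 nm, soft
backbone angles). The four sticker beads (L, F) carry the attractive
Lennard-Jones wells; the spacer beads are weakly interacting. The pH
toggle swaps the two terminal beads between a neutral sticky species
(high pH) and a charged, hydrophilic species carrying +1 (neutral pH),
mirroring the P6/Q5 terminal-bead switch used in Martini-style models
of such peptides.
Electrostatics are a Yukawa screened Coulomb (Debye length 0.8 nm by
default) so the charged termini both lose sticker cohesion and gain
mutual repulsion.

**Reactive monomer.** A benzene core bead with two thiol site beads at
0.25 nm and a 120 degree thiol-core-thiol angle (meta substitution).
Each thiol site can hold at most one intermolecular disulfide bond; the
two sites of one monomer can never bond each other. On reaction a
harmonic thiol-thiol bond (r0 = 0.30 nm) and two core-thiol-thiol angle
terms (150 degrees) are added.

**Reaction scheme.** The tabulated reactive potential of the
chemically detailed model is replaced by a stochastic bonding scheme.
Every `attempt_interval` steps, free thiol pairs within the capture
radius react with probability `1 - exp(-k_on * dt)`, processed nearest
first with deterministic tie-breaking; bonded pairs break with
probability `1 - exp(-k0_off * exp(-E/kT) * dt)`. The effective well
depth E enters only through this Arrhenius factor: at the default
E = 60 kJ/mol the per-attempt factor is ~3.5e-11 and bonds never break
on simulation time scales, while at E = 20 kJ/mol it is ~3.3e-4 and
disulfide exchange is observable -- reproducing the irreversible versus
reversible phenomenology without tabulated-potential machinery.

**Integrator.** BAOAB Langevin at fixed box (NVT; all analyses here are
density-ratio based, so no barostat is used). With zero friction the
scheme reduces to velocity Verlet; the suite checks a relative energy
drift below 1e-3 over 1e4 steps in that limit. All randomness flows
through R's RNG: one master seed makes placement, dynamics and the
reaction sequence bit-reproducible.

## Parameterization choices

The pair well depths were calibrated once, before any production
analysis was frozen, to meet the qualitative contracts the model must
express, and are recorded as the `species_table()` defaults:

* sticker-sticker epsilon 2.6 kJ/mol (~1 kT): the high-pH slab is a
  stable condensed liquid, while the charged-termini variant dissolves
  within a few nanoseconds. Stronger stickers (>= 3 kJ/mol) produce a
  glassy slab that tracer monomers cannot enter.
* core-sticker epsilon 3.0 kJ/mol: benzene-dithiol monomers
  preferentially partition into the peptide-rich phase (K well above 1,
  transfer free energy of a few kJ/mol, negative), matching the sign --
  not the magnitude -- of the chemically detailed result.
* monomer geometry: the disulfide angle stiffness (100 kJ/mol/rad^2)
  was chosen so that the doubly bridged 2-ring carries ~35 kJ/mol of
  strain while 3- and 4-rings are essentially unstrained. This encodes
  the known meta-substitution geometry: in dilute aqueous runs the modal
  closed ring is then the 3mer, with a tail of larger rings -- the
  experimentally observed pattern. With a soft angle (25 kJ/mol/rad^2)
  the model collapses to 2-rings, which is the known failure mode of an
  isotropic bonding scheme without directional specificity.
* bond stiffnesses default to 2500 kJ/mol/nm^2, keeping the 20 fs
  production timestep comfortably stable for the lightest bead.

## Scenario presets and problem sizes

The presets in `scenario()` encode the study conditions at sizes a
single CPU handles in minutes. The monomer-only conditions keep the
reference count of 216 reactive molecules; the box sets the
concentration (28 nm box, ~16 mM, for the dilute aqueous reference;
15.6 nm box for the ~94 mM condensate-interior concentration). The slab
presets use 110 peptides in a 5.5 x 5.5 x 16.5 nm box with a handful of
monomer tracers. The co-assembly series scales the 500/1500/2500-peptide
systems down to 12/36/72 peptides with 24 monomers in a 9.5 nm box; it
uses a reaction-limited attempt rate (k_on = 0.01/ps) so that the
observed rate is proportional to the local contact concentration -- this
is what lets condensate formation accelerate the reaction, the
"chaperone" effect: the median time to 50% consumption is clearly
shorter in the condensate-forming presets than in the dilute reference.
Two caveats are worth stating plainly. First, with three replicas per
preset the 6% and 12% medians are separated by less than the replicate
noise, so their relative order is not stable from configuration to
configuration. Second, the model has a genuine saturation regime: once
essentially all monomers have partitioned into the condensate, growing
the condensate further dilutes them and the rate plateaus or even drops
-- at desk scale the 12% preset sits near that optimum. The
capture-limited monomer-only presets use k_on = 50/ps, completing
within ~10^6 steps as intended.

What the generator deliberately does not emulate: explicit water is
optional and off by default (the thermostat provides the solvent
friction), and no strengthened backbone-water cross term is offered for
the solvated variant, there is no directional specificity in the reaction beyond
the post-hoc angle terms, no beta-sheet stacking of rings, and no
hybrid peptide-monomer chemistry. Passing tests therefore demonstrate
the mechanisms -- not chemical accuracy for any particular compound.

## Analysis methods

**Ring census.** Bonded thiol pairs project onto a monomer-level
multigraph with degree <= 2. Every component is classified exactly once:
isolated node (unreacted monomer), two degree-1 ends (open chain), all
degrees 2 (closed ring; the 2-node parallel-edge component is the
2-ring). The identity `sum(size x rings) + sum(length x chains) +
monomers = total` is asserted on every call, and the census is tested
against an independent igraph-based classifier on random multigraphs.
Open chains are reported separately from rings; ring counts are what
enter all ring-size statistics.

**Density profiles and partitioning.** Slab profiles are mass densities
binned along the slab normal after each frame is re-centred on the
circular-mean centroid of the condensate species -- the circular mean is
what makes centring well-defined when the slab straddles the periodic
boundary. A symmetric tanh interface model is fitted by least squares;
the dense and dilute plateaus, kept one interface width clear of the
fitted interface, define the phase masks for tracer partition
coefficients (K = dense/dilute density ratio, dG = -kT ln K) and the
water weight fraction.

**Diffusion.** The default wavevector is q = 2 pi / sigma_bead
(13.4 nm^-1 for the 0.47 nm reference bead), probing bead-scale
displacements; q is configurable and carried on every result. The
isotropic self-ISF estimator `F_s(q,t) =
<sin(q|dr|)/(q|dr|)>` is averaged over particles and evenly spaced time
origins on unwrapped coordinates. Single and weighted-double
exponentials are fitted with multi-start nonlinear least squares and
compared by plain AIC (`n log(RSS/n) + 2k`), exactly the procedure the
experimental analysis prescribes; the lower AIC wins with no threshold,
and the delta-AIC is always reported. Two degeneracy rules guard the
double model: time constants within 5%, or a minor component carrying
under 5% weight, are unidentifiable and fall back to single. A known
limitation: when ISF curves are estimated from heavily overlapping time
origins, residuals are strongly correlated and plain AIC over-selects
the double model (we measure ~13-17% false doubles on single-population
tracks, versus <10% on independently noisy curves); using fewer,
well-separated origins mitigates this.

**Free energies.** The transfer profile of a tagged monomer along the
slab normal is computed by umbrella sampling (harmonic bias on the
tracer relative to the condensate's mass centroid; default 12 windows
at 0.5 nm spacing, k = 500 kJ/mol/nm^2) followed by standard
self-consistent WHAM (tolerance 1e-6 kJ/mol on the window shifts). A
single zero-bias window reduces WHAM exactly to Boltzmann inversion of
the histogram, which doubles as the unbiased cross-check
(`boltzmann_invert()`). The WHAM implementation is validated by
recovering a known double-well potential from rejection-sampled biased
data to within 0.3 kT RMSD. Profiles are defined up to a constant, so
comparisons align profiles by their mean difference. Coordinates use the
signed axial distance (no spherical Jacobian), consistent with the slab
geometry.

**Assay arithmetic.** The experimental partition assay is reproduced
verbatim: an OLS calibration line with free intercept over the 0.05-0.2
mM standards, the mass-balance condensate concentration
`C_condensate = (C_total - n C_supernatant) (V_total / V_condensate)`
with `n = V_supernatant/V_total`, `K = C_condensate/C_supernatant`, and
`dG = -RT ln K`. The conversion temperature defaults to 300 K, which
reproduces the published -4.3 kJ/mol from K = 5.6; the assay's 4 C
incubation would give about -4.0 and is available through the
`temperature` argument. Replicate summaries propagate the K spread to
dG to first order (`RT sd(K)/mean(K)`).

## Numerical and design notes

* The nonbonded kernel is a truncated-and-shifted Lennard-Jones plus
  (optional) truncated-and-shifted Yukawa; forces are validated against
  a central-difference gradient of the energy to 1e-6 relative.
* Neighbour search is a Verlet list with a 0.6 nm skin rebuilt through a
  linked-cell pass; boxes too small for three cells per dimension fall
  back to a direct scan. Candidate reaction pairs are sorted by distance
  with index tie-breaks, so the sweep is deterministic given the RNG
  stream.
* Degenerate inputs are first-class: empty compositions build empty
  systems; zero-step runs return the initial frame and an empty event
  log; flat profiles report unit contrast instead of a spurious
  interface; unvisited PMF bins are NA, never extrapolated.
* The bond-event log is the audit trail: replaying it against the
  initial topology must reproduce the simulator's final bond network
  exactly, and the census time series is computed from replay rather
  than trusting the final state.
* Open chains at run end are counted and reported, but excluded from
  ring statistics -- whether the experimental distributions include
  unclosed material is not decidable from the published figures, so the
  conservative convention (rings only) is used.
* The ~94 mM "enriched" concentration is interpreted per droplet volume
  in the pre-partitioned preset; the box-volume interpretation is noted
  in the preset documentation.

## Worked example

A miniature irreversible run, its census and kinetics:

```{r example, eval = FALSE}
run <- run_scenario("aqueous", seed = 1, until_consumed = 0.95)
cns <- census(build_bond_graph(run$topology))
print(cns)
modal_ring_size(cns)       # 3 under the dilute reference condition
cc <- consumption_curve(census_series(run))
head(cc)
```

The same pipeline at the concentrated preset shifts `mean_ring_size()`
from about 3.5 to about 5 -- the concentration effect that the
condensate interior produces in the full-scale system.

## Limitations

The reduced model trades chemical specificity for testability. Absolute
densities, water content and PMF magnitudes are not comparable to
chemically detailed simulations or experiments; only signs, ratios and
orderings are. The Langevin friction sets an arbitrary time scale, so
times are comparable only within the model. Ring statistics at desk
scale carry replicate noise of a few counts per size; all headline ring
statistics are therefore pooled or averaged over three independent
replicas with standard errors reported.
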