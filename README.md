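# crxn — reactive coarse-grained simulation of macrocyclization in peptide condensates

`crxn` is an R package for studying how biomolecular condensates steer a
covalent reaction. It models the oxidative macrocyclization of
benzene-1,3-dithiol — bifunctional monomers whose two thiol sites form
disulfide (S–S) bonds, closing into rings — in the presence of a
phase-separating sticker–spacer peptide (L-F-S-S-F-L), using a reduced
reactive coarse-grained model with Langevin dynamics, plus the complete
analysis pipeline around it.

For whom: computational chemists and biophysicists who want a small,
fully testable sandbox for reaction–LLPS coupling — partitioning,
concentration effects on product distributions, and reversible disulfide
exchange — without a full molecular force field.

## The model in brief

* **Dynamics** — BAOAB Langevin integration (NVT, periodic box) over
  truncated-shifted Lennard-Jones, optional Yukawa screened Coulomb,
  harmonic bonds and angles. Units: nm, ps, amu, kJ/mol
  (kT = 2.494 kJ/mol at 300 K, cutoff 1.1 nm, 20 fs steps).
* **pH switch** — peptide termini are neutral sticky beads (high pH,
  condensates form) or +1 charged hydrophilic beads (neutral pH, no
  LLPS).
* **Reaction** — stochastic bonding: free thiol pairs within a capture
  radius bond with probability `1 − exp(−k_on Δt)`; bonds break with
  probability `1 − exp(−k0_off e^(−E/kT) Δt)`. The effective well depth
  E = 60 kJ/mol is irreversible in practice; E = 20 kJ/mol gives
  observable disulfide exchange.
* **Analyses** — ring/chain/monomer census over the disulfide bond
  graph; monomer-consumption kinetics; slab density profiles with tanh
  interface fits; partition coefficients K and ΔG = −kT ln K; droplet
  clustering; incoherent intermediate scattering functions F_s(q,t)
  with single- vs double-exponential fits selected by AIC; umbrella
  sampling + WHAM free-energy profiles; and the experimental
  partition-assay arithmetic
  `C_cond = (C_total − n·C_sup)·(V_total/V_cond)`, K = C_cond/C_sup,
  ΔG = −RT ln K.

## Worked example

Run the dilute aqueous reference condition (216 monomers, irreversible
bonding) until >95% of monomers have reacted, then census the products:

```r
library(crxn)
run <- run_scenario("aqueous", seed = 1, until_consumed = 0.95)
cns <- census(build_bond_graph(run$topology))
print(cns)
#> ring_census (t = NA ps): 216 monomers total
#>   rings:  3mer x22, 6mer x4, 4mer x17, 5mer x4, 2mer x6
#>   chains: len2 x8
#>   unreacted monomers: 10
modal_ring_size(cns)   # 3  -- trimers dominate in dilute water
mean_ring_size(cns)    # about 3.6
```

The numbers say: of 216 monomers, all but 10 reacted; the products are
overwhelmingly small closed rings with the 3mer as the modal size, plus
a thin tail of larger macrocycles. Re-running the same pipeline with
`run_scenario("aqueous-concentrated", ...)` — the same 216 monomers at
the ~94 mM concentration a condensate interior provides — shifts
`mean_ring_size()` up to about 5: the concentration effect by
which condensates favour larger macrocycles.

Partition-assay arithmetic, reproducing the published conversion:

```r
dG_from_K(5.6, 300)
#> [1] -4.297...   # kJ/mol, printed as -4.3
compute_partition(C_total = 0.2, C_supernatant = 0.1,
                  V_total = 440, V_supernatant = 396)[, c("C_condensate", "K")]
#>   C_condensate  K
#> 1          1.1 11
```

A shell front end with the same functionality is installed at
`exec/crxn` (`crxn simulate --scenario aqueous --out runs/aq --seed 1`,
`crxn rings`, `crxn density`, `crxn isf`, `crxn pmf`,
`crxn partition-sim`, `crxn assay`; see `crxn --help`).

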