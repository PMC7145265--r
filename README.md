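# msmgating

Markov state model (MSM) analysis of ion-channel conformational gating in R.

## The scientific problem

The "fast" (pore) gate of a CLC-type chloride channel is controlled by local
motions of its selectivity-filter residues: a backbone rotation of the
inner-gate strand (S168-G169-I170 in rCLC-2 numbering) opens the
intracellular pathway, and a rotameric flip of the external-gate glutamate
(GLU_ex, E211) clears — or, when protonated, occludes — the extracellular
site. Resolving the thermodynamics and kinetics of these motions from
molecular-dynamics data requires a statistical pipeline:

1. **Featurization** — signed φ, ψ, χ1, χ2 dihedrals of the 17
   selectivity-filter residues, one row per frame;
2. **tICA** — the slowest linearly decorrelating coordinates,
   `C_τ v = λ (C_0 + εI) v`, with the *kinetic map* scaling each projection
   by its eigenvalue so Euclidean distance approximates kinetic distance;
3. **Microstates** — mini-batch k-means (default k = 324) on the mapped
   projections;
4. **MSM** — reversible maximum-likelihood transition matrix at lag τ
   (default 28.8 ns), `π_i T_ij = π_j T_ji`, with equilibrium populations
   from the stationary eigenvector and uncertainty from 100
   trajectory-bootstrap models; free energies by Boltzmann inversion
   `ΔG_i = −kT ln(π_i / max_j π_j)`;
5. **Macrostates** — PCCA+ coarse-graining of the dominant eigenvectors,
   and a continuous-time rate matrix K (`P(τ) = exp(Kτ)`, detailed balance
   enforced) for the rates between macrostates;
6. **Structure** — maximal-inscribed-sphere pore-radius profiles along the
   conduction pathway, MSM-weighted binding-site occupancies, and
   Ramachandran densities per macrostate.

Because no public trajectory accompanies the system, the package ships a
first-class **synthetic-data module**: a calibrated four-state reference
kinetic model (states `C_oi`, `C_o`, `O`, `U`; the occluded `U` state exists
only under GLU_ex protonation) with Boltzmann-consistent rates, von Mises
dihedral emissions whose discriminative features mirror the real loading
pattern, Langevin surrogates with closed-form barriers, and analytic pore /
ion fixtures. Every stage of the pipeline is validated against this known
ground truth.

## Worked example

```r
library(msmgating)

cfg <- pipeline_config(n_traj = 80, n_steps = 6000, k = 324,
                       n_boot = 100, seeds = 2024)
res <- run_pipeline(cfg)
res
#> Gating-analysis pipeline result
#>   protonated: 4 macrostates; populations: O=0.0105 U=0.0102 C_o=0.2710 C_oi=0.7083
#>   deprotonated: 3 macrostates; populations: O=0.0090 C_o=0.2661 C_oi=0.7248

prot <- res$conditions$protonated
round(prot$free_energies, 3)
#>     O     U   C_o  C_oi
#> 2.513 2.526 0.573 0.000
```

Reading: the pipeline, given only dihedral time series, rediscovers four
macrostates under the protonated condition and three under the deprotonated
one (no occluded `U` basin). The open-like state `O` and the occluded state
`U` each hold ~1% of the equilibrium population (generator truth: 0.99%),
the inner-open closed state `C_o` sits ~0.6 kcal/mol above the global
minimum `C_oi`, and `O`/`U` lie in the 2–3 kcal/mol band. Bootstrap bands
for these populations come from `macro_population_bands(prot$macro,
prot$bootstrap)`; macrostate rates from `prot$rates` (the reverse rates
`O→C_o` and `U→C_o` exceed the forward rates, as expected for rare states).

Barrier heights along a slow coordinate are validated on a Langevin
surrogate with an analytic double well:

```r
langevin_barrier_recovery(2.0, n_steps = 1e6, seed = 10)$barrier_est
#> [1] 1.918528   # analytic barrier: 2.0 kcal/mol
```

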