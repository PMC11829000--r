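# afmi — structural ensembles of disordered proteins from AlphaFold-derived distance restraints

Intrinsically disordered and partially disordered proteins do not have a
single native structure: their observable properties are averages over broad
conformational ensembles. AlphaFold's single-structure predictions are poor
models of such proteins, but the *uncertainty output* of AlphaFold — the
distogram (a per-residue-pair probability distribution over binned Cβ–Cβ
distances), the predicted aligned error (PAE) and the per-residue confidence
score (pLDDT) — carries real ensemble-level information. `afmi` turns that
output into Bayesian distance restraints on a coarse-grained simulation and
produces reweighted conformational ensembles with validation statistics.

## The method

**Distogram statistics.** For each residue pair (i, j) with bin
probabilities p<sup>b</sup><sub>ij</sub> on 64 equal-width bins spanning
2.15625–21.84375 Å, the restrained distance and its spread are the
distribution moments over bin centers d<sup>b</sup>:

    d̂_ij = Σ_b d^b p^b_ij        σ_ij = sqrt( Σ_b (d^b − d̂_ij)² p^b_ij )

**Restraint selection.** A pair becomes a restraint only if (1) the mass in
the last bin, p(r ≥ 21.84 Å), is ≤ 0.02 (the distogram head is not trained
beyond its grid); (2) its symmetrized PAE is below a protein-level cutoff —
10 Å for hydrophilic sequences (mean Kyte–Doolittle score < −1.4) with at
least one 5-residue stretch of pLDDT > 75, otherwise 5 Å; (3) neither
residue lies in a structured segment (≥ 2 consecutive residues with
pLDDT > 75) — those segments are instead held near the predicted structure
by a one-sided harmonic RMSD wall; and (4) |i−j| ≥ 3.

**Metainference energy.** N_R replicas of a one-bead-per-residue CALVADOS-2
model (harmonic bonds, stickiness-scaled Ashbaugh–Hatch term, Debye–Hückel
electrostatics) are propagated by BAOAB Langevin dynamics (5 fs step,
friction 0.01 ps⁻¹) under

    E = E_MD(X) + (k_B T / 2) Σ_{r,i} [d_i − f_i(X)]² / (σ_B[r,i]² + σ_SEM[i]²) + E_σ

where f_i is the replica-averaged bead distance (a per-replica forward model
is available), σ_B is a per-replica, per-datapoint error parameter Gibbs
sampled every step on [10⁻⁴, 10] Å with 0.1 Å trial moves, and σ_SEM is the
standard error of the replica mean, refreshed every 200 steps.

**Sampling and reweighting.** Parallel-bias well-tempered metadynamics on
the radius of gyration and the end-to-end distance accelerates the slow
collective motions; the final bias evaluated at every frame gives
Torrie–Valleau weights w ∝ exp(+V/k_BT), and resampling by those weights
yields the final unbiased ensemble. Validation statistics: the pairwise
distance distribution P(r), the radius of gyration, the polymer scaling
exponent ν in ⟨R_ij²⟩<sup>1/2</sup> ∝ |i−j|^ν (ν = 0.5 is the Flory
random-coil value), and the Kullback–Leibler divergence
D_KL(P‖Q) = Σ P log(P/Q) between distance distributions.

A fixtures module synthesizes all inputs (sequence, reference ensemble,
distogram, PAE, pLDDT) so the whole pipeline runs and is testable with no
external data.

## Worked example

A synthetic 40-residue disordered protein whose "true" ensemble carries
three specific long-range contacts the plain coarse-grained model cannot
form; the distogram, PAE and pLDDT are generated from that truth, and the
restrained run has to recover it:

```r
library(afmi)

prot     <- make_synthetic_protein(40, seed = 11)
contacts <- make_synthetic_contacts(prot, seed = 11)
truth    <- make_reference_ensemble(prot, n_frames = 1500, seed = 11,
                                    contacts = contacts)
ann      <- make_synthetic_annotations(prot, truth, seed = 11)

fit <- afmi(prot$sequence, ann$distogram, ann$annotations,
            reference = truth, config = afmi_config("test"))
print(fit)
#> AlphaFold-Metainference run (40 residues, 2 replicas x 200000 steps)
#>   restraints kept:   357
#>   final ensemble:    2000 frames (ESS 2186 of 3602 )
#>   Rg = 11.27 +- 0.02 A, nu = 0.242, D_KL vs reference = 0.0013
print(fit$restraints)
#> AlphaFold-derived distance restraints
#>   kept pairs:         357
#>   PAE cutoff:         5 A
#>   structured segments: 0
#>   removed (tail/pae/segment/separation): 346/0/0/77
```

The truth ensemble has Rg = 11.05 Å; the restrained run lands at 11.27 Å
with D_KL = 0.0013 against the truth's P(r), while the identical run
*without* restraints stays near Rg ≈ 15 Å with D_KL ≈ 0.2 — the restraints,
not the force field, carry the structural signal. (The low ν reflects the
contact-compacted topology, not a random coil.) `plot(fit)` overlays P(r);
`plot(fit, "convergence")` shows the block free-energy profiles;
`summary(fit)` adds the filter provenance and the final error parameters.

A command-line front end with `fixtures`, `prepare`, `run` and `all`
subcommands is installed at `inst/cli/afmi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/afmi.R", package="afmi"))')" \
    all --length 40 --seed 1 --profile test --out rundir/
```

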