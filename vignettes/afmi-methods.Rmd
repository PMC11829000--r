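---
title: "Restrained ensembles from AlphaFold uncertainty output: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained ensembles from AlphaFold uncertainty output: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic experiments do and do not
demonstrate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Disordered and partially disordered proteins are ensembles, not structures.
AlphaFold's distogram head predicts, for every residue pair, a probability
distribution over 64 equal-width distance bins covering 2.15625 to
21.84375 Å (Cβ–Cβ; Cα for glycine), with the last bin absorbing everything
beyond the grid. Treated as pseudo-experimental ensemble-averaged data,
those distributions can restrain a molecular simulation toward ensembles
consistent with what the network has learned — provided the restraints are
filtered to where the network is likely to be right, and provided the
statistical machinery acknowledges that both the data and the simulation
model are imperfect. That machinery is metainference: a Bayesian
ensemble-restraint framework in which error parameters are sampled
alongside the coordinates.

## Distogram moments and the restraint filter

The per-pair restrained distance and spread are the mean and standard
deviation of the binned distribution over bin centers. Two reading choices
are fixed here: the "central value" of every bin, including the last, is
the midpoint of its finite edges (the overflow interpretation of bin 64 is
handled by the tail filter, not by shifting the mean); and the two printed
variants of the grid end (21.84375 Å and 21.84 Å) are treated as the same
last finite edge.

Filters are applied in a fixed order purely for provenance bookkeeping
(tail → PAE → structured segment → sequence separation); the kept set is
order-independent by construction, and a property test checks monotonicity
in the thresholds. Decisions worth calling out:

* **pLDDT scale.** The confidence score is kept on a 0–100 scale
  internally. The structured-segment criterion is printed elsewhere as
  "> 0.75" while the stretch criterion is "> 75"; both are read as 75 on
  the 0–100 scale, and both are config keys
  (`selection$segment_cutoff`, `selection$stretch_cutoff`).
* **Hydropathy threshold.** The protein-level PAE cutoff (10 Å vs 5 Å)
  branches on the mean Kyte–Doolittle score being below −1.4
  (hydrophilic); the sign convention — negative = hydrophilic — is easy to
  get backwards and is therefore documented at the config key
  (`selection$kd_threshold`).
* **PAE symmetrization.** PAE matrices are not symmetric; the conservative
  choice `max(PAE(i,j), PAE(j,i))` is used before the cutoff.
* **Minimum separation.** |i−j| ≥ 3 by default: bonded and next-neighbor
  geometry belongs to the force field, while short-range restraints beyond
  that are retained deliberately.
* **Degenerate case.** A chain with pLDDT = 100 everywhere yields one
  structured segment covering everything and an empty restraint set (a
  warning, not an error): the ensemble is then governed by the RMSD wall
  alone, which is the correct folded-protein limit.

## The coarse-grained prior

One bead per residue with the CALVADOS-2 functional forms: harmonic bonds
(k = 8033 kJ mol⁻¹ nm⁻², r₀ = 0.38 nm), the Ashbaugh–Hatch
stickiness-scaled Lennard-Jones term (ε = 0.8368 kJ mol⁻¹, cutoff 2.4 nm),
and Debye–Hückel electrostatics (cutoff 4 nm) with a
temperature-dependent water permittivity and the Debye length from the
standard closed form. Per-residue σ, λ, charge and mass values are shipped
as a plain-text table re-typed from the force-field publication; this
package's contribution is the restrained-ensemble machinery, and the force
field is a documented dependency re-implemented from its reference. Both
nonbonded terms are truncated *and shifted* so the energy is continuous —
cheap insurance for Langevin stability. Histidine charges follow
Henderson–Hasselbalch at the configured pH; terminal +1/−1 charges are on
by default and switchable. A `lambda_scale` argument uniformly scales the
stickiness; it exists as a model-perturbation handle for synthetic
experiments (below), not as a tuning knob for real proteins.

With charges off, λ = 0 *and* ε = 0 the chain reduces to a freely jointed
harmonic chain (ν = 0.5). Note that λ = 0 alone is not enough: the
Ashbaugh–Hatch split keeps the repulsive core at (1−λ)ε, which gives a
self-avoiding walk (ν ≈ 0.59), so the fixtures' `ideal_chain` override
zeroes ε as well.

## Metainference

The restrained energy adds, per datapoint i and replica r, a Gaussian data
term (k_BT/2)·[dᵢ − fᵢ]²/(σ_B²+σ_SEM²) and the error term
E_σ = k_BT Σ [s·(−log σ_B) + ½ log(σ_B²+σ_SEM²)]. Decisions:

* **Forward model.** The default is the replica-averaged distance — the
  maximum-entropy reading of ensemble-averaged data; the per-replica
  literal form is one flag away (`metainference$forward_model`).
* **Sign of the prior term (s).** As printed, s = +1 makes the σ_B
  conditional at fixed deviation monotone toward the upper bound: the
  restraints would self-deactivate over the run. Under the Jeffreys
  convention (s = −1) the conditional peaks near |deviation|/√2, which is
  the behavior that makes error marginalization useful. `error_energy()`
  defaults to the as-printed form so the equation can be inspected as
  written; the *simulation* default is `sigma_prior = "jeffreys"`. Both are
  exposed; nothing is silently corrected.
* **Gibbs sampling.** One sweep over all (r, i) per MD step: uniform
  proposals σ′ = σ ± U(0, 0.1 Å), rejected outside [10⁻⁴, 10] Å, Metropolis
  acceptance from the terms containing σ_{r,i}, with σ_SEM held fixed
  during the sweep. σ_B is initialized at the distogram per-pair spread
  clamped to the bounds. The sampler is validated against direct quadrature
  of the conditional (Kolmogorov–Smirnov distance on pooled chains).
* **σ_SEM estimation.** Per datapoint, the across-replica variance of the
  forward model divided by N_R, averaged over a 200-step window and
  square-rooted — the variance of the replica-mean estimator, which is what
  the term stands for. Two stabilizers were required and are the package's
  own numerical choices, both config keys:
  * `sem_floor` (default half a bin width, 0.1538 Å): the data are
    quantized at one distogram bin, so an error model claiming sub-bin
    precision is unphysical — and, practically, it makes restraint springs
    stiffer than a 5 fs integrator can resolve. σ_SEM is floored, not σ_B,
    so the printed σ_B sampling range stays fully observable.
  * `sem_alpha` (default 0.1): the raw 200-step window estimate carries
    ~40 % sampling noise with two replicas; feeding it in unsmoothed
    modulates every spring constant once per window and parametrically
    pumps heat into the weakly coupled (γ = 0.01 ps⁻¹) Langevin bath. An
    exponential moving average with weight 0.1 removes the pumping without
    changing the stationary estimate. σ_SEM is additionally seeded from the
    first step's across-replica spread so the combined variance never
    collapses before the first window refresh.
* **RMSD wall.** Structured segments are held by a one-sided harmonic on
  the Kabsch superposition RMSD to the reference (κ = 10⁴ kJ mol⁻¹ nm⁻²,
  threshold 0.1 nm — package defaults, none are printed anywhere).
  Gradients go through the optimal superposition by the envelope theorem;
  segments of fewer than three beads are rejected (under-determined
  superposition).

## Sampling, bias and reweighting

BAOAB splitting for the Langevin integrator (only the integrator family is
specified externally; BAOAB is chosen for its configurational accuracy),
5 fs time step, friction 0.01 ps⁻¹, NVT. The engine integrates all replicas
in one compiled loop; hooks (restraints, bias, wall, or an arbitrary R
callback) are evaluated once per step with a consistent snapshot of all
replicas, and every run is reproducible from a single seed.

Parallel-bias well-tempered metadynamics runs on two default collective
variables — radius of gyration and end-to-end distance, with grids sized
from the contour length and hill widths of ~10 % of a coil scale (hill
height 0.5 kJ mol⁻¹, bias factor 10, pace 500; all config keys; the
per-protein CV tables of the original protocol are not reproduced here).
The combined potential is the softmin
V_PB = −k_BT log((1/n) Σ exp(−V_k/k_BT)), gauged to zero at zero bias;
deposited heights carry both the well-tempered damping and the conditional
probability weight, so a single CV reduces exactly to well-tempered
metadynamics. The bias is shared across replicas (multiple-walker
convention) because the replicas are concatenated before reweighting.

"Final bias per frame" is computed exactly — the end-of-run bias evaluated
at every frame's CV values (either from the final grids or by direct
summation over the logged hills; the two agree to interpolation accuracy) —
rather than by approximating with an accelerated deposition pace.
Torrie–Valleau weights w ∝ exp(+V/k_BT) are computed with a max-shift;
they are invariant under constant bias offsets. Resampling is multinomial
by default (systematic available); the effective sample size
(Σw)²/Σw² is reported and a warning fires below 5 % of frames.
Convergence diagnostics use cumulative blocks of increasing coverage
(20 %, 40 %, …, 100 % of post-equilibration frames; the first 10 % of each
replica is discarded as equilibration), aligned by minimum.

## What the synthetic experiments show — and what they do not

The fixtures module generates everything: hydrophilic disorder-prone
sequences (optionally polyampholytic, optionally with designated ordered
segments), reference ensembles from unrestrained CG runs, and
AlphaFold-style annotations. The pLDDT and PAE generators are invented test
scaffolding: pLDDT is 90 ± 5 inside ordered segments and 40 ± 10 (capped at
75) outside; PAE is a noise-scaled increasing function of the per-pair
distance spread, floored at 0.25 Å — mimicking the observed correlation
between PAE maps and distance-fluctuation matrices, with no claim of
reproducing AlphaFold's actual error statistics.

The round-trip experiment is designed so that the data, not the prior,
carry the structural signal: the "truth" ensemble is generated with three
specific long-range contacts (6 Å targets, 0.5 Å spread, imposed as
fixed-σ restraints on the generating model) and a mild stickiness scaling
(λ × 1.2) that the plain prior does not have. This mirrors the real use
case — residual structure known to the network but not formable by a
generic coarse-grained force field. The restrained run must then (a)
reproduce the restrained distances (mean absolute deviation < 1 Å) and
(b) reproduce the truth's P(r) (D_KL < 0.05), with the *unrestrained
control strictly worse*. A mismatch of some kind is logically required for
(b)'s ordering: if the prior already equaled the truth, both runs would
match it and the comparison would be noise. Passing this experiment shows
the machinery — selection, restrained sampling, biasing, reweighting —
recovers a known ensemble from distogram-encoded information at desk
scale. It does not show that real AlphaFold output is accurate for any
particular protein, and the D_KL magnitudes are specific to the synthetic
setup.

Problem sizes are the package's test profile: a 40-residue chain, 2
replicas × 2 × 10⁵ steps, 1500-frame references (the production profile is
6 replicas × 10⁶ steps). The sampler-correctness check pools 300 error
parameters × 10⁵ sweeps; the metadynamics check runs a 1-CV double well for
3 × 10⁵ steps and requires the recovered profile within 0.5 k_BT RMS of the
closed form; thermostat and reweighting checks run 10⁶ and 4 × 10⁴ steps
respectively.

## Numerical details and degenerate inputs

* Distances are Å on disk and in the distogram; conversion to nm happens
  once at the restraint boundary. Coordinates are nm internally and Å in
  PDB files.
* Distogram rows are renormalized when within 10⁻³ of unity (error beyond
  that), but rows already within 10⁻¹² are left bit-identical so the JSON
  exchange format round-trips exactly (17 significant digits on disk).
* Ensemble-derived distograms clamp below-grid distances into bin 1 and
  beyond-grid distances into bin 64; rows are normalized exactly so that
  single-bin rows give a standard deviation of exactly zero.
* D_KL uses the natural logarithm (nats). Bins with P = 0 contribute zero;
  Q is regularized by a redistributed pseudo-mass ε = 10⁻⁸ so that a
  simulation missing a populated bin yields a large finite divergence
  rather than infinity. Distributions on different grids are re-binned to
  the coarser grid by proportional mass assignment first. P(r) includes
  |i−j| = 1 pairs by default (`min_separation` flag to exclude).
* The scaling fit uses log⟨R_ij²⟩^½ against log|i−j| over separations 5 to
  N/2 by least squares on ensemble averages.
* Starting coordinates default to a self-avoiding random walk at bond
  length. Such starts sit tens of Å from the restraint targets, so the
  pipeline relaxes them by L-BFGS against E_MD plus a fixed-σ version of
  the data term before the conventional 100-step minimization — playing
  the role of the predicted structure the production protocol starts from.
* Beads closer than 0.02 nm make `energy_forces()` error with advice to
  minimize; inside the minimizer, pair distances are floored at 10⁻³ nm so
  overlapping starts keep finite energies.

## Known limitations

* The distogram grid ends at ~22 Å; long-range pairs of expanded chains are
  mostly tail-filtered, so global dimensions are constrained only through
  the mid-range network. This is intrinsic to the data, not the
  implementation.
* Replica-averaged restraints constrain means, not distribution shapes; at
  N_R = 2 the marginal per-pair spread is prior-dominated.
* The error-sampling stabilizers (`sem_floor`, `sem_alpha`) are needed
  because a per-step Gibbs sweep under a weakly coupled thermostat is
  sensitive to spring-constant noise; at higher friction or larger N_R they
  matter less.
* All-atom priors, experimental (SAXS/NMR) restraints, non-Gaussian
  likelihoods and back-mapping to all-atom representations are out of
  scope; the ensemble lives at one bead per residue.
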