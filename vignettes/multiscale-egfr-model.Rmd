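---
title: "A multiscale Brownian-Dynamics model of EGFR/ERK-driven tumour initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale Brownian-Dynamics model of EGFR/ERK-driven tumour initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrsim)
```

## The model

`egfrsim` simulates the earliest stage of tumour growth as the interplay of
three processes at three scales, all in micrometres and minutes:

1. **Extracellular signalling.** Epidermal growth factors (EGF) are point
   particles introduced at a constant Poisson rate on a thin layer at the
   boundary of a spherical domain (default radius 120 µm). They diffuse by
   Brownian motion, reflect at the outer boundary and off every cell
   membrane, and are removed at an exponentially distributed degradation
   time. The introduction-to-degradation rate ratio fixes the cell-free
   stationary count at about 660 particles, the birth--death mean
   `introduction_rate / degradation_rate`.

2. **Receptors.** Each EGFR cluster is a pair of spheres clamped to the cell
   membrane along a radial anchor: a ligand-binding sphere outside and a
   G-protein sphere inside. A free EGF whose reaction radius overlaps an
   inactive receptor's outer sphere binds it; the receptor switches 'on' for
   an exponential residence time with mean 8 min and its ligand is consumed
   (a config flag re-releases it instead). Competing overlaps are resolved
   by globally nearest-pair greedy matching, which is deterministic given
   the positions and independent of particle ordering.

3. **Intracellular cascade.** Every cell carries 610 particles: 200 Ras, 60
   Raf, 300 ERK and 50 transcription factors (TF), all initially inactive.
   Ras and Raf diffuse in the cytoplasmic shell between nucleus and
   membrane; TFs in the nucleus; ERK in the cytoplasm when inactive and the
   whole cell once activated. Bimolecular activation fires whenever reaction
   radii overlap at the end of a step: the G-protein sphere of an active
   receptor activates Ras, active Ras activates Raf, active Raf activates
   ERK, and active ERK activates TF inside the nucleus. Catalysts are not
   consumed. Every activation draws an exponential residence time at the
   species' inactivation rate; K-Ras and B-Raf mutations multiply the Ras
   and Raf inactivation rates by a factor of 0.01, which is what makes their
   activation effectively constitutive. Counts per species never change
   during a cell's lifetime (no synthesis or degradation).

4. **Cell mechanics and fate.** Cells are soft spheres with an
   incompressible nucleus. Pairs at centre distance `h` below the sum of
   radii `h0` repel with force `K (h0 - h) / (h - (h0 - h1))`, which
   diverges as `h` approaches `h0 - h1` (the sum of nuclear radii), so
   nuclei can never interpenetrate. Motion follows `m x'' + m mu x' = sum f`
   with the inertial term retained, integrated by semi-implicit Euler. At
   the end of G1 (11 h into a 24 h ± 3 h cycle) a cell counts its active
   TFs: strictly more than `n_tf_star` commits it to linear volume growth up
   to twice its birth volume and division into two tangent daughters along a
   uniformly random axis; otherwise it is removed by apoptosis. Daughters
   inherit exactly half of each species (fair coin for odd counts), with
   on/off states and pending switch-off times preserved and positions
   re-drawn uniformly — the dilution noise of division.

The three subsystems are advanced by operator splitting within each step of
`dt = 0.005` min, in the order field → interiors → mechanics, and share one
clock that is synchronized at the end of the step. A config flag
(`operator_order`) permutes the order for sensitivity checks only.

## Sources of noise

Every stochastic influence is owned by exactly one operation: receptor
placement on the membrane (uniform anchors at cell creation and division);
receptor residence times (exponential draws at binding); low intracellular
copy numbers (the particle representation itself); EGF introduction
(Poisson counts, uniform shell placement) and degradation (exponential
deadlines); cell-cycle fluctuation (uniform cycle lengths on [21 h, 27 h]);
and protein dilution at division (the random split and re-draw). Each
subsystem draws from its own seeded random stream, so adding a cell never
perturbs another subsystem's draws, and a fixed master seed makes whole runs
bit-reproducible.

## Numerical choices

**Time step and the converged regime.** With reactions fired on
end-of-step overlap, the effective bimolecular rate depends on the ratio of
the per-step displacement `sqrt(2 D dt)` to the reaction range. The scheme
approaches its diffusion-limited, `dt`-independent limit only when the step
is smaller than the reaction range. The defaults (`d_protein = 0.5` µm²/min,
`r_bd = 0.1` µm, so a pair reaction range of 0.2 µm against a step of 0.07
µm at `dt = 0.005` min) put the default step inside that regime, which is
why ensemble means stop changing for `dt` at or below 0.005 min.
`run_convergence()` assesses this statistically: species means at 30 min
over a 25-replicate ensemble, compared per species against the finest
tested step with a Welch z-statistic. At that resolution `dt = 0.01` min is
clearly biased (the ERK mean is depressed) while any residual bias at 0.005
min is within the Monte-Carlo detection threshold — the same operational
notion of convergence the ensemble-mean comparison defines. A much larger
protein diffusivity
would break this property at the same `dt` and would also erase the
localized signalling that makes receptor placement matter.

**Calibrated rate constants.** The inactivation rates of the cascade are
not observable directly at this model's resolution; they were fixed once by
requiring that a single receptor cluster, active for exactly 8 min on an
otherwise quiescent cell, produces an ensemble-mean active-TF transient
that peaks near 40 min and returns to zero — the behaviour the single-cell
scenario is defined by. The frozen values are `k_inact = 0.08`/min for Ras,
Raf and ERK and `0.05`/min for TF, with receptor switch-off at `1/8`/min.
With the K-Ras or B-Raf multiplier (0.01) the corresponding species stays
active for ~1000 min on average, which converts the transient into
constitutive activation lasting beyond 12 h.

**Reflection.** Boundary handling is mirror reflection across the violated
spherical surface, iterated until the point is inside its compartment, so
even the rare large step terminates inside. A particle exactly at the
centre of a shell (undefined ray) is placed on the inner boundary; this is
unreachable in practice.

**Degenerate inputs.** Coincident cell centres fall back to a fixed push
axis; a pair at or below the incompressible distance (which the dynamics
prevent) is clamped just above it rather than producing an infinite force;
`repulsion_force()` raises an error instead, because user code calling it
directly should see the violation.

**Receptor geometry.** Receptor spheres (radius 0.5 µm) are recomputed
from the current cell centre, radius and anchor every step, so they track
cell motion and growth. The G-protein sphere activates Ras within
`r_receptor + r_bd`; the outer sphere binds EGF within `r_receptor + r_egf`.
Because the binding sphere straddles the membrane and ligands are reflected
off the cell body, the effective capture rate per receptor is far below the
free-space overlap estimate; the extracellular defaults (`d_egf`, `r_egf`)
are calibration parameters chosen so that a cell's EGF capture, and with it
the chance of passing the G1 checkpoint, separates the receptor-count
genotypes in the tumour scenarios.

**ERK compartment convention.** An ERK switched off while inside the
nucleus diffuses out freely and is re-confined to the cytoplasm only after
it has left; confining it instantly would teleport particles across the
nuclear envelope.

**Within-step causality.** Catalyst states are frozen at the start of the
reaction sub-step, so an activation cannot propagate down the whole cascade
within a single `dt`; this keeps the step's truncation error first-order in
`dt` instead of coupling it to cascade depth.

## What the scenario runners emulate

`run_single_cell()` reproduces the calibration experiment: one receptor
deterministically active for 8 min, no extracellular field, ensembles of 25
replicates by default. `run_receptor_placement()` puts two active receptors
either 20 degrees apart or at opposite poles; adjacent G-protein sites
compete for the same local pool of inactive Ras (a diffusive screening
effect), so the antipodal layout activates more Ras and drives a higher TF
response. `run_tumour()` runs the full coupling from one initiating cell;
by default the field starts pre-filled at its stationary count so the run
does not spend its first hour filling the domain.

Problem sizes are chosen for desk-scale reproducibility: the tumour runs
used by the tests cover 2 simulated days in a 60 µm domain at the same EGF
concentration as the 120 µm default, ensembles of a few replicates. These
sizes are large enough for the qualitative orderings (receptor-count
saturation, mutation-driven acceleration) but far below the two-week,
hundreds-of-cells scale at which spatial shielding of interior cells — the
necrotic-core morphology — fully develops.

## What passing tests do and do not show

The synthetic scenarios exercise every mechanism of the model, but they are
not data: copy numbers are reduced ~2000-fold below physiological values
(which exaggerates relative noise), MEK is absorbed into a single
Raf → ERK step, there are no feedbacks, no ligand gradients from secretion,
no adhesion or surrounding-tissue mechanics, and no corpse mechanics by
default (apoptotic cells vanish; `keep_corpses` retains them as inert
spheres). Quantitative predictions about real tissue are out of scope; the
model's purpose is qualitative exploration of how spatial stochastic
single-cell kinetics propagates to population-level behaviour.

## Known limitations

- The fixed-step overlap scheme under-resolves reactions if the user raises
  `d_protein` or `dt` out of the converged regime; `run_convergence()` is
  the diagnostic.
- Receptor binding uses one-per-step greedy matching; at extreme EGF
  densities this underestimates binding relative to an event-driven scheme.
- Mechanics uses brute-force pairwise forces, adequate for the tens of
  cells of the scaled scenarios; interior overlap searches use spatial
  binning (`use_grid`), with the brute-force path retained as an oracle.
- The inheritance rule halves every species at division and nothing is
  re-synthesized, so the per-cell proteome shrinks by half each generation:
  a first-generation daughter has 25 transcription factors, a
  second-generation one 12. Any fixed checkpoint threshold therefore caps
  the number of achievable generations, and multi-week exponential growth
  is outside the regime this dilution model can reach. The two-day tumour
  scenarios span the first two checkpoints (TF pools of 50 and 25), where
  the genotype orderings are well defined.
- Stepwise calls (`sim_step`) reseed substreams per call from
  (seed, subsystem, call index), so `sim_step(st, 10)` and ten calls of
  `sim_step(st, 1)` agree in distribution but not bit-for-bit; a fixed call
  sequence is bit-reproducible.
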