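---
title: "Coarse-grained modelling of phospho-regulated IDR conformations with cgphos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of phospho-regulated IDR conformations with cgphos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cgphos` simulates proteins at one bead per residue, centered on the
alpha carbon. Folded domains (an F-BAR dimer, SH3 domains) are integrated
as rigid bodies; all other residues are flexible beads joined by harmonic
bonds

$$U_{bond}(r) = K\,(r - r_0)^2, \qquad r_0 = 3.81\ \text{Å},\quad
K = 378\ \text{kcal/(mol Å}^2),$$

the LAMMPS `bond_style harmonic` convention (the effective spring constant
is $2K$). Nonbonded pairs interact through the Ashbaugh–Hatch form of the
hydropathy-scale (HPS) model,

$$
\Phi(r) =
\begin{cases}
\Phi_{LJ}(r) + (1-\lambda_{ij})\,\varepsilon, & r \le 2^{1/6}\sigma_{ij}\\
\lambda_{ij}\,\Phi_{LJ}(r), & 2^{1/6}\sigma_{ij} < r \le 3\sigma_{ij}\\
0, & r > 3\sigma_{ij},
\end{cases}
$$

with $\Phi_{LJ} = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$,
$\varepsilon = 0.2$ kcal/mol, $\sigma_{ij}$ and $\lambda_{ij}$ arithmetic
means of per-residue diameters and hydropathies ($\lambda_i \in [0,1]$,
Kapcha–Rossky-derived scale). The same functional form serves the
Kim–Hummer model D, where $\varepsilon_{ij} = |\alpha(e_{ij} - e_0)|$ from
a residue–residue contact matrix and $\lambda_{ij} = \pm 1$ selects an
attractive or repulsive tail. Charged residues (K, R: $+1$; D, E: $-1$;
histidine neutral by default) interact through Debye–Hückel screened
electrostatics,

$$U_{DH}(r) = \frac{C\,q_i q_j}{\epsilon_r\, r}\, e^{-r/D},
\qquad D = 10\ \text{Å},\quad \epsilon_r = 80,$$

with $C = 332.0637$ kcal Å/(mol e$^2$), truncated at 35 Å (the screening
length and dielectric are the study conditions; the cutoff follows the
common convention of HPS implementations, as the original sources do not
state one). Phosphorylation converts S/T beads to pS/pT carrying $-2e$ by
default or $-1.5e$ as an option (the physiological average lies between
$-1e$ and $-2e$). The shipped pS/pT hydropathy and diameter values are
package estimates mapped from aspartate with an enlarged radius and
phosphate mass — labelled synthetic in the data files — because the
published phospho-parameterization could not be redistributed; the charge,
which dominates the physics probed here, is exact. The KH-D contact
matrix shipped with the package is likewise a synthetic stand-in
constructed from the hydropathy scale; the KH machinery (mapping, pS→D
pair rule, SASA scaling) is fully functional and tested, but quantitative
KH-D results would require transcribing the published matrix.

Units are Å, fs, g/mol, kcal/mol, K throughout, with
$k_B = 0.0019872041$ kcal/(mol K).

## Integration

Dynamics are sampled in the NVT ensemble with a BAOAB-discretized Langevin
integrator, timestep 10 fs, friction $\gamma = 1\ \text{ps}^{-1}$
(interpreted as a 1 ps damping time, as in LAMMPS). With $\gamma = 0$ the
update reduces exactly to velocity Verlet (NVE), which the tests use to
bound secular energy drift. Rigid groups integrate net force and torque
about their center of mass with a quaternion orientation update in the
principal frame; member coordinates are reconstructed from the reference
geometry every step, so internal distances are preserved to machine
precision by construction. Velocities are initialized from
Maxwell–Boltzmann at the run temperature, and all stochastic terms derive
from a single recorded seed (a deterministic counter-based generator with
ziggurat normals), so a run is bit-reproducible on one platform.

Nonbonded pairs come from a Verlet list with a 4 Å skin, rebuilt every 10
steps and additionally whenever any bead has moved more than half the
skin. The list is built by a direct pairwise scan rather than a cell
grid: at the system sizes this package targets (tens to a few hundred
beads) the scan never dominates, and the engine's contract — frame-by-frame
equality with an $O(N^2)$ evaluation — is enforced by tests either way.
Bonded (1–2) neighbors and pairs internal to one rigid group are excluded
from nonbonded terms.

Two guards handle pathological configurations. A displacement cap
(`cap` in `simParams()`, mirroring `nve/limit`) rescales any per-step
move above the cap and clamps the offending bead's speed, which is what
makes the compaction protocol's deliberately overlapped starts integrable;
coincident beads are held at a minimal finite separation so forces stay
finite. Without a cap, a displacement above 10 Å in one step aborts the
run with the last good frame attached — at 10 fs this threshold is only
reachable by a genuine blow-up.

## Initial conditions and protocols

Single chains start either as a straight line at 3.81 Å spacing or from a
"semi-relaxed" configuration: a self-avoiding random walk (step 3.81 Å,
hard core 3.0 Å) rescaled isotropically about its center of mass to a
target radius of gyration — 65.3 Å for the 528-residue IDR model, matching
the study's stated starting condition. The rescale hits the target
exactly; its residual overlaps are what the displacement-capped warmup
resolves.

Dimers start "apart": the F-BAR rigid body at its reference coordinates,
each IDR arm extending in a straight line away from its anchor (the first
arm bead one bond length from the anchor, arms antiparallel), SH3 groups
continuing the line. The compaction-relaxation protocol then (1) runs
with the bond constant scaled to 0.378 kcal/(mol Å$^2$) while box and
flexible coordinates are affinely shrunk tenfold (rigid bodies translate
with their centers of mass, they are not internally scaled), and (2)
restores the bond constant in geometric stages (0.378 → 3.78 → 37.8 →
378), each stage displacement-capped at 0.1 Å/step. Stage durations
default to 10 ns; the tests exercise the protocol at shorter durations.
The "interacting" start applies a constant force (default 0.5
kcal/(mol Å) per bead) to each SH3 group toward the opposite side of the
F-BAR until both cross the midplane — the plane through the F-BAR center
of mass normal to the axis joining the two arm anchors — then re-relaxes
in capped stages.

## Observables and statistics

All analyses follow one pipeline: compute a per-frame scalar series
(mass-weighted $R_G$ or inter-selection center-of-mass distance; a
uniform-weight option exists since the original convention is not
stated), estimate the relaxation time by fitting $e^{-t/\tau}$ on the log
scale to the normalized autocorrelation, discard data before $2\tau$, and
summarize with the five-block estimator: the trimmed series is split into
five equal contiguous parts (remainder truncated), and the standard
deviation of the five part means (n−1 denominator) is the error bar.
The autocorrelation fit window runs to the first zero crossing or 20% of
the series, whichever is smaller, and additionally stops where the
autocorrelation falls below 0.2 — beyond that point log-scale noise biases
the fit long, which the Ornstein–Uhlenbeck recovery tests made visible. A
series whose correlation does not decay inside the window is flagged
under-sampled. In the production scans the trim is additionally capped at
20% of the run, so a single slowly relaxing replicate keeps enough frames
for the block estimator instead of aborting the pool.

`fractionAbove()` reports the fraction of post-trim frames with COM
separation strictly above a threshold (default 100 Å), pooling
trajectories weighted by frame count; a per-trajectory variant is provided
because the figure-caption wording ("fraction of trajectories") admits
both readings, and neither is asserted as the original. Contact maps
count frame fractions with bead pairs inside a 10 Å cutoff (a CG
alpha-carbon scale choice); "F-BAR tips" are the outermost 10% of rigid
beads along the body's first principal axis. Sequence charge diagnostics
(f+, f−, FCR, NCPR) classify sequences into the standard diagram-of-states
regions (globule/tadpole below FCR 0.25, boundary to 0.35, strong
polyampholyte/polyelectrolyte classes above); phospho residues count as
one negative charge for the count-based fractions regardless of the
−1.5/−2 mode, with a charge-weighted NCPR reported alongside.

## The synthetic test system

Real inputs (the Cdc15 sequence, the F-BAR crystal structure, the
AlphaFold SH3 model, the measured per-kinase phosphosites) cannot be
bundled, so the package generates stand-ins and labels the shipped ones
synthetic. The sequence generator draws charge-patterned sequences with
target FCR/NCPR and S/T density; the default regime (length 60, FCR 0.2,
NCPR 0, half the neutrals phosphorylatable) is a weak polyampholyte that
sits in the globule/tadpole region dephosphorylated and crosses toward
the polyelectrolyte side when its S/T union (22 sites) is
phosphorylated — chosen once so the directional tests probe the same
qualitative transition as the real IDR. The shipped 528-residue IDR
stand-in pins S/T at the 31 fixture phosphosite positions; the fixture's
per-kinase site counts (Pom1 22, Shk1 11, Kin1 5, Pck1 1, union 31) and
overlap structure follow the published mapping, while the membership
itself is a labelled reconstruction. The toy dimer is a rigid dumbbell
(default 10 beads, 60 Å tip-to-tip) with a 40-residue arm on each tip.

Directional reproduction runs use these sizes: single-chain scans at 5
seeds × 50 ns per state (deph, full at −1.5e, full at −2e, started from a
straight line and trimmed at $2\tau$); toy-dimer comparisons at 5 seeds ×
7 ns per state with a fixed one-third burn-in (the decay from the
"apart" start dominates the early series, and the autocorrelation fit is
unreliable on a strongly transient signal); the temperature scan at
250/300/350 K, 12 ns per temperature. These lengths give block errors small
enough to resolve the state ordering on the 60-mer while keeping the full
suite practical on a single CPU.

What passing these tests shows — and does not show. The synthetic
generator reproduces the charge-driven physics (collapse vs expansion,
arm–arm association vs separation, coil–globule direction) but not the
real IDR's specific sequence patterning, length, or the quantitative
$R_G$ values of the study system; agreement there would require the real
sequence, structures and force-field files. Kinetic temperatures of stiff
bond modes read ~8% low at the 10 fs timestep (a known discretization
artifact of kinetic estimators; configurational sampling is unaffected at
this order), which is why the thermostat test uses an ideal chain.

## Numerical choices and limitations

* Plain truncation (no energy shift) at $3\sigma_{ij}$ and at the 35 Å
  electrostatic cutoff. The electrostatic step (~0.004 kcal/mol per
  cutoff crossing for unit charges) makes the total energy of a charged
  NVE system execute a slow random walk; the energy-conservation test
  therefore uses an uncharged chain, where the residual
  Lennard–Jones-type steps are an order of magnitude smaller and the
  secular drift of the integrator itself is resolved.
* FIRE minimization moves flexible beads only (rigid bodies are frozen);
  it is a geometry relaxer, not a thermodynamic tool.
* Minimum-image periodic boundaries in a cubic box (default edge 2000 Å,
  far larger than any chain, so images never interact before
  compaction); coordinates are kept unwrapped.
* The SASA pair scale is the product of the two per-residue factors,
  floored at 0.01 — the per-residue definition is published but the pair
  combination rule is not; the product is the simplest symmetric choice.
* One chain per topology arm and at most one rigid group per bead; no
  pressure coupling, Ewald electrostatics, or multi-chain phase-coexistence
  simulation (the package studies single dimers/chains, not condensates).
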