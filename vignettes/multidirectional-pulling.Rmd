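---
title: "Probing mechanical anisotropy with multidirectional steered pulling"
author: "pullfan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing mechanical anisotropy with multidirectional steered pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pullfan)
```

## The problem

In constant-velocity steered molecular dynamics (SMD) a virtual spring of
stiffness $k$ is attached to the center of mass (COM) of a *pulled* atom
group while a *fixed* group is immobilized; the spring's free end moves at
velocity $v$ along a chosen unit vector $\hat d$, so the applied force is

$$F(t) = k\,\big(v\,t - (\mathbf{R}(t)-\mathbf{R}_0)\cdot\hat d\big),$$

with $\mathbf{R}$ the pulled COM. The maximum of $F(t)$ — the *rupture
force* — measures the mechanical stability of the complex along $\hat d$.
Because biomolecular interfaces are geometrically and energetically
lopsided, this number can change several-fold with the pulling direction.
`pullfan` automates probing many directions at once: generating the
directions, writing per-direction NAMD/GROMACS inputs, and analysing the
resulting force traces.

## The direction fan

The natural reference direction of a two-body complex is the **principal
axis** $\hat n$, the unit vector from the fixed group's COM to the pulled
group's COM. Pulling directions are parameterised by the polar angle
$\theta$ from $\hat n$ and an azimuth $\varphi$ in the transverse plane:

$$\hat v(\theta,\varphi) = \cos\theta\,\hat n +
  \sin\theta\,(\cos\varphi\,\hat e_1 + \sin\varphi\,\hat e_2).$$

The defaults $\theta \in \{0°, 45°, 90°\}$, $\varphi \in \{0°, 90°, 180°,
270°\}$ give $1 + 2\times4 = 9$ distinct directions (the pole is a single
direction whatever $\varphi$), covering the hemisphere on the pulled side.
Angles are evaluated with `cospi`/`sinpi`, so right angles are exact and
the reflection identity $\hat v(\theta,\varphi)+\hat v(\theta,\varphi+180°)
= 2\cos\theta\,\hat n$ holds to machine precision.

**The azimuthal origin is a convention, not physics.** Nothing in the
geometry of a complex singles out $\varphi = 0$. We fix the transverse
frame deterministically: $\hat e_1 = \widehat{z \times \hat n}$, except
within $\sim2.6°$ of the $z$ pole ($|\hat n\cdot\hat z| > 0.999$), where
$\hat e_1$ is $\hat x$ orthogonalized against $\hat n$ — chosen so that for
$\hat n = \hat z$ exactly the frame is the canonical $(\hat x,\hat y,\hat z)$.
$\hat e_2 = \hat n \times \hat e_1$ makes the triple right-handed. The rule
is continuous almost everywhere and reproducible across runs; users
comparing systems should remember that $\varphi$ labels are only comparable
when the principal axes (and hence frames) are comparable.

Duplicate vectors are collapsed with an angular tolerance of $10^{-6}$ rad —
far below any meaningful grid spacing, so only genuine degeneracies (the
pole) are merged. Labels (`theta_45_phi_90`) use integer-formatted angles
when integral, one decimal otherwise; they double as directory names.

## Engine input generation

Per direction, the scaffolder writes engine inputs that differ *only* in
the direction vector and the replica seed:

* **NAMD**: `SMDk`, `SMDVel`, `SMDDir`, plus a reference PDB in which fixed
  atoms carry B-factor 1.00 (`fixedAtomsCol B`) and pulled atoms occupancy
  1.00 — the standard NAMD column convention.
* **GROMACS**: pull-code keys (`pull-coord1-geometry = direction`,
  `pull-coord1-vec`, `-rate`, `-k`) with named index groups, and the fixed
  group immobilized via *freeze groups* rather than position restraints.
  Freezing needs no topology edit, which keeps the generator
  topology-agnostic; the trade-off — frozen atoms are excluded from
  pressure coupling — is acceptable for the pulling stage and is the
  user's to revisit for barostatted production runs.

Replicas differ only by the engine random seed, `base_seed + replica`,
recorded in the campaign config. Units are engine-native throughout
(kcal mol⁻¹ Å⁻², Å per timestep for NAMD; kJ mol⁻¹ nm⁻², nm ps⁻¹ for
GROMACS) and never converted silently; analysis-time conversions to
piconewtons use the exact constants 69.4786 pN/(kcal mol⁻¹ Å⁻¹) and
1.66054 pN/(kJ mol⁻¹ nm⁻¹). Numbers are rendered with a period decimal
separator independent of locale, in a representation chosen so parsing the
file recovers the double exactly.

## Force-trace analysis

* **Projection, not magnitude.** The primary force readout is the
  projection of the engine's force vector on the pulling direction
  (magnitude is available as an option). Projection preserves sign — a
  snapped-back complex pushes against the spring — and is what the spring
  law above actually controls.
* **Rupture force** is the global maximum of the unsmoothed series
  (earliest sample on ties). Smoothing (a centered running mean) exists for
  plots and as an explicit opt-in; a default window of 0 keeps the
  statistic honest, since smoothing systematically lowers sharp rupture
  peaks.
* **Replica aggregation** interpolates each replica linearly onto a uniform
  grid spanning the *intersection* of the replica time ranges (grid step =
  the smallest native sampling interval), then takes the pointwise mean and
  sample SD ($n-1$; defined as 0 for $n=1$). No extrapolation is ever
  fabricated beyond a trace's span.
* **Hydrogen bonds** use the de-facto standard geometric criterion:
  donor–acceptor distance ≤ 3.5 Å and donor–hydrogen–acceptor angle ≥ 150°,
  counted between fragments only (donor/acceptor lists carry fragment tags,
  and same-fragment pairs are skipped). Donor/acceptor lists are supplied
  by the caller, so side-chain-only analyses are a list choice, not a code
  path. Counts are invariant under rigid motion of a frame.
* Duplicate time stamps in NAMD logs (restart overlap) keep the last
  occurrence with a warning; decreasing step numbers are an error naming
  the offending line.

## The toy engine and what it can show

The bundled simulator integrates overdamped (Brownian) dynamics,

$$\Delta \mathbf r = \frac{\mathbf F}{\gamma}\,\Delta t +
  \sqrt{2 k_B T \Delta t/\gamma}\; \boldsymbol\xi,$$

with harmonic bonds that can *break irreversibly* when stretched past
`r_break`, the SMD spring force distributed over pulled beads by mass, and
$k_B = 0.0138065$ pN Å K⁻¹ (units: Å, ps, pN). Overdamped rather than full
Langevin dynamics is a deliberate simplification: one fewer parameter, an
unconditionally simple Euler–Maruyama integrator, and every analysis
surface of the package still gets exercised. The integrator core is
compiled (Rcpp) and draws its noise from R's RNG, so a seed makes runs
byte-identical.

Two closed forms anchor the tests: a free bead at $T=0$ obeys
$r(t) = vt - (\gamma v/k)(1-e^{-kt/\gamma})$, so the measured force must
approach the terminal drag $\gamma v$ (the suite demands 1%; the forward
Euler discretization bias is $O(k\,\Delta t/\gamma)$, which is why the
mathematical $10^{-6}$ limit statement is asserted at the
discretization-appropriate tolerance instead); and a single breakable bond
pulled quasi-statically must rupture at $k_b(r_\mathrm{break}-r_0)$ within
5%, cross-checked against a run at 10× smaller $\Delta t$ and $v$.

**The built-in anisotropic complex.** `make_anisotropic_complex()` joins a
fixed 3×3 plate to a compact 4-bead tetrahedral pulled cluster through five
breakable bonds whose anchors, stiffnesses (9.5–36.6 pN/Å) and break
lengths ($r_0$ + 0.82–2.86 Å) are deliberately lopsided. Three design
decisions matter:

1. *Compact pulled cluster.* Interface torques on a plate-shaped pulled
   cluster made it rotate along pathways that a rigid-body oracle relaxes
   differently, spoiling the comparison; a tetrahedron with a short lever
   arm keeps dynamics and oracle on the same pathway.
2. *Every symmetry broken.* Purely vertical parallel bonds load identically
   under ±x or ±y shear (bond-length change depends only on the initial
   bond vector), so bonds are tilted in distinct directions. The final
   stiffness/break-length values were chosen once, by maximizing the
   minimum gap between the nine quasi-static rupture forces (a
   Nelder–Mead search over log-parameters at design time), giving
   well-separated values from ≈44 to ≈119 pN (ratio ≈ 2.7, minimum
   inter-direction gap ≈ 4%).
3. *Noise below signal.* At $T = 10$ K (toy units) replica SDs of the
   rupture force are 1–5 pN, small against those gaps, so five replicas
   resolve the ordering; a small seeded coordinate jitter (±0.05 Å) breaks
   residual lattice symmetry without moving the physics.

Campaign defaults ($k = 50$ pN/Å, $v = 0.04$ Å/ps, $\Delta t = 2$ fs,
$2\times10^5$ steps) are set so the spring tip travels ≈16 Å — past the
last rupture event (≈11 Å) plus the spring lag $F_{\max}/k \approx 2.4$ Å.
A full 9-direction × 5-replica campaign takes under a minute on one CPU;
these problem sizes are also what the test suite and the acceptance script
use.

**The quasi-static oracle.** `quasistatic_force_scan()` estimates the
rupture force along a direction without any dynamics: the pulled cluster is
treated as a rigid body whose COM projection along $\hat d$ is constrained
to $s$; at each $s$ the interface-bond energy is minimized over the five
remaining rigid-body degrees of freedom (transverse translation +
rotation, warm-started along the scan), breakable bonds snap permanently
once their *relaxed* length exceeds `r_break`, and the projected restoring
force is recorded. This is an independent code path from the integrator,
and the pipeline-level test demands that the campaign's ranking of mean
rupture forces over the nine directions equals the oracle's.

**What passing these tests does *not* show.** The toy model has no solvent,
no electrostatics, no inertia and no real free-energy landscape; its
rupture forces are not comparable to any protein's. The tests demonstrate
that the *workflow* — direction generation, input rendering, log parsing,
unit handling, replica statistics, rank-resolving analysis — is correct,
not that 10 ns of all-atom SMD converges, which remains the user's
responsibility for real systems.

## Numerical choices and degenerate inputs

* Degenerate principal axis (COMs closer than $10^{-6}$ Å, below PDB
  coordinate precision) is an error, not a silent default.
* Unknown element symbols get a 12.011 amu fallback mass with a warning —
  coarse-grained and toy PDBs routinely lack element columns, and a hard
  failure there would block the main workflow for no benefit.
* Multi-MODEL PDB files: model 1 defines the structure for setup (setup
  needs one topology); all models are visible to the trajectory reader for
  H-bond and COM-distance analysis.
* Scaffolding refuses to write into a non-empty campaign root unless
  explicitly told to overwrite; analysis never mutates its inputs.
* Angle-to-axis checks in the tests use $\mathrm{atan2}(\|\hat v\times\hat
  n\|, \hat v\cdot\hat n)$ rather than $\arccos$, which is ill-conditioned
  at the pole.

## Known limitations

* Only constant-velocity pulling is generated (no constant-force mode).
* Binary trajectory formats (DCD/XTC/TRR) are not read; H-bond and
  distance analyses consume multi-model PDB or XYZ. Convert binary
  trajectories externally (e.g. with `catdcd` or `gmx trjconv`).
* The GROMACS freeze-group choice excludes frozen atoms from barostat
  coupling; use restraints manually if NPT pulling is required.
* The selection grammar is a deliberate minimal subset (chain / resid /
  name / segid with boolean combinators), not a full selection language.
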