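---
title: "Swarm-based docking with glowdock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-based docking with glowdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowdock)
```

## The model

glowdock builds three-dimensional models of a receptor–ligand complex
(protein, peptide or double-stranded DNA partners) by sampling ligand
*poses* and optimizing them against a pairwise interaction score. A pose
is a translation of the ligand centroid (Å), a unit quaternion rotation
about that centroid, and optionally a vector of normal-mode amplitudes
that deform the ligand backbone.

Sampling is organized in **swarms**: loci placed ~10 Å off the receptor
surface, each carrying an independent population of agents
("glowworms"). Each agent holds one candidate pose and a *luciferin*
level that tracks its score through the update

$$\ell \leftarrow (1-\rho)\,\ell + \gamma J,$$

whose fixed point for a constant objective is $\gamma J / \rho$. Agents
are attracted to strictly brighter agents within an adaptive vision
range; the pursued neighbor is drawn with probability proportional to
its luciferin excess, and the agent takes a fixed-length step toward it
in pose space. Because attraction is local, the population does not
collapse onto a single optimum: it splits over the multiple optima of
the score landscape, which is exactly what a rugged interaction-energy
surface calls for. After the configured number of steps (100 by
default) each swarm's population is clustered, cluster representatives
are ranked globally by raw score, and the top models are written out.

### Quaternions and the pose metric

Rotations are unit quaternions kept in canonical sign ($w \ge 0$), so
the antipodal pair $q$ and $-q$ — the same rotation — is a single point
of pose space. The pose metric is the Euclidean norm of
$[\,\Delta t,\; w_q\,\Delta q,\; \Delta\nu\,]$ with $w_q = 10$ Å per
quaternion unit; $w_q$ makes a typical rotation "cost" about as much as
a few Å of translation, so neighborhoods and movement treat the two on
comparable footing. Initial rotations are uniform on SO(3) (Shoemake's
method); translations are uniform in the swarm ball.

### Scoring

The default objective is a softcore Lennard-Jones plus screened Coulomb
sum over receptor–ligand heavy-atom pairs within 10 Å:

$$E = \sum_{ij}\varepsilon\left[\Big(\tfrac{\sigma_{ij}}{r'}\Big)^{12}
 - 2\Big(\tfrac{\sigma_{ij}}{r'}\Big)^{6}\right]
 + \frac{k_c\,q_i q_j}{\varepsilon_r\,r'},\qquad
 r' = \max(r, 1\,\text{Å}),\quad \sigma_{ij} = r_i + r_j,$$

and the score is $S = -E$ (higher is better). The 1 Å clamp keeps early
random poses finite instead of exploding at the $r^{-12}$ wall.
Element radii (C 1.9, N 1.7, O 1.6, S 2.0, P 2.1, default 1.8 Å), well
depth $\varepsilon = 0.1$ kcal/mol, dielectric $\varepsilon_r = 15$ and
$k_c = 332$ kcal·Å/(mol·e²) are all exposed in
`scoring_parameters()`. Charges are a coarse formal-charge table
(Asp/Glu carboxylates −0.5 per oxygen, Lys +1, Arg +0.5 per NH, DNA
phosphate oxygens −0.5). The objective is pluggable: anything mapping a
`Pose` to `list(S, f_sat, J)` can drive `run_swarm()`.

### Restraints

A restraint declares a residue to be at the interface
(`"A.411"`-style syntax). Restraints act four times:

1. **Swarm filtering** — swarms farther than `keep_cutoff` (20 Å) from
   every receptor-restraint residue are discarded before simulation.
2. **Pose orientation** — with ligand restraints, each initial pose is
   rotated so a randomly drawn ligand-restraint residue faces a randomly
   drawn receptor-restraint residue (minimal aligning rotation, then a
   random perturbation of at most 15°).
3. **Score biasing** — during optimization the objective is
   $J = S\cdot\max(f_{\text{sat}},\epsilon_b)$ for $S>0$ and
   $S/\max(f_{\text{sat}},\epsilon_b)$ otherwise, where $f_{\text{sat}}$
   is the fraction of restraint residues (receptor and ligand pooled)
   with a heavy atom within 5 Å of the partner. The sign-aware form
   guarantees violation always worsens the objective.
4. **Model filtering** — reported models must reach
   $f_{\text{sat}} \ge$ `min_fsat` (0.5).

Ligand-only restraints are rejected: they cannot focus the sampling
(swap the molecules instead). Global ranking uses the raw score $S$,
not the biased $J$: restraints shape the search, but reported energies
stay physical.

### Backbone flexibility

Ligand flexibility uses an anisotropic network model over CA atoms
(uniform springs, 15 Å cutoff). The `n_modes` (default 10)
lowest-frequency internal modes — after skipping the six rigid-body
zero modes — extend the pose with amplitudes bounded at ±3, scaled at
3 Å per unit. Each residue moves rigidly with its CA; this cheap
propagation is accurate for the low-frequency collective motions the
modes represent. These ANM constants follow common elastic-network
practice. Flexibility is implemented for the ligand; a
membrane-associated receptor is always rigid (it must stay fixed
relative to the membrane slab), and receptor-side modes are not
currently sampled — a known limitation.

### Dedicated modes

**Antibody.** An antibody receptor (chains `H`/`L`, already numbered
under Kabat, Chothia or IMGT) contributes its CDR loop residues as
automatic receptor restraints; the window tables live in
`extdata/cdr_windows.csv` so corrections need no code change. All
structurally present loop residues are used (no exposure filtering).

**Membrane.** Coarse-grained phosphate beads (`MMB` residues, atom
`BJ`) define a slab from their z-extrema; swarms inside the slab
widened by a 5 Å cushion are removed, restricting sampling to
extramembranous space. When no bead snapshot is available,
`build_membrane()` lays a single planar bead grid at an anchor
residue's CA height (5 Å spacing, 20 Å margin, 3 Å clash exclusion) —
one layer, not a bilayer: the slab degenerates to a plane and the
cushion supplies the thickness. The receptor must already be oriented
with the membrane normal along z.

## GSO parameters

| parameter | default | meaning |
|---|---|---|
| $\rho$ | 0.4 | luciferin decay |
| $\gamma$ | 0.6 | luciferin gain |
| $\beta$ | 0.08 | vision-range adaptation rate |
| $n_t$ | 5 | desired neighbor count |
| $s$ | 0.03 | movement step (pose-space units) |
| $r_s$ | 2 × swarm radius | maximum vision range |
| $\ell_0$ | 5 | initial luciferin |
| steps | 100 | iterations |

These are the standard constants of the GSO literature; all are exposed
in `gso_parameters()`. Each swarm consumes an RNG stream seeded
`seed + swarm_id`, so swarms are independent and execution order is
irrelevant; identical seeds give identical trajectories.

Numerical choices worth knowing: the movement step renormalizes and
re-canonicalizes the quaternion; amplitudes are clamped to their bound;
a zero pose distance is a no-op; an agent whose objective is non-finite
(e.g. a numerical overflow in a plug-in score) gets $-\infty$ luciferin
for that step — it is never pursued — and restarts its luciferin from
zero if it recovers. Movement decisions in a step use a snapshot of
luciferin and poses taken after scoring, so results do not depend on
agent order within the population.

## Swarm generation

Candidate centers displace every solvent-exposed heavy atom 10 Å
outward along its direction from the receptor centroid; accessibility
is a rolling-probe (1.4 Å) point-sampling test, with a cheaper
radial-distance fallback (`surface_atoms(method = "radial")`).
Candidates are thinned greedily — visiting by descending distance from
the centroid, ties by atom serial — so no two centers are closer than
10 Å. The swarm count is therefore a function of receptor size and
shape; `n_swarms` overrides it, counting swarms that actually run
(the override is applied after restraint/membrane filtering).

## Post-processing

Within each swarm, final poses are clustered by one-pass BSAS over
ligand CA (C1′ for DNA) RMSD without superposition — all poses share
the receptor frame — at a 4 Å cutoff, visiting agents by descending
luciferin so each cluster is represented by its brightest member. BSAS
was chosen because it is one-pass, order-stable under that visit rule,
and cheap. Representatives are ranked globally by raw score (ties
broken by swarm then glowworm id), filtered by restraint satisfaction,
and written as `rank.tsv` plus `model_<rank>.pdb` for the top 5 (or
10). A final-relaxation hook (`relax_models()`) exists as a documented
no-op plug-in point for a short energy minimization of top models.

## The synthetic fixtures

`build_extended_peptide()` produces an ideal-geometry extended chain
(φ = ψ = ω = 180°, backbone + CB) by forward kinematics — the standard
starting conformation for peptide docking.

`make_toy_complex()` generates the self-contained test problem used
throughout the test suite: a 60-residue pseudo-protein shell (radius
~16 Å) whose pole is molded into a groove complementary to a
12-residue helix-like ligand, with the closest heavy-atom gap set at
the pair-potential optimum (3.9 Å), a tapered ligand radius to break
end-for-end symmetry, and three buried salt-bridge pairs that mark the
native register. The native pose is therefore the designed global
optimum of the default score, and the native-contact residues double
as ground-truth restraints. What this emulates: a funnel-shaped
interface with electrostatic steering. What it does not: real side
chains, desolvation, conformational change on binding, or score-decoy
landscapes of real complexes — passing the recovery test demonstrates
that sampling, biasing, clustering and ranking work together, not that
the default score solves real docking problems.

Problem sizes in the tests were chosen at desk scale: the recovery run
uses 5 swarms × 50 glowworms × 100 steps (~1 minute), which samples
the ~6-dimensional pose basin sparsely; recovery of the rank-1 pose
below 5 Å CA-RMSD is reliable at that scale for fixed seeds but not
guaranteed for every seed. Production-scale settings (the dynamic
swarm count and 200 glowworms per swarm) sample far more densely.

## Degenerate inputs and tie-breaks

* Duplicate restraint tokens are de-duplicated preserving order;
  unknown restraint residues are an error at setup, not mid-run.
* Equal luciferin everywhere (e.g. a constant objective) empties every
  neighbor set — strict inequality — so the population freezes rather
  than drifting.
* Collinear CA chains make the elastic network rank-deficient (more
  than six zero modes); the mode count available is checked, and a
  disconnected network is an error.
* Score ties in ranking fall back to (swarm id, glowworm id) so
  reports are reproducible byte-for-byte.
* Clustering visits equal-luciferin agents by ascending id.

## Known limitations

* Receptor-side ANM flexibility is not sampled (ligand only).
* The default score has no desolvation or hydrogen-bond terms; it is a
  geometric-complementarity score with coarse electrostatics. The
  scoring contract is the extension point.
* Single first-model PDB parsing; mmCIF is out of scope.
* The membrane builder emits one planar layer, not a bilayer.
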