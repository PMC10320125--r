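# glowdock

Swarm-based macromolecular docking in R: rigid-body (optionally
backbone-flexible) sampling of receptor–ligand poses driven by Glowworm
Swarm Optimization (GSO), with residue-restraint guidance, an antibody
mode that turns CDR loops into restraints, and an explicit
coarse-grained membrane mode. It is aimed at structural biologists and
method developers who want a self-contained, scriptable docking
protocol whose every stage — swarm placement, agent optimization,
clustering, ranking, filtering — is an ordinary R function.

## The method in brief

A ligand pose is a translation $t \in \mathbb{R}^3$, a unit quaternion
$q$ (rotation about the ligand centroid) and optional normal-mode
amplitudes $\nu$. Sampling loci ("swarms") are placed ~10 Å off the
receptor surface, their number determined by receptor size and shape.
Each swarm holds a population of agents; agent $i$ carries a pose and a
luciferin level updated from the pose score $J_i$ as

$$\ell_i \leftarrow (1-\rho)\,\ell_i + \gamma J_i ,$$

moves a fixed step toward a probabilistically chosen brighter neighbor
within its adaptive vision range, and thereby the population converges
onto multiple optima of the score landscape simultaneously. The default
score is a softcore Lennard-Jones + screened Coulomb sum over
heavy-atom pairs, $S = -E$. Residue restraints (syntax `A.411`) filter
swarms, orient initial poses, bias the objective by the restraint
satisfaction fraction $f_{\text{sat}}$, and filter the final models.
Final populations are clustered (BSAS over ligand CA-RMSD, 4 Å),
representatives ranked by raw score, and the top 5 (or 10) models
written as PDB files. See `vignettes/glowdock-methods.Rmd` for the full
account.

## Worked example

Everything below is generated in code — no downloads. The synthetic toy
complex is a 60-residue shell receptor with a molded binding groove, a
12-residue helix-like ligand, the known native pose, and the native
interface residues as ground-truth restraints.

```r
library(glowdock)

tc  <- make_toy_complex(seed = 42)
cfg <- run_config(mode = "protein-protein", seed = 42,
                  n_swarms = 5, n_glowworms = 50, steps = 100)
res <- dock(tc$receptor, tc$ligand, cfg, restraints = tc$restraints,
            out_dir = "toy_run")

head(res$models[, c("rank", "swarm_id", "glowworm_id", "score", "f_sat", "cluster_id")], 3)
#>   rank swarm_id glowworm_id     score     f_sat cluster_id
#> 1    1       46          24 20.509412 0.9090909          1
#> 2    2       46          28 13.689988 0.7727273          2
#> 3    3       46          39  8.058212 0.6818182          4

anchors <- which(tc$ligand$atoms$name == "CA")
ligand_rmsd(apply_pose(tc$ligand, res$models$pose[[1]])[anchors, ],
            tc$native_coords[anchors, ])
#> [1] 4.146217
```

The rank-1 model scores 20.5 (kcal/mol-scale, higher is better),
satisfies 91% of the declared interface restraints, and sits 4.15 Å
ligand CA-RMSD from the designed native pose — pose recovery from
restraint-guided sampling alone. `toy_run/` now contains `rank.tsv`
(all ranked models), `model_1.pdb` … `model_5.pdb` (receptor + posed
ligand), per-swarm initial populations under `init/`, and
`run_config.json`, which fully reproduces the run.

A command-line front end mirroring the protocol verbs (`dock`,
`cdr-restraints`, `membrane-builder`, `peptide`, `toy-complex`) is
installed at `inst/cli/glowdock.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/glowdock.R", package="glowdock"))')" \
    peptide PQQATDD peptide.pdb
```

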