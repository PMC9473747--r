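# OligoTraj

Trajectory analysis of amyloid peptide oligomerization in R.

Short amyloidogenic peptides — the motivating system is the
transthyretin fragment TTR(105–115), sequence `YTIAALLSPYS` — aggregate
through a zoo of oligomeric states: disordered monomer clouds,
single-layer β-sheets, stacked m+n sheet bilayers, and open or closed
n-stranded β-barrels, the last widely suspected as the toxic
intermediate. Characterizing which of these states a simulated ensemble
visits requires a chain of structural analyses that OligoTraj provides
as one tested toolkit:

* **I/O** — multi-model PDB trajectories in and out (`readMultimodelPDB`,
  `writeMultimodelPDB`), atom selections, S4 containers
  (`PeptideSystem`, `PeptideTrajectory`).
* **Geometry** — hydrogen bonds by the geometric criterion
  d(N–O) ≤ 3.5 Å and ∠(N–H···O) ≥ 120° (`detectHBonds`); residue
  contacts at ≤ 5.4 Å between heavy atoms of discontinuous residues
  (`residueContacts`); radius of gyration (`radiusOfGyration`);
  Shrake–Rupley solvent-accessible surface area (`computeSASA`).
* **Secondary structure** — a full Kabsch–Sander (DSSP) implementation
  (`assignSS`): backbone H-bonds scored by
  E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with bonds
  at E < −0.5; codes H/G/I/E/B/T/S collapsed to the five reporting
  categories (coil, β-sheet, α-helix, bend, turn); inter-chain bridges
  supported. Validated against an independent reference DSSP.
* **Sheet topology** — strand segments (≥ 2 coherent E residues), the
  pairing graph (≥ 2 backbone H-bonds per sheet pairing, orientation
  labels), β-sheet contacts, and the oligomer classifier:
  closed barrel ⇔ the pairing graph contains a cycle; open barrel ⇔ an
  acyclic sheet curls toward closure; bilayer ⇔ two sheets stacked
  face-to-face without inter-layer pairing (`classifyOligomer`).
* **Clustering** — Kabsch superposition Cα-RMSD (`kabschRMSD`,
  `rmsdMatrix`) and gromos (Daura) clustering at the standard 0.4 nm
  cutoff (`dauraCluster`).
* **Landscapes** — the potential of mean force −RT ln H(x, y) over
  β-sheet contacts and Rg at 310 K (`pmf2d`), contact probability maps,
  interaction time series, convergence overlap.
* **Synthetic ensembles** — a generator of labelled conformations of all
  of the above states (`assembleState`, `makeTrajectory`) with ideal
  backbone geometry, deterministic H-bond registry and seeded Gaussian
  noise: the validation surface for every detector.

## Worked example

Generate a seeded aggregation sequence — five disordered frames, five
single-sheet frames, five open-barrel frames of a pentamer — then run
the full pipeline:

```r
library(OligoTraj)

out <- makeTrajectory(
  list(list(kind = "coil", frames = 5),
       list(kind = "sheet", frames = 5),
       list(kind = "open_barrel", frames = 5)),
  nChains = 5, seed = 42, noise = 0.15, path = "demo.pdb")

traj <- readMultimodelPDB("demo.pdb")
traj
#> PeptideTrajectory: 15 frame(s)
#> PeptideSystem: 5 chain(s) of 'YTIAALLSPYS' (residues 105-115), 325 atoms

res <- runPipeline(traj, "demo_out", window = 6:15)
res$topology[c(1, 6, 11), c("frame", "label", "strands", "betaContacts")]
#>    frame        label strands betaContacts
#> 1      1   disordered                    0
#> 6      6 single_sheet       5           16
#> 11    11  open_barrel       5           16

round(res$ssStats$overall, 3)
#>        coil  beta-sheet alpha-helix        bend        turn
#>       0.291       0.709       0.000       0.000       0.000

s <- summarizeRun("demo_out")
s$dominantClass
#> [1] "open_barrel"
```

Every frame's classification matches the generator's ground-truth
sidecar (`demo.pdb.json`): the coil frames are disordered, the sheet
frames a 5-stranded single sheet, the barrel frames a 5-stranded open
barrel with 16 β-sheet contacts feeding the free-energy landscape in
`demo_out/pmf.csv`. The β-sheet fraction of 0.709 over the analysis
window (frames 6–15) is the fraction of (frame, residue) observations
assigned E — strand cores of the 11-mer are 9 residues, so
10 frames × 9/11 ≈ 0.71.

Bookkeeping helpers reproduce the published system setups exactly:

```r
vapply(ttrSimulationPlan()$boxEdge, ionCount, integer(1),
       concentration = 0.15)
#> [1] 10 18 32
countAtoms("YTIAALLSPYS")   # zwitterionic termini
#> [1] 172
planTotals(ttrSimulationPlan())
#> [1] 31.5
```

## Documentation

The methods vignette (`vignettes/oligomer-analysis.Rmd`) describes the
algorithms, the tunable parameters with units and defaults, the
synthetic generator's constructions and their limitations, and the
design decisions taken where published methods leave choices open.
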