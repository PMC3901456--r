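# angtraj

Trajectory marker analysis and variant-effect classification for human
angiogenin (ANG).

Missense mutations in ANG are found in amyotrophic lateral sclerosis patients.
They can break either of the protein's two functions: ribonucleolytic activity
(catalytic triad His13/Lys40/His114) and nuclear translocation (NLS segment
29-IMRRRGL-35, arginines R31-R33). Molecular-dynamics studies have tied those
losses to four trajectory signatures, and `angtraj` implements the analysis
protocol that reads them from a pair of trajectories (mutant and wild type,
multi-model PDB):

1. **backbone RMSD** vs frame 0 after Kabsch superposition (stability);
2. **His114 rotamer switching** - chi1 discretised into the g-/t/g+ bins, the
   statistic is the fraction of frames outside the frame-0 bin;
3. **hydrogen-bond interaction path** from the mutation site to His114 with
   Leu115 as an interior node, on per-frame residue graphs whose edges are
   donor-acceptor heavy-atom pairs at <= 3.2 Å;
4. **SASA and compaction of R31-R33** (Shrake-Rupley solvent accessibility and
   side-chain radius of gyration).

The classifier mirrors the published decision logic:

```
loss of ribonucleolytic activity    <-  switch_fraction >= 0.20  AND  path_persistence >= 0.10
loss of nuclear translocation       <-  SASA reduction  >= 0.20  AND  gyration reduction >= 0.10
destabilized                        <-  mutant RMSD - WT RMSD > 1.0 Å (window means)
deleterious                         <-  any of the above
```

The package also provides PDB structure/trajectory I/O, in-silico point
mutation with ideal side-chain templates, a synthetic reference model of ANG
built in code (the true 123-residue sequence on an ideal extended backbone - a
synthetic stand-in for the 1B1I crystal structure), and a synthetic-trajectory
generator that injects each marker independently at known strength, which is
how the whole pipeline is validated without running molecular dynamics. See
`vignettes/marker-analysis.Rmd` for the methods.

## Worked example

Simulate the study conditions (wild-type-like control and an L35P-like mutant
trajectory, 100 frames at 1 ps), extract the markers, classify:

```r
library(angtraj)

base <- build_ang_model()
wt   <- generate_trajectory(make_preset("wt_like",   base = base, seed = 1))
l35p <- generate_trajectory(make_preset("l35p_like", base = base, seed = 2))

fw <- extract_features(wt)
fm <- extract_features(l35p, "L35P")
fm
#> feature_set L35P
#>   backbone RMSD window mean: 0.248 A
#>   His114 switch fraction:    0.4
#>   mediated-path persistence: 0.4
#>   modal path: 35-40-12-13-115-114
#>   NLS RRR SASA window mean:  470.5 A^2; gyration 3.98 A

classify(fm, fw)
#> Mutation: L35P
#> Overall call: DELETERIOUS
#>
#> Ribonucleolytic activity: predicted LOSS
#>   His114 conformational switching: 40.0% of frames outside native bin 'g+' (threshold 20%)
#>   Leu115-mediated H-bond path to His114: present in 40.0% of frames (threshold 10%)
#>   modal path: 35-40-12-13-115-114
#>
#> Nuclear translocation activity: predicted LOSS
#>   SASA of NLS residues 31RRR33: 470.5 A^2 vs wild-type 673.1 A^2 (reduction 30.1%, threshold 20%)
#>   RRR side-chain gyration: 3.98 A vs wild-type 5.69 A (reduction 30.0%, threshold 10%)
#>
#> Stability: comparable to wild type
#>   window-mean backbone RMSD: 0.25 A vs wild-type 0.25 A (margin 1.0 A)
```

Reading the numbers: His114 left its native g+ rotamer in 40% of frames and a
Leu115-mediated hydrogen-bond path from residue 35 to His114 was present in
40% of frames, so ribonucleolytic loss is called; the NLS arginines lost 30%
of their solvent accessibility together with 30% of their packing radius, so
nuclear-translocation loss is called; backbone RMSD stayed comparable to the
control, so the mutant is not flagged as destabilized. A K17I-like run flags
only the ribonucleolytic mechanism, and the control against itself is benign.

The same workflow is available from a shell:

```sh
exec/angtraj simulate --preset l35p_like --seed 2 --out l35p.pdb
exec/angtraj simulate --preset wt_like   --seed 1 --out wt.pdb
exec/angtraj analyze  --mut l35p.pdb --wt wt.pdb --mutation L35P --out-dir results/
exec/angtraj mutate   --in wt_structure.pdb --mutation K17I --out k17i.pdb
```

`analyze` writes per-series CSVs (RMSD, His114 dihedrals, NLS SASA/gyration),
feature and verdict JSON, a residue-interaction edge list, a representative
frame PDB, a plain-text report, and a run manifest.

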