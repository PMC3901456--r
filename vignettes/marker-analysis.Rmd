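---
title: "Trajectory markers and variant-effect classification for angiogenin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory markers and variant-effect classification for angiogenin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Human angiogenin (ANG) is a 123-residue secreted ribonuclease whose missense
mutations are found in amyotrophic lateral sclerosis (ALS) patients. The
protein has two separable functions, and a mutation can break either or both:

* **ribonucleolytic activity**, governed by the catalytic triad His13, Lys40
  and His114;
* **nuclear translocation**, which depends on the nuclear localization signal
  (NLS) segment 29-IMRRRGL-35, in particular the solvent exposure of the three
  arginines R31-R33.

Molecular-dynamics studies of ANG mutants have associated loss of the first
function with two trajectory signatures - a departure of the His114 side chain
from its crystallographic rotamer, and the appearance of a hydrogen-bond
interaction path that connects the mutation site to His114 with Leu115 as an
intermediate node - and loss of the second with local folding of the NLS
arginines, visible as a joint drop in their solvent-accessible surface area
(SASA) and packing radius. Overall stability is monitored through the backbone
RMSD relative to the starting frame.

`angtraj` implements the analysis half of that protocol as a reusable library
and command-line tool: given a wild-type and a mutant trajectory (multi-model
PDB), it extracts the four markers and combines them into a
deleterious/benign verdict with per-mechanism flags. Running the molecular
dynamics itself is out of scope; any engine that can write multi-model PDB at
a known frame interval can feed this package.

## The four markers

**Backbone RMSD.** For every frame, the N/CA/C/O atoms of all residues are
optimally superposed on frame 0 (Kabsch algorithm, SVD with a determinant
correction so the rotation is proper) and the RMSD is recorded. The stability
statistic is the mean over the final `analysis_window` fraction of frames
(default 0.5). A mutant is called *destabilized* when its window mean exceeds
the wild-type value by more than `rmsd_margin` (default 1.0 Å).

**His114 rotamer switching.** The side-chain dihedral chi1 (N-CA-CB-CG) is
computed per frame and discretised into the three canonical 120-degree rotamer
bins on chi1 mod 360: [0, 120) ("g-"), [120, 240) ("t"), [240, 360) ("g+").
The native state is the frame-0 bin; `switch_fraction` is the fraction of
frames spent outside it. Switching is declared at
`switch_threshold` (default 0.20). The published protocol assessed switching
visually; an occupancy fraction is the natural quantitative counterpart of
"time spent outside the local conformation", which is what the protocol's
output reports. chi2 is computed and exported for inspection but does not
enter the call, since the rotamer bins are defined on chi1.

**Hydrogen-bond interaction path.** For each frame a residue-level graph is
built: an edge joins two residues when some donor heavy atom (N/O/S bearing a
hydrogen in standard protonation chemistry; backbone amide N except proline,
plus the usual side-chain donors) of one residue lies within `hbond_cutoff`
(default 3.2 Å, the published criterion) of an acceptor heavy atom (backbone
carbonyl O, side-chain O/N/S acceptors) of the other. The criterion is
distance-only, matching the published definition literally; an optional
D-H...A angle filter (>= some minimum, applied only when hydrogens are
present) is available but off by default. The package then searches for the
shortest *simple* path from the mutation site to His114 that contains Leu115
as an interior node. That search is exact: an iterative-deepening DFS with
breadth-first-search distance bounds for pruning and a lexicographic
tie-break. (Composing shortest source-to-Leu115 and Leu115-to-His114 legs
greedily can miss mediated paths whose legs are individually non-minimal, so
the package does not do that.) `path_persistence` is the fraction of frames
with such a path; the rule threshold is `path_threshold` (default 0.10).
Branched paths are reported as the set of distinct qualifying simple paths;
mediation requires Leu115 interior on at least one.

**NLS SASA and compaction.** Solvent accessibility is computed with an
in-package Shrake-Rupley implementation: each heavy atom (vdW radii C 1.70,
N 1.55, O 1.52, S 1.80 Å) is expanded by the probe radius (1.4 Å) and covered
with a deterministic Fibonacci-lattice point set (`sasa_sphere_points`,
default 960); a point is accessible when outside every expanded neighbour
sphere. Per-frame SASA of R31/R32/R33 and the radius of gyration of their
pooled side-chain heavy atoms are recorded; window means feed the rule. Loss
of nuclear translocation is called when, relative to wild type, the SASA mean
drops by at least `sasa_reduction_threshold` (default 0.20) *and* the gyration
mean by at least `fold_threshold` (default 0.10); requiring both keeps the
"reduction in SASA" and "local folding" criteria distinct.

## The classifier

```
loss_ribonucleolytic      <- switch_fraction >= 0.20  AND  path_persistence >= 0.10
loss_nuclear_translocation <- SASA reduction >= 0.20  AND  gyration reduction >= 0.10
destabilized              <- mutant RMSD - WT RMSD > 1.0 Angstrom
deleterious               <- any of the above
```

The two ribonucleolytic attributes are combined with AND because the source
protocol always presents them together as joint evidence; a config switch
(`ribo_rule = "or"`) exists for sensitivity analysis. The ribonucleolytic rule
reads absolute mutant attributes (the wild type exhibits essentially no
switching), while the other two rules are relative to the wild-type baseline.
Consequently a self-comparison of wild-type features is benign by
construction, and the relative rules can never fire on any self-comparison.

The decision thresholds were never published (the original service e-mailed
them per job); the defaults above are this package's declared, configurable
stand-ins, chosen to sit far from both the null and the injected signal levels
used in validation (wild-type switching is ~0, case-study-like signals are
~0.4). The RMSD margin of 1.0 Å encodes "comparable to wild type" - also not
defined numerically in the source - at roughly the scale that separates
equilibrated implicit-solvent trajectories from visibly drifting ones.

## The synthetic reference model and trajectory generator

The package cannot ship the 1B1I crystal structure, so its reference structure
is **synthetic and built in code** (`build_ang_model()`): the true mature-ANG
sequence (all landmark residues verified - triad 13/40/114, Lys17, Leu35,
NLS arginines 31-33, Gln12, Asp15, Thr44, Ile46, Leu115, Asp116, Gln117) on an
ideal fully-extended backbone (phi = psi = omega = 180 degrees) with side
chains in Chemical Component Dictionary ideal geometry, His114 set to chi1 =
300 degrees (mid g+ bin). The extended conformation is deliberate: apart from
the covalent-neighbour donor-acceptor contacts (carbonyl O to next amide N,
~2.25 Å, present in any protein), no two residues touch, so the generator has
complete control over which hydrogen-bond edges exist. A Leu115-mediated path
cannot arise from chain-neighbour edges alone (reaching Leu115 from the
N-terminal side requires passing His114 first), so mediated-path persistence
is exactly the injected fraction.

`generate_trajectory()` injects each marker independently:

* **switching**: exactly `round(f * n_frames)` frames (never frame 1) have the
  His114 side chain beyond CB rotated by exactly 120 degrees about the CA-CB
  axis - an exact one-bin shift whatever the starting chi1;
* **path**: in exactly `round(f * n_frames)` frames, one side-chain
  donor/acceptor atom per consecutive residue pair is relocated to 3.0 Å of a
  partner atom (backbone atoms are never moved, so the RMSD detector is
  untouched; each atom moves at most once per frame and anchor atoms are
  protected);
* **compaction**: R31-R33 side-chain atoms are displaced toward their common
  centroid by the compaction factor in every frame;
* **drift**: a fixed random unit direction per residue, scaled by
  `amplitude * (k-1)/(n-1)`, so the final frame's backbone RMSD approximates
  the amplitude (the superposition fit absorbs a negligible fraction of a
  centred random field);
* **noise**: isotropic Gaussian jitter per atom, applied before the exact
  injections so counting statistics stay exact.

Presets encode the case-study conditions: `wt_like` (all injections zero,
0.1 Å noise), `k17i_like` (switching 0.4, the
Ile17-Asp15-Ile46-His13-Leu115-Gln117-Asp116-His114 path at persistence 0.4),
`l35p_like` (switching 0.4, the branched
Pro35-Lys40-Gln12-His13-(Thr44 and Leu115)-Gln117-Asp116-His114 path at 0.4,
compaction 0.3) and `destabilized` (3 Å drift). The mutant presets first apply
the point mutation to the base structure. The 0.4/0.4/0.3 signal strengths are
the generator's encoding of "changed significantly"/"conserved path"/"closely
packed": strong enough to be unambiguous, far from the thresholds, and - for
compaction 0.3 - empirically producing a ~30% SASA reduction, comfortably
beyond the 20% rule. Trajectories default to 100 frames at 1 ps; the published
protocol samples 25 ns at 1 ps, but every statistic here is a per-frame count
or mean whose validation does not improve with frame count, so the package's
own validation runs at the desk scale of 100 frames.

What the generator does **not** emulate: physical energetics, correlated
backbone motion, solvent, side-chain repacking, or any causal link between the
mutation and the markers. Passing the validation suite therefore demonstrates
that the detectors measure what they claim and that the classifier applies the
published rules - not that the rules themselves generalise to real
trajectories, which is an empirical claim of the source protocol.

## In-silico mutation

`mutate_residue()` keeps the backbone (N, CA, C, O, and CB when both residues
have one) fixed and transplants the remaining side-chain atoms from the
ideal-geometry template, superposed on N-CA-CB (N-CA-C when mutating glycine).
No rotamer optimisation or energy refinement is attempted: the original
protocol delegates relaxation to the simulation step, and every detector here
reads trajectories, not the built structure. The wild-type letter in the token
must match the residue found at that position; this guards against
renumbered inputs (mature-ANG numbering is assumed throughout, and the NLS
detector additionally verifies that residues 31-33 are arginines).

## Numerical choices and degenerate inputs

* Superposition requires >= 3 non-collinear points; collinear sets raise an
  error rather than returning an arbitrary rotation.
* Rotamer bins partition [0, 360) exactly; a chi1 on a boundary belongs to the
  upper bin. The generator places His114 60 degrees from the nearest boundary,
  so 0.1 Å jitter (a few degrees of chi1) cannot flip a bin.
* The Fibonacci point lattice is deterministic, so SASA values are exactly
  reproducible; rigid-body invariance holds to quadrature accuracy (~1% at 960
  points, tested), while dihedrals, RMSD and gyration are invariant to 1e-6.
* Equal-length path ties are broken lexicographically on residue numbers, so
  modal-path reporting is deterministic.
* An empty trajectory, a missing backbone atom, inconsistent atom counts
  across PDB models, and unknown elements in the SASA radii table are all
  hard errors naming the offending residue/line.

## Limitations

* The reference model is not the crystallographic fold; absolute SASA values
  and graph topology are not comparable to values computed on 1B1I. All rules
  are relative (mutant vs wild type under identical conditions), which is also
  how the source protocol uses them.
* The hydrogen-bond criterion is distance-only by design fidelity; with
  hydrogens absent (the usual case for X-ray-derived inputs) the optional
  angle filter is inert.
* Single-chain inputs with unique residue numbers are assumed; the verdict is
  the qualitative published call, with no probabilistic confidence score and
  no claim about ALS penetrance.
* mmCIF and binary trajectory formats (DCD/XTC) are not read; convert to
  multi-model PDB upstream.
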