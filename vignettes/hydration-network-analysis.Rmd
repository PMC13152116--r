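---
title: "Analysing internal hydration networks in class A GPCRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing internal hydration networks in class A GPCRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydronet)
```

## The scientific problem

High-resolution structures of active-state class A G protein-coupled
receptors resolve ordered water molecules threading the receptor core:
from the orthosteric ligand pocket, past the sodium-binding pocket
(D^2.50^, S^3.39^), through the NPxxY motif (N^7.49^...Y^7.53^) and the
DRY motif (R^3.50^), down to the interface with the Gα C-terminal helix.
These waters are not spectators — they form a hydrogen-bonded relay that
stabilises the active conformation and participates in G-protein
selectivity.  `hydronet` implements the analyses this picture rests on:

1. **Static network classification** — partition resolved waters into
   ligand-pocket (L), signalling (S, clusters 1–3) and G-interface (G)
   regions from hydrogen-bond geometry, and test whether the network forms
   one continuous path from the sodium pocket to the partner chain.
2. **Trajectory statistics** — per-pair hydrogen-bond episode lifetimes
   (`t_avg`), per-frame occupied-site counts `N_Wat(t)`, and the
   rehydration time at which a depleted network reforms.
3. **Cavity analysis** — grid-based dual-probe detection of the three
   hydration cavities (conserved CWC at 2.50/3.39/7.45, junctional JWC at
   7.53, extended EWC at 3.50/5.58/5.61), plus classification of the
   position-5.58 determinant of EWC hydration.
4. **Conservation** — alignment-column residue frequencies and
   property-conservation fractions at the cavity-defining generic
   (Ballesteros–Weinstein) positions.
5. **Synthetic data** — generators for every input class, each with a
   machine-readable ground-truth record, so that all estimators have
   closed-loop recovery tests.

## Models and statistics

### Hydrogen bonds without hydrogens

Cryo-EM models carry no hydrogens, so the detector works on heavy atoms:
a bond is a pair of polar atoms (N, O by default) within a distance
cutoff (default 3.5 Å) whose geometry passes an angle surrogate — the
covalent-antecedent–donor–acceptor angle must be at least 90°, evaluated
in either donor/acceptor orientation, and atoms without an antecedent
(water oxygens) impose no constraint.  Both parameters are configurable;
all outputs echo them.  The 3.5 Å / 90° choice is the conventional
heavy-atom criterion; nothing downstream is sensitive to it in the tested
regimes because fixture geometries are built several tenths of an
Ångström inside the cutoff.

### Region rules and tie-breaks

A water bonded to ligand atoms is L; bonded to ≥1 of the cluster rule
positions ({2.50, 3.39, 2.53, 7.45}, {7.49, 7.53}, {3.50, 5.58, 5.61}) is
S with that cluster; bonded to both a receptor residue and another
polymer chain is G.  When several rules match, precedence is fixed
G > S > L (interface bridging is the most specific evidence), and within
S the lowest-numbered cluster wins; every tie-break is recorded per water
in the output table.  One consequence worth knowing: a water touching
both 7.45 (cluster 1) and 7.49 (cluster 2) is cluster 1 by rule.  The
packaged receptor-like fixture is therefore built so that the
cluster-linking contacts sit on the waters whose cluster assignment they
do not flip; inter-cluster continuity is carried by the water–water
chain, which the connectivity graph includes anyway.

### Lifetimes

For a per-frame binary presence series, episodes are maximal runs of
bonded frames (gaps up to a configurable tolerance may be bridged;
default 0), and

$$t_\mathrm{avg} = \frac{1}{N_\mathrm{H\text{-}bond}}
  \sum_i t_{\mathrm{H\text{-}bond},i}$$

Episodes touching the series boundaries are included (censoring is
ignored — the simplest faithful reading of the formula), with the
censored count reported so a user can judge when it matters: it biases
`t_avg` down only when the series is short relative to the episode
length.  All times are picoseconds internally and nanoseconds in
reports.

### Occupancy, N_Wat and rehydration

A site is occupied in a frame iff at least one water oxygen lies within
the assignment radius (default 1.5 Å — small enough to discriminate
crystallographic sites ~2.8 Å apart, large enough for thermal jitter) of
the reference site position, after per-frame Cα superposition.  Multiple
waters in one site count once (events are tallied).  `N_Wat(t)` is the
row sum; the rehydration time is the first frame at which `N_Wat` reaches
its threshold (default: all tracked sites, generalising the
nine-site convention) and holds it for a sustain window (default 10
frames); with a sustain window of 1 it reduces to the first-passage time.

### Dual-probe cavity detection

Atoms (waters excluded — cavities are where the waters sit) are dilated
by their van der Waals radius plus the small probe (1.4 Å, a water);
voxels inside are occluded.  A flood fill from the box boundary through
voxels free of the *large*-probe dilation (4.0 Å) defines bulk solvent;
bulk is then re-grown by the probe-radius difference through accessible
space — implemented as Euclidean sphere stamping from the bulk surface,
because iterated 6-neighbour dilation overshoots diagonally and breaks
probe monotonicity.  What remains accessible but unreached is cavity;
6-connected components below 5 Å³ are suppressed as discretisation
specks.  Volume = voxel count × spacing³.

Numerical behaviour to be aware of:

* Atom centres snap to the grid, so measured volumes can move by roughly
  one surface-voxel layer between spacings; convergence is monotone in
  error across halvings (0.8 → 0.4 → 0.2 Å in the tests) but not smooth.
* A mouth lets bulk in only when its free aperture exceeds
  2·(atom radius + probe_out).  In a *cubic* open box the interior
  corners sit farther than (probe_out − probe_in) from any large-probe
  position, so ideal dual-probe detection genuinely leaves corner
  residues at any mouth width; the zero-cavity open fixture is therefore
  a spherical shell, whose accessible shell is exactly one probe-radius
  difference thick everywhere.
* Labels use the anchor sets with precedence CWC > JWC > EWC (ties
  logged).  The cavity *panel* instead measures each region inside a box
  around its own anchors and counts cavities satisfying that region's
  rule: in a connected receptor lumen the JWC anchor 7.53 is within one
  contact distance of the DRY-side compartment, so precedence alone would
  always report EWC = 0.

### Position 5.58

The residue class at 5.58 follows a fixed table: Ser/Thr/Cys/Asn are
small-polar (they permit water to fill the EWC), Tyr/Phe/Trp/Leu/Ile/
Met/His are bulky (they pack it), and anything else — including Gly —
is reported as `other` rather than silently binned, because the source
enumerations do not cover it.

## The synthetic world

The generators state a world once and the tests recover it; none of the
defaults were moved after observing a test result.

**Seven-helix bundle.**  Idealised poly-Ala helices (2.3 Å Cα radius,
100°/1.5 Å per residue) on a 9 Å circle, with GPR174-like author
numbering and twelve mapped generic positions.  The fourteen waters
transcribe the published inventory: five around a lipid-like ligand
headgroup, eight signalling waters descending the core in clusters
2/2/4, one interface water capped by the backbone carbonyl of residue
391 of a docked Gα-helix fragment.  Labelled residues carry one polar
side-chain pseudo-atom placed 2.85–2.9 Å from the water(s) they
coordinate, horizontally toward their Cα — real rotamer geometry is
deliberately not modelled because no operation consumes it.  Carbon
discs cap both membrane faces so the lumen is a closed vessel for the
cavity detector.  A `widen_ic` parameter tilts the intracellular halves
of TM5/TM6 outward (default fixture pair: 0 and 2.5 Å), enlarging the
extended water cavity; this is the known-ordering pair for the EWC test.
What this fixture does *not* emulate: side-chain rotamers, B-factors,
partial occupancy, lipid atoms, or any energetics — a green test
establishes bookkeeping and geometry, not physics.

**Two-state kinetics.**  Each site alternates exponential bound/unbound
dwells (defaults from the published regime: mean bound 1.34 ns or
0.19 ns against the ~10 ps bulk exchange scale; mean unbound 500 ps)
and is discretised at `dt` by the *continuous-bond* rule: a frame is
bound only if the bond persisted through the entire frame window, so
each discrete episode is one uninterrupted bond formation.  This is the
standard continuous hydrogen-bond convention and was chosen a priori
over point-sampling (which merges sub-frame unbinding events and
overestimates lifetimes by ~5–11% in these regimes); its own bias is
−0.2% at 1.34 ns/10 ps and −4.9% at 10 ps/1 ps, comfortably inside the
10%/15% acceptance tolerances.  Discretisation bias is a property of
the stated world, not something the estimator corrects.

**Alignments.**  Exact-count mode writes the specified residue multiset
into a column and then shuffles sequence order with the seed (so the
injected frequency is exact, e.g. 91/100 Tyr at the 7.53 column);
probabilistic mode samples.  Gaps count into a reported gap fraction and
never into denominators.

**Rigid-plus-noise trajectories.**  Frame k is a rigid transform of the
reference plus isotropic Gaussian noise of SD σ per coordinate, giving
the closed-form check E[RMSD] ≈ σ√3.

## Design choices where the design was open

* **Superposition** is weighted least-squares rigid fitting (Kabsch, SVD
  with determinant sign correction); the alignment selection defaults to
  Cα atoms.  The source protocol for its quoted RMSD values is unstated;
  least-squares is the field default.
* **Generic numbering** comes only from a user-supplied mapping table —
  no live database lookup, no renumbering heuristics; fusion-construct
  numbering discrepancies are the mapping's problem by contract.
* **Cluster boundaries** are defined by coordination only (not by depth
  along the membrane normal): the rule table is configurable and the
  defaults encode exactly the published coordination statements.
* **Residence times** are computed from hydrogen-bond episodes (the
  printed formula); site-residence durations are also available by
  applying the same episode machinery to occupancy columns
  (`occupancy_lifetimes`), so neither reading of "residence time" is
  guessed away.
* **Exit codes** (0/2/3/4) are returned, not `quit()`-ed, by
  `hydronet_cli`, so the CLI is testable in-process; a thin Rscript
  wrapper under `inst/cli/` does the quitting.

## Known limitations

* The PDB reader handles single-character chain IDs and standard v3.3
  columns only; mmCIF, insertion-code-heavy models and assemblies are
  out of scope.
* Cavity volumes depend on the atom-radius table and grid alignment at
  the ~10% level at 0.5 Å spacing; cross-structure comparisons should
  hold spacing and probes fixed (the panel does).
* The hydrogen-bond angle surrogate accepts a pair if either orientation
  passes; with hydrogens present a true donor–H–acceptor test would be
  stricter.  No energetic scoring is attempted.
* Published cavity volumes of deposited receptor structures are not
  reproduced here — that requires the deposited coordinates; the panel
  is exercised on synthetic bundles with a known volume ordering.
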