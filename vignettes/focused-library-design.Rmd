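---
title: "From active site to focused library: the focuslib workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From active site to focused library: the focuslib workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focuslib)
```

## The problem

Engineering an aminoacyl-tRNA synthetase (aaRS) to charge a noncanonical
amino acid (ncAA) is a search over an astronomically large sequence space:
full randomization of the 26 first- and second-shell positions of an
archaeal tyrosyl-tRNA synthetase active site encodes
$20^{26} \approx 6.7\times10^{33}$ sequences, while bacterial selection can
interrogate at most $10^8$–$10^9$ transformants.  `focuslib` implements, at
desk scale, the computational funnel that closes this gap: a
dihedral-diversified conformer ensemble of the ncAA is anchored into the
wild-type substrate pose, hydrogen-bonding contact residues are placed by
geometric matching, the surrounding shell is redesigned by simulated
annealing, the resulting models are filtered and clustered by substrate
orientation, and the sequence profile of the winning cluster is curated
into a small combinatorial library whose exact diversity and expected
transformant coverage the package computes exactly.

## Pipeline stages and their models

### Ligand conformer ensemble

A ligand is a user-declared atom table plus bonds and ordered
$\chi_1\ldots\chi_5$ dihedral definitions (`ligand_template()`).  Conformers
are generated by rigid rotation about the $\chi$ axes only, so bond lengths
and angles are invariant by construction.  The proximal angles
$\chi_1,\chi_2$ are pinned to the values the natural substrate adopts in
the crystal pose; the distal angles $\chi_3\ldots\chi_5$ are drawn from a
uniform grid with stratified random jitter (`sample_conformers()`).
Conformers with an intramolecular heavy-atom contact below 2.4 Å
(excluding 1-2/1-3 pairs) are rejected and resampled; two $\chi$ vectors
agreeing within 1° on every component count as duplicates.  A second copy
of the ensemble with $\chi_2$ rotated by exactly 180° (`flip_chi2()`)
doubles it, the standard trick for aromatic side-chain symmetry.  Grid
density is a free parameter (the original conformer generator's energy
window and deduplication settings are not recoverable), exposed as the
`sampled_chi` grids; the shipped defaults use a 30° grid, which supports
the canonical 500 → 1000 member pipeline comfortably.

### Anchoring and shells

Scaffolds are plain PDB structures (`read_scaffold()`); author numbering is
kept verbatim, alternate locations resolve to the highest-occupancy copy,
waters are dropped and insertion codes are rejected.  A conformer is placed
by least-squares (Kabsch) superposition of its rigid core — backbone plus
phenyl ring — onto the bound substrate anchor (`anchor_superpose()`).
Shells use half-open intervals on side-chain heavy-atom distances: first
shell $[0, 6)$ Å, second $[6, 9)$ Å, with CB counted as side chain.  The
catalytic set held fixed during design is a configuration input, not
inferred.

### Geometric matching

A `hbond_constraint()` declares the ligand polar group, the allowed residue
identities, and closed ranges for donor–acceptor distance and the two
flanking angles (optionally a torsion).  The defaults encode a standard
hydrogen bond: 2.6–3.2 Å with both angles ≥ 120°.  Constraints referencing
a catalytic residue's native geometry are derived by measurement
(`native_constraint()`), bracketing the observed values by ±0.3 Å and ±20°.
`find_matches()` enumerates (position × identity × rotamer) candidates per
constraint for every anchored conformer, keeps combinations in which all
constraints are satisfied at distinct positions with no side-chain/ligand
or side-chain/side-chain clash (heavy-atom pairs below 0.8 × the vdW-radius
sum), and deduplicates to sequence-unique matches; the representative is the
lexicographically smallest (conformer, position tuple) and output order is
by signature.  At fixture scale plain enumeration is exact, which is what
lets the test suite compare it against an independent brute-force oracle.

### Side-chain model and rotamers

Residues use a coarse-grained stub model: each identity grows 0–4
pseudo-atoms from CB with ideal sp3 geometry, one rotatable $\chi$ per
bond, with per-atom vdW radii and donor/acceptor flags on the terminal
atom (large aromatics carry a bulky ring pseudo-atom).  Rotamers are the
$\{-60°, 60°, 180°\}$ sp3 grid, with $\{-90°, 0°, 90°\}$ at ring-placing
torsions — a declared stand-in for a backbone-dependent library.  This is
deliberately not chemically faithful; it preserves the size/polarity logic
that drives packing decisions while keeping every matching and packing
problem small enough to enumerate exhaustively, which in turn is what makes
the oracle-equivalence tests possible.  Conclusions about real proteins
require a real rotamer library and energy function; the package validates
pipeline logic, not chemistry.

### Design stage

`redesign()` anneals (identity, rotamer) choices at all designable
positions — side-chain heavy atoms within 9 Å of the ligand, minus fixed
and match-assigned positions — under a three-term score
(`score_weights()`):

* **steric**: split soft Lennard-Jones over heavy-atom pairs.  Repulsion is
  zero at and beyond 0.8 × the vdW-radius sum and rises as an LJ well
  inside it; attraction is a flat $-\varepsilon$ well inside the radius sum
  decaying as an LJ tail outside ($\varepsilon = 0.2$ by default).
* **hydrogen bond**: a geometric well worth −1 at ideal geometry (distance
  at the range midpoint, angles at 180°) tapering linearly to 0 at the
  declared range edges.
* **constraint**: harmonic penalties outside the declared ranges, with
  spring constants 1 per Å² and 0.01 per deg².

The reported components are *ligand interface* (side chain ↔ ligand),
*internal* (side chain ↔ environment and side chain ↔ side chain, plus
per-identity reference energies), and *constraint*; the total is their sum
to within 1e-9, and side chains are never scored against atoms of their own
residue.  Annealing cools geometrically from T = 5 to T = 0.1 score units
over 200 sweeps by default and ends in a greedy zero-temperature quench;
the best state visited is returned, and zero sweeps returns the scored
wild-type state.  Repeat $r$ of match $m$ runs at the mixed seed
$((s \bmod 30011) \cdot 65537 + 211 m + r) \bmod 2147483629$ — an integer
mix chosen so every intermediate is exactly representable in doubles, which
makes runs bit-reproducible across platforms.  The published repeat count
(25 per match) is the default.  Backbone-anchor constraints (the analogue
of holding the ligand's peptide backbone to its two anchoring residues)
enter as ordinary measured constraints via `native_constraint()`.

### Triage

Three filters (`filter_designs()`): ligand-interface score, constraint
score, and preorganization RMS — the heavy-atom RMS of the active-site side
chains after repacking *without* the ligand (`preorganization_rms()`, same
annealer, identities fixed, active site = designable ∪ match positions;
side-chain atoms only is the declared reading).  The published run reports
no numeric thresholds, so they are configuration inputs with defaults
interface ≤ 0, constraint ≤ 1, RMS ≤ 1 Å.  Survivors are clustered by
ligand heavy-atom RMSD with greedy leader clustering at a 2 Å cutoff
(`cluster_by_orientation()`), chosen over hierarchical clustering for
determinism and O(nk) cost; input order is descending total score, clusters
sort by size with ties to the smallest leader id, and the library is built
from the largest cluster (`select_largest_cluster()`).

### Profile curation and library statistics

`compile_profile()` tabulates per-position identity frequencies over the
selected designs.  `curate_profile()` applies four rules **in this order**
(the order is a package decision; the published description lists the rules
unordered): (1) drop identities under 5% frequency; (2) drop listed
conservative mutations at distal positions; (3) collapse each similarity
group ({S,T}, {V,I,L} by default) to its highest-frequency member, ties
alphabetical; (4) re-add the wild type where substrate compatibility
demands it.  Positions reduced to wild type alone leave the library table —
this is exactly how 26 designable positions shrink to the published 17
diversified ones.  Every action is logged, and replaying the log against
the raw profile must reproduce the curated sets (an audit invariant the
tests enforce).

Diversity is the exact product of allowed-set sizes, computed with a small
arbitrary-precision integer type (`exact_product()`, base-10⁴ digits) so
that $20^{30}$-scale numbers are exact; scientific rendering uses two
significant figures to match how such numbers are quoted.  Expected
coverage of a diversity-$V$ library by $N$ transformants is
$1 - (1 - 1/V)^N$, evaluated through `log1p` for numerical stability —
$4\times10^9$ colonies cover a $1.6\times10^8$ library to more than 99%.
The fixed background mutation (D286R) is export metadata, never counted in
diversity.

## The synthetic fixtures and what they do (not) show

`make_toy_scaffold()` builds a pocket with planted ground truth: a
catalytic glutamine hydrogen-bonding the ligand carboxylate in its native
rotamer, two fixed serines anchoring the ligand backbone, 1–3
serine-satisfiable sites for the nitro constraint and up to one for the
*m*-hydroxy constraint (planted exactly on the −60° $\chi_1$ grid point),
plus apolar decoys in declared distance bands whose CB sits provably out of
hydrogen-bonding reach of every polar ligand atom.  The generator verifies
its own manifest (the planted matches must be recoverable) and applies a
seeded rigid motion, so different seeds share truth but no coordinates.
`make_toy_profile("table1")` inverts the curation rules: it constructs a
49-model, 26-position profile that curates *exactly* to the published
17-position library; `"raw26"` plants 26 observed-set sizes whose product
is exactly $8.4\times10^{17}$ (sixteen 10s, one 14, one 6, eight 1s).

Passing tests therefore demonstrate that the pipeline's logic — matching,
packing, filtering, clustering, curation, and all bookkeeping — is correct
on worlds where the answer is known by construction.  They do not
demonstrate that the simplified score ranks real sequences the way a
molecular-mechanics energy function would; the published match, survivor
and cluster counts (143 / 83 / 49 / 4) depend on that machinery and are
treated as workflow inputs, not reproduction targets.

## Worked example

```{r example, eval = FALSE}
fx <- make_toy_scaffold(fixture_recipe(seed = 1))
ens <- flip_chi2(sample_conformers(
  fx$template, fixed_chi = fx$native_chi[c("chi1", "chi2")],
  sampled_chi = list(chi3 = seq(-180, 150, 30), chi4 = seq(-180, 150, 30),
                     chi5 = seq(-180, 150, 30)),
  n = 500, seed = 1))
length(ens)                              # 1000
matches <- find_matches(fx$scaffold, ens, fx$constraints)
models <- run_design_stage(matches, fx$scaffold, n_repeats = 25,
                           base_seed = 1)
surv <- filter_designs(models)
cl <- cluster_by_orientation(surv)
sel <- select_largest_cluster(cl, surv)
prof <- compile_profile(sel)
spec <- curate_profile(prof, curation_rules(), fixed_background = "D286R")
profile_diversity(spec)
coverage_fraction(4e9, spec$diversity)
```

The published library table itself ships with the package:

```{r table1}
tab <- onby_library_table()
as.character(tab$spec$diversity)
format_sci(tab$spec$diversity)
mutation_count(tab$onbyrs1, tab$wild_type)
```

## Numerical choices and edge cases

* Dihedrals follow the IUPAC sign convention, reported in $[-180°, 180°)$;
  angles are compared modulo 360°.
* All constraint intervals are closed; a degenerate interval `[x, x]`
  accepts exactly `x`.
* Superposition needs ≥ 3 corresponding core atoms; fewer is an error, not
  a warning.
* Greedy clustering at cutoff 0 yields one cluster per distinct pose; at
  cutoff ∞ a single cluster.
* Empty inputs are values, not errors: an empty ensemble flips to an empty
  ensemble, an empty match list designs to zero models, an empty cluster
  list selects an empty member set.
* The annealer's running total is maintained in the same single-count
  metric as the reported components, so the returned state is genuinely the
  best visited under the reported score.
* Test and acceptance runs use deliberately small problem sizes — one or a
  few conformers for matching, short annealing schedules for the
  3575-model bookkeeping, restricted alphabets for enumeration oracles —
  chosen so the whole suite re-derives its expectations exhaustively.

## Known limitations

* The energy model is a three-term toy; it does not reproduce any
  molecular-mechanics energy and is not meant to.
* Backbone flexibility, waters, protonation and mmCIF input are out of
  scope; matching is plain enumeration with no hashing acceleration.
* Residues are stubs: branched side chains are approximated by inflated
  radii, and glycine positions (no side-chain heavy atoms) never enter
  distance-defined shells.
* Degenerate-codon (NNK-style) library planning is intentionally absent —
  the workflow targets direct gene synthesis of the enumerated identities.
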