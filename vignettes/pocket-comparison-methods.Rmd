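---
title: "Methods: early-recovery metrics and binding-pocket comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-recovery metrics and binding-pocket comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vspocket)
```

This vignette documents the models, conventions and numerical choices
behind `vspocket`, in the spirit of a methods section: what is computed,
under which assumptions, and where the design was genuinely open.

## The screening-evaluation model

A retrospective virtual screen ranks a library of known ligands ("true
positives") mixed with property-matched decoys ("false positives") by
docking score against one binding pocket. Because the docking search is
stochastic, each ligand is docked several times — three by convention —
and its best-scoring repeat represents it (`best_of_repeats()`). Scores
are energy-like: lower is better by default, configurable everywhere.

The ROC curve is built by sweeping the score threshold over *distinct*
score values. Compounds tied at one score advance the true- and
false-positive counts jointly, producing a diagonal segment. This is the
only order-independent convention: any tie-breaking by input order would
make the curve (and every statistic on it) depend on row shuffling. Under
this convention the trapezoid area equals the Mann–Whitney pair-counting
statistic with ties scored one half, which the test suite verifies against
an independent pairwise-counting oracle on hundreds of random instances.

### NSQ_AUC

Plain AUC weighs the whole ranking uniformly, but screening decisions are
made from the top of the list. The early-recovery statistic used here
transforms the false-positive axis by a square root and takes the area
under TPR as a function of $u = \sqrt{FPR}$ (`SQ_AUC`), then normalizes:

$$\mathrm{NSQ\_AUC} = 100\,\frac{\mathrm{SQ\_AUC}-\mathrm{SQ\_AUC_{random}}}
{\mathrm{SQ\_AUC_{perfect}}-\mathrm{SQ\_AUC_{random}}}$$

The reference terms are fixed analytically: the perfect curve (all
actives first) has unit area under the transform for any class counts, and
the random diagonal has $\int_0^1 u^2\,du = 1/3$. Consequently
$\mathrm{NSQ\_AUC} = 150\,\mathrm{SQ\_AUC} - 50$, perfect recovery scores
exactly 100, random exactly 0, and the worst ranking −50. Negative values
mean the pocket ranks decoys above actives. A finite-sample random
reference (the mean over permutations) would differ from 1/3 only at
order $1/N$ and would make the statistic depend on the realized tie
pattern; the analytic reference keeps the anchors exact and the statistic
deterministic.

On each ROC segment TPR is linear in FPR, hence quadratic in $u$, so the
transformed area is integrated in closed form segment by segment rather
than by sampling the curve. This is why the diagonal evaluates to exactly
1/3 even for a single tie block spanning the whole library.

### Enrichment factors

$EF_x = (TP_x/N_x)/(TP/N)$ at $x$ = 2, 5 and 10% of the ranked database,
computed per chemotype so that scaffold-selective recovery is visible.
The top-fraction size is $N_x = \mathrm{round}(xN/100)$ with a floor of
one compound; rounding is half-up, since round-half-to-even would make
$N_x$ depend on parity for the common case $xN/100 = k + 0.5$. A
chemotype with no true positives has no defined EF and is reported as a
missing value with a warning rather than 0.

### Repeat statistics and pocket comparison

Per-repeat NSQ_AUC values (one ROC per repeat, no best-of pooling) give a
mean ± SEM with $\mathrm{SEM} = s/\sqrt{R}$. Ligands missing any repeat
are dropped from per-repeat statistics (so each repeat's ROC covers the
same compounds) but kept in best-of-repeats pooling if at least one repeat
exists. Pockets are compared on those per-repeat values: one-way ANOVA
followed by Tukey's HSD when more than two pockets are compared, an
unpaired Welch t-test for exactly two, with stars at P ≤ 0.05 / 0.01 /
0.001 / 0.0001. With all observations identical the F ratio is 0/0; this
is reported as undefined rather than forced to a number.

## Library preparation

Libraries arrive as SDF. Each record's *constitution key* is its Open
Babel canonical SMILES with tetrahedral and cis/trans marks stripped and
re-canonicalized — the "2D depiction" of the molecule. Racemic
preparation flags every molecule with at least one stereocenter and
book-keeps $2^n$ enantiomer labels (capped at $2^{10}$ with a warning;
enumeration is label-only, since stereoisomer geometry generation belongs
to the docking engine's racemic sampling). Deduplication merges records
sharing a constitution — enantiomer doubles introduced by racemization —
keeping the lexicographically smallest id and returning an id map for
joining score tables; merging records with conflicting active/decoy labels
is an error, not a silent union.

Stereocenters are perceived from the 2D graph: a carbon with four
substituent branches (an implicit hydrogen counts as one) that are
pairwise distinguishable under Weisfeiler–Lehman label refinement on the
molecule with the candidate removed. This identifies *potential*
tetrahedral centers from constitution alone, which is the relevant notion
for racemic bookkeeping where configurations are deliberately
unspecified; it is not a CIP implementation and does not treat axial or
planar chirality.

### Chemotype clustering

Chemotypes are complete-linkage hierarchical clusters of pairwise
$1 - $ Tanimoto dissimilarity over ChemmineR atom-pair descriptors (a
folded 1024-bit fingerprint is available as an option; atom pairs resolve
small substituent changes better). The tree is cut per library: among the
heights at which exactly `max_clusters` clusters of size ≥ 2 exist, the
cut leaving the fewest unassigned singletons is taken, with the lowest
such height on ties. The "fewest singletons" refinement matters: with
well-separated scaffold families the *lowest* qualifying height alone
would cut while families are still fragmented into pairs. If no height
qualifies, the cut producing `max_clusters` clusters is used. Named
clusters are labeled A–D in decreasing size (ties broken by smallest
member id, making labels independent of input order); everything else is
"other". Each named cluster reports its medoid — the member minimizing
summed dissimilarity, smallest id on ties. Cut heights are per-library
quantities and not comparable across libraries. With fewer ligands than
`max_clusters`, each molecule is its own named cluster; an all-identical
library is a single cluster A.

## Structural comparison

Complexes are reduced to protein heavy atoms of the selected chain plus
one ligand copy; waters and other heteroatoms are removed and alternate
locations resolved to highest occupancy (ties to altloc A). Author residue
numbering is preserved and is the matching key across complexes
(insertion codes must match exactly). Ligand connectivity in coordinate
files is inferred from covalent-radius sums + 0.45 Å, the standard
fallback when no bond records exist.

The *pocket* is the union over the compared complexes of residues with any
heavy atom within 5 Å of any ligand heavy atom (4 Å is the docking-box
convention, exposed via the `radius` argument). Group superposition fits
backbone atoms (N, CA, C, O) of the shared pocket-union residues by
least squares (Kabsch, via bio3d) and applies the transform to all atoms
including the ligand. Backbone-only fitting is a deliberate choice: the
source protocol states only that complexes were superposed, and fitting on
side chains would let the very differences under study (side-chain and
ligand movement) distort the common frame.

Ligand RMSD is computed **without further fitting**, so it reflects both
pose and position in the pocket frame. Atom correspondence comes from
element-labeled graph isomorphism (igraph VF2); among all isomorphisms the
RMSD-minimizing one is used, so topologically equivalent atoms (flipped
rings, carboxylate oxygens) never inflate the value. The test suite checks
this against a brute-force enumeration oracle. Beyond 10^4 mappings the
code falls back to atom-name matching with a warning. Pocket RMSD runs
over heavy atoms present in both structures for each matched residue, so
missing side-chains reduce the atom count instead of failing.

### Interaction fingerprints

Seven boolean contact classes per pocket residue. The geometric rules are
literature-standard defaults, all exposed in `ifp_cutoffs()`:

| type | rule | default |
|---|---|---|
| hydrophobic | apolar C/S pair distance | ≤ 4.5 Å |
| H-bond (donor/acceptor) | donor–acceptor heavy-atom distance, antecedent–donor–acceptor angle | ≤ 3.5 Å, ≥ 90° |
| weak H-bond (C–H donor/acceptor) | C–H carbon to acceptor distance | ≤ 3.8 Å |
| ionic | opposite formal charges | ≤ 4.0 Å |
| aromatic | ring-centroid distance | ≤ 5.0 Å |

Structures carry no hydrogens, so protonation follows the pH-7
convention: Asp/Glu anionic, Lys/Arg cationic, His neutral (donor via
NE2, acceptor via ND1). Ligand atom roles are perceived from the bond
graph by simple rules — amines cationic and donating, carboxylate oxygens
anionic and accepting, planar 5–6-membered C/N rings aromatic, carbons
without N/O neighbors hydrophobic. The planarity test (0.1 Å from the
ring's least-squares plane) distinguishes aromatic rings from chair
cyclohexanes when bond orders are unknown. These fingerprints identify
*likely* interactions under fixed geometric rules; they are a comparison
tool across structures of the same receptor, not an energy model, and no
bit should be read as proof of an interaction.

### Model quality

RSCC and B-factor tables (computed upstream with crystallographic
software) are joined to the pocket: RSCC < 0.8 flags a poor local fit,
stronger when the B-factor also exceeds the pocket median. Residue types
prone to radiation damage — Asp, Glu, disulfide-bridged Cys (S–S ≤ 2.5 Å,
`find_disulfides()`), Met, Tyr — are flagged so that low RSCC on them is
not over-interpreted.

## What the synthetic data emulates — and what it does not

`simulate_scores()` draws a latent score per compound (decoys
N(μ₀, σ²); actives shifted better by the effect size plus a chemotype
shift) and adds independent repeat noise, reproducing the statistical
skeleton of a screen: overall enrichment, chemotype-selective EF
differences, repeat scatter, and the 39-decoys-per-active ratio. Defaults
are μ₀ = −20, σ = 3 (an energy-like spread), repeat noise 0.3 — repeat
scatter well below compound-to-compound spread, as expected when the same
molecule is re-docked — and a 40/30/20/10% chemotype split with the
largest family docking slightly better. Gaussian scores with additive
shifts are the simplest model producing these phenomena; real docking
scores are heavier-tailed and correlated within scaffolds, so passing
tests demonstrate correctness of the *analysis*, not realism of docking.

`simulate_library()` builds four scaffold families (benzimidazoles,
biphenyls, cyclohexane amides, pyridylmethyl amides) with varied
substituents so within-family dissimilarity is far below between-family —
the premise of chemotype clustering, which the tests verify directly on
the dissimilarity matrix before asserting cluster recovery. Chiral
substituents and enantiomer-double records exercise the racemic
bookkeeping. `build_toy_complex()` places idealized residues (not
rotamer-library conformers) around a fixed 12-atom ligand so each intended
contact is realized at an exact distance; fixtures need auditable
geometry, not realism.

Test and acceptance runs use desk-scale sizes — 50 actives × 1950 decoys ×
3 repeats per pocket, 20 seeds for ordering checks, 12-molecule libraries,
6-residue pockets — chosen so the full suite exercises every code path in
well under the patience of an interactive session while keeping
Monte-Carlo checks (e.g. the null NSQ_AUC centering test) adequately
powered.

## Known limitations

* Docking itself, rescoring and hydrogen placement are out of scope; the
  package consumes score tables and coordinates.
* Stereocenter perception is constitutional (potential centers), not CIP;
  meso compounds are counted by their centers, so the $2^n$ multiplicity
  is an upper bound on distinct stereoisomers.
* Interaction fingerprints use fixed geometric rules without hydrogens;
  borderline contacts flip with the cutoffs, which is why the cutoffs are
  configuration, not constants.
* Residue matching assumes consistent author numbering across the
  compared structures; renumbering (e.g. restoring gene numbering) must
  happen upstream.
* RSCC values are consumed, never computed.
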