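---
title: "Methods: interface sub-regions, contact conservation and its predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interface sub-regions, contact conservation and its predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppievol)
```

# The model of interface evolution

`ppievol` treats a protein–protein interface as a weighted contact graph:
nodes are interface residues of the two chains, edges are inter-chain
residue pairs, and the weight of an edge is the number of atomic contacts
between the pair. Comparing two homologous complexes (structural interologs)
then reduces to comparing two graphs over a shared vertex set given by a
residue correspondence. Every headline statistic of the package is a
functional of this representation: the weighted Jaccard conservation of a
contact type, the fraction of residues that leave the interface ("switch
out"), and the logistic models that predict both events per residue.

## Interface detection and burial

A residue is at the interface if it *gains at least one structural neighbor*
upon complexation or *makes at least one inter-chain atomic contact*.
Structural neighborhood is measured between Cβ atoms (Cα for glycine) at
8 Å; atomic contacts between heavy atoms at 5 Å. The 8 Å radius is used for
the gained-neighbor criterion because it is the radius that defines
"structural neighbor"; the 10 Å *extended* neighborhood is reserved for
burial.

Burial is a piecewise-linear index of the extended-neighbor count: 0 at 15
neighbors or fewer, 1 at 24 or more, `(n - 15)/9` in between. Sub-regions
follow from the monomer/complex pair of indices with strict comparisons:
core when the index rises by more than 0.5 upon binding, support when the
average exceeds 0.6, rim otherwise. These thresholds are part of the method
definition and are not tunable.

## Contact types and their thresholds

| quantity | default | notes |
|---|---|---|
| atomic contact | 5.0 Å heavy-atom cutoff | replaces an alpha-shape construction (below) |
| charged contact | 5.5 Å N(+)–O(−) | 6.0 Å selectable; both values are in circulation and the choice changes how many water-mediated interactions are captured indirectly |
| salt bridge | 3.5 Å | charged contact at the tight cutoff; always a subset of charged contacts |
| hydrogen bond | D–A ≤ 3.5 Å, antecedent angle ≥ 90° | hydrogen-free criterion; backbone–backbone pairs excluded |
| apolar contact | 4.5 Å side-chain C/S–C/S | atoms must be surface (monomer SASA > 0) and belong to interface residues; any residue type contributes |
| patch adjacency | 4.5 Å | same criterion as apolar contacts |
| anchor | ΔASA > 80 Å², ≤ 3 residues | pooled over both chains, core/support only |

Two deliberate design choices need explanation.

**Distance cutoffs instead of alpha shapes.** Contact detection via an
alpha-complex of the interface would weight contacts by surface adjacency;
we use plain distance cutoffs because they are reproducible, dependency-free
and — since every conservation statistic is a *ratio over relative contact
sets computed the same way in both interologs* — the systematic differences
largely cancel. Absolute per-interface contact counts do differ from
alpha-shape counts, which is why database-wide absolute numbers are out of
scope here.

**Side-chain-only apolar atoms and the 4.5 Å patch adjacency.** An
alpha-shape definition of patch contiguity connects atoms across the
molecular surface, where backbone carbons are effectively shielded by their
flanking polar N/O atoms. A raw distance criterion has no such shielding: at
5.5 Å it chains the Cβ atoms of *every* pair of adjacent interface residues
(Cβ–Cβ spacing in packed interfaces is typically 4.5–5.5 Å), collapsing each
interface side into one giant "patch" and making the ≥ 4-atom/≥ 2-residue
patch rule vacuous. We therefore (i) restrict the apolar atom set to
side-chain C/S atoms and (ii) use the same 4.5 Å proximity criterion for
patch adjacency as for apolar contacts. Both are configurable
(`contact_config(patch_adjacency_cutoff = )`).

## SASA

No installed SASA engine is assumed: `compute_sasa()` is a Shrake–Rupley
style numerical method with a deterministic Fibonacci-spiral point set
(default 960 points/atom, probe 1.4 Å), so results are seed-free and
reproducible to the point-set resolution. Radii are a fixed element table
(C 1.70, N 1.55, O 1.52, S 1.80 Å). Isolated-sphere areas are exact by
construction; two-body cases agree with a dense Monte-Carlo oracle within
2% at the default resolution. Hydrogens and waters never contribute, and
hetero/cofactor atoms are excluded from burial (configurable at the atom
table level). ΔASA is monomer minus complex per residue; tiny negative
values (< 0.1 Å²) are numerical noise.

## Conservation scoring

Both interfaces are restricted to residues with a mapped equivalent before
any statistic is computed; unmapped residues never contribute. The weighted
Jaccard rule — shared edges carry the average of the two weights, one-sided
edges their own weight — applies to atomic and apolar contacts. Polar
contact types (salt bridges, charged contacts, hydrogen bonds) are scored
unweighted (each residue-pair edge counts 1): the weighting prescription is
explicit only for atomic/apolar contacts, and per-pair polar interactions
are few and near-binary. An empty-versus-empty comparison yields a missing
value, not 0, so pooled averages are not biased by interfaces that simply
lack a contact type.

Charge-fate categories for a lost salt bridge are evaluated in priority
order `switch_out > SB_inter > SB_intra > CH_inter > CH_intra > other`; the
order is a package decision (the categories themselves do not prescribe
precedence) and encodes "most specific explanation first".

Minimum interface sequence identity is computed over mapped positions at the
interface of *both* complexes (the intersection), then the minimum over the
two chain pairs is binned into [0,30), [30,50), [50,70), [70,100].

## Correspondence

The reference procedure is a user-supplied pairwise alignment per chain
(aligned FASTA). When absent, a global Needleman–Wunsch alignment (BLOSUM62,
gap opening 11, extension 1, via Biostrings) stands in. A full structural
alignment engine is out of scope; for close homologs the sequence alignment
recovers the same correspondence, and the synthetic generator returns exact
ground-truth maps so that conservation statistics can be validated without
any aligner at all.

## The logistic predictors

Six features per interface residue: BLOSUM62 score of the residue against
its equivalent (`sim_res`); mean BLOSUM62 score of all residues contacting
it, both chains, in the reference complex (`sim_env`); overall minimum
percent identity with the interolog (`seq_id`, entered in percent, matching
the magnitude of its published coefficient); sub-region dummies with core as
reference; atomic contacts of the residue (`n_contacts`, computed in the
reference complex); and distance to the interface geometric center
normalized to a maximum of 1 (`dist_center`, centroid of Cβ/Cα reference
points, consistent with the neighbor definitions). Residues with no atomic
contact have an undefined environment score and are excluded with a warning.

Fitting is plain maximum likelihood via `glm` (IRLS); suspected perfect
separation is reported. The outcome for the contact-conservation model is
binarized as "≥ 50% of the residue's atomic-contact weight conserved" — the
published account does not print its binarization rule, so the threshold is
explicit and configurable (`residue_features(conserved_threshold = )`).
ROC/AUC uses the Mann–Whitney estimator with midrank tie handling; feature
importance is ranked by the deviance increase when each feature (the two
sub-region dummies as one) is dropped and the model refit. Train/test splits
operate at the couple level so residues of one interolog pair never straddle
the split.

# The synthetic-data generator

`build_toy_complex()` places each chain on a jittered square lattice
(default 11×11 per chain, 4.9 Å spacing, Cα planes 9.2 Å apart, ±0.05 Å
xy-jitter) with simplified straight side-chain templates carrying real atom
names and elements, so SASA, contact typing, hydrogen-bond geometry and
patch detection run unmodified. Planted features are created by scaling
side-chain extension so the two tip atoms sit at an exact target distance:
salt bridges at 2.9 Å, hydrogen-bond pairs at 3.0 Å, a 2×2-cell Leu patch
block per side with facing tips at 4.2 Å, isolated Val–Val apolar pairs at
4.0 Å, a Trp anchor protruding into a Leu-lined pocket (constructed burial
≈ 120 Å², always > 100 Å²), and one support site whose monomer burial is
raised by an under-layer ring of residues.

Three geometric choices make the planted ground truth exact rather than
probabilistic:

* every planted feature cell is surrounded by a glycine moat, so its side
  chain can never join a foreign patch component and rewired side chains
  cannot create new patches;
* glycine cells ride 1.5 Å above their plane so their Cα reference point
  keeps the same neighbor geometry as the Cβ of other cells;
* the 9.2 Å plane gap gives every interface residue several cross-chain
  neighbors, so displacing one residue out of the interface does not strip
  its partner of interface status (displacement of a residue's *entire*
  cross-neighborhood can still rarely cascade — the tests allow for this).

`derive_interolog()` applies three independent perturbations with exact
event logs: BLOSUM62-weighted substitutions (target amino acid sampled with
probability ∝ exp(0.3·B62)); rim-biased displacement out of the interface
(per-residue probabilities ∝ 2/1/0.5 for rim/support/core, rescaled so the
mean equals `switch_rate`, keeping the expected fraction equal to the
nominal rate while respecting the empirical rim bias of switching out); and
contact rewiring as a bounded lateral displacement (half a lattice cell,
≤ 2.5 Å) of the side chain beyond Cβ, which changes contact partners while
keeping the residue at the interface.

**What the generator emulates and what it does not.** It reproduces the
*statistical structure* needed to validate the pipeline: typed contacts at
controlled distances, contiguous apolar patches facing each other, an anchor
concentrating contacts and buried area, controlled substitution/switch-out/
rewiring rates with known expectations. It does not emulate real amino-acid
composition, secondary structure, side-chain rotamers, energetics, or the
correlated evolution of real interfaces. Passing tests therefore demonstrate
that the *measurement machinery* is correct and calibrated — not that real
interfaces behave like the lattice; database-scale statements require real
structure sets.

`simulate_logistic_dataset()` complements the structural generator with a
feature-table simulator used for parameter recovery: features are drawn from
fixed study distributions (BLOSUM62 score of a uniformly random amino-acid
pair; environment similarity N(1.5, 1.5²); identity U(10, 100); region
core/support/rim at 0.25/0.25/0.5; contacts 1 + Poisson(8); center distance
U(0, 1)), labels are Bernoulli under the chosen model. With n = 200,000 the
refit recovers every published coefficient within a few standard errors —
the basis of `scripts/acceptance.R`.

```{r recovery, eval = FALSE}
d <- simulate_logistic_dataset(200000, switching_out_model(), seed = 42)
fit_logistic(d)   # intercept ~ -1.99, n_contacts ~ -0.122
```

# Numerical choices and degenerate inputs

* SASA point count: 960 points/atom keeps the two-body error under 2% and a
  full toy-complex interface model under ~2 s on one CPU; tests and examples
  use the default sizes throughout (11×11 lattices, n = 200,000 simulated
  residues), which keep the whole suite in the minutes range.
* Anchor ties are broken by (chain, residue number); boundary comparisons
  (> 0.5, > 0.6, > 80 Å²) are strict, exactly as defined.
* A single-residue interface gets center distance 0 with a warning; an
  interface with no mapped residues is an error for identity computations.
* Alternate locations resolve to the highest-occupancy record; nonstandard
  residues map to their parent amino acid where known, else to `UNK`-like
  handling with element radii.
* Bootstrap intervals are percentile intervals over means of half-samples
  drawn *without replacement* (1000 draws), matching the definition of the
  aggregate confidence intervals; note that without-replacement half-samples
  have roughly half the variance of the naive `σ²/(n/2)` approximation
  (finite-population correction), which the tests account for.
* All stochastic operations (`random_patches`, `derive_interolog`,
  `simulate_logistic_dataset`, `bootstrap_mean_ci`, `split_train_test`) take
  an explicit seed and restore the caller's RNG state.

# Known limitations

* Contacts are distance-cutoff based; absolute contact counts are not
  comparable to alpha-shape or Voronoi-based counts, only conservation
  *ratios* are.
* The sequence-alignment correspondence degrades for remote homologs where a
  structural alignment would be needed; supplying curated alignments is the
  recommended route there.
* Hydrogen-bond detection is hydrogen-free and geometric; it will differ
  from donor-H-acceptor methods on borderline geometries.
* The random-patch null implements two constraint levels (size+composition
  matching, with or without the facing constraint); finer constraint
  gradations are possible but not provided.
* Obligate/non-obligate classification, water-mediated contacts and
  evolutionary-rate computation are out of scope; per-residue rate scores
  can be supplied externally and used to filter batch statistics.
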