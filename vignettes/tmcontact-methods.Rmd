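---
title: "Contact prediction in transmembrane helix bundles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact prediction in transmembrane helix bundles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

α-helical membrane proteins fold as bundles of membrane-spanning helices,
and knowing which residues of different helices touch constrains the
bundle's 3-D arrangement strongly. `tmcontact` treats contact prediction as
supervised classification over *candidate pairs*: every pair of residues
(i, j) lying in two different TM helices of a chain. A random forest scores
each pair, the top L/5 highest-scoring pairs are called contacts (L = total
TM-segment residue count), and two helices are called interacting when they
share at least one predicted contact.

Two label definitions are supported, reflecting the two conventions in the
field. **DEF1** declares a contact when the minimal distance between any
heavy atoms of the two residues (backbone or side chain, hydrogens
excluded) is strictly below 5.5 Å. **DEF2** uses the Cβ–Cβ distance
(Cα for glycine) strictly below 8 Å. Both are computed only between
residues of different TM helices; intra-helix and inter-chain contacts are
out of scope.

### Features

Each candidate pair carries 408 components:

| block | size | content |
|---|---|---|
| profile | 2 × 180 | nine-residue windows of 20-dim amino-acid frequencies |
| coevolution | 3 × 9 | MIc, OMES, McBASC at diagonal offsets −4…+4 |
| conservation | 2 × 9 | windows of standardized Shannon entropy |
| scalars | 3 | relative distance, sequence separation, helix count |

The *relative distance* |p₁/l₁ − p₂/l₂| measures the separation of the two
residues along the membrane normal: positions p within each helix are
counted from the cytoplasmic to the extracellular end, so the quantity is
small for residues at similar membrane depth — exactly the pairs that can
physically touch. The same orientation defines the "+" direction of the
coevolution windows. Orientation comes from the topology string: the
nearest non-TM label on a helix's N-terminal side decides whether its
N-terminus is inside (cytoplasmic, by the standard convention) or outside.
When the flanking annotation is unknown we fall back to N→C order with a
warning rather than guess.

### Alignment processing

Coevolution and conservation are computed on a filtered alignment: (1)
columns outside TM segments are dropped — the statistics are only needed at
TM positions and loop columns are noisy in membrane-protein alignments;
(2) rows with ≥ 25% gaps in any single TM segment are dropped; (3) pairwise
identity, measured over TM columns only, is capped at 90%. Identity pruning
is greedy top-down (a row is dropped when it exceeds the cap against any
already-kept row): the cap itself does not prescribe which of two
near-identical rows to keep, and greedy retention is deterministic and
order-stable. Non-standard residue codes (B, Z, X, U, O) count as gaps for
all frequency purposes.

MI uses natural logarithms with 0·ln 0 = 0 and pairwise gap deletion. MIp
subtracts the average-product correction MI(i,·)MI(j,·)/⟨MI⟩. For MIc the
literature describes a background-corrected covariance but no closed
formula in the text we follow; we default to the additive correction
MI(i,j) − (MI(i,·) + MI(j,·) − ⟨MI⟩) and expose the multiplicative (APC)
form as a configuration knob — both remove the column-background signal
that makes high-entropy columns look coupled. OMES is the
observed-minus-expected squared statistic over pairwise-ungapped rows, and
McBASC the Pearson correlation of McLachlan-similarity vectors over row
pairs (zero variance ⇒ 0; the similarity matrix is configurable). All
scores are min–max standardized per chain over all scored TM pairs, which
also makes the MI log base irrelevant downstream. No pseudocounts and no
sequence weighting are applied anywhere.

Same-helix column pairs are scored — the windowed encoding needs
S(i+k, j+k) values whose offsets can wander within each helix — but
same-helix pairs are never candidates.

### Model and sampling

Contacts are rare (a few percent of candidate pairs), so each forest is
trained on all contact pairs plus non-contacts sampled without replacement
at a 1:4 positive:negative ratio (all of them, with a warning, when fewer
exist). The forest grows 100 trees with m = ⌊√M⌋ features per split; the
prediction score of a pair is the fraction of trees voting contact. These
defaults follow standard practice for this classifier and are exposed in
`model_config()`. Evaluation uses leave-one-protein-out jackknifing: each
chain is scored by a model trained on the balanced sample of all other
chains' pairs, with per-fold seeds derived deterministically from the
configuration seed.

### Feature selection

`select_features()` implements correlation-based feature selection.
Features are first discretized against the class with Fayyad–Irani MDL
binning (recursive entropy splits accepted only when the information gain
beats the minimum-description-length cost); uninformative features collapse
to a single bin and automatically drop out. Subset quality is the CFS merit
k·r̄cf / √(k + k(k−1)·r̄ff) over symmetric uncertainties, searched by
best-first forward search with a stall limit of 5 non-improving expansions
and ties broken by lowest feature index. The protocol draws 10 balanced
subsamples (all positives plus an equal number of random negatives) and
unions the 10 selected subsets. Note one algebraic consequence of the merit
formula: a perfect duplicate of a selected feature yields *equal* merit
(2U/√(2+2) = U), so redundant copies are never added, while an equally
informative independent feature strictly increases merit.

### Evaluation measures

Accuracy at depth k = ⌊L/d⌋ (d = 5, 2, 1; floored, minimum 1 since a ranked
list of zero predictions is meaningless) is TP/k; coverage is TP over
observed contacts and is undefined — and excluded from averages — for
chains without observed contacts. δ-accuracy credits a prediction when an
observed contact in the *same helix pair* lies within δ = 4 residues on
both helices; matching across different helix pairs would compare
geometrically unrelated positions. Precision–recall curves are computed per
chain along the full ranked candidate list, sampled at a recall grid
(0 to 1, step 0.01; the precision at the smallest rank reaching each grid
recall), vertically averaged across chains, and integrated by trapezoid for
the AUPRC. Helix-level metrics count the confusion matrix over all helix
pairs of each chain; MCC is defined as 0 when a denominator factor
vanishes. All averages are chain-level means.

Ranking ties are broken lexicographically by (helix pair, positions), so
every reported number is deterministic given the seeds.

## The synthetic study

Real training corpora for this task are built from curated PDB subsets with
PSI-BLAST profiles against large sequence databases; neither can ship in a
package. The generator instead produces desk-scale inputs with known ground
truth:

- **Bundles**: ideal α-helices (rise 1.5 Å, twist 100°/residue, Cα radius
  2.3 Å) at the vertices of a regular polygon, alternating up/down through
  the membrane, with a pseudo-Cβ 1.53 Å beyond each Cα along the outward
  normal. Loops get topology labels but no coordinates, which exercises the
  unresolved-residue path of the structure reader. Contact ground truth is
  always recomputed from the coordinates by the labeling module, never
  emitted analytically, keeping generator and labeler independent. Since
  the fixtures have no full side chains, DEF1 on fixtures effectively means
  "backbone + Cβ atoms"; glycine-specific behaviour is tested separately
  with hand-built coordinates, and the synthetic helices avoid Gly/Pro.
- **Alignments**: rows drawn i.i.d. from a hydrophobic-enriched background,
  except that each planted column pair is drawn jointly from a small
  paired-state table with a configurable coupling probability. Planting the
  pairs at the true closest DEF2 contacts makes the coevolution features
  genuinely informative, as they are assumed to be in real alignments. The
  query is the column-wise modal sequence; gaps are inserted uniformly in
  non-query rows.

The default study (20 chains for the end-to-end test, 12 for the
acceptance script; 4–5 helices of 11–13 residues at 10.0–10.8 Å spacing;
120 alignment rows; coupling 0.9; 5% gaps) was chosen to resemble small
polytopic membrane proteins with realistic contact prevalence of a few
percent, and to contain both interacting (adjacent) and non-interacting
(diagonal) helix pairs so that helix-level specificity and MCC are
non-degenerate. These sizes are the package's reference conditions for its
tests and are stated once here.

What the synthetic study does **not** emulate: side-chain packing and
rotamers, helix kinks and irregular geometry, loop-mediated contacts,
phylogenetic correlation between alignment rows (rows are exchangeable), and
alignment errors. Passing the end-to-end tests therefore demonstrates that
the pipeline recovers planted geometric and covariation signal through the
full feature→forest→ranking path — not that it attains any particular
accuracy on real membrane proteins, which depends on profile quality and
alignment depth.

## Numerical choices and degenerate inputs

- Min–max standardization maps a constant score vector to all zeros (no
  information, rather than an error).
- Entropy of an all-gap column is 0; a gap-only profile column is uniform
  1/20.
- Fewer than 2 ungapped rows ⇒ MI/OMES 0 with a warning; fewer than 3 rows
  ⇒ McBASC 0.
- ⟨MI⟩ = 0 ⇒ MIp = MIc = 0.
- Missing Cβ on a non-glycine falls back to Cα with a warning; residues
  with no usable atom are skipped and recorded.
- Structure residues map to the sequence by residue number when consistent
  (identity-checked), else by serial order; over 5% identity mismatches
  abort.
- Contact cutoffs are strict inequalities; 5.5 Å exactly is not a DEF1
  contact.
- All tolerances in the test suite compare against independent brute-force
  oracles at 1e-10 for exact algebra and use binomial/simulation bounds for
  stochastic properties.

## Limitations

The package predicts contacts and helix interactions; it does not assemble
3-D bundles from them, predict topology (users supply it, as the
established topology predictors do that job), run PSI-BLAST, or support
mmCIF/multi-model structures. DCA-style global coevolution models are
deliberately absent: the method is defined over the local pair statistics
described above.
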