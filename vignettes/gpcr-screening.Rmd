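---
title: "Consensus screening of transcriptomes for GPCR candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus screening of transcriptomes for GPCR candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevenTMscreen)
```

## The problem

G protein-coupled receptors (GPCRs) share a conserved architecture — seven
transmembrane (7TM) helices joined by alternating intra- and extracellular
loops — but often show little sequence similarity across families, and next
to none between distantly related species. In a *de novo* transcriptome of a
non-model organism (for instance, the sensory appendages of a tick, whose
Haller's organ carries the olfactory sensilla), pure homology search
therefore misses much of the receptor repertoire, and assemblies from short
or pyrosequencing reads contain many partial transcripts for which a
full-length 7TM topology can never be observed. `sevenTMscreen` implements a
screening procedure built around these two constraints: it combines
sequence-similarity evidence with alignment-free and topology-based
predictors, and it deliberately retains partial candidates rather than
demanding seven helices of every ORF.

The pipeline stages are:

1. **ORF extraction** (`find_orfs`, `find_orfs_set`): every unigene is
   translated in all six reading frames; ORFs are *maximal stop-free runs*
   (stop-to-stop, or stop-to-sequence-end) of at least 50 amino acids. No
   start codon is required, because assembled fragments carry no guarantee of
   a complete 5' end; a 50-aa floor removes products too short to be any part
   of a receptor. Each ORF records the number of in-frame stop codons
   upstream and downstream — the signal used later to distinguish complete
   coding regions from truncated ones.
2. **Topology classification** (`classify_tm`, `classify_batch`): each ORF,
   with a transmembrane-helix count from TMHMM output (`parse_tmhmm`) or from
   the built-in hydropathy caller (`predict_tm_hydropathy`), is sorted by an
   explicit decision tree into `FULL_LENGTH`, `POSSIBLE_FULL_LENGTH`,
   `PARTIAL` or `DISCARDED`.
3. **Consensus** (`aggregate_evidence`, `basic_set`, `venn_partition`,
   `consistency_report`): verdicts from four approaches — alignment methods
   (BLAST plus Pfam, collapsed into one approach), the topology protocol, a
   dipeptide-composition SVM-style predictor and a multi-descriptor
   predictor — are merged per ORF into a "Pred. by" letter code over
   `T`, `A`, `G`, `P`. ORFs supported by at least three approaches form the
   basic candidate set; agreement between the two composition predictors'
   subfamily labels flags the most consistent candidates.
4. **Structure scoring** (`assign_helices`, `score_model`): 3D model chains
   of candidates are scored `+h` when all `h` assigned helices are intact and
   `-h` when any is broken; `+7` marks a strong full-length candidate, `+3`
   to `+6` a partial one.
5. **Phylogeny** (`p_distance_matrix`, `neighbor_joining`): candidates are
   related by a neighbor-joining tree over p-distances from a supplied
   multiple alignment.

## The topology decision tree

The classification uses three quantities per ORF: its length, its predicted
helix count, and its flanking stop counts. The thresholds (all configurable
via `topology_rules()`) are:

* **Length cut, 235 aa.** Seven helices of typical transmembrane length plus
  six loops need roughly this much protein; ORFs at or above 235 aa are
  "long" (could be a complete GPCR), shorter ones can only be partial.
* **Helix band, 6–8 for long and 3–6 for short ORFs.** A GPCR has exactly 7
  TM helices, but predicted counts wobble by one for real receptors; partial
  transcripts are expected to retain only part of the bundle.
* **Stop requirement, ≥ 2 in-frame stops on *both* sides.** A single
  bounding stop can be a sequencing or assembly artifact; two independent
  in-frame stops on each side argue the ORF is a complete coding region.

The tree is: a long ORF inside the helix band is a candidate —
`FULL_LENGTH` if the stop requirement holds, `POSSIBLE_FULL_LENGTH`
otherwise. A short ORF inside its band is `PARTIAL` *unless* the stop
requirement holds — in that case it is a complete protein that demonstrably
lacks the 7TM bundle, and is discarded. Everything outside the bands is
discarded. The decisive subtlety is that the stop requirement acts in
*opposite directions* for long and short ORFs, which is why the package
tests enumerate the whole (length × helices × stops) grid against an
independently written truth table.

Flanking stops are counted in the ORF's own frame and strand, and the
bounding stops count toward the totals (so a stop-delimited ORF has at least
(1, 1)); an ORF truncated by the sequence end has zero on that side. Codons
containing ambiguity codes translate to `X`, which neither terminates a run
nor counts as a stop — conservative toward keeping candidates.

## The hydropathy caller and its limits

`predict_tm_hydropathy` is a deliberately simple first-pass helix caller:
Kyte–Doolittle window means (window 19, cutoff 1.6), above-threshold
positions merged into runs, runs widened by half a window and dropped below
17 residues. It is useful for screening and for validating the synthetic
generator, but windowed hydropathy has a known physical limit: a loop
shorter than about half a window between two strongly hydrophobic helices
cannot push the window mean below threshold, so such neighbours fuse into
one called helix. Real GPCRs do have loops in that range. Consequently, on
synthetic 7TM proteins with 5–30 aa loops the caller returns 7 helices for
most draws but 6 (one fusion) or 5 (two fusions) for a substantial minority
— one reason the decision tree accepts 6–8 helices rather than exactly 7.
When loops are at least 10 aa the caller recovers exactly seven helices
almost always, and the tests pin both behaviours. The fidelity path for
topology is ingesting TMHMM output (`parse_tmhmm`, `tmhmm_to_topology`),
exactly as the screening procedure does when the external predictor is
available; when TMHMM records are supplied, the hydropathy caller is not
consulted at all.

## Composition descriptors and the stand-in classifier

`gpcr_features` provides the descriptor families used by
composition-based GPCR predictors: amino-acid and dipeptide composition,
Chou's type-1 pseudo amino acid composition (sequence-order correlation
factors over normalized hydropathy, hydrophilicity and side-chain mass,
weight `w = 0.05`, `lambda = 10` by default), Moreau–Broto autocorrelation
of standardized Kyte–Doolittle values, composition/transition/distribution
descriptors over the standard seven three-class property groupings, and
quasi-sequence-order coupling numbers. The residue-pair distance behind the
quasi-sequence-order block is, by default, the Euclidean distance in the
standardized three-property space already shipped for PseAAC; any 20 × 20
matrix (for instance a published physicochemical distance matrix) can be
passed instead. Non-standard residues (`X`, `B`, `Z`, `U`) are excluded from
every count.

`train_standin_classifier` is a nearest-centroid rule on column-standardized
descriptors. It exists so that the full four-approach consensus can be
exercised without the external web services; it is an explicit surrogate,
tagged as such in the evidence records, and parsing the real predictors'
output tables (`parse_prediction_table`) is the faithful route. A
nearest-centroid rule was chosen over a heavier learner because it is exactly
reproducible, order-invariant, parameter-free and sufficient to separate
membrane-biased from soluble composition — the only claim the synthetic
validation makes of it.

## Consensus rules

Evidence is reduced per ORF: an approach is positive if any of its records
is. The pred-by code concatenates positive approaches in the fixed order
`T`, `A`, `G`, `P`; the basic set keeps ORFs with at least three positive
approaches. Subfamily labels are compared after normalization (lowercase,
alphanumerics only, a small synonym map), so `"(Rhod)opsin"` and
`"Rhodopsin"` agree while a missing label (`"-"`) never does. The
consistency count requires topology (`T`) support by default — agreement
between the two composition predictors is only claimed for candidates whose
topology also looks receptor-like — and `require_tmhmm = FALSE` exposes the
unrestricted count; both behaviours are tested against the bundled 46-row
consensus table, where they give 17 and 18. Class-level agreement without
subfamily labels is tracked separately (`class_consistent`) and never enters
the subfamily-consistency count.

## Structure scoring

`assign_helices` works from declared HELIX records when a model file has
them, otherwise from backbone φ/ψ dihedrals (helical windows φ ∈ [−100, −30],
ψ ∈ [−80, 0], runs ≥ 6 residues). Two runs separated by at most 4 coil
residues are paired as one *broken* helix — a quantitative stand-in for
"broken in the middle", declared here rather than inferred — and an isolated
run must reach 15 residues to be intact, since a shorter fragment cannot
span a membrane. The signed score is `+h` or `−h`; the category map
(`+7` strong full-length, `+3..+6` partial, otherwise rejected) is exact by
construction and enumerated in the tests. The original procedure also
included a visual comparison of each model against curated GPCR structures;
that judgment is not automatable from a score, so the report instead carries
a `needs_review` flag for models with 6–8 helices. Ideal and deliberately
broken test chains are generated analytically (`build_helix_chain`, standard
backbone geometry, ω = 180°), and the dihedral code is cross-checked against
an independent implementation.

## Neighbor joining

`neighbor_joining` is the classical Saitou–Nei agglomeration with the
standard Q-criterion and branch-length formulas, a deterministic tie-break
(lowest row, then column, index), and clamping of negative branch estimates
to zero with a warning. On an additive matrix it recovers the generating
tree exactly (topology and lengths), which the tests verify on random trees;
on noisy matrices it is cross-checked against an independent implementation.
Distances default to p-distances over gap-free column pairs of a supplied
alignment — the alignment itself (an MSA tool's output) is consumed, not
computed, and no substitution model is layered on top, since the tree is
used for neighborhood structure among candidates rather than for divergence
dating. Newick export uses fixed 6-decimal branch lengths and quotes labels
containing metacharacters (candidate ORF ids contain parentheses).

## The synthetic benchmark

`generate_dataset` builds a transcriptome-like FASTA with per-unigene ground
truth. Intact receptors are seven hydrophobic helix blocks (19–25 aa, drawn
from `{L, I, V, F, M, A, W}` with weights favouring Leu/Ile/Val) joined by
mixed loops (5–30 aa, all residues with a mild hydrophilic bias) and
hydrophilic tails; membrane decoys have the same construction with 1–5 or
9–11 helices; soluble decoys are loop-composition sequences redrawn until
the hydropathy caller finds no helix, so their negative label holds by
construction. Proteins are reverse-translated with uniform synonymous codon
choice (no internal stops by construction), wrapped in random UTRs
(30–300 nt) carrying a bounding stop plus at least one planted in-frame stop
per side, placed on either strand with probability one half, and — for
partial transcripts — truncated so that 20–60% of the coding region and one
flank's stops are lost. The default dataset is 40 unigenes per class.

Because the topology source in the real procedure is an external predictor,
the generator also emulates its output (`emulate_tmhmm_records`): the
planted helix segments of each true coding ORF, mapped into ORF coordinates
(clipped fragments under 10 aa dropped, as a predictor would miss them), and
zero helices for every bystander ORF. This is an idealized emulation — it
has no prediction error — so end-to-end recovery tests validate the ORF
geometry, stop-count bookkeeping, parsing and classification logic, *not*
any claim about predictor accuracy on real data. Likewise the generator does
not simulate sequencing error, frameshifts, codon-usage bias or assembly
artifacts, so passing recovery tests say nothing about robustness to those;
frameshift simulation in particular would break the stop-count semantics and
is left as an extension.

Problem sizes used in the shipped validation: the ORF finder is checked
against a brute-force six-frame scan on 1,000 random unigenes of 150–700 nt;
recovery runs on the default 160-unigene dataset; classifier validation is a
5-fold cross-validation of receptor-vs-soluble on the true coding proteins
with a binomial confidence interval.

## Numerical and design choices

* Coordinates are 0-based half-open internally; parsed external formats
  (TMHMM, PDB) keep their native 1-based inclusive convention, with
  conversion at the module boundary.
* E-value filters use strict inequality (`evalue < cutoff`), so a hit at
  exactly the cutoff is dropped.
* The ORF id scheme `<unigene>_<len>(length)_<strand>(strand)_<frame>(frame)`
  is not injective; collisions get a positional `#k` suffix in reports while
  preserving the core format.
* Helix-band boundaries are inclusive; the length cut compares with `>=`
  (234 aa is short, 235 aa long).
* The stand-in classifier's confidence is a logistic transform of the margin
  between the two nearest centroids — monotone in the margin and bounded in
  [0.5, 1], not a calibrated probability.
* All stochastic components (generator, classifier seeds) are driven by
  explicit integer seeds; identical configuration reruns produce
  byte-identical report bundles, which the tests assert.

## Known limitations

* The hydropathy caller fuses helices across short loops (see above); treat
  its counts as a screen, not a topology.
* The consensus quality is bounded by its inputs: with only stand-in
  classifiers, the `G`/`P` letters carry membrane-vs-soluble composition
  signal, not family-level knowledge.
* Subfamily normalization is a string operation with a small synonym map; it
  does not consult any receptor ontology.
* The structure score counts helix integrity only; it cannot reproduce a
  curator's judgment that a fold "looks like" a receptor bundle.
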