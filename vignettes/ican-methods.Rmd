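---
title: "Carbon-neighborhood counting arrays: methods and design notes"
author: "ican package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-neighborhood counting arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ican)
```

## The encoding

Most machine-learning models want fixed-length, structured numeric input;
most molecular representations are variable-length strings or graphs. The
iCAN encoding (interpretable Carbon-based Array of Neighborhoods) bridges
the two by exploiting the fact that organic molecules — peptides and
proteins in particular — are organized around a carbon backbone. For every
carbon atom of a molecule the encoding records, per neighborhood level
$\ell$, how many atoms of each element sit at shortest-path graph distance
exactly $\ell$ from that carbon. Arranged with one column per backbone
carbon (in a fixed traversal order) and one row per (element, level) pair,
this gives the *counting array*

$$ A[(e,\ell),\, j] \;=\; \bigl|\{\, u : d(c_j, u) = \ell,\ \mathrm{elem}(u) = e \,\}\bigr|, $$

where $c_j$ is the $j$-th backbone carbon and $d$ is the unweighted
shortest-path distance over the full atom graph, explicit hydrogens
included. The array is integer-valued, deterministic, and readable: column
$j$ literally describes the chemical surroundings of the $j$-th carbon, so
a trained model's feature importances can be mapped back onto positions and
elements of the molecule.

The pipeline is:

1. **Input.** Peptides in FASTA (20 standard single-letter codes) or any
   organic molecule as SMILES. Peptides are converted to SMILES by N-to-C
   condensation of per-residue fragments — one water removed per peptide
   bond, free N-terminal amine, free C-terminal acid. Letters outside the
   20 standard codes (B, J, O, U, X, Z) are rejected rather than guessed;
   exotic residues should be supplied as SMILES directly.
2. **Graph.** SMILES are parsed (OpenBabel, via ChemmineOB) into an
   element-labeled graph; aromatic notation is kekulized and hydrogens are
   made explicit so that hydrogen counts are well defined. Heavy atoms keep
   their order of first appearance in the SMILES text; this ordinal is the
   only source of ordering in the whole encoding, which is what makes the
   encoding a pure function of the input text.
3. **Backbone indexing.** The carbon-induced subgraph is traversed
   depth-first from the carbon with the smallest ordinal; at a branch the
   unvisited neighbor carbons are taken in ascending ordinal order, each
   branch exhausted before the next; a carbon reached again through a ring
   closure is not revisited, so cycles are *opened* into a linear stretch of
   the column order. Extra connected components (dot-separated SMILES
   fragments, e.g. salts) follow, each traversed the same way.
4. **Counting.** Per carbon and level, element occurrences are tallied for
   the chosen alphabet. Bond order never matters: a double bond is one
   adjacency. Ring closures *do* count as adjacencies — opening a cycle is
   a statement about column order, not about deleting bonds.
5. **Flattening.** Arrays are flattened column by column and zero-padded at
   the tail to the data-set maximum carbon count, giving one fixed-length
   vector per molecule. The layout (alphabet, levels, maximum carbons) is
   stored alongside so any vector — including a feature-importance vector —
   can be un-flattened back into array coordinates.

## Tunable parameters

* **Alphabet mode.** `mode1` counts H, C, N, O, S — the five most abundant
  elements in proteins, in that fixed row order. `mode2` drops hydrogen
  (C, N, O, S), halving sensitivity to protonation bookkeeping. `mode3` is
  data-driven: every element present in the input set, ordered H, C, N, O,
  S first, then alphabetically. For data sets of standard peptides the
  three modes carry nearly the same information; mode 3 matters for
  halogenated or otherwise exotic molecules. Default: mode 1.
* **Neighborhood levels** (`levels`, default 2). Level 1 is immediate
  bonding; level 2 adds the second shell, which distinguishes e.g. a
  hydroxyl carbon from a carboxyl carbon. Using both first- and
  second-level information is the default because it measurably helps
  classification while keeping the feature count at
  $|\text{alphabet}| \times 2 \times \max_j(\text{carbons})$.
* **Harness settings.** The evaluation harness pins the random-forest
  configuration in code — 100 trees, Gini impurity, $\sqrt{p}$ feature
  subsampling, minimum node size 1, bootstrap sampling — so that "default
  hyper-parameters" cannot drift with dependency upgrades. Cross-validation
  is stratified 5-fold, 10 repeats, with every seed derived from one master
  seed (default 42); feature importances are mean-decrease-in-impurity,
  normalized to sum to one. The Mann–Whitney U comparison of two score
  distributions is one-sided by default ("is encoding A actually better?"),
  uses the normal approximation with tie and continuity corrections —
  repeated-CV F1 samples are heavily tied, so an exact permutation null is
  unavailable anyway — and flags significance at $\alpha = 0.05$.

## Design choices where the design was open

* **Traversal start and tie-breaks.** Nothing canonical forces a
  particular start carbon or branch order; we fix smallest-ordinal start
  and ascending-ordinal branches because they are deterministic and
  reproducible from the SMILES text alone. The cost is that the column
  order is a property of the *written* SMILES, not of the abstract
  molecule — two SMILES of the same molecule can encode differently. We
  deliberately do not canonicalize (Morgan/InChI ranking): the encoding is
  defined relative to the input ordering, and canonicalization would change
  the meaning of "position $j$" under the user's feet.
* **Distances over the full graph.** Shortest paths are computed with
  hydrogens present. Since hydrogens have degree 1 they can never shorten a
  heavy-atom path, so this agrees with the hydrogen-free reading as well.
* **Terminal groups of converted peptides.** The converter produces the
  free acid and free amine termini (no amidation), the most common neutral
  form.
* **Row order within a level.** H, C, N, O, S — the order in which the
  array rows are conventionally walked through (hydrogen row first, then
  carbon, nitrogen, oxygen, sulfur). Level blocks are level-major: all
  elements at level 1, then all at level 2.
* **Padding.** Trailing, value 0 — zero already means "no atoms here", so
  padding is indistinguishable from genuinely empty neighborhoods beyond
  the molecule's end, which is the intended semantics.
* **All-zero arrays.** Grayscale normalization divides by the array
  maximum; for an all-zero array that rule divides by zero, and we define
  the result as all white (no signal).
* **Image normalization scope** is per-molecule by default (each array
  divided by its own maximum); a global maximum can be passed for
  cross-molecule comparability.
* **Lenient SMILES readers.** OpenBabel silently repairs some malformed
  SMILES (e.g. an unclosed parenthesis). A token-level validator in front
  of the conversion rejects unbalanced parentheses/brackets, unpaired
  ring-closure digits and out-of-grammar tokens with an error naming the
  offending token, so that typos fail loudly instead of encoding the wrong
  molecule.

## The synthetic-data generators

`genRandomPeptides` draws i.i.d. uniform sequences over the 20 standard
codes — a composition null, not a model of any organism's proteome.

`genSeparableTask` is the acceptance fixture for the whole
encode–classify–explain loop, and its design is worth spelling out. The
labeling rule is: positive iff the sequence contains at least one
sulfur-bearing residue (Cys or Met). Sulfur is the rarest of the five
mode-1 elements, so the sulfur rows of the encoding are the unambiguous
expected "hot" rows of a relevance heat map. For the signal to be
*learnable by a default random forest*, and not merely present, the sulfur
features must line up across peptides: a forest splits on one feature at a
time, and a signal smeared over 75 sparse position-specific columns is
invisible to it even when a row-sum would separate the classes perfectly.
The generator therefore uses an alanine/serine background — Ala, Ser and
Cys all contribute exactly three backbone carbons, so residue $r$ always
occupies columns $3r-2 \ldots 3r$ — with cysteines placed in positives at a
per-position rate of 0.3 (at least one forced), lengths 8–12. This
emulates the real contrast between cysteine-rich peptide families (e.g.
defensins) and cysteine-free peptides. What passing the harness check does
*not* show: performance on natural, compositionally diverse peptides,
where class signals are weaker and positionally unstable — that is exactly
the regime the published benchmark data sets probe, and it is out of scope
here.

## Numerical and scale notes

* Everything in the encoder is integer arithmetic; no tolerances are
  involved. Determinism of the harness relies on single-threaded forest
  fitting and per-repeat seeds derived from the master seed.
* Problem sizes used by the test suite: fixture molecules up to 30 atoms
  against a brute-force all-pairs-shortest-path oracle; 100 random
  peptides for round-trip checks; the n = 200 sulfur task under the full
  5 × 10 CV; 1,000 simulated null pairs for the U test's type-I error;
  encoding-time scaling measured on 100–10,000 total residues.
* The V2000 molfile format used in the SMILES-to-graph conversion caps a
  single connected molecule at 999 atoms (roughly a 50–60-residue
  peptide). Larger proteins should be encoded per-domain or supplied as
  pre-built graphs; lifting this is future work.
* Stereochemistry is not encoded (the graph distance of an atom does not
  depend on chirality), and bond multiplicity is deliberately ignored.

## A compact worked example

```{r phenol}
g <- parseSmiles("C1=CC=C(C=C1)O")   # phenol, C6H6O
ca <- encodeMolecule(g, buildAlphabet("mode1"), levels = 1)
counts(ca)
```

Each of the six columns is one ring carbon in traversal order; the fourth
carries the hydroxyl (one O neighbor, no H on the ring carbon), every
other ring carbon sees one hydrogen and two carbons. `arrayToImage(ca)`
turns this table into a 5 × 6 grayscale image with the C row uniformly
dark — the visual signature of an aromatic ring.
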