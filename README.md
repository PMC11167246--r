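# ican — interpretable carbon-based array-of-neighborhoods encodings

Machine-learning models for peptide and small-molecule classification need
fixed-length, structured numeric input, but molecules come as
variable-length sequences and graphs. `ican` implements the iCAN encoding
(interpretable Carbon-based Array of Neighborhoods): a deterministic
fingerprint that walks the carbon backbone of a molecule and records, for
every backbone carbon *c<sub>j</sub>* and neighborhood level ℓ, the number
of atoms of each element at shortest-path distance exactly ℓ:

&nbsp;&nbsp;&nbsp;&nbsp;*A*[(e, ℓ), j] = |{ u : d(c<sub>j</sub>, u) = ℓ, elem(u) = e }|

Columns of the counting array *A* are the backbone carbons in a fixed,
deterministic traversal order (depth-first, branches in atom-ordinal order,
cycles opened); rows are (element, level) pairs over a chosen element
alphabet — H, C, N, O, S by default. Because every feature has an explicit
chemical meaning ("how many oxygens touch carbon 4"), classifier feature
importances can be mapped straight back onto the molecule as relevance
heat maps.

The package is aimed at cheminformatics and peptide-ML practitioners and
covers the full loop:

* FASTA → SMILES conversion for the 20 standard residues
  (N-to-C condensation, one water per peptide bond);
* SMILES → explicit-hydrogen molecular graphs (OpenBabel underneath);
* deterministic backbone indexing and per-level neighbor directories;
* counting arrays, flattening and zero-padding into ML-ready matrices
  (`EncodedDataset`, a `SummarizedExperiment`);
* grayscale image export and relevance heat maps;
* a seeded evaluation harness: random forest under repeated stratified
  5×10 cross-validation, binary F1, impurity feature importances, and
  Mann–Whitney U comparison of two encodings' score distributions;
* synthetic peptide generators so everything is testable offline.

## Worked example

Phenol (`C1=CC=C(C=C1)O`, C₆H₆O) under the default alphabet at level 1:

```r
library(ican)
g  <- parseSmiles("C1=CC=C(C=C1)O")
ca <- encodeMolecule(g, buildAlphabet("mode1"), levels = 1)
counts(ca)
#>      C1 C2 C3 C4 C5 C6
#> H_L1  1  1  1  0  1  1
#> C_L1  2  2  2  2  2  2
#> N_L1  0  0  0  0  0  0
#> O_L1  0  0  0  1  0  0
#> S_L1  0  0  0  0  0  0
```

Six columns — one per ring carbon in traversal order. Column 4 is the
hydroxyl-bearing carbon: no hydrogen, two carbons, one oxygen. The C row is
uniformly 2 (every ring carbon touches two ring carbons);
`writeGrayImage(arrayToImage(ca, zoom = 20), "phenol.png")` renders the
same table as an image with a uniformly dark carbon row.

The classification loop on a synthetic sulfur task (positives are
cysteine-containing peptides, negatives cysteine-free):

```r
task <- genSeparableTask(n = 200, seed = 7)
ed   <- encodeDataset(task@sequences, mode = 1, levels = 2)
res  <- evaluateEncoding(ed, task@labels, folds = 5, repeats = 10, seed = 42)
meanF1(res)
#> [1] 0.956477

imp <- computeFeatureImportances(ed, task@labels, seed = 42)
rd  <- SummarizedExperiment::rowData(ed)
sort(tapply(imp, paste0(rd$element, "_L", rd$level), sum), decreasing = TRUE)[1:3]
#>     S_L1     S_L2     H_L2
#> 0.339755 0.320208 0.109891
```

The forest recovers the class signal (mean F1 0.956 over 50 folds) and the
sulfur rows carry the bulk of the importance — exactly where the signal was
planted. `renderRelevanceHeatmap(imp, ed, "heat.png")` draws those rows hot.

A thin command-line front end over the same functions lives at
`inst/scripts/ican.R`
(`encode`, `image`, `heatmap`, `evaluate`, `compare`, `fixtures`).

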