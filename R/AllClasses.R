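#' @import methods
NULL

#' Labeled molecular graph with explicit hydrogens
#'
#' An undirected, element-labeled graph of a single (possibly multi-fragment)
#' molecule. Atom ordinals follow first appearance in the source SMILES
#' string; explicit hydrogens are appended after the heavy atoms. Bond orders
#' are recorded but all neighborhood operations treat a bond as a single
#' adjacency.
#'
#' @slot elements character vector of IUPAC element symbols, one per atom,
#'   in atom-ordinal order.
#' @slot bonds two-column integer matrix of atom ordinals (1-based), one row
#'   per bond; no self-loops.
#' @slot bondOrders integer vector of formal bond orders parallel to
#'   \code{bonds}.
#' @slot smiles the SMILES string the graph was built from.
#'
#' @seealso [parseSmiles()], [indexCarbons()], [neighborDirectory()]
#' @export
setClass("MolGraph",
  slots = c(
    elements   = "character",
    bonds      = "matrix",
    bondOrders = "integer",
    smiles     = "character"
  )
)

setValidity("MolGraph", function(object) {
  msg <- character(0)
  n <- length(object@elements)
  b <- object@bonds
  if (!is.numeric(b) || ncol(b) != 2L)
    return("bonds must be a two-column numeric matrix")
  if (nrow(b) != length(object@bondOrders))
    msg <- c(msg, "bondOrders length must equal the number of bonds")
  if (nrow(b) > 0) {
    if (any(b < 1L) || any(b > n))
      msg <- c(msg, "bond endpoints out of atom range")
    if (any(b[, 1L] == b[, 2L]))
      msg <- c(msg, "self-loop bonds are not allowed")
  }
  if (!all(grepl("^[A-Z][a-z]?$", object@elements)))
    msg <- c(msg, "element symbols must be IUPAC symbols (e.g. C, Cl)")
  hyd <- which(object@elements == "H")
  if (length(hyd) > 0 && nrow(b) > 0) {
    deg <- tabulate(c(b[, 1L], b[, 2L]), nbins = n)
    if (any(deg[hyd] != 1L))
      msg <- c(msg, "hydrogen atoms must have degree exactly 1")
  }
  if (length(msg)) msg else TRUE
})

#' Ordered element alphabet for neighborhood counting
#'
#' The ordered set of element symbols whose occurrences are tallied per
#' carbon neighborhood. Three modes exist: \code{mode1} is the fixed list
#' H, C, N, O, S (the five most abundant elements in proteins); \code{mode2}
#' drops hydrogen (C, N, O, S); \code{mode3} is data-driven and holds every
#' element present in the input set, in canonical order (H, C, N, O, S first
#' where present, remaining symbols alphabetically).
#'
#' @slot mode one of \code{"mode1"}, \code{"mode2"}, \code{"mode3"}.
#' @slot symbols ordered character vector of unique element symbols.
#'
#' @seealso [buildAlphabet()]
#' @export
setClass("ElementAlphabet",
  slots = c(mode = "character", symbols = "character")
)

setValidity("ElementAlphabet", function(object) {
  msg <- character(0)
  if (!(object@mode %in% c("mode1", "mode2", "mode3")))
    msg <- c(msg, "mode must be one of 'mode1', 'mode2', 'mode3'")
  if (anyDuplicated(object@symbols))
    msg <- c(msg, "alphabet symbols must be unique")
  if (object@mode == "mode1" &&
      !identical(object@symbols, c("H", "C", "N", "O", "S")))
    msg <- c(msg, "mode1 alphabet must be exactly H, C, N, O, S")
  if (object@mode == "mode2" &&
      !identical(object@symbols, c("C", "N", "O", "S")))
    msg <- c(msg, "mode2 alphabet must be exactly C, N, O, S")
  if (length(msg)) msg else TRUE
})

#' Per-molecule counting array
#'
#' The core encoding of one molecule: an integer matrix whose columns are the
#' backbone carbons in traversal order and whose rows are (element, level)
#' pairs, level-major (all alphabet elements at level 1, then all at level 2,
#' and so on). Entry (e, l, j) is the number of atoms of element e whose
#' shortest-path distance from backbone carbon j is exactly l.
#'
#' @slot counts integer matrix, \code{length(symbols) * levels} rows by
#'   number-of-carbons columns.
#' @slot alphabet the [ElementAlphabet-class] used.
#' @slot levels number of neighborhood levels encoded.
#' @slot carbons integer vector of carbon atom ordinals in traversal
#'   (column) order.
#' @slot smiles source SMILES of the molecule.
#'
#' @seealso [encodeMolecule()], [arrayToImage()], [flattenEncodings()]
#' @export
setClass("CountingArray",
  slots = c(
    counts   = "matrix",
    alphabet = "ElementAlphabet",
    levels   = "integer",
    carbons  = "integer",
    smiles   = "character"
  )
)

setValidity("CountingArray", function(object) {
  msg <- character(0)
  K <- length(object@alphabet@symbols)
  if (nrow(object@counts) != K * object@levels)
    msg <- c(msg, "row count must equal |alphabet| * levels")
  if (ncol(object@counts) != length(object@carbons))
    msg <- c(msg, "column count must equal the number of backbone carbons")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (object@levels < 1L)
    msg <- c(msg, "levels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Encoded data set of flattened, zero-padded counting arrays
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"encoding"} assay
#' holds one column per molecule and one row per feature, where features are
#' the counting-array cells flattened column-by-column (backbone position
#' major, then level, then element) and zero-padded to the data-set maximum
#' carbon count. Row data records the (element, level, carbon position) of
#' every feature; column data records per-molecule SMILES and true carbon
#' counts; \code{metadata()} stores the layout (mode, symbols, levels,
#' maxCarbons) needed to un-flatten any column.
#'
#' @seealso [encodeDataset()], [flattenEncodings()], [unflattenVector()],
#'   [featureMatrix()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("EncodedDataset", contains = "SummarizedExperiment")

setValidity("EncodedDataset", function(object) {
  msg <- character(0)
  lay <- S4Vectors::metadata(object)$layout
  if (is.null(lay) ||
      !all(c("mode", "symbols", "levels", "maxCarbons") %in% names(lay)))
    return("metadata()$layout must hold mode, symbols, levels, maxCarbons")
  expected <- length(lay$symbols) * lay$levels * lay$maxCarbons
  if (nrow(object) != expected)
    msg <- c(msg, sprintf("feature count %d != |alphabet|*levels*maxCarbons = %d",
                          nrow(object), expected))
  if (!("nCarbons" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must record nCarbons per molecule")
  if (length(msg)) msg else TRUE
})

#' Grayscale image of a counting array
#'
#' One pixel per array cell, intensity in [0, 1] where 0 renders white and 1
#' renders black. Produced by normalizing a counting array by its maximum
#' entry.
#'
#' @slot pixels numeric matrix in [0, 1], same shape as the source array.
#' @slot zoom integer magnification applied on export (each cell becomes a
#'   zoom-by-zoom pixel block).
#'
#' @seealso [arrayToImage()], [writeGrayImage()]
#' @export
setClass("GrayscaleImage",
  slots = c(pixels = "matrix", zoom = "integer")
)

setValidity("GrayscaleImage", function(object) {
  msg <- character(0)
  if (any(object@pixels < 0) || any(object@pixels > 1))
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (object@zoom < 1L)
    msg <- c(msg, "zoom must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' Per-fold positive-class F1 scores from repeated stratified k-fold
#' cross-validation of a random forest on an encoded data set, together with
#' the seed and the pinned classifier configuration that make the run
#' reproducible.
#'
#' @slot scores numeric matrix, folds rows by repeats columns, each entry a
#'   binary F1 score in [0, 1].
#' @slot seed master seed of the run.
#' @slot positive label treated as the positive class.
#' @slot config list of pinned random-forest and CV settings.
#'
#' @seealso [evaluateEncoding()], [compareScoreDistributions()]
#' @export
setClass("CVResult",
  slots = c(
    scores   = "matrix",
    seed     = "integer",
    positive = "character",
    config   = "list"
  )
)

setValidity("CVResult", function(object) {
  msg <- character(0)
  s <- object@scores
  if (any(is.na(s)) || any(s < 0) || any(s > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Mann-Whitney U comparison of two score distributions
#'
#' @slot statistic the U statistic of the first sample against the second.
#' @slot pValue p-value under the normal approximation with continuity and
#'   tie correction.
#' @slot alternative direction of the test ("greater", "less", "two.sided").
#' @slot alpha significance level.
#' @slot significant whether pValue < alpha.
#'
#' @seealso [compareScoreDistributions()]
#' @export
setClass("ComparisonResult",
  slots = c(
    statistic   = "numeric",
    pValue      = "numeric",
    alternative = "character",
    alpha       = "numeric",
    significant = "logical"
  )
)

setValidity("ComparisonResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    "pValue must lie in [0, 1]" else TRUE
})

#' Synthetic labeled peptide classification task
#'
#' A set of random peptide sequences with binary labels generated by a pure
#' function of the sequence (e.g. presence of a sulfur-bearing residue), used
#' to exercise the encoding and evaluation pipeline without external data.
#'
#' @slot sequences an [Biostrings::AAStringSet-class] of peptide sequences.
#' @slot labels integer vector of 0/1 labels parallel to \code{sequences}.
#' @slot rule human-readable description of the labeling rule.
#' @slot seed seed the task was generated from.
#'
#' @seealso [genSeparableTask()]
#' @export
#' @importClassesFrom Biostrings AAStringSet
setClass("SyntheticTask",
  slots = c(
    sequences = "AAStringSet",
    labels    = "integer",
    rule      = "character",
    seed      = "integer"
  )
)

setValidity("SyntheticTask", function(object) {
  msg <- character(0)
  if (length(object@sequences) != length(object@labels))
    msg <- c(msg, "labels must be parallel to sequences")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be binary 0/1")
  if (length(unique(object@labels)) < 2L)
    msg <- c(msg, "both classes must be non-empty")
  if (length(msg)) msg else TRUE
})
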