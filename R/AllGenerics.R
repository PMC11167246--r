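#' Accessors for the encoding classes
#'
#' Small accessor generics: \code{atomElements} and \code{atomBonds} expose a
#' [MolGraph-class]; \code{alphabetSymbols} and \code{alphabetMode} expose an
#' [ElementAlphabet-class] (or the alphabet of a [CountingArray-class]);
#' \code{neighborLevels} gives the number of encoded levels; \code{carbonIds}
#' the backbone carbon ordinals in column order; \code{cvScores} the per-fold
#' F1 matrix of a [CVResult-class] and \code{meanF1} its mean.
#'
#' @param x an object of the documented classes.
#' @return the slot value described above.
#' @name accessors
#' @aliases atomElements atomBonds alphabetSymbols alphabetMode
#'   neighborLevels carbonIds cvScores meanF1
#' @examples
#' g <- parseSmiles("CC")
#' atomElements(g)
#' ca <- encodeMolecule(g, buildAlphabet("mode1"), levels = 1)
#' alphabetSymbols(ca)
#' carbonIds(ca)
NULL

#' @rdname accessors
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))
#' @rdname accessors
#' @export
setGeneric("atomBonds", function(x) standardGeneric("atomBonds"))
#' @rdname accessors
#' @export
setGeneric("alphabetSymbols", function(x) standardGeneric("alphabetSymbols"))
#' @rdname accessors
#' @export
setGeneric("alphabetMode", function(x) standardGeneric("alphabetMode"))
#' @rdname accessors
#' @export
setGeneric("neighborLevels", function(x) standardGeneric("neighborLevels"))
#' @rdname accessors
#' @export
setGeneric("carbonIds", function(x) standardGeneric("carbonIds"))
#' @rdname accessors
#' @export
setGeneric("cvScores", function(x) standardGeneric("cvScores"))
#' @rdname accessors
#' @export
setGeneric("meanF1", function(x) standardGeneric("meanF1"))

#' @rdname accessors
#' @export
setMethod("atomElements", "MolGraph", function(x) x@elements)
#' @rdname accessors
#' @export
setMethod("atomBonds", "MolGraph", function(x) x@bonds)

#' @rdname accessors
#' @export
setMethod("alphabetSymbols", "ElementAlphabet", function(x) x@symbols)
#' @rdname accessors
#' @export
setMethod("alphabetMode", "ElementAlphabet", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("alphabetSymbols", "CountingArray", function(x) x@alphabet@symbols)
#' @rdname accessors
#' @export
setMethod("alphabetMode", "CountingArray", function(x) x@alphabet@mode)
#' @rdname accessors
#' @export
setMethod("neighborLevels", "CountingArray", function(x) x@levels)
#' @rdname accessors
#' @export
setMethod("carbonIds", "CountingArray", function(x) x@carbons)

#' Counting-array matrix
#'
#' Returns the integer matrix of a [CountingArray-class]: rows are
#' (element, level) pairs level-major, columns are backbone carbons in
#' traversal order.
#'
#' @param object a [CountingArray-class].
#' @param ... ignored.
#' @return labeled integer matrix.
#' @importFrom BiocGenerics counts
#' @aliases counts,CountingArray-method
#' @examples
#' counts(encodeMolecule(parseSmiles("C"), buildAlphabet("mode1"), 1))
#' @export
setMethod("counts", "CountingArray", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("cvScores", "CVResult", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("meanF1", "CVResult", function(x) mean(x@scores))

setMethod("show", "MolGraph", function(object) {
  tab <- table(object@elements)
  cat("MolGraph:", length(object@elements), "atoms,",
      nrow(object@bonds), "bonds\n")
  cat("  formula:",
      paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = ""), "\n")
  cat("  smiles: ", object@smiles, "\n", sep = "")
})

setMethod("show", "ElementAlphabet", function(object) {
  cat("ElementAlphabet (", object@mode, "): ",
      paste(object@symbols, collapse = ", "), "\n", sep = "")
})

setMethod("show", "CountingArray", function(object) {
  cat("CountingArray: ", nrow(object@counts), " x ", ncol(object@counts),
      " (", length(object@alphabet@symbols), " elements x ", object@levels,
      " levels; ", ncol(object@counts), " backbone carbons)\n", sep = "")
  cat("  smiles: ", object@smiles, "\n", sep = "")
  print(object@counts)
})

setMethod("show", "GrayscaleImage", function(object) {
  cat("GrayscaleImage: ", nrow(object@pixels), " x ", ncol(object@pixels),
      " pixels (zoom ", object@zoom, "); 0 = white, 1 = black\n", sep = "")
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult: ", nrow(object@scores), " folds x ", ncol(object@scores),
      " repeats, seed ", object@seed, "\n", sep = "")
  cat(sprintf("  mean F1 = %.4f (sd %.4f), positive class '%s'\n",
              mean(object@scores), stats::sd(object@scores),
              object@positive))
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult (Mann-Whitney U, ", object@alternative, ")\n",
      sep = "")
  cat(sprintf("  U = %.1f, p = %.4g, alpha = %g -> %ssignificant\n",
              object@statistic, object@pValue, object@alpha,
              if (object@significant) "" else "not "))
})

setMethod("show", "SyntheticTask", function(object) {
  cat("SyntheticTask:", length(object@sequences), "peptides (",
      sum(object@labels == 1L), "positive /", sum(object@labels == 0L),
      "negative ), seed", object@seed, "\n")
  cat("  rule:", object@rule, "\n")
})
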