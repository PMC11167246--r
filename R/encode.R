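#' Build an element alphabet
#'
#' Mode 1 is the fixed five-element list H, C, N, O, S (the most abundant
#' elements in proteins, in the row order of the counting array); mode 2
#' excludes hydrogen (C, N, O, S); mode 3 is data-driven and collects every
#' element present in the supplied molecular graphs, canonical order.
#'
#' @param mode \code{"mode1"}, \code{"mode2"} or \code{"mode3"} (the bare
#'   integers 1, 2, 3 are also accepted).
#' @param graphs list of [MolGraph-class] objects; required for mode 3.
#' @return an [ElementAlphabet-class].
#' @examples
#' buildAlphabet("mode1")
#' buildAlphabet(3, list(parseSmiles("C1=CC=C(C=C1)O")))
#' @export
buildAlphabet <- function(mode, graphs = NULL) {
  if (is.numeric(mode)) mode <- paste0("mode", mode)
  mode <- match.arg(mode, c("mode1", "mode2", "mode3"))
  symbols <- switch(mode,
    mode1 = c("H", "C", "N", "O", "S"),
    mode2 = c("C", "N", "O", "S"),
    mode3 = {
      if (is.null(graphs) || length(graphs) == 0L)
        stop("mode3 is data-driven: supply the list of molecular graphs")
      collectUniqueElements(graphs)
    })
  methods::new("ElementAlphabet", mode = mode, symbols = symbols)
}

#' Encode one molecule into a counting array
#'
#' Walks the indexed carbon backbone and, for every carbon and every
#' neighborhood level, counts the atoms of each alphabet element at exactly
#' that shortest-path distance. Rows are level-major: all alphabet elements
#' at level 1 first, then level 2, and so on; columns follow the backbone
#' traversal order. Elements outside the alphabet are not counted anywhere.
#'
#' @param graph a [MolGraph-class] (or a SMILES string, parsed on the fly).
#' @param alphabet an [ElementAlphabet-class].
#' @param levels number of neighborhood levels (>= 1); the default 2 uses
#'   first- and second-level neighborhoods.
#' @return a [CountingArray-class].
#' @examples
#' encodeMolecule(parseSmiles("C1=CC=C(C=C1)O"), buildAlphabet("mode1"), 1)
#' @export
encodeMolecule <- function(graph, alphabet, levels = 2L) {
  if (is.character(graph)) graph <- parseSmiles(graph)
  stopifnot(methods::is(graph, "MolGraph"),
            methods::is(alphabet, "ElementAlphabet"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  indexing <- indexCarbons(graph)
  dir <- neighborDirectory(graph, indexing, maxLevel = levels)
  syms <- alphabet@symbols
  K <- length(syms)
  m <- matrix(0L, nrow = K * levels, ncol = length(indexing))
  for (j in seq_along(indexing)) {
    for (lvl in seq_len(levels)) {
      tab <- table(dir[[j]][[lvl]])
      hit <- syms %in% names(tab)
      if (any(hit))
        m[(lvl - 1L) * K + which(hit), j] <-
          as.integer(tab[syms[hit]])
    }
  }
  rownames(m) <- paste0(rep(syms, times = levels),
                        "_L", rep(seq_len(levels), each = K))
  colnames(m) <- paste0("C", seq_along(indexing))
  methods::new("CountingArray", counts = m, alphabet = alphabet,
               levels = levels, carbons = indexing, smiles = graph@smiles)
}

# Feature names of the flattened layout, position-major:
# ELEM_L{level}_C{column} for column 1..maxCarbons, level 1..L, element 1..K.
.featureNames <- function(symbols, levels, maxCarbons) {
  K <- length(symbols)
  paste0(rep(symbols, times = levels * maxCarbons),
         "_L", rep(rep(seq_len(levels), each = K), times = maxCarbons),
         "_C", rep(seq_len(maxCarbons), each = K * levels))
}

#' Flatten counting arrays into a padded feature data set
#'
#' Flattens each molecule's counting array column-by-column into a single
#' vector and pads it with trailing zeros so that every vector has length
#' |alphabet| x levels x maxCarbons, where maxCarbons is the largest carbon
#' count in the set. All arrays must share one alphabet and level count.
#'
#' @param arrays list of [CountingArray-class] objects.
#' @param ids optional character vector of molecule identifiers.
#' @return an [EncodedDataset-class] (molecules in columns, features in
#'   rows); \code{metadata()$layout} records mode, symbols, levels and
#'   maxCarbons.
#' @examples
#' a <- buildAlphabet("mode1")
#' flattenEncodings(list(encodeMolecule(parseSmiles("CC"), a, 1),
#'                       encodeMolecule(parseSmiles("CCC"), a, 1)))
#' @export
flattenEncodings <- function(arrays, ids = NULL) {
  if (length(arrays) == 0L)
    stop("cannot flatten an empty list of counting arrays")
  stopifnot(all(vapply(arrays, methods::is, logical(1L), "CountingArray")))
  syms <- arrays[[1L]]@alphabet@symbols
  mode <- arrays[[1L]]@alphabet@mode
  levels <- arrays[[1L]]@levels
  same <- vapply(arrays, function(a)
    identical(a@alphabet@symbols, syms) && a@levels == levels, logical(1L))
  if (!all(same))
    stop("all counting arrays must share one alphabet and level count")
  if (is.null(ids)) ids <- paste0("mol", seq_along(arrays))
  stopifnot(length(ids) == length(arrays))

  maxC <- max(vapply(arrays, function(a) ncol(a@counts), integer(1L)))
  K <- length(syms)
  rowlen <- K * levels * maxC
  mat <- vapply(arrays, function(a) {
    v <- numeric(rowlen)
    nc <- ncol(a@counts)
    if (nc) v[seq_len(K * levels * nc)] <- as.vector(a@counts)
    v
  }, numeric(rowlen))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = rowlen)
  rownames(mat) <- .featureNames(syms, levels, maxC)
  colnames(mat) <- ids

  rowdat <- S4Vectors::DataFrame(
    element = rep(syms, times = levels * maxC),
    level   = rep(rep(seq_len(levels), each = K), times = maxC),
    carbon  = rep(seq_len(maxC), each = K * levels)
  )
  coldat <- S4Vectors::DataFrame(
    id       = ids,
    smiles   = vapply(arrays, function(a) a@smiles, character(1L)),
    nCarbons = vapply(arrays, function(a) ncol(a@counts), integer(1L))
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(encoding = mat),
    rowData = rowdat, colData = coldat,
    metadata = list(layout = list(mode = mode, symbols = syms,
                                  levels = levels, maxCarbons = maxC))
  )
  methods::new("EncodedDataset", se)
}

#' Layout of an encoded data set
#'
#' @param x an [EncodedDataset-class], or a layout list.
#' @return list with elements \code{mode}, \code{symbols}, \code{levels},
#'   \code{maxCarbons}.
#' @export
encodingLayout <- function(x) {
  if (methods::is(x, "EncodedDataset")) return(S4Vectors::metadata(x)$layout)
  stopifnot(is.list(x),
            all(c("symbols", "levels", "maxCarbons") %in% names(x)))
  x
}

#' Feature matrix for machine learning
#'
#' The encoded data set transposed to the orientation classifiers expect:
#' one row per molecule, one column per feature.
#'
#' @param x an [EncodedDataset-class].
#' @return numeric matrix, molecules x features.
#' @export
featureMatrix <- function(x) {
  stopifnot(methods::is(x, "EncodedDataset"))
  t(SummarizedExperiment::assay(x, "encoding"))
}

#' Un-flatten a padded feature vector back into array coordinates
#'
#' Exact inverse of the column-by-column flattening used by
#' [flattenEncodings()]: reshapes a padded vector into the
#' (|alphabet| x levels) by maxCarbons matrix, including the all-zero padding
#' columns.
#'
#' @param v numeric vector of length |alphabet| x levels x maxCarbons.
#' @param layout an [EncodedDataset-class] or its layout list.
#' @return labeled numeric matrix in counting-array coordinates.
#' @export
unflattenVector <- function(v, layout) {
  lay <- encodingLayout(layout)
  K <- length(lay$symbols)
  expected <- K * lay$levels * lay$maxCarbons
  if (length(v) != expected)
    stop("vector length ", length(v),
         " does not match the layout's padded length ", expected)
  m <- matrix(v, nrow = K * lay$levels, ncol = lay$maxCarbons)
  rownames(m) <- paste0(rep(lay$symbols, times = lay$levels),
                        "_L", rep(seq_len(lay$levels), each = K))
  colnames(m) <- paste0("C", seq_len(lay$maxCarbons))
  m
}

#' Encode a set of molecules or peptides into one feature data set
#'
#' End-to-end pipeline: reads FASTA or SMILES input, converts peptide
#' sequences to SMILES by residue condensation, parses every molecule into a
#' graph with explicit hydrogens, builds the element alphabet (data-driven
#' for mode 3), encodes each molecule and assembles the flattened,
#' zero-padded feature matrix. Deterministic: identical inputs and
#' configuration give identical output.
#'
#' Per-record parse failures are collected and reported as a warning naming
#' the failing records; the run aborts only if every record fails.
#'
#' @param input one of: path to a FASTA file; path to a SMILES file (one per
#'   line, optionally CSV with a \code{column}); an
#'   [Biostrings::AAStringSet-class]; a character vector of sequences or
#'   SMILES.
#' @param mode element-alphabet mode (1, 2 or 3).
#' @param levels neighborhood levels (default 2).
#' @param format \code{"auto"} (by file extension / content), \code{"fasta"}
#'   or \code{"smiles"}.
#' @param column CSV column name holding SMILES, when input is a CSV file.
#' @return an [EncodedDataset-class].
#' @examples
#' ed <- encodeDataset(c(p1 = "GG"), mode = 1, levels = 2, format = "fasta")
#' dim(ed)
#' @export
encodeDataset <- function(input, mode = "mode1", levels = 2L,
                          format = c("auto", "fasta", "smiles"),
                          column = "smiles") {
  format <- match.arg(format)
  rec <- .resolveInput(input, format, column)
  smiles <- rec$smiles
  ids <- rec$ids

  graphs <- vector("list", length(smiles))
  errs <- character(0)
  for (i in seq_along(smiles)) {
    graphs[i] <- list(tryCatch(parseSmiles(smiles[[i]]),
                               error = function(e) {
      errs <<- c(errs, paste0(ids[[i]], ": ", conditionMessage(e)))
      NULL
    }))
  }
  ok <- !vapply(graphs, is.null, logical(1L))
  if (!any(ok))
    stop("all records failed to parse:\n  ",
         paste(errs, collapse = "\n  "))
  if (length(errs))
    warning("skipped ", length(errs), " unparseable record(s):\n  ",
            paste(errs, collapse = "\n  "), call. = FALSE)

  alphabet <- buildAlphabet(mode, graphs[ok])
  arrays <- lapply(graphs[ok], encodeMolecule, alphabet = alphabet,
                   levels = levels)
  flattenEncodings(arrays, ids = ids[ok])
}

.resolveInput <- function(input, format, column) {
  if (methods::is(input, "AAStringSet")) {
    sm <- fastaToSmiles(input)
    ids <- names(input)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sm))
    return(list(smiles = unname(sm), ids = ids))
  }
  stopifnot(is.character(input))
  if (length(input) == 1L && file.exists(input) && !dir.exists(input)) {
    ext <- tolower(tools::file_ext(input))
    if (format == "fasta" || (format == "auto" &&
                              ext %in% c("fasta", "fa", "faa"))) {
      aa <- readFasta(input)
      return(list(smiles = unname(fastaToSmiles(aa)), ids = names(aa)))
    }
    if (ext == "csv") {
      df <- utils::read.csv(input, stringsAsFactors = FALSE)
      if (!(column %in% names(df)))
        stop("CSV file '", input, "' has no column '", column, "'")
      ids <- if ("id" %in% names(df)) as.character(df$id)
             else paste0("mol", seq_len(nrow(df)))
      return(list(smiles = df[[column]], ids = ids))
    }
    ln <- readLines(input, warn = FALSE)
    ln <- trimws(ln)
    ln <- ln[nzchar(ln)]
    if (format == "auto" && any(startsWith(ln, ">"))) {
      aa <- readFasta(input)
      return(list(smiles = unname(fastaToSmiles(aa)), ids = names(aa)))
    }
    # "SMILES id" or bare SMILES per line
    parts <- strsplit(ln, "[[:space:]]+")
    sm <- vapply(parts, `[[`, character(1L), 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else paste0("mol", i),
      character(1L))
    return(list(smiles = sm, ids = ids))
  }
  # in-memory character vector; in auto mode records are classified one by
  # one: a string over the 20 residue letters that contains a letter which is
  # not a SMILES atom symbol (e.g. G, A, W) is a peptide, anything else is
  # taken as SMILES (so "CC" is ethane, "GG" is diglycine; pass
  # format = "fasta" to force peptide reading of ambiguous strings).
  ids <- names(input)
  if (is.null(ids)) ids <- paste0("mol", seq_along(input))
  if (format == "fasta")
    return(list(smiles = unname(fastaToSmiles(input)), ids = ids))
  sm <- unname(input)
  if (format == "auto") {
    pep <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sm) &
           grepl("[ADEGKLMQRTVWY]", sm)
    if (any(pep)) sm[pep] <- unname(fastaToSmiles(sm[pep]))
  }
  list(smiles = sm, ids = ids)
}

#' Persist / reload an encoded data set
#'
#' \code{writeEncoding} writes \code{PREFIX.csv} (one row per molecule, a
#' header of feature names \code{ELEM_L<level>_C<col>}, an \code{id} column)
#' and \code{PREFIX.layout.json} (layout metadata plus per-molecule SMILES
#' and carbon counts). \code{readEncoding} reconstructs the
#' [EncodedDataset-class] from the pair.
#'
#' @param x an [EncodedDataset-class].
#' @param prefix output path prefix.
#' @return \code{writeEncoding}: the two file paths, invisibly;
#'   \code{readEncoding}: an [EncodedDataset-class].
#' @export
writeEncoding <- function(x, prefix) {
  stopifnot(methods::is(x, "EncodedDataset"))
  csv <- paste0(prefix, ".csv")
  lay <- paste0(prefix, ".layout.json")
  df <- as.data.frame(featureMatrix(x), check.names = FALSE)
  df <- cbind(id = colnames(x), df)
  utils::write.csv(df, csv, row.names = FALSE)
  cd <- SummarizedExperiment::colData(x)
  meta <- c(encodingLayout(x),
            list(ids = colnames(x), smiles = cd$smiles,
                 nCarbons = cd$nCarbons))
  jsonlite::write_json(meta, lay, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, layout = lay))
}

#' @rdname writeEncoding
#' @export
readEncoding <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  layf <- paste0(prefix, ".layout.json")
  if (!file.exists(csv) || !file.exists(layf))
    stop("missing ", csv, " or ", layf)
  meta <- jsonlite::read_json(layf, simplifyVector = TRUE)
  df <- utils::read.csv(csv, check.names = FALSE)
  ids <- as.character(df$id)
  mat <- t(as.matrix(df[, setdiff(names(df), "id"), drop = FALSE]))
  colnames(mat) <- ids
  K <- length(meta$symbols)
  rowdat <- S4Vectors::DataFrame(
    element = rep(meta$symbols, times = meta$levels * meta$maxCarbons),
    level   = rep(rep(seq_len(meta$levels), each = K),
                  times = meta$maxCarbons),
    carbon  = rep(seq_len(meta$maxCarbons), each = K * meta$levels)
  )
  coldat <- S4Vectors::DataFrame(id = ids, smiles = meta$smiles,
                                 nCarbons = as.integer(meta$nCarbons))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(encoding = mat), rowData = rowdat, colData = coldat,
    metadata = list(layout = list(mode = meta$mode, symbols = meta$symbols,
                                  levels = as.integer(meta$levels),
                                  maxCarbons = as.integer(meta$maxCarbons))))
  methods::new("EncodedDataset", se)
}
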