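#' Generate random peptide sequences
#'
#' Sequences are i.i.d. uniform over the 20 standard residue letters, with
#' lengths uniform over \code{lengthRange}. A pure function of the seed.
#'
#' @param n number of peptides (>= 1).
#' @param lengthRange integer pair (min, max) with 1 <= min <= max.
#' @param seed random seed.
#' @return an [Biostrings::AAStringSet-class] named \code{pep1..pepN}.
#' @examples
#' genRandomPeptides(3, c(5, 8), seed = 1)
#' @export
genRandomPeptides <- function(n, lengthRange = c(5L, 30L), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || any(is.na(lengthRange)) ||
      lengthRange[1L] < 1L || lengthRange[1L] > lengthRange[2L])
    stop("lengthRange must be (min, max) with 1 <= min <= max")
  set.seed(seed)
  lens <- .uniformLengths(n, lengthRange)
  aa <- standardResidues()
  seqs <- vapply(lens, function(L)
    paste0(sample(aa, L, replace = TRUE), collapse = ""), character(1L))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- paste0("pep", seq_len(n))
  out
}

# uniform draw over [min, max] that is safe for min == max
.uniformLengths <- function(n, lengthRange) {
  lengthRange[1L] +
    sample.int(lengthRange[2L] - lengthRange[1L] + 1L, n,
               replace = TRUE) - 1L
}

#' Generate a sulfur-separable binary classification task
#'
#' Balanced synthetic task whose label is a pure function of the sequence:
#' positives contain at least one sulfur-bearing residue (cysteine or
#' methionine), negatives contain none. The design emulates cysteine-rich
#' peptide families (such as defensins) against a cysteine-free background:
#' negatives are random alanine/serine peptides, positives additionally
#' carry cysteines at a per-position rate of \code{sulfurRate} (at least one
#' guaranteed). Alanine, serine and cysteine each contribute exactly three
#' backbone carbons, so residue positions map to fixed counting-array
#' columns and the sulfur rows of the encoding carry the entire class
#' signal — under every alphabet mode (sulfur is in all three), which makes
#' the expected hot rows of a relevance heat map unambiguous.
#'
#' @param n total number of peptides (split n %/% 2 negatives, rest
#'   positives).
#' @param lengthRange peptide length range.
#' @param sulfurRate per-position probability of a cysteine in positives.
#' @param seed random seed.
#' @return a [SyntheticTask-class].
#' @examples
#' genSeparableTask(n = 10, seed = 7)
#' @export
genSeparableTask <- function(n = 200L, lengthRange = c(8L, 12L),
                             sulfurRate = 0.3, seed = 7L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2")
  set.seed(seed)
  nNeg <- n %/% 2L
  nPos <- n - nNeg
  lens <- .uniformLengths(n, as.integer(lengthRange))
  background <- c("A", "S")
  seqs <- character(n)
  for (i in seq_len(nNeg))
    seqs[i] <- paste0(sample(background, lens[i], replace = TRUE),
                      collapse = "")
  for (i in seq(nNeg + 1L, n)) {
    s <- sample(background, lens[i], replace = TRUE)
    k <- which(stats::runif(lens[i]) < sulfurRate)
    if (!length(k)) k <- sample.int(lens[i], 1L)  # guarantee >= 1 sulfur
    s[k] <- "C"
    seqs[i] <- paste0(s, collapse = "")
  }
  labels <- c(rep(0L, nNeg), rep(1L, nPos))
  ord <- sample.int(n)                      # shuffle class blocks
  sequences <- Biostrings::AAStringSet(seqs[ord])
  names(sequences) <- paste0("pep", seq_len(n))
  methods::new("SyntheticTask", sequences = sequences,
               labels = labels[ord],
               rule = "positive iff the sequence contains >= 1 sulfur-bearing residue (C or M)",
               seed = as.integer(seed))
}

#' Curated small-molecule fixtures
#'
#' A fixed list of small organic molecules with their SMILES and molecular
#' formulas, used as ground truth throughout: parsing must reproduce each
#' formula exactly, and the symmetric members (cyclohexane) pin down the
#' neighborhood counts by symmetry. Includes a cyclic peptide
#' (2,5-diketopiperazine, cyclo-GG) to exercise ring opening on a peptide
#' backbone.
#'
#' @return data.frame with columns \code{name}, \code{smiles},
#'   \code{formula}.
#' @examples
#' fixtureMolecules()
#' @export
fixtureMolecules <- function() {
  data.frame(
    name = c("methane", "ethane", "propane", "isobutane", "cyclohexane",
             "phenol", "glycine", "alanine", "methionine", "ethanol",
             "diketopiperazine"),
    smiles = c("C", "CC", "CCC", "CC(C)C", "C1CCCCC1",
               "C1=CC=C(C=C1)O", "NCC(=O)O", "NC(C)C(=O)O",
               "NC(CCSC)C(=O)O", "CCO",
               "C1C(=O)NCC(=O)N1"),
    formula = c("CH4", "C2H6", "C3H8", "C4H10", "C6H12",
                "C6H6O", "C2H5NO2", "C3H7NO2",
                "C5H11NO2S", "C2H6O",
                "C4H6N2O2"),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic task to FASTA + labels CSV
#'
#' @param task a [SyntheticTask-class].
#' @param prefix output path prefix; writes \code{PREFIX.fasta} and
#'   \code{PREFIX.labels.csv} (columns id, label).
#' @return the two paths, invisibly.
#' @export
writeTask <- function(task, prefix) {
  stopifnot(methods::is(task, "SyntheticTask"))
  fa <- paste0(prefix, ".fasta")
  lb <- paste0(prefix, ".labels.csv")
  writeFasta(task@sequences, fa)
  utils::write.csv(
    data.frame(id = names(task@sequences), label = task@labels),
    lb, row.names = FALSE)
  invisible(c(fasta = fa, labels = lb))
}
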