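#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
NULL

# SMILES fragments of the 20 standard residues, written N-to-C so that a
# linear peptide is the concatenation of its residue fragments plus a final
# "O" (free C-terminal acid). No stereo markers: the encoding does not see
# stereochemistry. Aromatic side chains use aromatic SMILES; kekulization
# and hydrogen addition happen at parse time.
.RESIDUE_SMILES <- c(
  A = "NC(C)C(=O)",
  C = "NC(CS)C(=O)",
  D = "NC(CC(=O)O)C(=O)",
  E = "NC(CCC(=O)O)C(=O)",
  F = "NC(Cc1ccccc1)C(=O)",
  G = "NCC(=O)",
  H = "NC(Cc1c[nH]cn1)C(=O)",
  I = "NC(C(C)CC)C(=O)",
  K = "NC(CCCCN)C(=O)",
  L = "NC(CC(C)C)C(=O)",
  M = "NC(CCSC)C(=O)",
  N = "NC(CC(N)=O)C(=O)",
  P = "N1CCCC1C(=O)",
  Q = "NC(CCC(N)=O)C(=O)",
  R = "NC(CCCNC(=N)N)C(=O)",
  S = "NC(CO)C(=O)",
  T = "NC(C(O)C)C(=O)",
  V = "NC(C(C)C)C(=O)",
  W = "NC(Cc1c[nH]c2ccccc12)C(=O)",
  Y = "NC(Cc1ccc(O)cc1)C(=O)"
)

#' The 20 standard amino-acid single-letter codes
#'
#' @return character vector of the accepted residue letters.
#' @examples standardResidues()
#' @export
standardResidues <- function() names(.RESIDUE_SMILES)

#' Read a peptide FASTA file
#'
#' Reads a multi-record FASTA file of peptide sequences in single-letter
#' code. Sequences are uppercased and whitespace-stripped; records with an
#' empty sequence or with letters outside the 20 standard codes (this
#' includes the ambiguity/rare codes B, J, O, U, X, Z) are rejected with a
#' diagnostic naming the record and the offending character. Exotic residues
#' must be supplied as SMILES instead.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet-class], one element per record, named
#'   by header.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "GGCA"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  aa <- tryCatch(
    readAAStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aa) == 0L)
    stop("no FASTA records in '", path, "'")
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aa)))
  ids <- names(aa)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("malformed FASTA header (empty identifier) in '", path, "'")
  .validateResidues(seqs, ids)
  out <- AAStringSet(seqs)
  names(out) <- ids
  out
}

.validateResidues <- function(seqs, ids) {
  ok <- standardResidues()
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]]))
      stop("empty sequence in record '", ids[[i]], "'", call. = FALSE)
    letters <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!(letters %in% ok))
    if (length(bad))
      stop("record '", ids[[i]], "': non-standard residue letter '",
           letters[bad[1L]], "' at position ", bad[1L],
           " (only the 20 standard codes are convertible; supply SMILES ",
           "for exotic residues)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write peptide sequences to FASTA
#'
#' @param x an [Biostrings::AAStringSet-class] or named character vector.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- AAStringSet(x)
  }
  writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Convert a peptide sequence to SMILES
#'
#' Builds the SMILES of the linear peptide by N-to-C condensation of
#' per-residue fragments: each peptide bond removes one water, the N-terminal
#' amine and C-terminal carboxylic acid are left free. Vectorized over
#' sequences.
#'
#' @param sequence character vector of peptide sequences in single-letter
#'   code (or an [Biostrings::AAStringSet-class]).
#' @return character vector of SMILES strings.
#' @examples
#' fastaToSmiles("G")    # glycine, "NCC(=O)O"
#' fastaToSmiles("GG")   # glycylglycine
#' @export
fastaToSmiles <- function(sequence) {
  if (methods::is(sequence, "AAStringSet"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence))
  ids <- if (!is.null(names(sequence))) names(sequence)
         else as.character(seq_along(sequence))
  seqs <- toupper(gsub("[[:space:]]", "", sequence))
  .validateResidues(seqs, ids)
  out <- vapply(seqs, function(s) {
    letters <- strsplit(s, "")[[1L]]
    paste0(paste0(.RESIDUE_SMILES[letters], collapse = ""), "O")
  }, character(1L), USE.NAMES = FALSE)
  names(out) <- names(sequence)
  out
}

# ---- SMILES validation ------------------------------------------------------

# OpenBabel silently repairs some malformed SMILES, so syntactic problems are
# caught here first: unbalanced parentheses/brackets, unpaired ring-closure
# digits, and tokens outside the SMILES grammar all raise an error naming the
# offending token and its position.
.validateSmiles <- function(smiles) {
  if (!nzchar(smiles)) stop("empty SMILES string", call. = FALSE)
  chars <- strsplit(smiles, "")[[1L]]
  i <- 1L; n <- length(chars)
  depth <- 0L
  open_rings <- integer(0)
  bad <- function(tok, pos)
    stop("invalid SMILES '", smiles, "': unexpected token '", tok,
         "' at position ", pos, call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("invalid SMILES '", smiles,
                      "': unclosed bracket atom starting at position ", i,
                      call. = FALSE)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]*([A-Z][a-z]?|[bcnops]|se|as|\\*)(@{0,2}(TH|AL|SP|TB|OH)?[0-9]*)?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?(:[0-9]+)?$",
                 body))
        bad(paste0("[", body, "]"), i)
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      # two-letter organic-subset halogens
      if (ch == "C" && i < n && chars[i + 1L] == "l") i <- i + 2L
      else if (ch == "B" && i < n && chars[i + 1L] == "r") i <- i + 2L
      else i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      if (i == n) stop("invalid SMILES '", smiles,
                       "': dangling bond symbol '", ch, "' at position ", i,
                       call. = FALSE)
      i <- i + 1L
    } else if (ch == "(") {
      depth <- depth + 1L; i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) bad(")", i)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      num <- as.integer(ch)
      open_rings <- .toggleRing(open_rings, num)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste0(chars[(i + 1L):(i + 2L)], collapse = "")))
        bad("%", i)
      num <- as.integer(paste0(chars[(i + 1L):(i + 2L)], collapse = ""))
      open_rings <- .toggleRing(open_rings, num)
      i <- i + 3L
    } else if (ch == ".") {
      i <- i + 1L
    } else {
      bad(ch, i)
    }
  }
  if (depth != 0L)
    stop("invalid SMILES '", smiles, "': unclosed parenthesis",
         call. = FALSE)
  if (length(open_rings))
    stop("invalid SMILES '", smiles, "': unpaired ring-closure digit(s) ",
         paste(open_rings, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.toggleRing <- function(open, num) {
  if (num %in% open) setdiff(open, num) else c(open, num)
}

# ---- SMILES -> MolGraph -----------------------------------------------------

#' Parse a SMILES string into a molecular graph
#'
#' Converts SMILES to an element-labeled graph with explicit hydrogens added
#' to satisfy standard valences (aromatic SMILES are kekulized first). Heavy
#' atoms keep their order of first appearance in the SMILES text; hydrogens
#' are appended after them. Bond orders are recorded but neighborhood
#' counting treats every bond as a single adjacency. Multi-fragment
#' (dot-separated) SMILES are accepted; the molecule must contain at least
#' one carbon atom.
#'
#' @param smiles a single SMILES string.
#' @return a [MolGraph-class].
#' @examples
#' parseSmiles("C")                # methane: 1 C + 4 H
#' parseSmiles("C1=CC=C(C=C1)O")   # phenol: 13 atoms, 13 bonds
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  .validateSmiles(smiles)
  sdf <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "",
                           stringsAsFactors = FALSE)),
    error = function(e) stop("SMILES conversion failed for '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!nzchar(sdf))
    stop("SMILES conversion produced no molecule for '", smiles, "'",
         call. = FALSE)
  g <- .sdfToMolGraph(sdf, smiles)
  if (!any(g@elements == "C"))
    stop("no carbon backbone: '", smiles, "' contains no carbon atom",
         call. = FALSE)
  g
}

# Minimal V2000 molfile reader for OpenBabel output (atom order preserved,
# no properties needed beyond elements and bonds).
.sdfToMolGraph <- function(sdf, smiles) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || natoms < 1L)
    stop("SMILES conversion produced an empty molecule for '", smiles, "'",
         call. = FALSE)
  atom_lines <- lines[5L:(4L + natoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  if (nbonds > 0L) {
    bond_lines <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bonds <- cbind(as.integer(substr(bond_lines, 1L, 3L)),
                   as.integer(substr(bond_lines, 4L, 6L)))
    orders <- as.integer(substr(bond_lines, 7L, 9L))
  } else {
    bonds <- matrix(integer(0), ncol = 2L)
    orders <- integer(0)
  }
  methods::new("MolGraph", elements = elements, bonds = bonds,
               bondOrders = orders, smiles = smiles)
}

# ---- element collection -----------------------------------------------------

# Canonical element order: the five protein-abundant elements first (where
# present), remaining symbols alphabetically.
.canonicalElementOrder <- function(symbols) {
  first <- c("H", "C", "N", "O", "S")
  c(first[first %in% symbols], sort(setdiff(symbols, first)))
}

#' Collect the unique elements across molecular graphs
#'
#' Union of element symbols over a set of [MolGraph-class] objects, in
#' canonical order: H, C, N, O, S first (those present), remaining symbols
#' alphabetically. This is the data-driven (mode-3) element alphabet.
#'
#' @param graphs a list of [MolGraph-class] objects.
#' @return ordered character vector of element symbols.
#' @examples
#' collectUniqueElements(list(parseSmiles("C"), parseSmiles("C1=CC=C(C=C1)O")))
#' @export
collectUniqueElements <- function(graphs) {
  if (length(graphs) == 0L)
    stop("cannot collect elements from an empty set of molecules")
  stopifnot(all(vapply(graphs, methods::is, logical(1L), "MolGraph")))
  .canonicalElementOrder(unique(unlist(lapply(graphs, atomElements))))
}
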