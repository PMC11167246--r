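test_that("readFasta parses records, uppercases, and round-trips", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "gg", ">p2", "ACDE", "FGHI"), tf)
  aa <- readFasta(tf)
  expect_identical(names(aa), c("p1", "p2"))
  expect_identical(as.character(aa), c(p1 = "GG", p2 = "ACDEFGHI"))

  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(aa, tf2)
  expect_identical(as.character(readFasta(tf2)), as.character(aa))
})

test_that("readFasta rejects degenerate and non-standard input", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", ""), tf)
  expect_error(readFasta(tf), "empty sequence")

  writeLines(c(">p1", "GXG"), tf)
  expect_error(readFasta(tf), "'X' at position 2")

  writeLines(c(">p1", "GBG"), tf)   # B is ambiguous, rejected not guessed
  expect_error(readFasta(tf), "'B'")

  writeLines("no header at all", tf)
  expect_error(readFasta(tf))
})

test_that("fastaToSmiles condenses residues N-to-C with one water per bond", {
  expect_identical(unname(fastaToSmiles("G")), "NCC(=O)O")
  expect_identical(unname(fastaToSmiles("GG")), "NCC(=O)NCC(=O)O")

  # formula oracle: graph element counts equal residue-sum minus waters
  for (s in c("G", "GG", "A", "ACD", "GAVLSTK", "WWP", "MQR")) {
    g <- parseSmiles(unname(fastaToSmiles(s)))
    want <- peptideFormula(s)
    got <- graphFormula(g)
    expect_identical(got[sort(names(got))], want[sort(names(want))],
                     label = paste("formula of", s))
  }
})

test_that("fastaToSmiles names the unknown residue and its position", {
  expect_error(fastaToSmiles("GGZG"), "'Z' at position 3")
  expect_error(fastaToSmiles("U"), "'U'")
})

test_that("a k-residue peptide graph has exactly k-1 amide C-N bonds", {
  # amide motif: a carbon double-bonded to O and single-bonded to N; the
  # chosen residues have no side-chain amides or guanidines
  countAmides <- function(g) {
    b <- atomBonds(g); e <- atomElements(g); o <- g@bondOrders
    hits <- 0L
    carbons <- which(e == "C")
    for (c in carbons) {
      rows <- which(b[, 1] == c | b[, 2] == c)
      partners <- ifelse(b[rows, 1] == c, b[rows, 2], b[rows, 1])
      hasCO2 <- any(e[partners] == "O" & o[rows] == 2L)
      hasN1 <- any(e[partners] == "N" & o[rows] == 1L)
      if (hasCO2 && hasN1) hits <- hits + 1L
    }
    hits
  }
  for (s in c("G", "GG", "GAV", "STKLA", "GGGGGG")) {
    g <- parseSmiles(unname(fastaToSmiles(s)))
    expect_identical(countAmides(g), nchar(s) - 1L,
                     label = paste("amide bonds in", s))
  }
})

test_that("parseSmiles builds explicit-hydrogen graphs with SMILES atom order", {
  g <- parseSmiles("C")
  expect_identical(sort(atomElements(g)), c("C", "H", "H", "H", "H"))
  expect_identical(nrow(atomBonds(g)), 4L)

  ph <- parseSmiles("C1=CC=C(C=C1)O")
  expect_identical(atomElements(ph)[1:7],
                   c("C", "C", "C", "C", "C", "C", "O"))
  expect_identical(length(atomElements(ph)), 13L)
  expect_identical(nrow(atomBonds(ph)), 13L)
  # bond census: 6 ring C-C, 1 C-O, 5 C-H, 1 O-H
  e <- atomElements(ph)
  kinds <- apply(atomBonds(ph), 1L, function(p)
    paste(sort(e[p]), collapse = "-"))
  expect_identical(sum(kinds == "C-C"), 6L)
  expect_identical(sum(kinds == "C-O"), 1L)
  expect_identical(sum(kinds == "C-H"), 5L)
  expect_identical(sum(kinds == "H-O"), 1L)
})

test_that("parseSmiles rejects carbon-free and malformed input", {
  expect_error(parseSmiles("[Na+]"), "no carbon backbone")
  expect_error(parseSmiles("C("), "unclosed parenthesis")
  expect_error(parseSmiles("C1CC"), "ring-closure")
  expect_error(parseSmiles("CX"), "token 'X' at position 2")
  expect_error(parseSmiles("CC="), "dangling bond")
  expect_error(parseSmiles(""), "empty")
})

test_that("multi-fragment SMILES are accepted and traversed in ordinal order", {
  g <- parseSmiles("CC.O")                 # ethane + water
  expect_identical(sum(atomElements(g) == "C"), 2L)
  expect_identical(indexCarbons(g), c(1L, 2L))
  ca <- encodeMolecule(g, buildAlphabet("mode1"), 1)
  expect_identical(ncol(counts(ca)), 2L)
})

test_that("collectUniqueElements returns the canonical-order union", {
  methane <- parseSmiles("C")
  phenol <- parseSmiles("C1=CC=C(C=C1)O")
  glycine <- parseSmiles("NCC(=O)O")
  expect_identical(collectUniqueElements(list(methane)), c("H", "C"))
  expect_identical(collectUniqueElements(list(phenol, methane)),
                   c("H", "C", "O"))
  expect_identical(collectUniqueElements(list(glycine)),
                   c("H", "C", "N", "O"))
  expect_error(collectUniqueElements(list()), "empty")
  # non-CHNOS symbols sort alphabetically after the protein five
  chloro <- parseSmiles("CCl")
  fluoro <- parseSmiles("CF")
  expect_identical(collectUniqueElements(list(chloro, fluoro, glycine)),
                   c("H", "C", "N", "O", "Cl", "F"))
})

test_that("fixture molecules parse to their known molecular formulas", {
  fm <- fixtureMolecules()
  for (i in seq_len(nrow(fm))) {
    g <- parseSmiles(fm$smiles[i])
    expect_same_formula(g, fm$formula[i])
  }
})
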