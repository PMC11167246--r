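test_that("buildAlphabet produces the three documented alphabets", {
  expect_identical(alphabetSymbols(buildAlphabet("mode1")),
                   c("H", "C", "N", "O", "S"))
  expect_identical(alphabetSymbols(buildAlphabet("mode2")),
                   c("C", "N", "O", "S"))
  expect_identical(alphabetSymbols(buildAlphabet(1)),
                   alphabetSymbols(buildAlphabet("mode1")))
  ph <- parseSmiles("C1=CC=C(C=C1)O")
  expect_identical(alphabetSymbols(buildAlphabet("mode3", list(ph))),
                   c("H", "C", "O"))
  expect_error(buildAlphabet("mode3"), "data-driven")
})

test_that("encodeMolecule reproduces the worked single-molecule arrays", {
  a1 <- buildAlphabet("mode1")

  methane <- counts(encodeMolecule(parseSmiles("C"), a1, 1))
  expect_identical(dim(methane), c(5L, 1L))
  expect_identical(unname(methane[, 1]), c(4L, 0L, 0L, 0L, 0L))

  phenol <- counts(encodeMolecule(parseSmiles("C1=CC=C(C=C1)O"), a1, 1))
  expect_identical(dim(phenol), c(5L, 6L))
  expect_identical(unname(phenol[, 4]), c(0L, 2L, 0L, 1L, 0L))
  for (j in c(1:3, 5:6))
    expect_identical(unname(phenol[, j]), c(1L, 2L, 0L, 0L, 0L))

  ethane <- counts(encodeMolecule(parseSmiles("CC"), a1, 2))
  expect_identical(dim(ethane), c(10L, 2L))
  for (j in 1:2)
    expect_identical(unname(ethane[, j]),
                     c(3L, 1L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L))
})

test_that("row blocks are level-major and labeled element_Llevel", {
  ca <- encodeMolecule(parseSmiles("CC"), buildAlphabet("mode1"), 3)
  expect_identical(rownames(counts(ca))[1:6],
                   c("H_L1", "C_L1", "N_L1", "O_L1", "S_L1", "H_L2"))
})

test_that("elements outside the alphabet are not counted anywhere", {
  # chloromethane under mode 1: Cl invisible, H block only
  ca <- counts(encodeMolecule(parseSmiles("CCl"), buildAlphabet("mode1"), 1))
  expect_identical(unname(ca[, 1]), c(3L, 0L, 0L, 0L, 0L))
  # under mode 3 the chlorine appears
  g <- parseSmiles("CCl")
  ca3 <- counts(encodeMolecule(g, buildAlphabet("mode3", list(g)), 1))
  expect_identical(unname(ca3[, 1]), c(3L, 0L, 1L))   # H, C, Cl
})

test_that("increasing levels preserves the lower-level row prefix", {
  a1 <- buildAlphabet("mode1")
  for (s in c("CC(C)C", "C1=CC=C(C=C1)O", "NCC(=O)O")) {
    g <- parseSmiles(s)
    c2 <- counts(encodeMolecule(g, a1, 2))
    c3 <- counts(encodeMolecule(g, a1, 3))
    expect_identical(c3[1:10, , drop = FALSE], c2, label = s)
  }
})

test_that("mode-3 level-1 column sums equal the carbon degree", {
  for (s in fixtureMolecules()$smiles) {
    g <- parseSmiles(s)
    ca <- encodeMolecule(g, buildAlphabet("mode3", list(g)), 1)
    b <- atomBonds(g)
    deg <- tabulate(c(b[, 1], b[, 2]), nbins = length(atomElements(g)))
    expect_identical(as.integer(colSums(counts(ca))), deg[carbonIds(ca)],
                     label = s)
  }
})

test_that("flattenEncodings pads column-by-column with trailing zeros", {
  a1 <- buildAlphabet("mode1")
  one <- flattenEncodings(list(encodeMolecule(parseSmiles("CC"), a1, 1)))
  expect_identical(dim(one), c(10L, 1L))

  two <- flattenEncodings(list(
    encodeMolecule(parseSmiles("CC"), a1, 1),
    encodeMolecule(parseSmiles("CCC"), a1, 1)))
  m <- SummarizedExperiment::assay(two, "encoding")
  expect_identical(dim(m), c(15L, 2L))
  expect_identical(unname(m[11:15, 1]), rep(0, 5))   # padding region
  expect_false(all(m[11:15, 2] == 0))
  expect_identical(rownames(m)[1:5],
                   c("H_L1_C1", "C_L1_C1", "N_L1_C1", "O_L1_C1", "S_L1_C1"))
  expect_identical(rownames(m)[6], "H_L1_C2")
})

test_that("flattenEncodings rejects mixed configurations and empty input", {
  a1 <- buildAlphabet("mode1")
  a2 <- buildAlphabet("mode2")
  g <- parseSmiles("CC")
  expect_error(flattenEncodings(list()), "empty")
  expect_error(flattenEncodings(list(encodeMolecule(g, a1, 1),
                                     encodeMolecule(g, a2, 1))),
               "share one alphabet")
  expect_error(flattenEncodings(list(encodeMolecule(g, a1, 1),
                                     encodeMolecule(g, a1, 2))),
               "share one alphabet")
})

test_that("un-flattening any padded row reproduces the array plus zeros", {
  a1 <- buildAlphabet("mode1")
  arrays <- list(encodeMolecule(parseSmiles("CC"), a1, 2),
                 encodeMolecule(parseSmiles("CC(C)C"), a1, 2),
                 encodeMolecule(parseSmiles("C1=CC=C(C=C1)O"), a1, 2))
  ed <- flattenEncodings(arrays)
  m <- SummarizedExperiment::assay(ed, "encoding")
  for (i in seq_along(arrays)) {
    back <- unflattenVector(m[, i], ed)
    orig <- counts(arrays[[i]])
    nc <- ncol(orig)
    expect_identical(unname(back[, seq_len(nc)]), unname(orig) * 1.0)
    if (nc < ncol(back))
      expect_true(all(back[, (nc + 1):ncol(back)] == 0))
  }
  expect_error(unflattenVector(1:3, ed), "padded length")
})

test_that("encodeDataset composes conversion, encoding and padding", {
  ed <- encodeDataset(c(p1 = "GG"), mode = 1, levels = 2, format = "fasta")
  expect_identical(dim(ed), c(40L, 1L))     # 10 rows x 4 carbons
  expect_identical(SummarizedExperiment::colData(ed)$nCarbons, 4L)

  # determinism: identical calls give identical objects
  ed2 <- encodeDataset(c(p1 = "GG"), mode = 1, levels = 2, format = "fasta")
  expect_identical(SummarizedExperiment::assay(ed, "encoding"),
                   SummarizedExperiment::assay(ed2, "encoding"))
})

test_that("mixed peptide and SMILES records encode into one matrix", {
  ed <- encodeDataset(c(pep = "GG", mol = "C1=CC=C(C=C1)O"),
                      mode = 1, levels = 1)
  expect_identical(ncol(ed), 2L)
  expect_identical(SummarizedExperiment::colData(ed)$smiles[1],
                   "NCC(=O)NCC(=O)O")
  expect_identical(SummarizedExperiment::colData(ed)$nCarbons, c(4L, 6L))
})

test_that("per-record failures are collected; total failure aborts", {
  expect_warning(
    ed <- encodeDataset(c(ok = "CC", bad = "C("), mode = 1, levels = 1,
                        format = "smiles"),
    "skipped 1")
  expect_identical(colnames(ed), "ok")
  expect_error(
    suppressWarnings(encodeDataset(c(bad1 = "C(", bad2 = "[Na+]"),
                                   mode = 1, levels = 1,
                                   format = "smiles")),
    "all records failed")
})

test_that("encoding written to CSV + layout JSON reloads identically", {
  prefix <- withr::local_tempfile()
  peps <- genRandomPeptides(5, c(4, 8), seed = 11)
  ed <- encodeDataset(peps, mode = 1, levels = 2)
  writeEncoding(ed, prefix)
  back <- readEncoding(prefix)
  expect_equal(SummarizedExperiment::assay(back, "encoding"),
               SummarizedExperiment::assay(ed, "encoding"))
  expect_identical(encodingLayout(back)$symbols, encodingLayout(ed)$symbols)
  expect_identical(encodingLayout(back)$maxCarbons,
                   encodingLayout(ed)$maxCarbons)

  # byte determinism: re-encoding and re-writing the same input produces
  # byte-identical files
  prefix2 <- withr::local_tempfile()
  writeEncoding(encodeDataset(peps, mode = 1, levels = 2), prefix2)
  expect_identical(readLines(paste0(prefix, ".csv")),
                   readLines(paste0(prefix2, ".csv")))
})

test_that("record order permutes rows but not their content", {
  sm <- c(a = "CC", b = "CCC", c = "CC(C)C")
  ed1 <- encodeDataset(sm, mode = 1, levels = 1, format = "smiles")
  ed2 <- encodeDataset(sm[c(3, 1, 2)], mode = 1, levels = 1,
                       format = "smiles")
  m1 <- SummarizedExperiment::assay(ed1, "encoding")
  m2 <- SummarizedExperiment::assay(ed2, "encoding")
  expect_identical(m1[, c("c", "a", "b")], m2)
})
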