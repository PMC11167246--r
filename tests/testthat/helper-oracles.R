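# Independent oracles used across the suite. None of these share code with
# the package: distances come from adjacency-matrix powers, formulas from a
# residue-formula table plus water bookkeeping, and the rank-sum p-value is
# computed from first principles.

# Brute-force all-pairs shortest paths: d[i,j] is the first power k of the
# adjacency matrix with a nonzero (i,j) entry.
oracleDistances <- function(graph) {
  n <- length(atomElements(graph))
  A <- matrix(0L, n, n)
  b <- atomBonds(graph)
  for (k in seq_len(nrow(b))) {
    A[b[k, 1], b[k, 2]] <- 1L
    A[b[k, 2], b[k, 1]] <- 1L
  }
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- P %*% A
    newly <- which(P > 0 & is.infinite(d))
    if (length(newly) == 0) break
    d[newly] <- k
  }
  d
}

# Element multiset at exactly distance `level` from atom `v`, by the oracle.
oracleNeighborhood <- function(graph, v, level) {
  d <- oracleDistances(graph)
  sort(atomElements(graph)[which(d[v, ] == level)])
}

# Parse a molecular formula string ("C6H6O") into named element counts.
parseFormula <- function(f) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  syms <- sub("[0-9]+$", "", toks)
  cnts <- as.integer(sub("^[A-Z][a-z]?", "", toks))
  cnts[is.na(cnts)] <- 1L
  stats::setNames(cnts, syms)
}

# Element counts of a parsed graph, as a named integer vector.
graphFormula <- function(graph) {
  tab <- table(atomElements(graph))
  stats::setNames(as.integer(tab), names(tab))
}

expect_same_formula <- function(graph, formula) {
  want <- parseFormula(formula)
  got <- graphFormula(graph)
  expect_setequal(names(got), names(want))
  expect_identical(got[sort(names(got))], want[sort(names(want))])
}

# Free-amino-acid molecular formulas (independent of the residue SMILES
# table); a k-residue peptide is the sum minus (k-1) waters.
RESIDUE_FORMULA <- list(
  A = c(C = 3, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 7, N = 1, O = 2, S = 1),
  D = c(C = 4, H = 7, N = 1, O = 4),
  E = c(C = 5, H = 9, N = 1, O = 4),
  F = c(C = 9, H = 11, N = 1, O = 2),
  G = c(C = 2, H = 5, N = 1, O = 2),
  H = c(C = 6, H = 9, N = 3, O = 2),
  I = c(C = 6, H = 13, N = 1, O = 2),
  K = c(C = 6, H = 14, N = 2, O = 2),
  L = c(C = 6, H = 13, N = 1, O = 2),
  M = c(C = 5, H = 11, N = 1, O = 2, S = 1),
  N = c(C = 4, H = 8, N = 2, O = 3),
  P = c(C = 5, H = 9, N = 1, O = 2),
  Q = c(C = 5, H = 10, N = 2, O = 3),
  R = c(C = 6, H = 14, N = 4, O = 2),
  S = c(C = 3, H = 7, N = 1, O = 3),
  T = c(C = 4, H = 9, N = 1, O = 3),
  V = c(C = 5, H = 11, N = 1, O = 2),
  W = c(C = 11, H = 12, N = 2, O = 2),
  Y = c(C = 9, H = 11, N = 1, O = 3)
)

peptideFormula <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  elems <- c("C", "H", "N", "O", "S")
  tot <- stats::setNames(rep(0L, 5), elems)
  for (l in letters) {
    f <- RESIDUE_FORMULA[[l]]
    tot[names(f)] <- tot[names(f)] + f
  }
  k <- length(letters)
  tot["H"] <- tot["H"] - 2L * (k - 1L)
  tot["O"] <- tot["O"] - (k - 1L)
  tot <- tot[tot > 0]
  storage.mode(tot) <- "integer"
  tot
}

# Brute-force one-sided Mann-Whitney U ("a greater"): U by pairwise
# comparison, p by the normal approximation with tie and continuity
# correction computed from scratch.
oracleUTest <- function(a, b, alternative = "greater") {
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ties <- table(c(a, b))
  mu <- n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  if (alternative == "greater") {
    z <- (U - mu - 0.5) / sigma
    p <- stats::pnorm(z, lower.tail = FALSE)
  } else if (alternative == "less") {
    z <- (U - mu + 0.5) / sigma
    p <- stats::pnorm(z)
  } else {
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  }
  list(U = U, p = min(1, p))
}
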