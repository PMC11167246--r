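#' Deterministically index the backbone carbons of a molecule
#'
#' Orders every carbon atom of the molecule by a depth-first walk over the
#' carbon-induced subgraph. The walk starts at the carbon with the smallest
#' atom ordinal (first appearance in the SMILES text); at a branch point the
#' unvisited carbon neighbors are explored in ascending ordinal order, each
#' branch followed to exhaustion before the next; a carbon reached again via
#' a ring-closure edge is not revisited, so cycles are opened into a linear
#' stretch of the backbone. Additional connected components are indexed the
#' same way, in ascending order of their smallest carbon ordinal.
#'
#' The resulting order defines the column order of the counting array and is
#' a pure function of the input SMILES text.
#'
#' @param graph a [MolGraph-class] with at least one carbon.
#' @return integer vector of carbon atom ordinals; position i holds the i-th
#'   backbone carbon.
#' @examples
#' indexCarbons(parseSmiles("CC(C)C"))  # isobutane: branch methyls in ordinal order
#' @export
indexCarbons <- function(graph) {
  stopifnot(methods::is(graph, "MolGraph"))
  carbons <- which(graph@elements == "C")
  if (length(carbons) == 0L)
    stop("no carbon backbone: the molecule contains no carbon atom")
  n <- length(graph@elements)
  adj <- .adjacencyList(graph@bonds, n)
  isC <- graph@elements == "C"
  visited <- logical(n)
  out <- integer(0)
  for (root in carbons) {          # ascending ordinal across components
    if (visited[root]) next
    stack <- root
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (visited[v]) next          # ring closure: cycle opened
      visited[v] <- TRUE
      out <- c(out, v)
      nb <- adj[[v]]
      nb <- sort(nb[isC[nb] & !visited[nb]])
      if (length(nb))
        stack <- c(stack, rev(nb))  # smallest ordinal popped first
    }
  }
  out
}

.adjacencyList <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1L]; b <- bonds[k, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

.igraphFromMolGraph <- function(graph) {
  igraph::graph_from_edgelist(graph@bonds, directed = FALSE) |>
    igraph::add_vertices(max(0L, length(graph@elements) -
                               max(c(0L, graph@bonds))))
}

#' Per-carbon, per-level neighbor directory
#'
#' For each indexed backbone carbon, collects the element symbols of all
#' atoms at shortest-path distance exactly l, for l = 1..maxLevel. Distances
#' are breadth-first over the full atom graph, hydrogens included as nodes;
#' every bond counts as a single adjacency regardless of bond order, and
#' ring-closure bonds contribute like any other bond (cycle opening affects
#' column order only, never distances).
#'
#' @param graph a [MolGraph-class].
#' @param indexing integer vector of carbon ordinals from [indexCarbons()];
#'   computed if missing.
#' @param maxLevel highest neighborhood level (>= 1).
#' @return a named list, one entry per backbone carbon in column order; each
#'   entry is a list of \code{maxLevel} character vectors of element symbols
#'   (sorted, multiset semantics).
#' @examples
#' neighborDirectory(parseSmiles("CC"), maxLevel = 2)
#' @export
neighborDirectory <- function(graph, indexing = indexCarbons(graph),
                              maxLevel = 2L) {
  stopifnot(methods::is(graph, "MolGraph"))
  maxLevel <- as.integer(maxLevel)
  if (maxLevel < 1L) stop("maxLevel must be >= 1")
  ig <- .igraphFromMolGraph(graph)
  d <- igraph::distances(ig, v = indexing, mode = "all")
  out <- lapply(seq_along(indexing), function(i) {
    lapply(seq_len(maxLevel), function(lvl) {
      sort(graph@elements[which(d[i, ] == lvl)])
    })
  })
  names(out) <- paste0("C", indexing)
  for (i in seq_along(out)) names(out[[i]]) <- paste0("L", seq_len(maxLevel))
  out
}

#' Dump a neighbor directory as JSON
#'
#' Debug/inspection helper: serializes the per-carbon, per-level element
#' multisets to pretty-printed JSON.
#'
#' @param directory output of [neighborDirectory()].
#' @param path optional file path; if missing the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
dumpNeighborDirectory <- function(directory, path = NULL) {
  js <- jsonlite::toJSON(directory, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
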