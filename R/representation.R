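#' Convert a counting array to a grayscale image
#'
#' Normalizes the array by its own maximum entry and maps values to gray
#' intensities: 0 renders white, 1 (the maximum) renders black. The mapping
#' is scale-invariant: multiplying every cell by a positive constant leaves
#' the image unchanged. An all-zero array maps to all white (no signal). A
#' data-set-global maximum can be supplied for cross-molecule comparability.
#'
#' @param array a [CountingArray-class] (or a bare numeric matrix).
#' @param zoom integer magnification used on export (each cell becomes a
#'   zoom x zoom block of pixels).
#' @param maxValue optional normalization maximum overriding the array's
#'   own; must be > 0.
#' @return a [GrayscaleImage-class].
#' @examples
#' ca <- encodeMolecule(parseSmiles("C"), buildAlphabet("mode1"), 1)
#' arrayToImage(ca)  # top pixel black (4 hydrogens), rest white
#' @export
arrayToImage <- function(array, zoom = 1L, maxValue = NULL) {
  m <- if (methods::is(array, "CountingArray")) counts(array) else array
  stopifnot(is.matrix(m), all(m >= 0))
  mx <- if (is.null(maxValue)) max(m) else maxValue
  px <- if (mx > 0) m / mx else m * 0
  storage.mode(px) <- "double"
  methods::new("GrayscaleImage", pixels = px, zoom = as.integer(zoom))
}

#' Write a grayscale image to an 8-bit PNG
#'
#' Each cell becomes a zoom x zoom pixel block with 8-bit intensity
#' \code{round(255 * (1 - value))} (so 0 is white, 1 is black).
#'
#' @param image a [GrayscaleImage-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(methods::is(image, "GrayscaleImage"))
  z <- image@zoom
  px <- kronecker(image@pixels, matrix(1, z, z))
  png::writePNG(1 - px, target = path)
  invisible(path)
}

#' Reshape a feature-importance vector into counting-array coordinates
#'
#' Un-flattens an importance vector (one value per padded feature) into the
#' (element x level) by backbone-position matrix of the data-set layout —
#' the exact inverse of the encoder's column-by-column flattening. This is
#' the relevance map underlying the heat-map rendering.
#'
#' @param importances non-negative numeric vector whose length equals the
#'   layout's padded length.
#' @param layout an [EncodedDataset-class] or its layout list.
#' @return labeled numeric matrix (rows element x level, columns backbone
#'   carbon position).
#' @seealso [renderRelevanceHeatmap()], [computeFeatureImportances()]
#' @export
relevanceMap <- function(importances, layout) {
  lay <- encodingLayout(layout)
  expected <- length(lay$symbols) * lay$levels * lay$maxCarbons
  if (length(importances) != expected)
    stop("importance vector length ", length(importances),
         " does not match the layout's padded length ", expected)
  if (any(importances < 0))
    stop("importances must be non-negative")
  unflattenVector(importances, lay)
}

#' Render a relevance heat map
#'
#' Un-flattens a feature-importance vector into counting-array coordinates
#' and renders it with a sequential, perceptually uniform color ramp
#' (viridis), columns labeled as backbone carbon positions and rows as
#' element x level pairs. Optionally writes the numeric map alongside as
#' CSV.
#'
#' @param importances numeric vector of per-feature importances (padded
#'   layout length).
#' @param layout an [EncodedDataset-class] or its layout list.
#' @param path output PNG path.
#' @param csvPath optional path for the numeric relevance map as CSV.
#' @param width,height device size in pixels.
#' @return the relevance-map matrix, invisibly.
#' @export
renderRelevanceHeatmap <- function(importances, layout, path,
                                   csvPath = NULL,
                                   width = 900L, height = 500L) {
  map <- relevanceMap(importances, layout)
  if (!is.null(csvPath))
    utils::write.csv(as.data.frame(map), csvPath, row.names = TRUE)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(256L, "viridis")
  graphics::par(mar = c(4.5, 6, 2, 1))   # device-local, dies with dev.off
  nr <- nrow(map); nc <- ncol(map)
  zlim <- range(map)
  if (zlim[1L] == zlim[2L]) zlim <- zlim + c(0, 1e-12)  # flat map renders cold
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(map[rev(seq_len(nr)), , drop = FALSE]),
                  col = pal, zlim = zlim, axes = FALSE,
                  xlab = "backbone carbon position",
                  ylab = "")
  graphics::mtext("element × level", side = 2, line = 4.5)
  graphics::axis(1, at = seq_len(nc), labels = colnames(map), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(map)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(map)
}
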