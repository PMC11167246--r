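# Random-forest settings pinned in one place so "default hyper-parameters"
# cannot drift with dependency upgrades: 100 trees, gini impurity, sqrt
# feature subsampling, bootstrap sampling, minimum node size 1.
.forestConfig <- function(p) {
  list(num.trees = 100L,
       mtry = max(1L, floor(sqrt(p))),
       min.node.size = 1L,
       splitrule = "gini",
       replace = TRUE)
}

# Binary F1 of the positive class, 2TP / (2TP + FP + FN); defined as 0 when
# the denominator is 0 (no true or predicted positives).
.f1Score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  den <- 2 * tp + fp + fn
  if (den == 0) 0 else 2 * tp / den
}

# Stratified fold assignment: within each class, indices are shuffled and
# fold labels 1..k assigned round-robin, so class proportions are preserved
# up to rounding. Deterministic given the seed.
.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.resolveFeatures <- function(x) {
  if (methods::is(x, "EncodedDataset")) return(featureMatrix(x))
  stopifnot(is.matrix(x) || is.data.frame(x))
  as.matrix(x)
}

.resolveLabels <- function(labels, n) {
  if (is.logical(labels)) labels <- as.integer(labels)
  y <- factor(labels)
  if (length(y) != n)
    stop("labels length ", length(y), " != number of samples ", n)
  if (nlevels(y) < 2L)
    stop("labels contain a single class; a binary task is required")
  if (nlevels(y) > 2L)
    stop("labels must be binary; got ", nlevels(y), " classes")
  y
}

#' Evaluate an encoding with a seeded random-forest harness
#'
#' Repeated stratified k-fold cross-validation (default 5 folds, 10 repeats)
#' of a random-forest classifier on the encoded features, recording the
#' binary F1 score of the positive class on every held-out fold. The forest
#' uses the pinned default hyper-parameters (100 trees, gini impurity, sqrt
#' feature subsampling, minimum node size 1) and all randomness — fold
#' assignment and tree growing — derives deterministically from \code{seed},
#' so the same call reproduces the same 50 scores bit for bit.
#'
#' @param x an [EncodedDataset-class] or a samples-by-features matrix.
#' @param labels binary label vector (0/1, logical, or two-level factor).
#' @param folds number of CV folds.
#' @param repeats number of CV repeats.
#' @param seed master seed.
#' @param positive label treated as positive; defaults to the second factor
#'   level (so 1 for 0/1 labels).
#' @param macro if TRUE report macro-averaged F1 over both classes instead
#'   of the positive-class F1.
#' @return a [CVResult-class].
#' @examples
#' \donttest{
#' task <- genSeparableTask(n = 40, seed = 1)
#' ed <- encodeDataset(task@sequences, mode = 1, levels = 2)
#' res <- evaluateEncoding(ed, task@labels, folds = 5, repeats = 2, seed = 42)
#' meanF1(res)
#' }
#' @export
evaluateEncoding <- function(x, labels, folds = 5L, repeats = 10L,
                             seed = 42L, positive = NULL, macro = FALSE) {
  feat <- .resolveFeatures(x)
  y <- .resolveLabels(labels, nrow(feat))
  folds <- as.integer(folds); repeats <- as.integer(repeats)
  if (min(table(y)) < folds)
    stop("each class needs at least as many samples as folds (",
         folds, "); smallest class has ", min(table(y)))
  if (is.null(positive)) positive <- levels(y)[2L]
  positive <- as.character(positive)
  if (!(positive %in% levels(y)))
    stop("positive class '", positive, "' not among the labels")

  cfg <- .forestConfig(ncol(feat))
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, repeats)
  scores <- matrix(NA_real_, nrow = folds, ncol = repeats,
                   dimnames = list(paste0("fold", seq_len(folds)),
                                   paste0("rep", seq_len(repeats))))
  df <- as.data.frame(feat)
  names(df) <- paste0("f", seq_len(ncol(feat)))
  for (r in seq_len(repeats)) {
    foldId <- .stratifiedFolds(y, folds, repSeeds[[r]])
    for (f in seq_len(folds)) {
      tr <- foldId != f
      fit <- ranger::ranger(
        x = df[tr, , drop = FALSE], y = y[tr],
        num.trees = cfg$num.trees, mtry = cfg$mtry,
        min.node.size = cfg$min.node.size, splitrule = cfg$splitrule,
        replace = cfg$replace, seed = repSeeds[[r]] %% 1000000L + f,
        num.threads = 1L, verbose = FALSE)
      pred <- stats::predict(fit, data = df[!tr, , drop = FALSE],
                             num.threads = 1L)$predictions
      truth <- y[!tr]
      scores[f, r] <- if (macro) {
        mean(vapply(levels(y), function(cl) .f1Score(truth, pred, cl),
                    numeric(1L)))
      } else .f1Score(truth, pred, positive)
    }
  }
  methods::new("CVResult", scores = scores, seed = as.integer(seed),
               positive = positive,
               config = c(cfg, list(folds = folds, repeats = repeats,
                                    macro = macro)))
}

#' Compare two cross-validation score distributions (Mann-Whitney U)
#'
#' Tests whether the F1 scores of encoding \code{a} are stochastically
#' greater than those of encoding \code{b} (one-sided by default, the
#' directional question "is a actually higher on average"; two-sided and
#' "less" available). Uses the normal approximation with continuity and tie
#' correction, appropriate for the heavily tied score samples repeated CV
#' produces.
#'
#' @param a,b [CVResult-class] objects or numeric score vectors.
#' @param alpha significance level.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @return a [ComparisonResult-class].
#' @examples
#' compareScoreDistributions(c(0.9, 0.95, 0.92), c(0.5, 0.55, 0.52))
#' @export
compareScoreDistributions <- function(a, b, alpha = 0.05,
                                      alternative = c("greater", "less",
                                                      "two.sided")) {
  alternative <- match.arg(alternative)
  sa <- if (methods::is(a, "CVResult")) as.vector(cvScores(a)) else
    as.numeric(a)
  sb <- if (methods::is(b, "CVResult")) as.vector(cvScores(b)) else
    as.numeric(b)
  if (length(sa) == 0L || length(sb) == 0L)
    stop("both score samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(
    sa, sb, alternative = alternative, exact = FALSE, correct = TRUE))
  p <- unname(wt$p.value)
  methods::new("ComparisonResult",
               statistic = unname(wt$statistic),
               pValue = p, alternative = alternative,
               alpha = alpha, significant = p < alpha)
}

#' Impurity-based feature importances of a random forest
#'
#' Fits one random forest (same pinned configuration as
#' [evaluateEncoding()]) on the full data set and returns the mean decrease
#' in impurity per feature, normalized to sum to 1 when any split occurred.
#' Un-flatten with [relevanceMap()] to see which element/level/backbone
#' positions drive the prediction.
#'
#' @param x an [EncodedDataset-class] or samples-by-features matrix.
#' @param labels binary label vector.
#' @param seed seed for the forest.
#' @return named non-negative numeric vector, one value per feature.
#' @export
computeFeatureImportances <- function(x, labels, seed = 42L) {
  feat <- .resolveFeatures(x)
  y <- .resolveLabels(labels, nrow(feat))
  cfg <- .forestConfig(ncol(feat))
  df <- as.data.frame(feat)
  fnames <- colnames(feat)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(ncol(feat)))
  names(df) <- paste0("f", seq_len(ncol(feat)))
  fit <- ranger::ranger(
    x = df, y = y, importance = "impurity",
    num.trees = cfg$num.trees, mtry = cfg$mtry,
    min.node.size = cfg$min.node.size, splitrule = cfg$splitrule,
    replace = cfg$replace, seed = as.integer(seed), num.threads = 1L,
    verbose = FALSE)
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- fnames
  imp
}

#' Write / read cross-validation results as JSON
#'
#' Schema: \code{{scores: [...], mean_f1, seed, config}} with scores in
#' fold-major order.
#'
#' @param x a [CVResult-class].
#' @param path JSON file path.
#' @return \code{writeCVResult}: the path invisibly; \code{readCVResult}:
#'   a [CVResult-class].
#' @export
writeCVResult <- function(x, path) {
  stopifnot(methods::is(x, "CVResult"))
  jsonlite::write_json(
    list(scores = as.vector(x@scores), mean_f1 = mean(x@scores),
         seed = x@seed, positive = x@positive,
         folds = nrow(x@scores), repeats = ncol(x@scores),
         config = x@config[setdiff(names(x@config),
                                   c("folds", "repeats"))]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCVResult
#' @export
readCVResult <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- matrix(j$scores, nrow = j$folds, ncol = j$repeats)
  methods::new("CVResult", scores = scores, seed = as.integer(j$seed),
               positive = as.character(j$positive),
               config = as.list(j$config))
}
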