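#' Fit a principal component space on z-scored expression profiles
#'
#' Each feature is z-scored across the training samples (zero-variance
#' features are dropped first) and the centered matrix is decomposed with
#' [stats::prcomp()]. The space stores the loadings, the eigenvalues of the
#' data covariance, the training-sample coordinates and labels, and the
#' z-scoring parameters needed to project new samples.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Optional class labels per training sample (`"control"` or
#'   hours); required for [classify_nearest()].
#' @return A `component_space`.
#' @export
fit_pca <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs >= 2 samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all features have zero variance")
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  structure(list(loadings = pc$rotation,
                 eigenvalues = pc$sdev^2,
                 scores = pc$x,
                 center = mu[keep], scale = sdv[keep],
                 features = colnames(z),
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "component_space")
}

#' @export
print.component_space <- function(x, ...) {
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat("component_space:", length(x$features), "features,",
      nrow(x$scores), "samples;",
      "PC1-2 explain", sprintf("%.1f%%", 100 * sum(ev[1:min(2, length(ev))])),
      "\n")
  invisible(x)
}

#' Project new profiles into a fitted component space
#'
#' @param space A `component_space`.
#' @param x Named profile vector or samples x features matrix (raw scale).
#' @return Matrix of coordinates (samples x components).
#' @export
project_pca <- function(space, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) {
    miss <- setdiff(space$features, colnames(x))
    if (length(miss)) stop("profile lacks feature(s): ", miss[1L])
    x <- x[, space$features, drop = FALSE]
  } else if (ncol(x) != length(space$features)) {
    stop("profile has ", ncol(x), " features; space expects ",
         length(space$features))
  }
  z <- sweep(sweep(x, 2L, space$center), 2L, space$scale, "/")
  z %*% space$loadings
}

#' Classify by the nearest training sample in component space
#'
#' The test profile is z-scored with the training means/sds, projected, and
#' compared to every training coordinate by Euclidean distance over the first
#' `n_components` components; the label of the nearest training sample is
#' returned. Equidistant neighbours with different labels resolve to the
#' earlier time point, flagged as a tie.
#'
#' @param space A `component_space` fitted with labels.
#' @param x Named test profile (raw FPKM scale).
#' @param n_components Number of leading components to use (default: all).
#' @return List with `result` (a `classification_result` whose scores are the
#'   minimal distance per class), `nearest` (sample index) and `distances`
#'   (per training sample).
#' @export
classify_nearest <- function(space, x, n_components = NULL) {
  stopifnot(inherits(space, "component_space"))
  if (is.null(space$labels)) stop("component space was fitted without labels")
  k <- ncol(space$scores)
  if (is.null(n_components)) n_components <- k
  if (n_components > k)
    stop("n_components (", n_components, ") exceeds available components (", k, ")")
  proj <- project_pca(space, x)[1L, seq_len(n_components)]
  tr <- space$scores[, seq_len(n_components), drop = FALSE]
  d <- sqrt(rowSums(sweep(tr, 2L, proj)^2))
  per_class <- tapply(d, space$labels, min)
  res <- classification_result(stats::setNames(as.numeric(per_class),
                                               names(per_class)),
                               higher_is_better = FALSE, method = "pca_nearest")
  list(result = res, nearest = which.min(d), distances = d)
}

#' Rank features by loading-eigenvalue weight
#'
#' Per-feature weight is the dot product of its absolute loadings with the
#' component eigenvalues, `sum_c |loading(f, c)| * lambda_c`; features with
#' the highest weights drive the most variance between the classes.
#'
#' @param space A `component_space`.
#' @return Data frame of `feature` and `weight`, sorted descending.
#' @export
rank_loading_features <- function(space) {
  stopifnot(inherits(space, "component_space"))
  w <- drop(abs(space$loadings) %*% space$eigenvalues)
  out <- data.frame(feature = rownames(space$loadings), weight = w,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}
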