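#' Train all pairwise linear SVMs
#'
#' One soft-margin linear-kernel SVM (cost 1) per unordered class pair, so K
#' classes yield choose(K, 2) models (10 classes: the control pool plus nine
#' injured time points, 45 models). Features are z-scored with means/sds
#' computed once on the full training matrix; zero-variance features are
#' dropped. Training runs at replicate level.
#'
#' @param x Numeric matrix, samples x features (e.g. `t(study$values)` after
#'   feature selection).
#' @param labels Character vector of class labels per sample (`"control"` or
#'   hours).
#' @param cost Soft-margin cost (default 1).
#' @param scale Z-score features before training (default `TRUE`).
#' @return An `svm_pairwise_ensemble`: list of hyperplane models (each with
#'   normal vector `w`, intercept `b`, and the `positive`/`negative` class it
#'   separates), plus the scaling parameters and class set.
#' @export
train_pairwise <- function(x, labels, cost = 1, scale = TRUE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("one label per sample row required")
  classes <- names(sort(stats::setNames(
    ifelse(unique(labels) == "control", -Inf,
           suppressWarnings(as.numeric(unique(labels)))), unique(labels))))
  if (length(classes) < 2L) stop("need >= 2 classes")
  empty <- classes[!classes %in% labels]
  if (length(empty)) stop("class with zero samples: ", empty[1L])
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  keep <- sd > 0
  if (!any(keep)) stop("all features have zero variance")
  if (!scale) { mu[] <- 0; sd[] <- 1 }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep], "/")
  models <- list()
  for (i in seq_len(length(classes) - 1L)) {
    for (j in (i + 1L):length(classes)) {
      a <- classes[i]; b <- classes[j]
      idx <- labels %in% c(a, b)
      y <- factor(labels[idx], levels = c(a, b))
      fit <- e1071::svm(xs[idx, , drop = FALSE], y, kernel = "linear",
                        cost = cost, scale = FALSE)
      # libsvm decision value f(z) = w.z - rho; the positive side is the
      # class libsvm saw first (fit$labels order), not the first factor level
      w <- drop(crossprod(fit$coefs, fit$SV))
      models[[paste(a, b, sep = " vs ")]] <-
        list(w = stats::setNames(w, colnames(xs)), b = -fit$rho,
             positive = fit$levels[fit$labels[1L]],
             negative = fit$levels[fit$labels[2L]])
    }
  }
  structure(list(models = models, classes = classes,
                 center = mu[keep], scale = sd[keep],
                 features = colnames(xs)), class = "svm_pairwise_ensemble")
}

#' Perpendicular distance of a profile from a hyperplane
#'
#' `R = |w . x + b| / ||w||` for a hyperplane with normal vector `w` and
#' intercept `b`.
#'
#' @param model A single hyperplane model (element of
#'   `svm_pairwise_ensemble$models`, or any list with `w` and `b`).
#' @param x Numeric profile of the model's dimensionality (already in the
#'   space the model was trained in).
#' @return Non-negative distance.
#' @export
hyperplane_distance <- function(model, x) {
  if (length(x) != length(model$w))
    stop("profile has ", length(x), " dimensions; hyperplane expects ",
         length(model$w))
  abs(sum(model$w * x) + model$b) / sqrt(sum(model$w^2))
}

# project a raw profile into the ensemble's z-scored feature space
ensemble_space <- function(ensemble, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(ensemble$features, names(x))
    if (length(miss)) stop("profile lacks feature(s): ", miss[1L])
    x <- x[ensemble$features]
  } else if (length(x) != length(ensemble$features)) {
    stop("profile has ", length(x), " dimensions; ensemble expects ",
         length(ensemble$features))
  }
  (x - ensemble$center) / ensemble$scale
}

#' One-vs-one classification by distance-weighted voting
#'
#' Every pairwise model votes for its predicted side's class, and the vote is
#' weighted by the sample's distance from that model's hyperplane. Weighted
#' votes are summed per class; the class with the highest tally wins (ties go
#' to the earlier time point and are flagged).
#'
#' @param ensemble An `svm_pairwise_ensemble` from [train_pairwise()].
#' @param x Named FPKM profile of a test sample (raw scale; the ensemble's
#'   stored scaling is applied).
#' @return List with `tally` (named per-class weighted vote totals, the
#'   Fig.-style bar heights) and `result` (a `classification_result`).
#' @export
classify_one_vs_one <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "svm_pairwise_ensemble"))
  z <- ensemble_space(ensemble, x)
  tally <- stats::setNames(numeric(length(ensemble$classes)), ensemble$classes)
  for (m in ensemble$models) {
    f <- sum(m$w * z) + m$b
    side <- if (f >= 0) m$positive else m$negative
    tally[side] <- tally[side] + abs(f) / sqrt(sum(m$w^2))
  }
  list(tally = tally,
       result = classification_result(tally, method = "svm_one_vs_one"))
}

#' One-vs-all elimination cascade
#'
#' Stage one trains control vs all injured; a sample on the injured side then
#' enters an elimination loop: each remaining time point is trained against
#' the rest of the remaining set, and the time point whose one-vs-rest
#' classifier pushes the sample furthest toward "rest" is eliminated, one per
#' round, until a single time point survives.
#'
#' @param x_train Training matrix, samples x features.
#' @param labels Training class labels (`"control"` or hours).
#' @param x Named FPKM profile of the test sample.
#' @param cost,scale Passed to the underlying SVM fits.
#' @return List with `result` (a `classification_result` over the surviving
#'   class; scores are the final-round signed margins, with eliminated classes
#'   at `-Inf`) and `elimination_order` (classes in the order discarded).
#' @export
classify_one_vs_all <- function(x_train, labels, x, cost = 1, scale = TRUE) {
  x_train <- as.matrix(x_train)
  labels <- as.character(labels)
  if (is.null(names(x))) names(x) <- colnames(x_train)
  x <- x[colnames(x_train)]
  # signed distance of x from the (target vs rest) hyperplane; > 0 = target side
  binary_margin <- function(xt, lab2, target) {
    mu <- colMeans(xt); sdv <- apply(xt, 2L, stats::sd)
    keep <- sdv > 0
    if (!scale) { mu[] <- 0; sdv[] <- 1 }
    xs <- sweep(sweep(xt[, keep, drop = FALSE], 2L, mu[keep]), 2L,
                sdv[keep], "/")
    y <- factor(ifelse(lab2 == target, target, "rest"),
                levels = c(target, "rest"))
    fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    xz <- (x[keep] - mu[keep]) / sdv[keep]
    f <- (sum(w * xz) - fit$rho) / sqrt(sum(w^2))
    if (fit$levels[fit$labels[1L]] == target) f else -f
  }
  f_ctrl <- binary_margin(x_train, labels, "control")
  if (f_ctrl >= 0) {
    return(list(result = classification_result(c(control = f_ctrl),
                                               method = "svm_one_vs_all"),
                elimination_order = character(0)))
  }
  inj <- labels != "control"
  x_inj <- x_train[inj, , drop = FALSE]
  lab_inj <- labels[inj]
  remaining <- unique(lab_inj)[order(as.numeric(unique(lab_inj)))]
  order_out <- character(0)
  final_scores <- stats::setNames(rep(-Inf, length(remaining)), remaining)
  while (length(remaining) > 1L) {
    idx <- lab_inj %in% remaining
    margins <- vapply(remaining, function(t)
      binary_margin(x_inj[idx, , drop = FALSE], lab_inj[idx], t), 0)
    final_scores[remaining] <- margins
    drop_cls <- remaining[which.min(margins)]
    order_out <- c(order_out, drop_cls)
    remaining <- setdiff(remaining, drop_cls)
  }
  final_scores[remaining] <- max(final_scores[is.finite(final_scores)], 0) + 1
  list(result = classification_result(final_scores, method = "svm_one_vs_all"),
       elimination_order = order_out)
}
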