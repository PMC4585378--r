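#' Fit the time point-specific signature model
#'
#' Each feature earns a directional weight of one over the number of time
#' points at which it was called in that direction: a gene up at two time
#' points and down at one carries up-weight 1/2 and down-weight 1. Up and
#' down counts are kept separate; a direction with no calls has no weight.
#'
#' @param fc_train Training `fold_change_matrix` (typically restricted to a
#'   significant-feature subset via [subset_fold_changes()]).
#' @return A `specific_signature_model`: per-feature `up_weight` and
#'   `down_weight` (NA when undefined), the `expected` call matrix, and
#'   `time_points`.
#' @export
fit_specific <- function(fc_train) {
  stopifnot(inherits(fc_train, "fold_change_matrix"))
  n_up <- rowSums(fc_train$call == "up")
  n_down <- rowSums(fc_train$call == "down")
  structure(list(
    up_weight = ifelse(n_up > 0, 1 / n_up, NA_real_),
    down_weight = ifelse(n_down > 0, 1 / n_down, NA_real_),
    expected = fc_train$call,
    time_points = fc_train$time_points), class = "specific_signature_model")
}

#' Score a test profile against one candidate class (specific method)
#'
#' The match score starts at zero; every feature whose test call equals the
#' model's expected call at the candidate class contributes its directional
#' weight (up or down), or `none_increment` when both calls are "none". The
#' control candidate expects "none" everywhere.
#'
#' @param model A `specific_signature_model`.
#' @param test_calls Named character vector of test calls (`"up"`, `"down"`,
#'   `"none"`) over the model's features, e.g. `test_profile(...)$call`.
#' @param candidate `"control"` or an hour in `model$time_points`.
#' @param none_increment Increment for a none/none match (default 0.5).
#' @return The match score (numeric scalar).
#' @export
score_specific <- function(model, test_calls, candidate, none_increment = 0.5) {
  stopifnot(inherits(model, "specific_signature_model"))
  feats <- intersect(rownames(model$expected), names(test_calls))
  if (!length(feats))
    stop("test profile shares no features with the signature model")
  expected <- expected_calls(model, candidate)[feats]
  tc <- test_calls[feats]
  match_up <- expected == "up" & tc == "up"
  match_down <- expected == "down" & tc == "down"
  match_none <- expected == "none" & tc == "none"
  sum(model$up_weight[feats][match_up], na.rm = TRUE) +
    sum(model$down_weight[feats][match_down], na.rm = TRUE) +
    none_increment * sum(match_none)
}

expected_calls <- function(model, candidate) {
  cand <- as.character(candidate)
  if (cand == "control")
    return(stats::setNames(rep("none", nrow(model$expected)),
                           rownames(model$expected)))
  j <- match(cand, colnames(model$expected))
  if (is.na(j)) stop("unknown candidate class: ", cand)
  stats::setNames(model$expected[, j], rownames(model$expected))
}

#' Classify a test profile with the specific signature method
#'
#' Scores the profile against every candidate class (all training time points
#' plus control) and returns the argmax with its confidence tier.
#'
#' @inheritParams score_specific
#' @param confidence_high,confidence_medium Margin thresholds passed to
#'   [assign_confidence()].
#' @return A `classification_result`.
#' @export
classify_specific <- function(model, test_calls, none_increment = 0.5,
                              confidence_high = 100, confidence_medium = 50) {
  cands <- c("control", as.character(model$time_points))
  scores <- vapply(cands, function(k)
    score_specific(model, test_calls, k, none_increment), 0)
  assign_confidence(classification_result(scores, method = "specific"),
                    high = confidence_high, medium = confidence_medium)
}

#' Fit the time point-weighted signature model
#'
#' Per feature, the maximum |log2 fold change| over the time points is found
#' and every time point's weight is its |log2 fold change| as a fraction of
#' that maximum (so the peak time point carries weight 1). Expected direction
#' comes from the training calls; an all-zero row is inert (all weights 0).
#'
#' @param fc_train Training `fold_change_matrix`.
#' @return A `weighted_signature_model`: `weights` matrix in [0, 1],
#'   `expected` call matrix, per-feature `peak_tp` (hour of maximum
#'   |fold change|; NA for inert rows), and `time_points`.
#' @export
fit_weighted <- function(fc_train) {
  stopifnot(inherits(fc_train, "fold_change_matrix"))
  afc <- abs(fc_train$log2fc)
  mx <- apply(afc, 1L, max)
  w <- afc / ifelse(mx > 0, mx, 1)
  w[mx == 0, ] <- 0
  peak <- stats::setNames(fc_train$time_points[apply(afc, 1L, which.max)],
                          rownames(afc))
  peak[mx == 0] <- NA_real_
  structure(list(weights = w, expected = fc_train$call, peak_tp = peak,
                 time_points = fc_train$time_points),
            class = "weighted_signature_model")
}

#' Score a test profile against one candidate class (weighted method)
#'
#' A feature matches when its test call equals the model's expected call at
#' the candidate time point; a directional match contributes the model's
#' normalized fold-change weight there, a none/none match contributes
#' `none_increment`. The control candidate expects "none" everywhere.
#'
#' @param model A `weighted_signature_model`.
#' @param test_calls Named character vector of test calls over the model's
#'   features.
#' @param candidate `"control"` or an hour in `model$time_points`.
#' @param none_increment Increment for a none/none match (default 0.5).
#' @return The match score.
#' @export
score_weighted <- function(model, test_calls, candidate, none_increment = 0.5) {
  stopifnot(inherits(model, "weighted_signature_model"))
  feats <- intersect(rownames(model$expected), names(test_calls))
  if (!length(feats))
    stop("test profile shares no features with the signature model")
  cand <- as.character(candidate)
  if (cand == "control") {
    expected <- stats::setNames(rep("none", length(feats)), feats)
    w <- stats::setNames(rep(0, length(feats)), feats)
  } else {
    j <- match(cand, colnames(model$expected))
    if (is.na(j)) stop("unknown candidate class: ", cand)
    expected <- stats::setNames(model$expected[feats, j], feats)
    w <- stats::setNames(model$weights[feats, j], feats)
  }
  tc <- test_calls[feats]
  directional <- (expected == "up" & tc == "up") |
    (expected == "down" & tc == "down")
  sum(w[directional]) + none_increment * sum(expected == "none" & tc == "none")
}

#' Classify a test profile with the weighted signature method
#'
#' @inheritParams score_weighted
#' @param confidence_high,confidence_medium Margin thresholds passed to
#'   [assign_confidence()].
#' @return A `classification_result`.
#' @export
classify_weighted <- function(model, test_calls, none_increment = 0.5,
                              confidence_high = 100, confidence_medium = 50) {
  cands <- c("control", as.character(model$time_points))
  scores <- vapply(cands, function(k)
    score_weighted(model, test_calls, k, none_increment), 0)
  assign_confidence(classification_result(scores, method = "weighted"),
                    high = confidence_high, medium = confidence_medium)
}

#' Build the +1/0/-1 score matrix of single-time-point features
#'
#' Restricted to features significant at exactly one training time point:
#' +1 at an up-called time point, -1 at a down-called one, 0 elsewhere.
#'
#' @param fc A `fold_change_matrix` (any features; rows with other than
#'   exactly one call are dropped).
#' @return Integer matrix (features x time points) with entries in
#'   \{-1, 0, +1\}.
#' @export
score_matrix <- function(fc) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  keep <- rowSums(fc$call != "none") == 1L
  calls <- fc$call[keep, , drop = FALSE]
  m <- matrix(0L, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  m[calls == "up"] <- 1L
  m[calls == "down"] <- -1L
  m
}

#' Classify by minimum L1 distance between score matrices
#'
#' The test sample's signed fold-change profile is thresholded into a
#' +1/0/-1 vector over the training matrix's features; for every candidate
#' time point the element-wise absolute difference against the corresponding
#' training column is summed, and the candidate with the smallest total
#' distance wins. A control candidate (all-zero column) is included.
#'
#' @param train_scores Training score matrix from [score_matrix()].
#' @param test_log2fc Named signed log2 fold-change vector of the test sample
#'   (vs the control reference), or an already-thresholded -1/0/+1 vector
#'   given as integers.
#' @param min_fold Threshold used to build the test score vector (default 2).
#' @return A `classification_result` (scores are distances; smaller wins).
#' @export
score_matrix_classify <- function(train_scores, test_log2fc, min_fold = 2) {
  feats <- intersect(rownames(train_scores), names(test_log2fc))
  if (!length(feats))
    stop("test profile shares no features with the training score matrix")
  ts <- test_log2fc[feats]
  s <- if (all(ts %in% c(-1L, 0L, 1L))) as.integer(ts)
  else {
    calls <- fold_change_calls(ts, min_fold)
    ifelse(calls == "up", 1L, ifelse(calls == "down", -1L, 0L))
  }
  tr <- train_scores[feats, , drop = FALSE]
  d <- colSums(abs(tr - s))
  d <- c(control = sum(abs(s)), d)
  classification_result(d, higher_is_better = FALSE, method = "score_matrix")
}

#' Serialize a signature model as long-format TSV
#'
#' @param model A `specific_signature_model` or `weighted_signature_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature_model <- function(model, path) {
  tps <- model$time_points
  feats <- rownames(model$expected)
  if (inherits(model, "specific_signature_model")) {
    w <- matrix(NA_real_, length(feats), length(tps))
    up <- model$expected == "up"; dn <- model$expected == "down"
    w[up] <- rep(model$up_weight, length(tps))[up]
    w[dn] <- rep(model$down_weight, length(tps))[dn]
  } else {
    w <- model$weights
  }
  long <- data.frame(feature = rep(feats, times = length(tps)),
                     time_point_h = rep(tps, each = length(feats)),
                     weight = as.vector(w),
                     expected_call = as.vector(model$expected))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
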