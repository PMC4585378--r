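#' Thresholds for significance filtering
#'
#' @param mode One of `all_significant_genes`, `single_tp_genes`,
#'   `all_significant_isoforms`, `single_tp_isoforms`. The isoform modes are
#'   identical in logic and exist so callers can tag which feature table a
#'   run used.
#' @param min_fpkm Minimum aggregate FPKM a feature must reach at one or more
#'   time points/conditions (1 for the discovery filter, 0.5 for the
#'   classification filter).
#' @param q_max Significance cutoff on upstream q-values, or `NULL` to disable.
#' @param min_fold Minimum fold change (ratio scale; 2 means |log2 fc| >= 1).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(mode = c("all_significant_genes", "single_tp_genes",
                                 "all_significant_isoforms", "single_tp_isoforms"),
                        min_fpkm = 0.5, q_max = NULL, min_fold = 2) {
  mode <- match.arg(mode)
  if (min_fpkm <= 0) stop("`min_fpkm` must be > 0")
  if (min_fold <= 1) stop("`min_fold` must be > 1")
  if (!is.null(q_max) && (q_max <= 0 || q_max > 1)) stop("`q_max` must lie in (0, 1]")
  structure(list(mode = mode, min_fpkm = min_fpkm, q_max = q_max,
                 min_fold = min_fold), class = "filter_spec")
}

#' Threshold signed log2 fold changes into up/down/none calls
#'
#' @param log2fc Numeric vector or matrix of log2 fold changes.
#' @param min_fold Fold-change threshold on the ratio scale (default 2).
#' @return Character object of the same shape with entries `"up"`, `"down"`,
#'   `"none"`.
#' @export
fold_change_calls <- function(log2fc, min_fold = 2) {
  thr <- log2(min_fold)
  out <- ifelse(log2fc >= thr, "up", ifelse(log2fc <= -thr, "down", "none"))
  if (is.matrix(log2fc)) dimnames(out) <- dimnames(log2fc)
  out
}

#' Per-time-point fold-change matrix
#'
#' For each feature and time point computes
#' `log2((injured + eps) / (control + eps))` from the aggregated injured and
#' control profiles, pairing every injured time point with its control of the
#' same hour (the contralateral design), and assigns up/down/none calls from
#' the two-fold rule.
#'
#' @param injured Aggregated `expression_study` of injured samples (one column
#'   per time point), or a full aggregated study containing both conditions.
#' @param control Aggregated control `expression_study`; omit when `injured`
#'   carries both conditions.
#' @param pseudocount Added to numerator and denominator before the ratio
#'   (default 0.5), so zero/zero yields log2 fc 0.
#' @param spec A [filter_spec()] supplying the call threshold.
#' @return A `fold_change_matrix`: list with `log2fc` and `call` matrices
#'   (features x time points), `fpkm_max` (per-feature maximum aggregate FPKM
#'   over all time points and conditions), `time_points`, and `qvalues` when
#'   the study carried them.
#' @export
compute_fold_changes <- function(injured, control = NULL, pseudocount = 0.5,
                                 spec = filter_spec()) {
  stopifnot(inherits(injured, "expression_study"))
  if (is.null(control)) {
    full <- injured
    inj_idx <- full$samples$condition == "injured"
    injured <- subset_samples(full, full$samples$sample_id[inj_idx])
    control <- subset_samples(full, full$samples$sample_id[!inj_idx])
  }
  stopifnot(inherits(control, "expression_study"))
  if (!identical(rownames(injured$values), rownames(control$values)))
    stop("injured and control studies must share the same feature list")
  tps <- sort(unique(injured$samples$time_point_h))
  ctl_tps <- control$samples$time_point_h
  missing_tp <- setdiff(tps, ctl_tps)
  if (length(missing_tp))
    stop("no control counterpart for time point(s): ",
         paste(missing_tp, collapse = ", "), " h")
  inj_cols <- match(tps, injured$samples$time_point_h)
  ctl_cols <- match(tps, ctl_tps)
  if (anyDuplicated(injured$samples$time_point_h) ||
      max(table(ctl_tps)) > 1L)
    stop("expected aggregated studies with one column per time point")
  num <- injured$values[, inj_cols, drop = FALSE] + pseudocount
  den <- control$values[, ctl_cols, drop = FALSE] + pseudocount
  l2 <- log2(num / den)
  colnames(l2) <- as.character(tps)
  fpkm_max <- pmax(apply(injured$values, 1L, max), apply(control$values, 1L, max))
  qv <- injured$qvalues
  if (!is.null(qv)) qv <- qv[, as.character(tps), drop = FALSE]
  structure(list(log2fc = l2,
                 call = fold_change_calls(l2, spec$min_fold),
                 fpkm_max = fpkm_max,
                 time_points = tps,
                 qvalues = qv),
            class = "fold_change_matrix")
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat("fold_change_matrix:", nrow(x$log2fc), "features x",
      length(x$time_points), "time points\n")
  cat("calls:", sum(x$call == "up"), "up,", sum(x$call == "down"), "down\n")
  invisible(x)
}

#' Select significant features
#'
#' Applies the three-clause rule: maximum aggregate FPKM at or above
#' `min_fpkm`, q-value below `q_max` at one or more time points (when q-values
#' are enabled and available), and at least one time point with an up or down
#' call. The `single_tp_*` modes additionally require exactly one called time
#' point (up and down counted together).
#'
#' @param fc A `fold_change_matrix`.
#' @param spec A [filter_spec()].
#' @return Character vector of selected feature ids.
#' @export
select_features <- function(fc, spec = filter_spec()) {
  stopifnot(inherits(fc, "fold_change_matrix"), inherits(spec, "filter_spec"))
  calls <- fold_change_calls(fc$log2fc, spec$min_fold)
  n_called <- rowSums(calls != "none")
  keep <- fc$fpkm_max >= spec$min_fpkm & n_called >= 1L
  if (!is.null(spec$q_max)) {
    if (is.null(fc$qvalues))
      stop("filter_spec enables q_max but the fold-change matrix has no q-values")
    keep <- keep & rowSums(fc$qvalues < spec$q_max, na.rm = TRUE) >= 1L
  }
  if (spec$mode %in% c("single_tp_genes", "single_tp_isoforms"))
    keep <- keep & n_called == 1L
  rownames(fc$log2fc)[keep]
}

#' Restrict a fold-change matrix to a feature subset
#'
#' @param fc A `fold_change_matrix`.
#' @param features Feature ids to keep.
#' @return The restricted `fold_change_matrix`.
#' @export
subset_fold_changes <- function(fc, features) {
  stopifnot(inherits(fc, "fold_change_matrix"))
  idx <- match(features, rownames(fc$log2fc))
  if (anyNA(idx)) stop("unknown feature: ", features[is.na(idx)][1L])
  structure(list(log2fc = fc$log2fc[idx, , drop = FALSE],
                 call = fc$call[idx, , drop = FALSE],
                 fpkm_max = fc$fpkm_max[idx],
                 time_points = fc$time_points,
                 qvalues = if (is.null(fc$qvalues)) NULL else
                   fc$qvalues[idx, , drop = FALSE]),
            class = "fold_change_matrix")
}

#' Fold-change profile of a single test sample
#'
#' Computes the signed log2 fold change of one sample's FPKM vector against a
#' control reference profile, plus the up/down/none call under the two-fold
#' rule. This is the per-sample view the signature classifiers consume.
#'
#' @param x Named FPKM vector (one test sample) or an `expression_study` with
#'   a single column.
#' @param control_ref Named control reference vector (see
#'   [control_reference()]).
#' @param pseudocount Pseudocount for the ratio (default 0.5).
#' @param min_fold Call threshold on the ratio scale (default 2).
#' @return List with `log2fc` and `call`, both named by feature.
#' @export
test_profile <- function(x, control_ref, pseudocount = 0.5, min_fold = 2) {
  if (inherits(x, "expression_study")) {
    if (ncol(x$values) != 1L) stop("`x` must be a single sample")
    x <- x$values[, 1L]
  }
  common <- intersect(names(x), names(control_ref))
  if (!length(common)) stop("test sample and control reference share no features")
  l2 <- log2((x[common] + pseudocount) / (control_ref[common] + pseudocount))
  list(log2fc = l2, call = fold_change_calls(l2, min_fold))
}

#' Serialize a fold-change matrix as long-format TSV
#'
#' @param fc A `fold_change_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fold_changes <- function(fc, path) {
  long <- data.frame(
    feature = rep(rownames(fc$log2fc), times = length(fc$time_points)),
    time_point_h = rep(fc$time_points, each = nrow(fc$log2fc)),
    log2fc = as.vector(fc$log2fc),
    call = as.vector(fc$call))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
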