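#' Exclude poorly correlating replicates
#'
#' Within each (time point, condition) group, pairwise Pearson correlation is
#' computed across all features. A replicate is excluded when it is a clear
#' outlier: its squared correlation falls below `r2_min` against every other
#' replicate of its group, and the group holds at least three replicates so
#' the outlier is identifiable. A discordant pair (two replicates below the
#' threshold with no third to adjudicate) is retained with a warning.
#' Exclusion is decided in a single simultaneous pass, not iteratively;
#' singleton groups pass untouched.
#'
#' @param study An `expression_study` at replicate level.
#' @param r2_min Minimum squared Pearson correlation a replicate must attain
#'   against every other replicate in its group (default 0.95).
#' @param log_space If `TRUE`, correlate `log2(FPKM + 0.5)` instead of raw FPKM.
#' @return A list with `study` (the filtered `expression_study`) and
#'   `excluded` (character vector of dropped sample ids).
#' @export
filter_replicates <- function(study, r2_min = 0.95, log_space = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$samples
  grp <- interaction(meta$condition, meta$time_point_h, drop = TRUE)
  vals <- if (log_space) log2(study$values + 0.5) else study$values
  excluded <- character(0)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    cm2 <- stats::cor(vals[, idx, drop = FALSE])^2
    diag(cm2) <- 1
    bad <- if (length(idx) >= 3L)
      vapply(seq_along(idx), function(i) max(cm2[i, -i]) < r2_min, TRUE)
    else rep(FALSE, length(idx))
    if (all(bad))
      stop("replicate filter emptied group ", g,
           " (no replicate correlates with any other at R^2 >= ", r2_min, ")")
    keep_i <- idx[!bad]
    if (length(keep_i) >= 2L) {
      km <- cm2[!bad, !bad, drop = FALSE]
      if (min(km[upper.tri(km)]) < r2_min)
        warning("group ", g, " retains replicates below the R^2 threshold ",
                "with no identifiable outlier", call. = FALSE)
    }
    excluded <- c(excluded, meta$sample_id[idx[bad]])
  }
  keep <- setdiff(meta$sample_id, excluded)
  list(study = subset_samples(study, keep), excluded = excluded)
}

#' Aggregate replicates into one profile per group
#'
#' For every (time point, condition) group, each feature's replicate FPKMs are
#' merged: if their median is 0 the aggregate is 0, otherwise their mean. The
#' result carries one pseudo-sample per group (replicate slot `NA`).
#'
#' @param study A replicate-level `expression_study` (ideally after
#'   [filter_replicates()]).
#' @return An aggregated `expression_study`.
#' @export
aggregate_replicates <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  meta <- study$samples
  key <- paste(meta$condition, meta$time_point_h, sep = "@")
  groups <- unique(key)
  agg <- matrix(0, nrow(study$values), length(groups),
                dimnames = list(rownames(study$values), NULL))
  out_meta <- data.frame(sample_id = character(length(groups)),
                         condition = character(length(groups)),
                         time_point_h = numeric(length(groups)),
                         replicate = NA_integer_,
                         stringsAsFactors = FALSE)
  for (j in seq_along(groups)) {
    idx <- which(key == groups[j])
    block <- study$values[, idx, drop = FALSE]
    med <- apply(block, 1L, stats::median)
    mn <- rowMeans(block)
    agg[, j] <- ifelse(med == 0, 0, mn)
    out_meta$condition[j] <- meta$condition[idx[1L]]
    out_meta$time_point_h[j] <- meta$time_point_h[idx[1L]]
    out_meta$sample_id[j] <- paste0(meta$condition[idx[1L]], "_",
                                    meta$time_point_h[idx[1L]], "h_agg")
  }
  colnames(agg) <- out_meta$sample_id
  expression_study(agg, out_meta, study$qvalues)
}

#' Pooled control reference profile
#'
#' Mean of the aggregated control columns; used as the denominator when a test
#' sample's own paired control is unknown (blinded samples).
#'
#' @param agg An aggregated `expression_study` containing control columns.
#' @return Named numeric vector, one value per feature.
#' @export
control_reference <- function(agg) {
  stopifnot(inherits(agg, "expression_study"))
  ctrl <- agg$samples$condition == "control"
  if (!any(ctrl)) stop("study contains no control samples")
  rowMeans(agg$values[, ctrl, drop = FALSE])
}
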