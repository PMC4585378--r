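#' Mean pathway expression scores
#'
#' A pathway's activation score in a sample/time-point column is the
#' arithmetic mean FPKM over its member features present in the study;
#' members absent from the (possibly filtered) table are dropped from the
#' mean, and a pathway with no members present is skipped with a warning.
#'
#' @param study An aggregated `expression_study` (or any `expression_study`;
#'   scores are computed per column), or a plain features x columns matrix.
#' @param sets A `gene_set_collection` from [read_gmt()].
#' @return A `pathway_score_matrix`: list with `scores` (pathways x columns),
#'   `coverage` (members found per pathway), `skipped` (pathway names with no
#'   members present) and the column metadata when a study was given.
#' @export
pathway_scores <- function(study, sets) {
  vals <- if (inherits(study, "expression_study")) study$values else as.matrix(study)
  meta <- if (inherits(study, "expression_study")) study$samples else NULL
  feats <- rownames(vals)
  keep_members <- lapply(sets, function(s) intersect(unique(s$members), feats))
  coverage <- vapply(keep_members, length, 1L)
  skipped <- names(sets)[coverage == 0L]
  if (length(skipped))
    warning("skipping ", length(skipped),
            " pathway(s) with no members in the study: ",
            paste(utils::head(skipped, 3L), collapse = ", "),
            if (length(skipped) > 3L) ", ..." else "")
  used <- names(sets)[coverage > 0L]
  scores <- t(vapply(used, function(nm) {
    colMeans(vals[keep_members[[nm]], , drop = FALSE])
  }, numeric(ncol(vals))))
  if (ncol(vals) == 1L) {
    scores <- matrix(scores, ncol = 1L, dimnames = list(used, colnames(vals)))
  }
  structure(list(scores = scores, coverage = coverage[used],
                 skipped = skipped, samples = meta),
            class = "pathway_score_matrix")
}

#' Pathway activation Z-scores across the injured time course
#'
#' Standardizes each pathway's score profile across the injured time points:
#' `Z_t = (score_t - mean) / sd`, with the mean and sd taken over the time
#' points. Pathways with zero spread are flagged inert (Z undefined). A
#' |Z| > 2 flag marks time points where activation deviates significantly
#' (two-sided normal tail, p < 0.05).
#'
#' @param pscores A `pathway_score_matrix` whose columns are the injured
#'   time-point aggregates.
#' @param z_threshold Significance threshold on |Z| (default 2).
#' @return A `pathway_zscores`: list with `z` (pathways x time points),
#'   `significant` (logical matrix, `|Z| > z_threshold`) and `inert`
#'   (pathway names with zero sd).
#' @export
pathway_zscores <- function(pscores, z_threshold = 2) {
  stopifnot(inherits(pscores, "pathway_score_matrix"))
  s <- pscores$scores
  if (ncol(s) < 2L) stop("Z-scores need >= 2 time points")
  mu <- rowMeans(s)
  sdv <- apply(s, 1L, stats::sd)
  z <- (s - mu) / ifelse(sdv > 0, sdv, NA_real_)
  inert <- rownames(s)[sdv == 0]
  sig <- !is.na(z) & abs(z) > z_threshold
  structure(list(z = z, significant = sig, inert = inert,
                 z_threshold = z_threshold), class = "pathway_zscores")
}

#' Select significantly modulated pathways
#'
#' Keeps pathways with |Z| above the threshold at one or more time points in
#' conjunction with at least a `min_fold` change (injured vs control pathway
#' scores) at one or more time points.
#'
#' @param z A `pathway_zscores`.
#' @param fc Pathway-level `fold_change_matrix` (from [compute_fold_changes()]
#'   run on injured and control pathway-score studies).
#' @param min_fold Fold-change clause threshold (default 2).
#' @return Character vector of selected pathway names.
#' @export
select_significant_pathways <- function(z, fc, min_fold = 2) {
  stopifnot(inherits(z, "pathway_zscores"), inherits(fc, "fold_change_matrix"))
  common <- intersect(rownames(z$z), rownames(fc$log2fc))
  z_ok <- rowSums(z$significant[common, , drop = FALSE]) >= 1L
  calls <- fold_change_calls(fc$log2fc[common, , drop = FALSE], min_fold)
  fc_ok <- rowSums(calls != "none") >= 1L
  common[z_ok & fc_ok]
}

#' Convert pathway scores into an expression-study container
#'
#' Lets every gene-level classifier run unchanged at pathway resolution:
#' pathways become the features.
#'
#' @param pscores A `pathway_score_matrix` computed from an
#'   `expression_study` (so column metadata is available).
#' @return An `expression_study` whose features are pathways.
#' @export
pathway_study <- function(pscores) {
  stopifnot(inherits(pscores, "pathway_score_matrix"))
  if (is.null(pscores$samples))
    stop("pathway scores were computed from a bare matrix; no sample metadata")
  expression_study(pscores$scores, pscores$samples)
}

#' Classify a test sample at pathway resolution
#'
#' Substitutes pathway score profiles for gene profiles and delegates to the
#' chosen classifier; the winning class is also mapped to its coarse healing
#' period (early 3--24 h, middle 48--168 h, late 336--672 h).
#'
#' @param train_agg Aggregated training `expression_study` (both conditions,
#'   gene level).
#' @param train_reps Replicate-level training `expression_study` (needed for
#'   `method = "svm"`; ignored otherwise).
#' @param test Single-sample test `expression_study` or named FPKM vector
#'   (gene level).
#' @param sets A `gene_set_collection`.
#' @param method One of `"specific"`, `"weighted"`, `"pca"`, `"svm"`.
#' @param pseudocount,min_fold Fold-change parameters for the signature
#'   methods.
#' @return List with `result` (a `classification_result`), `coarse` (the
#'   winner's coarse period) and `method`.
#' @export
classify_at_pathway_level <- function(train_agg, test, sets,
                                      method = c("specific", "weighted",
                                                 "pca", "svm"),
                                      train_reps = NULL,
                                      pseudocount = 0.5, min_fold = 2) {
  method <- match.arg(method)
  stopifnot(inherits(train_agg, "expression_study"))
  ps_train <- suppressWarnings(pathway_scores(train_agg, sets))
  train_pw <- pathway_study(ps_train)
  xt <- if (inherits(test, "expression_study")) test$values[, 1L] else test
  ps_test <- suppressWarnings(
    pathway_scores(matrix(xt, ncol = 1L,
                          dimnames = list(names(xt), "test")), sets))
  x_pw <- ps_test$scores[, 1L]
  result <- switch(method,
    specific = {
      fc <- compute_fold_changes(train_pw, pseudocount = pseudocount,
                                 spec = filter_spec(min_fold = min_fold))
      tp <- test_profile(x_pw, control_reference(train_pw), pseudocount, min_fold)
      classify_specific(fit_specific(fc), tp$call)
    },
    weighted = {
      fc <- compute_fold_changes(train_pw, pseudocount = pseudocount,
                                 spec = filter_spec(min_fold = min_fold))
      tp <- test_profile(x_pw, control_reference(train_pw), pseudocount, min_fold)
      classify_weighted(fit_weighted(fc), tp$call)
    },
    pca = {
      space <- fit_pca(t(train_pw$values),
                       labels = ifelse(train_pw$samples$condition == "control",
                                       "control",
                                       as.character(train_pw$samples$time_point_h)))
      classify_nearest(space, x_pw)$result
    },
    svm = {
      if (is.null(train_reps))
        stop("method = 'svm' needs replicate-level training data (`train_reps`)")
      ps_reps <- suppressWarnings(pathway_scores(train_reps, sets))
      reps_pw <- pathway_study(ps_reps)
      labs <- ifelse(reps_pw$samples$condition == "control", "control",
                     as.character(reps_pw$samples$time_point_h))
      ens <- train_pairwise(t(reps_pw$values), labs)
      classify_one_vs_one(ens, x_pw)$result
    })
  list(result = result, coarse = coarse_period(result$winner), method = method)
}

#' Serialize pathway Z-scores as long-format TSV
#'
#' @param z A `pathway_zscores`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pathway_zscores <- function(z, path) {
  long <- data.frame(pathway = rep(rownames(z$z), times = ncol(z$z)),
                     column = rep(colnames(z$z), each = nrow(z$z)),
                     z = as.vector(z$z),
                     significant = as.vector(z$significant))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
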