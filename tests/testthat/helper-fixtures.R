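# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

# aggregated study with one injured and one control column per time point
make_agg_study <- function(inj, ctl, tps = as.numeric(colnames(inj))) {
  stopifnot(identical(dim(inj), dim(ctl)))
  vals <- cbind(inj, ctl)
  colnames(vals) <- c(sprintf("injured_%sh_agg", tps), sprintf("control_%sh_agg", tps))
  meta <- data.frame(
    sample_id = colnames(vals),
    condition = rep(c("injured", "control"), each = length(tps)),
    time_point_h = rep(tps, 2),
    replicate = NA_integer_)
  expression_study(vals, meta)
}

# fold_change_matrix built directly from a log2fc matrix (columns = hours)
make_fc <- function(log2fc, min_fold = 2, fpkm_max = NULL, qvalues = NULL) {
  if (is.null(rownames(log2fc)))
    rownames(log2fc) <- sprintf("g%03d", seq_len(nrow(log2fc)))
  if (is.null(fpkm_max)) fpkm_max <- rep(10, nrow(log2fc))
  names(fpkm_max) <- rownames(log2fc)
  structure(list(log2fc = log2fc,
                 call = fold_change_calls(log2fc, min_fold),
                 fpkm_max = fpkm_max,
                 time_points = as.numeric(colnames(log2fc)),
                 qvalues = qvalues),
            class = "fold_change_matrix")
}

# random log2fc matrix with a mix of strong and null entries
rand_log2fc <- function(n_feat, tps = c(3, 10, 24, 48, 72, 168, 336, 504, 672)) {
  m <- matrix(stats::rnorm(n_feat * length(tps), 0, 1.5), n_feat,
              dimnames = list(sprintf("g%03d", seq_len(n_feat)),
                              as.character(tps)))
  m
}

# replicate-level study with well-separated classes for the SVM/PCA tests:
# class means drawn per feature, small within-class noise
make_labeled_matrix <- function(classes, n_per_class = 3, n_feat = 15,
                                sep = 4, noise = 0.3) {
  centers <- matrix(stats::rnorm(length(classes) * n_feat, 0, sep),
                    length(classes), n_feat,
                    dimnames = list(classes, sprintf("f%02d", seq_len(n_feat))))
  x <- do.call(rbind, lapply(seq_along(classes), function(i) {
    sweep(matrix(stats::rnorm(n_per_class * n_feat, 0, noise),
                 n_per_class, n_feat), 2L, centers[i, ], "+")
  }))
  colnames(x) <- colnames(centers)
  list(x = x, labels = rep(classes, each = n_per_class), centers = centers)
}

# small deterministic generator config for fast end-to-end tests
quick_config <- function(seed = 1L, ...) {
  args <- list(n_features = 400, effect_log2fc_range = c(2, 4), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(generator_config, args)
}

class_label <- function(meta) {
  ifelse(meta$condition == "control", "control", as.character(meta$time_point_h))
}

sealed_label <- function(sealed) {
  ifelse(sealed$condition == "control", "control",
         as.character(sealed$time_point_h))
}
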