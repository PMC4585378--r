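#' Configuration for an end-to-end pipeline run
#'
#' Either a synthetic study is simulated (`generator` supplied) or expression
#' and metadata tables are read from disk.
#'
#' @param out_dir Output directory for per-stage artifacts.
#' @param generator A [generator_config()] to simulate the training study and
#'   blinded tests, or `NULL` to read from files.
#' @param blinded_labels Labels for simulated blinded samples (see
#'   [generate_blinded_tests()]); default mirrors the held-out test design of
#'   six controls and two samples each at 3, 10 and 168 h.
#' @param expression,metadata,test_expression,test_metadata Input TSV paths
#'   used when `generator` is `NULL`.
#' @param gmt Optional GMT path enabling the pathway stage.
#' @param methods Classifiers to run: subset of `"specific"`, `"weighted"`,
#'   `"score_matrix"`, `"pca"`, `"svm"`.
#' @param filter A [filter_spec()] for feature selection.
#' @param pseudocount Pseudocount for fold changes.
#' @param r2_min Replicate-filter threshold.
#' @param confidence_high,confidence_medium Signature confidence margins.
#' @param seed Seed for the run (forwarded to the generator when simulating).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("healstage_run_"),
                       generator = NULL,
                       blinded_labels = c(rep("control", 6), "3", "3", "10",
                                          "10", "168", "168"),
                       expression = NULL, metadata = NULL,
                       test_expression = NULL, test_metadata = NULL,
                       gmt = NULL,
                       methods = c("specific", "weighted", "score_matrix",
                                   "pca", "svm"),
                       filter = filter_spec("all_significant_genes",
                                            min_fpkm = 0.5, q_max = 0.05),
                       pseudocount = 0.5, r2_min = 0.95,
                       confidence_high = 100, confidence_medium = 50,
                       seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(generator) && (is.null(expression) || is.null(metadata)))
    stop("supply either `generator` or `expression` + `metadata` paths")
  if (!is.null(gmt) && !file.exists(gmt))
    stop("GMT file not found: ", gmt)
  structure(list(out_dir = out_dir, generator = generator,
                 blinded_labels = blinded_labels,
                 expression = expression, metadata = metadata,
                 test_expression = test_expression,
                 test_metadata = test_metadata, gmt = gmt,
                 methods = methods, filter = filter,
                 pseudocount = pseudocount, r2_min = r2_min,
                 confidence_high = confidence_high,
                 confidence_medium = confidence_medium,
                 seed = as.integer(seed)), class = "run_config")
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full staging pipeline
#'
#' Stages, in order: simulate or load the training study; replicate filter and
#' aggregation; fold-change profiling and feature selection; model fitting;
#' classification of every test sample with the requested methods; optional
#' pathway-level analysis; report. All artifacts land under
#' `config$out_dir` and every artifact records the config fingerprint and
#' seed.
#'
#' @param config A [run_config()].
#' @return A run report: list with `calls` (data frame of per-sample,
#'   per-method call, margin, confidence, coarse period), `accuracy` (per
#'   method, when sealed labels are available), `selected_features`,
#'   `excluded_replicates`, `pathways` (when a GMT was given), `config_hash`
#'   and `seed`. Also written as JSON to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fingerprint <- config_fingerprint(config)
  sealed <- NULL
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- config$seed
    sim <- generate_study(gen)
    train <- sim$study
    blind <- generate_blinded_tests(gen, config$blinded_labels,
                                    seed = config$seed + 1000L)
    test <- blind$study
    sealed <- blind$sealed
    write_expression(train, file.path(config$out_dir, "training_fpkm.tsv"),
                     file.path(config$out_dir, "training_samples.tsv"))
    write_expression(test, file.path(config$out_dir, "test_fpkm.tsv"))
    jsonlite::write_json(sealed, file.path(config$out_dir, "sealed_labels.json"),
                         dataframe = "rows")
    truth_out <- list(feature_class = as.list(table(sim$truth$feature_class)),
                      config_hash = fingerprint, seed = config$seed)
    jsonlite::write_json(truth_out, file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  } else {
    train <- read_expression(config$expression, "tsv", config$metadata)
    test <- if (!is.null(config$test_expression))
      read_expression(config$test_expression, "tsv", config$test_metadata)
    else NULL
    if (!is.null(config$test_metadata) && !is.null(test))
      sealed <- test$samples
  }
  filt <- filter_replicates(train, r2_min = config$r2_min)
  agg <- aggregate_replicates(filt$study)
  fc_all <- compute_fold_changes(agg, pseudocount = config$pseudocount,
                                 spec = config$filter)
  selected <- select_features(fc_all, config$filter)
  if (!length(selected)) stop("stage `diff` failed: no feature passed the filter")
  fc <- subset_fold_changes(fc_all, selected)
  write_fold_changes(fc, file.path(config$out_dir, "fold_changes.tsv"))

  models <- list()
  if ("specific" %in% config$methods) models$specific <- fit_specific(fc)
  if ("weighted" %in% config$methods) models$weighted <- fit_weighted(fc)
  if ("score_matrix" %in% config$methods) models$score_matrix <- score_matrix(fc)
  lab_of <- function(meta) ifelse(meta$condition == "control", "control",
                                  as.character(meta$time_point_h))
  if ("pca" %in% config$methods) {
    models$pca <- fit_pca(t(agg$values[selected, , drop = FALSE]),
                          labels = lab_of(agg$samples))
  }
  if ("svm" %in% config$methods) {
    models$svm <- train_pairwise(t(filt$study$values[selected, , drop = FALSE]),
                                 lab_of(filt$study$samples))
  }

  calls <- NULL
  if (!is.null(test) && ncol(test$values) > 0L) {
    ctrl_ref <- control_reference(agg)[selected]
    rows <- list()
    for (s in test$samples$sample_id) {
      x <- test$values[selected, s]
      tp <- test_profile(x, ctrl_ref, config$pseudocount, config$filter$min_fold)
      for (m in config$methods) {
        res <- switch(m,
          specific = classify_specific(models$specific, tp$call,
                                       confidence_high = config$confidence_high,
                                       confidence_medium = config$confidence_medium),
          weighted = classify_weighted(models$weighted, tp$call,
                                       confidence_high = config$confidence_high,
                                       confidence_medium = config$confidence_medium),
          score_matrix = score_matrix_classify(models$score_matrix, tp$log2fc,
                                               config$filter$min_fold),
          pca = classify_nearest(models$pca, x)$result,
          svm = classify_one_vs_one(models$svm, x)$result)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, method = m, call = res$winner,
          margin = res$margin, confidence = res$confidence,
          tie = res$tie, coarse = coarse_period(res$winner),
          stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, rows)
    utils::write.table(cbind(calls, config_hash = fingerprint,
                             seed = config$seed),
                       file.path(config$out_dir, "classification_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  accuracy <- NULL
  if (!is.null(calls) && !is.null(sealed)) {
    truth_lab <- ifelse(sealed$condition == "control", "control",
                        as.character(sealed$time_point_h))
    names(truth_lab) <- sealed$sample_id
    calls$correct <- calls$call == truth_lab[calls$sample_id]
    accuracy <- vapply(split(calls$correct, calls$method), mean, 0)
  }

  pathways <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    inj <- agg$samples$condition == "injured"
    ps_inj <- suppressWarnings(pathway_scores(
      subset_samples(agg, agg$samples$sample_id[inj]), sets))
    pz <- pathway_zscores(ps_inj)
    ps_all <- suppressWarnings(pathway_scores(agg, sets))
    fc_pw <- compute_fold_changes(pathway_study(ps_all),
                                  pseudocount = config$pseudocount)
    sig <- select_significant_pathways(pz, fc_pw)
    write_pathway_zscores(pz, file.path(config$out_dir, "pathway_z.tsv"))
    pathways <- list(n_scored = nrow(ps_inj$scores),
                     n_significant = length(sig), significant = sig)
  }

  report <- list(config_hash = fingerprint, seed = config$seed,
                 n_features = nrow(train$values),
                 excluded_replicates = filt$excluded,
                 n_selected_features = length(selected),
                 selected_features = selected,
                 calls = calls, accuracy = as.list(accuracy),
                 pathways = pathways)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(report)
}
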