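#' Construct an expression study
#'
#' An expression study bundles a non-negative FPKM matrix (features x samples)
#' with per-sample metadata and, optionally, per-feature/per-time-point q-values
#' carried over from upstream differential testing.
#'
#' @param values Numeric matrix of FPKM values, features in rows, samples in
#'   columns. Row names are feature identifiers, column names sample ids.
#' @param samples Data frame with one row per sample and columns `sample_id`,
#'   `condition` ("injured" or "control"; `NA` allowed for blinded samples),
#'   `time_point_h` (hours post injury; `NA` for pooled/blinded) and
#'   `replicate` (integer).
#' @param qvalues Optional numeric matrix (features x time points) of q-values;
#'   column names are hours.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(values, samples, qvalues = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have feature identifiers as row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (any(!is.finite(values)))
    stop("FPKM matrix contains missing or non-finite values")
  if (any(values < 0))
    stop("FPKM values must be >= 0")
  samples <- as.data.frame(samples)
  required <- c("sample_id", "condition", "time_point_h", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample metadata rows (", nrow(samples), ") != matrix columns (", ncol(values), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (ncol(values) > 0L &&
      !identical(colnames(values), as.character(samples$sample_id)))
    stop("matrix column names do not match metadata sample_id order")
  bad <- !is.na(samples$condition) & !samples$condition %in% c("injured", "control")
  if (any(bad)) stop("condition must be 'injured' or 'control'")
  no_tp <- !is.na(samples$condition) & samples$condition == "injured" &
    is.na(samples$time_point_h)
  if (any(no_tp)) stop("injured samples must carry a time point")
  if (!is.null(qvalues)) {
    qvalues <- as.matrix(qvalues)
    if (nrow(qvalues) != nrow(values) ||
        !identical(rownames(qvalues), rownames(values)))
      stop("qvalues rows must match the feature list")
  }
  structure(list(values = values, samples = samples, qvalues = qvalues),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "features x", ncol(x$values), "samples\n")
  tab <- table(condition = x$samples$condition,
               time_point_h = x$samples$time_point_h, useNA = "ifany")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Subset a study to a set of samples
#'
#' @param study An `expression_study`.
#' @param sample_ids Character vector of sample ids to keep, in order.
#' @return The subsetted `expression_study`.
#' @export
subset_samples <- function(study, sample_ids) {
  stopifnot(inherits(study, "expression_study"))
  keep <- match(sample_ids, study$samples$sample_id)
  if (anyNA(keep)) stop("unknown sample id: ", sample_ids[is.na(keep)][1L])
  expression_study(study$values[, keep, drop = FALSE],
                   study$samples[keep, , drop = FALSE],
                   study$qvalues)
}

#' Read an expression table
#'
#' Two dialects are supported: a plain TSV matrix (feature id in the first
#' column, one column per sample) paired with a sample-metadata TSV, and a
#' Cufflinks `fpkm_tracking`-style table where `tracking_id` names the feature
#' and per-sample abundances live in `<sample>_FPKM` columns.
#'
#' @param path Path to the expression table.
#' @param dialect `"tsv"` or `"fpkm_tracking"`.
#' @param metadata Path to a sample-metadata TSV (columns `sample_id`,
#'   `condition`, `time_point_h`, `replicate`). Required for the `"tsv"`
#'   dialect; for `"fpkm_tracking"` it may be omitted, in which case metadata
#'   is parsed from sample names of the form `condition_<hours>h_rep<k>`.
#' @return An `expression_study`.
#' @export
read_expression <- function(path, dialect = c("tsv", "fpkm_tracking"),
                            metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "tsv") {
    if (ncol(tab) < 2L) stop("malformed header in ", path, " (line 1)")
    feats <- as.character(tab[[1L]])
    dup <- which(duplicated(feats))
    if (length(dup))
      stop("duplicate feature id '", feats[dup[1L]], "' (line ", dup[1L] + 1L, ")")
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- feats
  } else {
    if (!"tracking_id" %in% names(tab))
      stop("malformed header in ", path, " (line 1): no tracking_id column")
    fpkm_cols <- grep("_FPKM$", names(tab), value = TRUE)
    if (!length(fpkm_cols))
      stop("malformed header in ", path, " (line 1): no *_FPKM columns")
    feats <- as.character(tab$tracking_id)
    dup <- which(duplicated(feats))
    if (length(dup))
      stop("duplicate feature id '", feats[dup[1L]], "' (line ", dup[1L] + 1L, ")")
    mat <- as.matrix(tab[, fpkm_cols, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- feats
    colnames(mat) <- sub("_FPKM$", "", fpkm_cols)
  }
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0L)[1L]
    stop("missing FPKM value (line ", bad + 1L, ")")
  }
  if (any(mat < 0)) {
    bad <- which(rowSums(mat < 0) > 0L)[1L]
    stop("negative FPKM value (line ", bad + 1L, ")")
  }
  meta <- if (!is.null(metadata)) {
    utils::read.delim(metadata, stringsAsFactors = FALSE)
  } else if (dialect == "fpkm_tracking") {
    parse_sample_names(colnames(mat))
  } else {
    stop("the tsv dialect requires a `metadata` table")
  }
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing sample(s): ",
         paste(setdiff(colnames(mat), meta$sample_id), collapse = ", "))
  rownames(meta) <- NULL
  expression_study(mat, meta)
}

# condition_<hours>h_rep<k> -> metadata row; "control" pools allowed
parse_sample_names <- function(ids) {
  m <- regmatches(ids, regexec("^(injured|control)_([0-9]+)h_rep([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("cannot parse sample name '", ids[bad][1L],
         "'; supply a metadata table instead")
  data.frame(sample_id = ids,
             condition = vapply(m, `[`, "", 2L),
             time_point_h = as.numeric(vapply(m, `[`, "", 3L)),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write an expression study as TSV
#'
#' @param study An `expression_study`.
#' @param path Output path for the FPKM matrix TSV.
#' @param metadata Output path for the sample-metadata TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(study, path, metadata = NULL) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(feature = rownames(study$values), study$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    utils::write.table(study$samples, metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member feature ids, tab-separated.
#' Duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of lists with `description` and
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT parse error (line ", i, "): expected >= 3 tab-separated fields")
    nm <- parts[[1L]]
    if (nm %in% names(sets)) stop("GMT parse error (line ", i, "): duplicate set '", nm, "'")
    sets[[nm]] <- list(description = parts[[2L]],
                       members = unique(parts[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
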