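#' Configuration for the synthetic time-course generator
#'
#' The defaults emulate the design of a mouse muscle freeze-injury time course:
#' nine post-injury time points, per-time-point injured replicate counts of
#' 2--5 (30 injured samples) and 4 control replicates per time point (36
#' controls), log-normal baseline abundances, multiplicative replicate noise
#' tight enough that replicate pairs typically correlate with R^2 >= 0.95, and
#' waves of up/down regulation in which multi-time-point response genes span
#' contiguous windows so that adjacent time points share active genes.
#'
#' @param n_features Number of features (genes or isoforms).
#' @param time_points Ordered vector of hours post injury.
#' @param n_control_reps_per_tp Control replicates per time point (scalar or
#'   per-time-point vector).
#' @param n_injured_reps_per_tp Injured replicates per time point (scalar or
#'   per-time-point vector; default mirrors the study enumeration 2,5,4,3,4,2,3,3,4).
#' @param frac_single_tp_genes Fraction of features responding at exactly one
#'   time point.
#' @param frac_multi_tp_genes Fraction responding over a contiguous window of
#'   2--4 time points.
#' @param effect_log2fc_range Interval from which the peak |log2 fold change|
#'   of a responding feature is drawn.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline FPKM.
#' @param replicate_noise_cv Coefficient of variation of the multiplicative
#'   replicate noise (default 0.1).
#' @param transition_tp Optional hour whose injured replicates get 3x noise
#'   variance (emulates heterogeneity of the regenerative transition at 168 h);
#'   `NULL` disables.
#' @param seed Integer seed fixing the feature-effect model and the training
#'   replicates.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_features = 2000,
                             time_points = c(3, 10, 24, 48, 72, 168, 336, 504, 672),
                             n_control_reps_per_tp = 4,
                             n_injured_reps_per_tp = c(2, 5, 4, 3, 4, 2, 3, 3, 4),
                             frac_single_tp_genes = 0.15,
                             frac_multi_tp_genes = 0.25,
                             effect_log2fc_range = c(1, 4),
                             baseline_meanlog = log(8),
                             baseline_sdlog = 1.2,
                             replicate_noise_cv = 0.1,
                             transition_tp = NULL,
                             seed = 1L) {
  cfg <- list(n_features = n_features, time_points = time_points,
              n_control_reps_per_tp = n_control_reps_per_tp,
              n_injured_reps_per_tp = n_injured_reps_per_tp,
              frac_single_tp_genes = frac_single_tp_genes,
              frac_multi_tp_genes = frac_multi_tp_genes,
              effect_log2fc_range = effect_log2fc_range,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              replicate_noise_cv = replicate_noise_cv,
              transition_tp = transition_tp,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid `", field, "`: ", msg)
  chk(length(cfg$n_features) == 1L && cfg$n_features >= 1, "n_features", "need >= 1")
  tp <- cfg$time_points
  chk(length(tp) >= 1L && all(tp > 0) && !is.unsorted(tp, strictly = TRUE),
      "time_points", "must be strictly increasing and > 0")
  for (f in c("frac_single_tp_genes", "frac_multi_tp_genes"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  chk(cfg$frac_single_tp_genes + cfg$frac_multi_tp_genes <= 1,
      "frac_multi_tp_genes", "frac_single + frac_multi must be <= 1")
  er <- cfg$effect_log2fc_range
  chk(length(er) == 2L && er[1] <= er[2] && er[1] >= 0,
      "effect_log2fc_range", "need 0 <= lower <= upper")
  chk(all(rep_counts(cfg$n_control_reps_per_tp, length(tp)) >= 1),
      "n_control_reps_per_tp", "need >= 1 per time point")
  chk(all(rep_counts(cfg$n_injured_reps_per_tp, length(tp)) >= 1),
      "n_injured_reps_per_tp", "need >= 1 per time point")
  chk(cfg$replicate_noise_cv > 0, "replicate_noise_cv", "must be > 0")
  if (!is.null(cfg$transition_tp))
    chk(cfg$transition_tp %in% tp, "transition_tp", "must be one of time_points")
  invisible(cfg)
}

rep_counts <- function(n, n_tp) {
  if (length(n) == 1L) rep(n, n_tp)
  else if (length(n) == n_tp) n
  else stop("invalid replicate count vector: length must be 1 or ", n_tp)
}

# Deterministic feature-effect model shared by training and blinded studies.
# Multi-tp features respond over a contiguous window with a peaked magnitude
# profile (neighbours at 70% of the peak) so adjacent time points overlap.
feature_model <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_features
  tps <- cfg$time_points
  n_tp <- length(tps)
  feats <- sprintf("gene%05d", seq_len(n))
  baseline <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  names(baseline) <- feats
  n_single <- round(cfg$frac_single_tp_genes * n)
  n_multi <- round(cfg$frac_multi_tp_genes * n)
  cls <- rep("null", n)
  ord <- sample.int(n)
  cls[ord[seq_len(n_single)]] <- "single"
  if (n_multi > 0) cls[ord[n_single + seq_len(n_multi)]] <- "multi"
  effects <- matrix(0, n, n_tp, dimnames = list(feats, as.character(tps)))
  er <- cfg$effect_log2fc_range
  zero_effect <- er[2] <= 0
  for (i in which(cls == "single")) {
    if (zero_effect) next
    t0 <- sample.int(n_tp, 1L)
    effects[i, t0] <- stats::runif(1L, er[1], er[2]) * sample(c(-1, 1), 1L)
  }
  for (i in which(cls == "multi")) {
    if (zero_effect) next
    len <- sample(2:min(4L, n_tp), 1L)
    start <- sample.int(n_tp - len + 1L, 1L)
    win <- start:(start + len - 1L)
    peak_pos <- sample(seq_along(win), 1L)
    mag <- stats::runif(1L, er[1], er[2]) * sample(c(-1, 1), 1L)
    prof <- mag * 0.7^abs(seq_along(win) - peak_pos)
    effects[i, win] <- prof
  }
  if (zero_effect) cls[] <- "null"
  list(features = feats, baseline = baseline, class = cls, effects = effects)
}

noise_sdlog <- function(cv) sqrt(log(1 + cv^2))

# mean-one multiplicative log-normal noise
rnoise <- function(n, cv) {
  s <- noise_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic training study
#'
#' Draws replicate-level FPKM values under the configured design: control
#' replicates are baseline times noise; injured replicates at a feature's
#' active time points have expected FPKM equal to baseline times
#' `2^(signed log2 effect)`. Per-time-point q-values (Welch t-test on
#' `log2(FPKM + 0.5)`, Benjamini-Hochberg across features) are attached so
#' downstream significance filters have the column they consume.
#'
#' @param config A [generator_config()].
#' @return A list with `study` (an `expression_study`) and `truth` (a
#'   `ground_truth`: per-feature response class, signed effect matrix, active
#'   time points, and the per-sample design).
#' @export
generate_study <- function(config) {
  validate_generator_config(config)
  fm <- feature_model(config)
  tps <- config$time_points
  n_tp <- length(tps)
  nc <- rep_counts(config$n_control_reps_per_tp, n_tp)
  ni <- rep_counts(config$n_injured_reps_per_tp, n_tp)
  n <- config$n_features
  cols <- list(); meta <- list()
  for (j in seq_len(n_tp)) {
    for (r in seq_len(nc[j])) {
      id <- sprintf("control_%dh_rep%d", tps[j], r)
      cols[[id]] <- fm$baseline * rnoise(n, config$replicate_noise_cv)
      meta[[id]] <- data.frame(sample_id = id, condition = "control",
                               time_point_h = tps[j], replicate = r)
    }
    cv <- config$replicate_noise_cv
    if (!is.null(config$transition_tp) && tps[j] == config$transition_tp) {
      # 3x log-scale noise variance at the transition time point
      cv <- sqrt(exp(3 * noise_sdlog(cv)^2) - 1)
    }
    mu <- fm$baseline * 2^fm$effects[, j]
    for (r in seq_len(ni[j])) {
      id <- sprintf("injured_%dh_rep%d", tps[j], r)
      cols[[id]] <- mu * rnoise(n, cv)
      meta[[id]] <- data.frame(sample_id = id, condition = "injured",
                               time_point_h = tps[j], replicate = r)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- fm$features
  meta <- do.call(rbind, unname(meta))
  qv <- study_qvalues(vals, meta, tps)
  study <- expression_study(vals, meta, qv)
  truth <- structure(list(
    feature_class = stats::setNames(fm$class, fm$features),
    effects = fm$effects,
    active = abs(fm$effects) > 0,
    samples = meta[, c("sample_id", "condition", "time_point_h")],
    config_seed = config$seed), class = "ground_truth")
  list(study = study, truth = truth)
}

# Vectorized Welch t-test on log2(FPKM+0.5), BH-adjusted across features per tp
study_qvalues <- function(vals, meta, tps) {
  lv <- log2(vals + 0.5)
  qv <- matrix(NA_real_, nrow(vals), length(tps),
               dimnames = list(rownames(vals), as.character(tps)))
  for (j in seq_along(tps)) {
    inj <- meta$condition == "injured" & meta$time_point_h == tps[j]
    ctl <- meta$condition == "control" & meta$time_point_h == tps[j]
    n1 <- sum(inj); n2 <- sum(ctl)
    if (n1 < 2L || n2 < 2L) next
    x <- lv[, inj, drop = FALSE]; y <- lv[, ctl, drop = FALSE]
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1); v2 <- rowSums((y - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    se2 <- pmax(se2, .Machine$double.eps)
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    df <- pmax(df, 1)
    p <- 2 * stats::pt(-abs(tstat), df)
    qv[, j] <- stats::p.adjust(p, method = "BH")
  }
  qv
}

#' Generate blinded test samples
#'
#' Produces one single-replicate sample per requested label from the same
#' feature-effect model as the paired training study (the model is a
#' deterministic function of `config`), with fresh replicate noise driven by
#' `seed`. Condition and time point are withheld from the emitted metadata;
#' the true labels travel in a separate sealed record.
#'
#' @param config The [generator_config()] used for the training study.
#' @param labels Vector of requested labels: `"control"` or an hour present in
#'   `config$time_points` (numeric or character).
#' @param seed Seed for the test samples' replicate noise.
#' @return A list with `study` (metadata blinded) and `sealed` (data frame of
#'   true `sample_id`, `condition`, `time_point_h`).
#' @export
generate_blinded_tests <- function(config, labels, seed = config$seed + 1000L) {
  validate_generator_config(config)
  fm <- feature_model(config)
  tps <- config$time_points
  lab <- as.character(labels)
  ok <- lab %in% c("control", as.character(tps))
  if (any(!ok)) stop("label not in design: ", lab[!ok][1L])
  n <- config$n_features
  set.seed(as.integer(seed))
  if (length(lab) == 0L) {
    vals <- matrix(numeric(0), n, 0, dimnames = list(fm$features, NULL))
    meta <- data.frame(sample_id = character(0), condition = character(0),
                       time_point_h = numeric(0), replicate = integer(0))
    sealed <- data.frame(sample_id = character(0), condition = character(0),
                         time_point_h = numeric(0))
    return(list(study = expression_study(vals, meta), sealed = sealed))
  }
  cols <- matrix(0, n, length(lab), dimnames = list(fm$features, NULL))
  sealed <- data.frame(sample_id = sprintf("test_%02d", seq_along(lab)),
                       condition = ifelse(lab == "control", "control", "injured"),
                       time_point_h = suppressWarnings(as.numeric(lab)),
                       stringsAsFactors = FALSE)
  for (k in seq_along(lab)) {
    cv <- config$replicate_noise_cv
    if (lab[k] == "control") {
      mu <- fm$baseline
    } else {
      j <- match(as.numeric(lab[k]), tps)
      mu <- fm$baseline * 2^fm$effects[, j]
      if (!is.null(config$transition_tp) && tps[j] == config$transition_tp)
        cv <- sqrt(exp(3 * noise_sdlog(cv)^2) - 1)
    }
    cols[, k] <- mu * rnoise(n, cv)
  }
  colnames(cols) <- sealed$sample_id
  meta <- data.frame(sample_id = sealed$sample_id, condition = NA_character_,
                     time_point_h = NA_real_, replicate = 1L,
                     stringsAsFactors = FALSE)
  list(study = expression_study(cols, meta), sealed = sealed)
}
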