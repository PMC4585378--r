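test_that("expression tables round-trip through the TSV dialect", {
  vals <- matrix(c(1.5, 0, 2, 7.25), 2,
                 dimnames = list(c("gA", "gB"),
                                 c("injured_3h_rep1", "control_3h_rep1")))
  meta <- data.frame(sample_id = colnames(vals),
                     condition = c("injured", "control"),
                     time_point_h = 3, replicate = 1L)
  study <- expression_study(vals, meta)
  expect_equal(dim(study), c(2L, 2L))
  f <- tempfile(fileext = ".tsv"); m <- tempfile(fileext = ".tsv")
  write_expression(study, f, m)
  back <- read_expression(f, "tsv", metadata = m)
  expect_equal(back$values, study$values)
  expect_equal(back$samples$condition, study$samples$condition)
})

test_that("malformed expression input is rejected with a line reference", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2", "gA\t1\t2", "gB\t-1\t0"), f)
  m <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\ttime_point_h\treplicate",
               "s1\tinjured\t3\t1", "s2\tcontrol\t3\t1"), m)
  expect_error(read_expression(f, "tsv", m), "negative FPKM.*line 3")
  writeLines(c("feature\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), f)
  expect_error(read_expression(f, "tsv", m), "duplicate feature")
  writeLines(c("feature\ts1\ts2", "gA\t1\t2", "gB\tNA\t0"), f)
  expect_error(read_expression(f, "tsv", m), "missing FPKM")
})

test_that("fpkm_tracking dialect maps tracking_id and *_FPKM columns", {
  f <- tempfile(fileext = ".fpkm_tracking")
  hdr <- paste("tracking_id", "class_code", "nearest_ref_id", "gene_id",
               "gene_short_name", "tss_id", "locus", "length", "coverage",
               "injured_3h_rep1_FPKM", "injured_3h_rep1_conf_lo",
               "injured_3h_rep1_conf_hi", "injured_3h_rep1_status",
               "control_3h_rep1_FPKM", "control_3h_rep1_conf_lo",
               "control_3h_rep1_conf_hi", "control_3h_rep1_status",
               sep = "\t")
  row <- function(id, a, b)
    paste(id, "-", "-", id, id, "-", "chr1:1-100", "1000", "5",
          a, "0", "0", "OK", b, "0", "0", "OK", sep = "\t")
  writeLines(c(hdr, row("gA", "2.5", "1.0"), row("gB", "0", "4")), f)
  study <- read_expression(f, "fpkm_tracking")
  expect_equal(rownames(study$values), c("gA", "gB"))
  expect_equal(unname(study$values["gA", ]), c(2.5, 1.0))
  expect_equal(study$samples$condition, c("injured", "control"))
  expect_equal(study$samples$time_point_h, c(3, 3))
})

test_that("GMT collections parse, deduplicate, and reject short lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tg1\tg2", "P2\tother\tg1\tg1\tg3"), f)
  sets <- read_gmt(f)
  expect_length(sets, 2)
  expect_equal(sets$P1$members, c("g1", "g2"))
  expect_equal(sets$P2$members, c("g1", "g3"))
  f2 <- tempfile(fileext = ".gmt")
  writeLines(character(0), f2)
  expect_length(read_gmt(f2), 0)
  writeLines("P1\tdesc_only", f2)
  expect_error(read_gmt(f2), "line 1")
  # round trip
  f3 <- tempfile(fileext = ".gmt")
  write_gmt(sets, f3)
  expect_equal(read_gmt(f3)$P2$members, c("g1", "g3"))
})

test_that("replicate filter excludes the outlier replicate", {
  set.seed(101)
  n <- 300
  base <- exp(rnorm(n, 2, 1.2))
  good1 <- base * exp(rnorm(n, 0, 0.05))
  good2 <- base * exp(rnorm(n, 0, 0.05))
  bad <- base * exp(rnorm(n, 0, 0.9))
  stopifnot(cor(good1, bad)^2 < 0.95, cor(good1, good2)^2 >= 0.95)
  vals <- cbind(good1, good2, bad)
  rownames(vals) <- sprintf("g%03d", 1:n)
  colnames(vals) <- paste0("injured_3h_rep", 1:3)
  meta <- data.frame(sample_id = colnames(vals), condition = "injured",
                     time_point_h = 3, replicate = 1:3)
  res <- filter_replicates(expression_study(vals, meta))
  expect_equal(res$excluded, "injured_3h_rep3")
  # identical replicates are never excluded
  vals2 <- cbind(good1, good1)
  colnames(vals2) <- paste0("injured_3h_rep", 1:2)
  rownames(vals2) <- rownames(vals)
  meta2 <- meta[1:2, ]; meta2$sample_id <- colnames(vals2)
  expect_length(filter_replicates(expression_study(vals2, meta2))$excluded, 0)
  # a discordant pair cannot be adjudicated: kept with a warning
  vals3 <- cbind(good1, bad)
  colnames(vals3) <- paste0("injured_3h_rep", 1:2)
  rownames(vals3) <- rownames(vals)
  meta3 <- meta[1:2, ]; meta3$sample_id <- colnames(vals3)
  expect_warning(res3 <- filter_replicates(expression_study(vals3, meta3)),
                 "no identifiable outlier")
  expect_length(res3$excluded, 0)
  # three mutually uncorrelated replicates empty the group: error names it
  set.seed(102)
  vals4 <- sapply(1:3, function(i) exp(rnorm(n, 2, 1.2)))
  rownames(vals4) <- rownames(vals)
  colnames(vals4) <- paste0("control_72h_rep", 1:3)
  meta4 <- data.frame(sample_id = colnames(vals4), condition = "control",
                      time_point_h = 72, replicate = 1:3)
  expect_error(filter_replicates(expression_study(vals4, meta4)),
               "emptied group control.72")
})

test_that("replicate filter matches an independent pairwise-correlation oracle", {
  set.seed(202)
  for (trial in 1:8) {
    n <- 150
    base <- exp(rnorm(n, 2, 1))
    reps <- sapply(1:4, function(i) base * exp(rnorm(n, 0, runif(1, 0.02, 0.8))))
    rownames(reps) <- sprintf("g%03d", 1:n)
    colnames(reps) <- paste0("control_24h_rep", 1:4)
    meta <- data.frame(sample_id = colnames(reps), condition = "control",
                       time_point_h = 24, replicate = 1:4)
    # oracle: a replicate is an outlier when every pairwise R^2 fails
    bad <- rep(TRUE, 4)
    for (i in 1:4) for (j in 1:4) {
      if (i != j && cor(reps[, i], reps[, j])^2 >= 0.95) bad[i] <- FALSE
    }
    study <- expression_study(reps, meta)
    if (all(bad)) {
      expect_error(filter_replicates(study), "emptied group")
    } else {
      res <- suppressWarnings(filter_replicates(study))
      expect_setequal(res$excluded, colnames(reps)[bad])
      # idempotence: a second pass excludes nothing
      expect_length(suppressWarnings(filter_replicates(res$study))$excluded, 0)
    }
  }
})

test_that("replicate aggregation applies the median-zero rule", {
  vals <- rbind(gA = c(0, 0, 5), gB = c(1, 2, 3), gC = c(0, 4, 6))
  colnames(vals) <- paste0("injured_10h_rep", 1:3)
  meta <- data.frame(sample_id = colnames(vals), condition = "injured",
                     time_point_h = 10, replicate = 1:3)
  agg <- aggregate_replicates(expression_study(vals, meta))
  expect_equal(ncol(agg$values), 1)
  expect_equal(unname(agg$values["gA", 1]), 0)       # median 0 -> 0
  expect_equal(unname(agg$values["gB", 1]), 2)       # mean
  expect_equal(unname(agg$values["gC", 1]), 10 / 3)  # median 4 != 0 -> mean
})

test_that("aggregation is invariant under replicate permutation", {
  set.seed(7)
  vals <- matrix(rexp(60, 0.2), 10,
                 dimnames = list(sprintf("g%02d", 1:10),
                                 paste0("control_48h_rep", 1:6)))
  vals[sample(60, 12)] <- 0
  meta <- data.frame(sample_id = colnames(vals), condition = "control",
                     time_point_h = 48, replicate = 1:6)
  a <- aggregate_replicates(expression_study(vals, meta))
  perm <- sample(6)
  vals2 <- vals[, perm]
  meta2 <- meta[perm, ]
  b <- aggregate_replicates(expression_study(vals2, meta2))
  expect_equal(unname(a$values), unname(b$values))
})

test_that("study invariants are enforced at construction", {
  vals <- matrix(1, 2, 1, dimnames = list(c("a", "b"), "s1"))
  meta <- data.frame(sample_id = "s1", condition = "injured",
                     time_point_h = NA_real_, replicate = 1L)
  expect_error(expression_study(vals, meta), "time point")
  meta$time_point_h <- 3
  expect_silent(expression_study(vals, meta))
  vals[1] <- -2
  expect_error(expression_study(vals, meta), ">= 0")
})
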