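tps9 <- c(3, 10, 24, 48, 72, 168, 336, 504, 672)

# one gene up at 3 h and 10 h, down at 504 h
worked_example_fc <- function() {
  l2 <- matrix(0, 1, 9, dimnames = list("gene1", as.character(tps9)))
  l2[1, c("3", "10")] <- 2
  l2[1, "504"] <- -2
  make_fc(l2)
}

test_that("specific weights are one over the per-direction call counts", {
  m <- fit_specific(worked_example_fc())
  expect_equal(unname(m$up_weight["gene1"]), 1 / 2)
  expect_equal(unname(m$down_weight["gene1"]), 1)
  # a gene up everywhere carries weight 1/9
  l2 <- matrix(2, 1, 9, dimnames = list("g", as.character(tps9)))
  expect_equal(unname(fit_specific(make_fc(l2))$up_weight["g"]), 1 / 9)
  # a direction with no calls has no weight
  expect_true(is.na(fit_specific(make_fc(l2))$down_weight["g"]))
})

test_that("specific weights match a per-row counting oracle on random matrices", {
  set.seed(53)
  for (trial in 1:20) {
    fc <- make_fc(rand_log2fc(40))
    m <- fit_specific(fc)
    for (f in sample(rownames(fc$call), 10)) {
      n_up <- 0; n_down <- 0
      for (t in colnames(fc$call)) {
        if (fc$call[f, t] == "up") n_up <- n_up + 1
        if (fc$call[f, t] == "down") n_down <- n_down + 1
      }
      expect_equal(unname(m$up_weight[f]),
                   if (n_up > 0) 1 / n_up else NA_real_)
      expect_equal(unname(m$down_weight[f]),
                   if (n_down > 0) 1 / n_down else NA_real_)
    }
  }
})

test_that("a no-change gene in both profiles contributes exactly 0.5", {
  l2 <- matrix(0, 1, 9, dimnames = list("g", as.character(tps9)))
  m <- fit_specific(make_fc(l2))
  expect_equal(score_specific(m, c(g = "none"), "3"), 0.5)
  expect_equal(score_specific(m, c(g = "none"), "control"), 0.5)
})

test_that("a ten-gene single-time-point panel scores 9 x 0.5 + 1 on itself", {
  l2 <- matrix(0, 10, 9, dimnames = list(sprintf("g%02d", 1:10),
                                         as.character(tps9)))
  l2[1, "24"] <- 2.5  # exactly one gene active at 24 h
  other_tps <- as.character(setdiff(tps9, 24))
  for (i in 2:10) l2[i, other_tps[(i - 2) %% 8 + 1]] <- 2.5
  fc <- make_fc(l2)
  m <- fit_specific(fc)
  test_calls <- stats::setNames(fc$call[, "24"], rownames(l2))
  expect_equal(score_specific(m, test_calls, "24"), 9 * 0.5 + 1)
})

test_that("disjoint feature sets raise an error", {
  m <- fit_specific(worked_example_fc())
  expect_error(score_specific(m, c(other = "up"), "3"), "no features")
  wm <- fit_weighted(worked_example_fc())
  expect_error(score_weighted(wm, c(other = "up"), "3"), "no features")
})

test_that("weighted model normalizes by the per-gene maximum fold change", {
  l2 <- matrix(c(4, 2, 1, 0, 0, 0, 0, 0, 0), 1,
               dimnames = list("g", as.character(tps9)))
  m <- fit_weighted(make_fc(l2))
  expect_equal(unname(m$weights["g", 1:4]), c(1, 0.5, 0.25, 0))
  expect_equal(unname(m$peak_tp["g"]), 3)
  # an all-zero row is inert, not an error
  z <- matrix(0, 1, 9, dimnames = list("z", as.character(tps9)))
  mz <- fit_weighted(make_fc(z))
  expect_true(all(mz$weights["z", ] == 0))
  expect_true(is.na(mz$peak_tp["z"]))
})

test_that("weighted weights match a per-row normalization oracle", {
  set.seed(59)
  for (trial in 1:20) {
    fc <- make_fc(rand_log2fc(30))
    m <- fit_weighted(fc)
    f <- sample(rownames(fc$log2fc), 1)
    mx <- max(abs(fc$log2fc[f, ]))
    expect_equal(unname(m$weights[f, ]),
                 unname(abs(fc$log2fc[f, ]) / mx))
  }
})

test_that("weighted scoring increments by the normalized weight on a match", {
  l2 <- matrix(0, 1, 9, dimnames = list("g", as.character(tps9)))
  l2[1, "3"] <- 2.5; l2[1, "10"] <- 2
  m <- fit_weighted(make_fc(l2))
  w10 <- 2 / 2.5
  expect_equal(score_weighted(m, c(g = "up"), "10"), w10)
  expect_equal(score_weighted(m, c(g = "none"), "24"), 0.5)
  expect_equal(score_weighted(m, c(g = "down"), "10"), 0)
})

test_that("signature scores match loop-based oracles and ignore feature order", {
  set.seed(61)
  for (trial in 1:10) {
    fc <- make_fc(rand_log2fc(50))
    ms <- fit_specific(fc)
    mw <- fit_weighted(fc)
    calls <- stats::setNames(sample(c("up", "down", "none"), 50, TRUE),
                             rownames(fc$call))
    cand <- sample(c("control", colnames(fc$call)), 1)
    # oracle: explicit feature loop over the increment rules
    exp_s <- 0; exp_w <- 0
    for (f in names(calls)) {
      ec <- if (cand == "control") "none" else fc$call[f, cand]
      if (ec == "up" && calls[f] == "up") {
        exp_s <- exp_s + 1 / sum(fc$call[f, ] == "up")
        exp_w <- exp_w + mw$weights[f, cand]
      } else if (ec == "down" && calls[f] == "down") {
        exp_s <- exp_s + 1 / sum(fc$call[f, ] == "down")
        exp_w <- exp_w + mw$weights[f, cand]
      } else if (ec == "none" && calls[f] == "none") {
        exp_s <- exp_s + 0.5
        exp_w <- exp_w + 0.5
      }
    }
    expect_equal(score_specific(ms, calls, cand), exp_s)
    expect_equal(score_weighted(mw, calls, cand), exp_w)
    perm <- sample(names(calls))
    expect_equal(score_specific(ms, calls[perm], cand), exp_s)
    expect_equal(score_weighted(mw, calls[perm], cand), exp_w)
  }
})

test_that("a training aggregate beats every other class on its own profile", {
  cfg <- quick_config(seed = 67)
  sim <- generate_study(cfg)
  agg <- aggregate_replicates(sim$study)
  fc <- compute_fold_changes(agg, spec = filter_spec(q_max = 0.05))
  sel <- select_features(fc, filter_spec(q_max = 0.05))
  fcs <- subset_fold_changes(fc, sel)
  ms <- fit_specific(fcs); mw <- fit_weighted(fcs)
  for (t in as.character(cfg$time_points)) {
    calls <- stats::setNames(fcs$call[, t], rownames(fcs$call))
    expect_equal(classify_specific(ms, calls)$winner, t)
    expect_equal(classify_weighted(mw, calls)$winner, t)
  }
  none_calls <- stats::setNames(rep("none", nrow(fcs$call)), rownames(fcs$call))
  expect_equal(classify_specific(ms, none_calls)$winner, "control")
  expect_equal(classify_weighted(mw, none_calls)$winner, "control")
})

test_that("the score matrix keeps only single-time-point features as +/-1 rows", {
  l2 <- matrix(0, 3, 9, dimnames = list(c("s_up", "s_dn", "multi"),
                                        as.character(tps9)))
  l2["s_up", "3"] <- 2; l2["s_dn", "72"] <- -2
  l2["multi", c("3", "10")] <- 2
  sm <- score_matrix(make_fc(l2))
  expect_equal(rownames(sm), c("s_up", "s_dn"))
  expect_equal(unname(sm["s_up", "3"]), 1L)
  expect_equal(unname(sm["s_dn", "72"]), -1L)
  expect_equal(rowSums(abs(sm) != 0), c(s_up = 1, s_dn = 1))
})

test_that("score-matrix classification minimizes the element-wise L1 distance", {
  set.seed(71)
  tps <- as.character(tps9)
  for (trial in 1:20) {
    n <- 30
    tr <- matrix(0L, n, 9, dimnames = list(sprintf("g%02d", 1:n), tps))
    for (i in 1:n) tr[i, sample(9, 1)] <- sample(c(-1L, 1L), 1)
    s <- stats::setNames(sample(c(-1L, 0L, 1L), n, TRUE,
                                prob = c(0.2, 0.6, 0.2)),
                         rownames(tr))
    res <- score_matrix_classify(tr, s)
    # oracle: explicit cell loop, including the all-zero control column
    d <- stats::setNames(numeric(10), c("control", tps))
    for (f in rownames(tr)) {
      d["control"] <- d["control"] + abs(0 - s[f])
      for (t in tps) d[t] <- d[t] + abs(tr[f, t] - s[f])
    }
    expect_equal(res$scores, d[names(res$scores)])
    expect_equal(unname(res$scores[res$winner]), min(d))
  }
  # identical profile: distance zero at the true column
  tr1 <- matrix(0L, 2, 9, dimnames = list(c("a", "b"), tps))
  tr1["a", "48"] <- 1L; tr1["b", "48"] <- -1L
  res <- score_matrix_classify(tr1, c(a = 1L, b = -1L))
  expect_equal(res$winner, "48")
  expect_equal(unname(res$scores["48"]), 0)
  # opposite sign costs 2 per cell
  res2 <- score_matrix_classify(tr1, c(a = -1L, b = 0L))
  expect_equal(unname(res2$scores["48"]), 2 + 1)
})

test_that("confidence tiers follow the margin thresholds", {
  r <- function(margin) {
    classification_result(c(control = 0, "3" = margin + 1, "10" = 1))
  }
  expect_equal(assign_confidence(r(120))$confidence, "high")
  expect_equal(assign_confidence(r(75))$confidence, "medium")
  expect_equal(assign_confidence(r(100))$confidence, "medium")
  expect_equal(assign_confidence(r(10))$confidence, "low")
  tie <- classification_result(c("3" = 5, "10" = 5, control = 1))
  expect_true(tie$tie)
  expect_equal(tie$winner, "3")  # earlier time point wins
  expect_equal(assign_confidence(tie)$confidence, "low")
  expect_equal(tie$margin, 0)
})
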